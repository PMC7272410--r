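#' Photoelectron spectrum with angular anisotropies
#'
#' Holds an intensity spectrum `S` on either a pixel-radius or an energy
#' grid, together with the Legendre anisotropy curves `beta2(grid)` and
#' `beta4(grid)` of the angular distribution
#' \deqn{I(\varepsilon,\theta) = \sigma/4\pi\,[1 + \beta_2 P_2(\cos\theta)
#'   + \beta_4 P_4(\cos\theta)]}
#' and optional per-point fit diagnostics.
#'
#' @param grid strictly increasing abscissa (pixel radius or energy in eV)
#' @param S intensity (arbitrary units)
#' @param beta2,beta4 anisotropy curves (NA where S vanishes)
#' @param domain `"radius"` or `"energy"`
#' @param S_err,beta2_err optional 1-sigma uncertainties
#' @param diagnostics optional list (clip fraction, residual counters, ...)
#' @return object of class `pes`
#' @export
pes <- function(grid, S, beta2 = NULL, beta4 = NULL,
                domain = c("energy", "radius"), S_err = NULL,
                beta2_err = NULL, diagnostics = list()) {
  domain <- match.arg(domain)
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  S <- as.numeric(S)
  if (length(S) != length(grid)) stop("S and grid lengths differ")
  if (!all(is.finite(S))) stop("S must be finite")
  if (is.null(beta2)) beta2 <- rep(0, length(grid))
  if (is.null(beta4)) beta4 <- rep(0, length(grid))
  structure(list(domain = domain, grid = grid, S = S,
                 beta2 = as.numeric(beta2), beta4 = as.numeric(beta4),
                 S_err = S_err, beta2_err = beta2_err,
                 diagnostics = diagnostics),
            class = "pes")
}

#' @export
print.pes <- function(x, ...) {
  cat(sprintf("<pes> %d points (%s domain), total intensity %.4g\n",
              length(x$grid), x$domain, sum(x$S)))
  invisible(x)
}

# Convert an energy-domain pes to per-unit-radius shell weights on the
# integer radius grid 1..r_max (inverse of the calibration Jacobian).
pes_to_radial <- function(p, k_cal, r_max) {
  r <- seq_len(r_max)
  eps_r <- k_cal * r^2
  S_eps <- approx(p$grid, p$S, xout = eps_r, yleft = 0, yright = 0,
                  rule = 1)$y
  S_eps[is.na(S_eps)] <- 0
  b2 <- approx(p$grid, ifelse(is.na(p$beta2), 0, p$beta2), xout = eps_r,
               yleft = 0, yright = 0)$y
  b4 <- approx(p$grid, ifelse(is.na(p$beta4), 0, p$beta4), xout = eps_r,
               yleft = 0, yright = 0)$y
  b2[is.na(b2)] <- 0
  b4[is.na(b4)] <- 0
  list(r = r, S = S_eps * 2 * k_cal * r, beta2 = b2, beta4 = b4)
}

#' Forward-project a spectrum onto a velocity-map image
#'
#' Computes the expectation image of the cylindrically symmetric 3-D
#' distribution defined by the spectrum and its anisotropy curves: each
#' energy (or radius) bin becomes a spherical shell at radius
#' `r = sqrt(eps / k_cal)` whose line-of-sight integral is evaluated in
#' closed form.  Total counts are conserved up to pixel discretisation.
#'
#' @param p a [pes()] (energy or radius domain)
#' @param image_size edge length in pixels (square image)
#' @param k_cal calibration constant in eV/pixel^2 (energy-domain input)
#' @param centre image centre; defaults to the geometric centre
#' @param delay_fs metadata passed to the result
#' @return a [vmi_image()] with real-valued expectation counts
#' @export
forward_project <- function(p, image_size, k_cal = NULL, centre = NULL,
                            delay_fs = NA_real_) {
  stopifnot(inherits(p, "pes"))
  nx <- ny <- as.integer(image_size)
  if (is.null(centre)) centre <- c((nx - 1) / 2, (ny - 1) / 2)
  edge <- min(centre[1], centre[2], nx - 1 - centre[1], ny - 1 - centre[2])
  if (p$domain == "energy") {
    if (is.null(k_cal) || k_cal <= 0) {
      stop("energy-domain projection needs k_cal > 0")
    }
    rad <- pes_to_radial(p, k_cal, r_max = ceiling(sqrt(max(p$grid) / k_cal)))
  } else {
    b2 <- ifelse(is.na(p$beta2), 0, p$beta2)
    b4 <- ifelse(is.na(p$beta4), 0, p$beta4)
    if (!all(p$grid == seq_along(p$grid))) {
      stop("radius-domain projection expects the integer grid 1..n")
    }
    rad <- list(r = p$grid, S = p$S, beta2 = b2, beta4 = b4)
  }
  nz <- which(rad$S > 1e-12 * max(rad$S, 1e-300))
  r_support <- if (length(nz)) max(nz) else 0L
  if (r_support + 0.5 > edge + 0.5 + 1e-9) {
    stop(sprintf(
      "image too small: spectrum extends to radius %d px, need >= %d x %d",
      r_support, 2 * r_support + 2, 2 * r_support + 2))
  }
  keep <- seq_len(min(length(rad$S), floor(edge + 0.5)))
  counts <- cpp_project_shells(rad$S[keep], rad$beta2[keep], rad$beta4[keep],
                               nx, ny, centre[1], centre[2])
  vmi_image(counts, centre = centre, delay_fs = delay_fs)
}

#' Sample Poisson counting noise onto an expectation image
#'
#' @param img a [vmi_image()] with non-negative expectation counts
#' @param n_electrons if not `NULL`, rescale the expectation so its total is
#'   `n_electrons` before sampling; `0` yields an empty frame
#' @param seed RNG seed; a fixed seed gives a bit-identical frame.  The
#'   caller's RNG state is left untouched.
#' @return a [vmi_image()] with integer counts
#' @export
sample_counts <- function(img, n_electrons = NULL, seed = 1L) {
  stopifnot(inherits(img, "vmi_image"))
  ex <- img$counts
  if (any(ex < 0)) stop("expectation image has negative pixels")
  if (!is.null(n_electrons)) {
    if (n_electrons < 0) stop("n_electrons must be >= 0")
    tot <- sum(ex)
    ex <- if (tot > 0 && n_electrons > 0) ex * (n_electrons / tot) else ex * 0
  }
  counts <- with_preserved_rng(seed, {
    matrix(rpois(length(ex), lambda = as.vector(ex)), nrow(ex), ncol(ex))
  })
  vmi_image(counts, centre = img$centre, delay_fs = img$meta$delay_fs,
            n_electrons = if (is.null(n_electrons)) img$meta$n_electrons
            else n_electrons,
            seed = seed)
}

with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
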