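#' Resample a velocity-map image onto a polar grid
#'
#' Bilinear resampling onto `(r, theta)` with `theta` measured from the
#' (vertical) polarisation axis over `[0, pi/2]`, averaging the four
#' reflection-symmetric quadrant samples, as the angular distribution of
#' one-photon (and collinear two-photon) detachment has up/down and
#' left/right mirror symmetry.
#'
#' @param img a [vmi_image()]
#' @param n_r number of radial bins (1 px step); default: largest radius
#'   fully inside the image.  A larger request is clipped with a warning.
#' @param n_theta number of angular bins over `[0, pi/2]` (default 128)
#' @return matrix `n_r x n_theta` of interpolated counts per pixel area
#' @export
to_polar <- function(img, n_r = NULL, n_theta = 128) {
  stopifnot(inherits(img, "vmi_image"), n_theta >= 8)
  if (!all(is.finite(img$counts))) stop("image contains non-finite pixels")
  nx <- ncol(img$counts)
  ny <- nrow(img$counts)
  edge <- floor(min(img$centre[1], img$centre[2],
                    nx - 1 - img$centre[1], ny - 1 - img$centre[2]))
  if (is.null(n_r)) n_r <- edge
  if (n_r > edge) {
    warning(sprintf("r range clipped from %d to %d (image bounds)", n_r,
                    edge))
    n_r <- edge
  }
  if (n_r < 8) stop("need at least 8 radial bins inside the image")
  cpp_to_polar(img$counts, img$centre[1], img$centre[2], as.integer(n_r),
               as.integer(n_theta))
}

#' Weighted Legendre decomposition of an angular distribution
#'
#' Least-squares fit of
#' `I(theta) = c0 [1 + beta2 P2(cos theta) + beta4 P4(cos theta)]`
#' to sampled intensities; `sigma = 4 pi c0` is the angle-integrated
#' cross-section.  Limiting values: `I ~ cos^2(theta)` gives `beta2 = +2`
#' (emission parallel to the polarisation axis) and `I ~ sin^2(theta)` gives
#' `beta2 = -1` (perpendicular).
#'
#' @param theta angles in radians (>= 5 distinct samples in `[0, pi]`)
#' @param intensity sampled intensities
#' @param weights optional non-negative weights
#' @param orders Legendre orders to fit, subset of `c(0, 2, 4)`
#' @return list with `sigma`, `beta2`, `beta4`, coefficient vector `coef`,
#'   covariance `cov`, and `flagged` (TRUE when the input is all zero and
#'   the betas are undefined)
#' @export
legendre_fit <- function(theta, intensity, weights = NULL,
                         orders = c(0, 2, 4)) {
  stopifnot(length(theta) == length(intensity), all(orders %in% c(0, 2, 4)))
  if (length(unique(round(theta, 12))) < 5) {
    stop("need at least 5 distinct theta samples")
  }
  if (is.null(weights)) weights <- rep(1, length(theta))
  if (any(weights < 0)) stop("weights must be non-negative")
  x <- cos(theta)
  cols <- list(`0` = rep(1, length(x)), `2` = 0.5 * (3 * x^2 - 1),
               `4` = 0.125 * (35 * x^4 - 30 * x^2 + 3))
  X <- do.call(cbind, cols[as.character(sort(orders))])
  if (all(intensity == 0)) {
    return(list(sigma = 0, beta2 = NA_real_, beta4 = NA_real_,
                coef = setNames(rep(0, ncol(X)), sort(orders)),
                cov = matrix(NA_real_, ncol(X), ncol(X)), flagged = TRUE))
  }
  W <- weights
  G <- crossprod(X * sqrt(W))
  cf <- solve(G, crossprod(X, W * intensity))
  res <- intensity - X %*% cf
  dof <- max(1, length(theta) - ncol(X))
  s2 <- sum(W * res^2) / dof
  cov <- s2 * solve(G)
  cf <- drop(cf)
  names(cf) <- as.character(sort(orders))
  c0 <- if ("0" %in% names(cf)) cf[["0"]] else 0
  list(sigma = 4 * pi * c0,
       beta2 = if (c0 != 0 && "2" %in% names(cf)) cf[["2"]] / c0 else
         if (c0 == 0) NA_real_ else 0,
       beta4 = if (c0 != 0 && "4" %in% names(cf)) cf[["4"]] / c0 else
         if (c0 == 0) NA_real_ else 0,
       coef = cf, cov = cov, flagged = c0 == 0)
}

#' Polar onion peeling inversion of a velocity-map image
#'
#' Recovers the 3-D electron velocity distribution from its 2-D projection
#' under the assumption of cylindrical symmetry about the polarisation
#' axis.  Working from the outermost ring inward, the residual angular
#' slice at each radius is decomposed in `{P0, P2, P4}(cos theta)`, the
#' shell's spectrum and anisotropies are recorded, and the shell's own
#' forward projection is subtracted from all interior rings.  Negative
#' shell intensities are clipped at zero and the clip fraction logged.
#'
#' @param img a [vmi_image()]
#' @param n_r,n_theta polar grid, see [to_polar()]
#' @param freeze_beta4 fit only `{P0, P2}` and force `beta4 = 0`
#' @return a radius-domain [pes()] with per-ring uncertainties and
#'   diagnostics (`clip_fraction`, `negative_residuals`)
#' @export
pop_invert <- function(img, n_r = NULL, n_theta = 128,
                       freeze_beta4 = FALSE) {
  polar <- to_polar(img, n_r = n_r, n_theta = n_theta)
  peel <- cpp_peel(polar, freeze_beta4)
  pes(grid = seq_len(nrow(polar)), S = peel$S, beta2 = peel$beta2,
      beta4 = peel$beta4, domain = "radius", S_err = peel$S_err,
      beta2_err = peel$beta2_err,
      diagnostics = list(clip_fraction = peel$clip_fraction,
                         negative_residuals = peel$negative_residuals,
                         n_theta = n_theta))
}

#' Radius-to-energy calibration of a photoelectron spectrum
#'
#' Applies `eps = k_cal * r^2` with the Jacobian transform
#' `S(eps) = S(r) / (2 k_cal r)`; anisotropy curves are re-indexed
#' unchanged.  An `r = 0` bin would have no energy-domain image and is
#' dropped.
#'
#' @param p radius-domain [pes()]
#' @param k_cal calibration constant in eV/pixel^2 (> 0)
#' @return energy-domain [pes()]
#' @export
calibrate_energy <- function(p, k_cal) {
  stopifnot(inherits(p, "pes"), p$domain == "radius")
  if (!is.numeric(k_cal) || k_cal <= 0) stop("k_cal must be > 0")
  keep <- p$grid > 0
  r <- p$grid[keep]
  jac <- 1 / (2 * k_cal * r)
  pes(grid = k_cal * r^2, S = p$S[keep] * jac, beta2 = p$beta2[keep],
      beta4 = p$beta4[keep], domain = "energy",
      S_err = if (!is.null(p$S_err)) p$S_err[keep] * jac,
      beta2_err = if (!is.null(p$beta2_err)) p$beta2_err[keep],
      diagnostics = c(p$diagnostics, list(k_cal = k_cal)))
}

#' Energy calibration from a reference peak
#'
#' @param eps_ref known electron kinetic energy of a calibration peak (eV),
#'   e.g. from the photodetachment spectrum of iodide
#' @param r_ref observed peak radius in pixels
#' @return `k_cal` in eV/pixel^2
#' @export
fit_kcal <- function(eps_ref, r_ref) {
  stopifnot(eps_ref > 0, r_ref > 0)
  eps_ref / r_ref^2
}
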