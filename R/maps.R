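#' Assemble time-resolved spectral and anisotropy maps
#'
#' Stacks per-delay energy-domain spectra into a `(delay x energy)` signal
#' map (`trpes_map`) and the matching `beta2` map (`beta_map`).  All spectra
#' must share one energy grid; delays must be strictly increasing.
#'
#' @param pes_list list of energy-domain [pes()] objects
#' @param delays_fs numeric vector of pump-probe delays (fs)
#' @return list with elements `signal` (a `trpes_map`) and `beta` (a
#'   `beta_map`, mask all-true)
#' @export
build_maps <- function(pes_list, delays_fs) {
  stopifnot(length(pes_list) == length(delays_fs), length(pes_list) >= 1)
  if (any(diff(delays_fs) <= 0)) {
    stop("delays must be strictly increasing (sorted)")
  }
  ref <- pes_list[[1]]$grid
  for (i in seq_along(pes_list)) {
    p <- pes_list[[i]]
    if (!inherits(p, "pes") || p$domain != "energy") {
      stop("all elements must be energy-domain pes objects")
    }
    if (length(p$grid) != length(ref) || any(abs(p$grid - ref) > 1e-9)) {
      stop(sprintf("energy grid mismatch at delay %g fs", delays_fs[i]))
    }
  }
  signal <- do.call(rbind, lapply(pes_list, `[[`, "S"))
  beta2 <- do.call(rbind, lapply(pes_list, `[[`, "beta2"))
  s_err <- if (all(vapply(pes_list, function(p) !is.null(p$S_err), TRUE))) {
    do.call(rbind, lapply(pes_list, `[[`, "S_err"))
  }
  b_err <- if (all(vapply(pes_list,
                          function(p) !is.null(p$beta2_err), TRUE))) {
    do.call(rbind, lapply(pes_list, `[[`, "beta2_err"))
  }
  smap <- structure(list(delays_fs = as.numeric(delays_fs), energy = ref,
                         signal = signal, signal_err = s_err,
                         background_subtracted = FALSE, normalised = FALSE),
                    class = "trpes_map")
  bmap <- structure(list(delays_fs = as.numeric(delays_fs), energy = ref,
                         beta2 = beta2, beta2_err = b_err,
                         mask = matrix(TRUE, nrow(beta2), ncol(beta2))),
                    class = "beta_map")
  list(signal = smap, beta = bmap)
}

#' @export
print.trpes_map <- function(x, ...) {
  cat(sprintf(
    "<trpes_map> %d delays x %d energies [%sbackground-subtracted, %s]\n",
    length(x$delays_fs), length(x$energy),
    if (x$background_subtracted) "" else "not ",
    if (x$normalised) "normalised" else "raw"))
  invisible(x)
}

#' Subtract the pre-time-zero background from a map
#'
#' The mean of all `t < 0` rows is removed from every row, leaving only the
#' time-evolving signals; negative values are retained.
#'
#' @param map a `trpes_map` with at least one `t < 0` frame
#' @return background-subtracted `trpes_map`
#' @export
subtract_background <- function(map) {
  stopifnot(inherits(map, "trpes_map"))
  neg <- map$delays_fs < 0
  if (!any(neg)) stop("no t < 0 frame available for background subtraction")
  bg <- colMeans(map$signal[neg, , drop = FALSE])
  map$signal <- sweep(map$signal, 2, bg)
  map$background_subtracted <- TRUE
  map
}

#' Normalise a map to its global maximum
#'
#' @param map a `trpes_map` with a positive maximum
#' @return normalised map (idempotent)
#' @export
normalise_map <- function(map) {
  stopifnot(inherits(map, "trpes_map"))
  m <- max(map$signal)
  if (!is.finite(m) || m <= 0) stop("map maximum must be positive")
  map$signal <- map$signal / m
  if (!is.null(map$signal_err)) map$signal_err <- map$signal_err / m
  map$normalised <- TRUE
  map
}

# integral of the piecewise-linear interpolant of y(x) over [lo, hi]
# (exactly additive over adjacent windows); also returns the effective
# per-point weights for error propagation
plin_integral <- function(x, y, lo, hi) {
  n <- length(x)
  w <- numeric(n)
  for (i in seq_len(n - 1)) {
    a <- max(lo, x[i])
    b <- min(hi, x[i + 1])
    if (b <= a) next
    h <- x[i + 1] - x[i]
    # integral of the linear segment over [a, b] in terms of y_i, y_{i+1}
    t1 <- (a - x[i]) / h
    t2 <- (b - x[i]) / h
    w[i] <- w[i] + (b - a) - h * (t2^2 - t1^2) / 2
    w[i + 1] <- w[i + 1] + h * (t2^2 - t1^2) / 2
  }
  list(value = sum(w * y), weights = w)
}

#' Integrate a map over a spectral window
#'
#' Trapezoidal (piecewise-linear) integral of each delay row over
#' `[eps_lo, eps_hi]`, with uncertainty propagated from per-point errors if
#' present.  Integrals are exactly additive over adjacent windows.
#'
#' @param map a `trpes_map`
#' @param eps_lo,eps_hi window bounds (eV), inside the energy grid
#' @param label window label (e.g. `"eps1"`)
#' @return object of class `window_trace` with fields `delays_fs`, `s`,
#'   `err`, `bounds`, `label`
#' @export
integrate_window <- function(map, eps_lo, eps_hi, label = "") {
  stopifnot(inherits(map, "trpes_map"))
  if (!(eps_lo < eps_hi)) stop("need eps_lo < eps_hi")
  if (eps_hi < min(map$energy) || eps_lo > max(map$energy)) {
    stop("window does not overlap the energy grid")
  }
  nT <- length(map$delays_fs)
  s <- numeric(nT)
  err <- rep(NA_real_, nT)
  for (i in seq_len(nT)) {
    pl <- plin_integral(map$energy, map$signal[i, ], eps_lo, eps_hi)
    s[i] <- pl$value
    if (!is.null(map$signal_err)) {
      err[i] <- sqrt(sum((pl$weights * map$signal_err[i, ])^2))
    }
  }
  structure(list(label = label, bounds = c(eps_lo, eps_hi),
                 delays_fs = map$delays_fs, s = s, err = err),
            class = "window_trace")
}

#' @export
print.window_trace <- function(x, ...) {
  cat(sprintf("<window_trace> '%s' [%.2f, %.2f] eV, %d delays\n", x$label,
              x$bounds[1], x$bounds[2], length(x$delays_fs)))
  invisible(x)
}

#' Total (full-grid) photoelectron signal per delay
#'
#' @param map a background-subtracted `trpes_map`
#' @return a `window_trace` covering the whole energy grid
#' @export
total_signal <- function(map) {
  stopifnot(inherits(map, "trpes_map"))
  if (!map$background_subtracted) {
    stop("total_signal expects a background-subtracted map")
  }
  integrate_window(map, min(map$energy), max(map$energy), label = "total")
}

#' Mask low-signal regions and smooth an anisotropy map
#'
#' Entries where the normalised signal falls below `threshold` are masked
#' (the anisotropy is statistically undefined there); the surviving values
#' are smoothed with a centred moving average along the energy axis that
#' shrinks at run edges and never crosses a mask boundary.
#'
#' @param bmap a `beta_map`
#' @param smap the matching normalised `trpes_map`
#' @param threshold mask threshold on the normalised signal (default 0.1)
#' @param window moving-average width in energy points (odd, default 5)
#' @return masked and smoothed `beta_map`
#' @export
mask_and_smooth <- function(bmap, smap, threshold = 0.1, window = 5) {
  stopifnot(inherits(bmap, "beta_map"), inherits(smap, "trpes_map"))
  if (!smap$normalised) stop("signal map must be normalised first")
  if (window %% 2 == 0) stop("window must be odd (centred average)")
  if (!identical(dim(bmap$beta2), dim(smap$signal))) {
    stop("beta and signal maps have different shapes")
  }
  mask <- smap$signal >= threshold
  half <- (window - 1) / 2
  sm <- bmap$beta2
  for (i in seq_len(nrow(sm))) {
    row <- bmap$beta2[i, ]
    ok <- mask[i, ] & is.finite(row)
    out <- rep(NA_real_, length(row))
    j <- 1
    n <- length(row)
    while (j <= n) {
      if (!ok[j]) {
        j <- j + 1
        next
      }
      k <- j
      while (k < n && ok[k + 1]) k <- k + 1
      for (m in j:k) {
        lo <- max(j, m - half)
        hi <- min(k, m + half)
        out[m] <- mean(row[lo:hi])
      }
      j <- k + 1
    }
    sm[i, ] <- out
  }
  bmap$beta2 <- sm
  bmap$mask <- mask
  bmap
}

#' Signal-weighted feature anisotropy
#'
#' Averages `beta2(eps)` over a spectral feature, weighting by the signal,
#' to give one anisotropy value per feature as used when comparing with
#' Dyson-orbital model predictions.  The uncertainty combines the
#' propagated fit covariances and the weighted dispersion of `beta2` across
#' the window in quadrature.
#'
#' @param p an energy-domain [pes()]
#' @param eps_lo,eps_hi window bounds (eV)
#' @return list with `beta2` (weighted mean) and `se` (uncertainty)
#' @export
feature_beta <- function(p, eps_lo, eps_hi) {
  stopifnot(inherits(p, "pes"), p$domain == "energy", eps_lo < eps_hi)
  sel <- p$grid >= eps_lo & p$grid <= eps_hi & is.finite(p$beta2)
  w <- pmax(p$S[sel], 0)
  if (sum(w) <= 0) stop("window contains no signal (zero total weight)")
  b <- p$beta2[sel]
  m <- sum(w * b) / sum(w)
  n_eff <- sum(w)^2 / sum(w^2)
  disp <- sqrt(sum(w * (b - m)^2) / sum(w)) / sqrt(max(n_eff, 1))
  fit <- if (!is.null(p$beta2_err)) {
    e <- p$beta2_err[sel]
    e[!is.finite(e)] <- 0
    sqrt(sum((w * e)^2)) / sum(w)
  } else 0
  list(beta2 = m, se = sqrt(disp^2 + fit^2))
}
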