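#' Wavepacket trajectory along the isomerisation coordinate
#'
#' Dimensionless reaction-coordinate position `q(t)`: `q = 0` is the S1
#' planar minimum (PM), `q = 1` the single-bond rotated minimum (SB).  The
#' wavepacket leaves PM at `t = 0`, reaches SB at `T/2`, and the coherent
#' oscillation damps with time constant `tau_d`, after which the packet
#' settles at the SB minimum:
#' \deqn{q(t) = 1 - \cos^2(\pi t / T)\, e^{-t/\tau_d}, \quad t \ge 0}
#' and `q = 0` for `t < 0`.  In the undamped limit this is
#' `sin^2(pi t / T)`: a full excursion to SB at `T/2` and back at `T`.
#'
#' @param t_fs time grid in fs (finite)
#' @param cfg configuration list (only the `generator` section is used)
#' @return `q(t)` in `[0, 1]`
#' @export
trajectory <- function(t_fs, cfg = pck_fixture()) {
  g <- cfg$generator
  stopifnot(all(is.finite(t_fs)), g$period_fs > 0, g$tau_damp_fs > 0)
  q <- 1 - cos(pi * t_fs / g$period_fs)^2 * exp(-t_fs / g$tau_damp_fs)
  q[t_fs < 0] <- 0
  pmin(pmax(q, 0), 1)
}

# erfc via pnorm: erfc(x) = 2 pnorm(-x sqrt(2))
erfc <- function(x) 2 * pnorm(-x * sqrt(2))

# S1 population decay convolved with the Gaussian IRF: the analytic
# step-exponential (x) Gaussian expression; sigma in fs.
irf_exp_decay <- function(t_fs, tau_fs, sigma_fs) {
  if (sigma_fs <= 0) return(ifelse(t_fs >= 0, exp(-t_fs / tau_fs), 0))
  0.5 * exp(sigma_fs^2 / (2 * tau_fs^2) - t_fs / tau_fs) *
    erfc((sigma_fs / tau_fs - t_fs / sigma_fs) / sqrt(2))
}

# step (x) Gaussian rise
irf_step <- function(t_fs, sigma_fs) {
  if (sigma_fs <= 0) return(as.numeric(t_fs >= 0))
  pnorm(t_fs / sigma_fs)
}

# evaluate an endpoint beta2 specification (constant or table) on a grid
eval_beta_curve <- function(spec, eps) {
  if (is.numeric(spec) && length(spec) == 1) return(rep(spec, length(eps)))
  if (is.list(spec) && !is.null(spec$eps) && !is.null(spec$beta)) {
    return(approx(as.numeric(unlist(spec$eps)), as.numeric(unlist(spec$beta)),
                  xout = eps, rule = 2)$y)
  }
  stop("beta2 endpoint must be a constant or a list(eps=..., beta=...) table")
}

# energy grid implied by the generator image geometry
generator_energy_grid <- function(g) {
  r_max <- floor((g$image_size - 1) / 2)
  r <- seq_len(r_max)
  list(r = r, eps = g$k_cal * r^2, r_max = r_max)
}

#' Model photoelectron spectrum at a reaction coordinate position
#'
#' The spectrum is the sum of (i) a moving Gaussian peak centred at
#' `(1-q)*eps_pm_centre + q*eps_sb_centre` whose amplitude follows the
#' IRF-convolved S1 population decay, carrying the linearly interpolated
#' anisotropy `beta2 = (1-q) beta2_PM + q beta2_SB`; (ii) a static
#' low-energy channel that rises with the IRF and carries `beta2 = 0`; and
#' (iii) the delay-independent `t < 0` background (`beta2 = 0`).
#' `beta4 = 0` throughout.
#'
#' @param q reaction coordinate in `[0, 1]`
#' @param t_fs pump-probe delay (fs), used for the population amplitude
#' @param cfg configuration list
#' @return a [pes()] on the generator energy grid
#' @export
model_pes <- function(q, t_fs, cfg = pck_fixture()) {
  if (!is.finite(q) || q < 0 || q > 1) {
    stop("q must lie in [0, 1]")
  }
  g <- cfg$generator
  gr <- generator_energy_grid(g)
  eps <- gr$eps
  sigma_irf <- g$irf_fwhm_fs / (2 * sqrt(2 * log(2)))
  pop <- irf_exp_decay(t_fs, g$lifetime_ps * 1000, sigma_irf)
  rise <- irf_step(t_fs, sigma_irf)
  centre <- (1 - q) * g$eps_pm_centre + q * g$eps_sb_centre
  peak <- pop * dnorm(eps, centre, g$peak_width_ev)
  b2_peak <- (1 - q) * eval_beta_curve(g$beta2_pm, eps) +
    q * eval_beta_curve(g$beta2_sb, eps)
  eps3 <- rise * g$eps3_rel_amp * dnorm(eps, g$eps3_centre, g$eps3_width_ev)
  bg <- g$bg_amp * exp(-eps / g$bg_scale_ev) / g$bg_scale_ev
  S <- peak + eps3 + bg
  beta2 <- ifelse(S > 0, b2_peak * peak / S, 0)
  pes(eps, S, beta2 = beta2, beta4 = rep(0, length(eps)), domain = "energy")
}

# Instantaneous excited-state spectral components at time-since-pump x >= 0
# (no IRF, no background).  Returns S (signal) and B (signal * beta2).
inst_excited <- function(x_fs, eps, g) {
  q <- 1 - cos(pi * x_fs / g$period_fs)^2 * exp(-x_fs / g$tau_damp_fs)
  pop <- exp(-x_fs / (g$lifetime_ps * 1000))
  centre <- (1 - q) * g$eps_pm_centre + q * g$eps_sb_centre
  peak <- pop * dnorm(eps, centre, g$peak_width_ev)
  b2 <- (1 - q) * eval_beta_curve(g$beta2_pm, eps) +
    q * eval_beta_curve(g$beta2_sb, eps)
  eps3 <- g$eps3_rel_amp * dnorm(eps, g$eps3_centre, g$eps3_width_ev)
  list(S = peak + eps3, B = peak * b2, q = q, pop = pop, peak = peak)
}

# IRF-convolved expectation spectrum at delay t: background + integral of the
# excited part against the Gaussian IRF over x >= 0 (Gauss-Legendre nodes).
convolved_spectrum <- function(t_fs, eps, g, n_nodes = 40) {
  sigma <- g$irf_fwhm_fs / (2 * sqrt(2 * log(2)))
  bg <- g$bg_amp * exp(-eps / g$bg_scale_ev) / g$bg_scale_ev
  S <- bg
  B <- rep(0, length(eps))
  qbar <- 0
  if (sigma <= 0) {
    if (t_fs >= 0) {
      comp <- inst_excited(t_fs, eps, g)
      S <- S + comp$S
      B <- comp$B
      qbar <- comp$q
    }
  } else {
    lo <- max(0, t_fs - 5 * sigma)
    hi <- t_fs + 5 * sigma
    if (hi > 0) {
      gq <- statmod::gauss.quad(n_nodes, kind = "legendre")
      x <- (hi + lo) / 2 + (hi - lo) / 2 * gq$nodes
      w <- (hi - lo) / 2 * gq$weights * dnorm(t_fs - x, 0, sigma)
      wsum <- 0
      for (i in seq_along(x)) {
        comp <- inst_excited(x[i], eps, g)
        S <- S + w[i] * comp$S
        B <- B + w[i] * comp$B
        qbar <- qbar + w[i] * comp$q * comp$pop
        wsum <- wsum + w[i] * comp$pop
      }
      qbar <- if (wsum > 0) qbar / wsum else 0
    }
  }
  list(S = S, B = B, beta2 = ifelse(S > 0, B / S, 0), qbar = qbar)
}

#' Generate a synthetic time-resolved photoelectron image stack
#'
#' Produces one velocity-map image per configured delay from the wavepacket
#' model, with all time-dependent amplitudes convolved with the Gaussian
#' instrument response, and stores the generating ground truth (trajectory,
#' peak centre, window traces, beta2 map) for test assertions.  With
#' `n_electrons = 0` the frames are noiseless expectation images; otherwise
#' Poisson counts are drawn with a per-frame seed derived from the
#' configured seed, so a fixed configuration is bit-reproducible.
#'
#' @param cfg configuration list; `cfg$generator$delays_fs` must contain at
#'   least two delays before time zero
#' @return object of class `synthetic_dataset`: fields `frames` (list of
#'   [vmi_image()]), `cfg`, `energy` (grid), `truth` (data frame),
#'   `beta2_map` and `spectra` (expectation, delays x energy)
#' @export
generate_dataset <- function(cfg = pck_fixture()) {
  g <- cfg$generator
  delays <- g$delays_fs
  if (is.null(delays)) delays <- pck_delays()
  delays <- as.numeric(delays)
  if (any(diff(delays) <= 0)) stop("delays must be strictly increasing")
  if (sum(delays < 0) < 2) {
    stop("delay list must include at least 2 frames with t < 0")
  }
  gr <- generator_energy_grid(g)
  eps <- gr$eps
  nT <- length(delays)

  spectra <- matrix(0, nT, length(eps))
  bmap <- matrix(0, nT, length(eps))
  qbar <- numeric(nT)
  for (i in seq_len(nT)) {
    cs <- convolved_spectrum(delays[i], eps, g)
    spectra[i, ] <- cs$S
    bmap[i, ] <- cs$beta2
    qbar[i] <- cs$qbar
  }
  # scale so the brightest frame carries n_electrons expected counts
  deps <- 2 * g$k_cal * gr$r  # d(eps)/dr on the radial grid
  totals <- as.numeric(spectra %*% deps)
  scale <- if (g$n_electrons > 0) g$n_electrons / max(totals) else 1
  spectra <- spectra * scale

  centre_px <- c((g$image_size - 1) / 2, (g$image_size - 1) / 2)
  frames <- vector("list", nT)
  for (i in seq_len(nT)) {
    p <- pes(eps, spectra[i, ], beta2 = bmap[i, ], domain = "energy")
    img <- forward_project(p, g$image_size, k_cal = g$k_cal,
                           centre = centre_px, delay_fs = delays[i])
    if (g$n_electrons > 0) {
      img <- sample_counts(img, n_electrons = NULL,
                           seed = (g$seed + i) %% .Machine$integer.max)
    }
    frames[[i]] <- img
  }

  trapz <- function(y, x) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  win_int <- function(lo, hi) {
    vapply(seq_len(nT), function(i) {
      sel <- eps >= lo & eps <= hi
      trapz(spectra[i, sel], eps[sel])
    }, 0)
  }
  w <- cfg$analysis
  truth <- data.frame(
    delay_fs = delays,
    q = qbar,
    centre_ev = (1 - qbar) * g$eps_pm_centre + qbar * g$eps_sb_centre,
    pop = irf_exp_decay(delays, g$lifetime_ps * 1000,
                        g$irf_fwhm_fs / (2 * sqrt(2 * log(2)))),
    s_eps1 = win_int(w$window_eps1[1], w$window_eps1[2]),
    s_eps2 = win_int(w$window_eps2[1], w$window_eps2[2]),
    s_eps3 = win_int(w$window_eps3[1], w$window_eps3[2]),
    total = as.numeric(spectra %*% deps))
  structure(list(frames = frames, cfg = cfg, energy = eps, truth = truth,
                 beta2_map = bmap, spectra = spectra),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d frames, %d x %d px, seed %d\n",
              length(x$frames), x$cfg$generator$image_size,
              x$cfg$generator$image_size, x$cfg$generator$seed))
  invisible(x)
}
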