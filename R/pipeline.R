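#' Invert every frame of a dataset
#'
#' Runs [pop_invert()] and [calibrate_energy()] on each frame, giving one
#' energy-domain spectrum per delay on a common grid.
#'
#' @param frames list of [vmi_image()] (or a `synthetic_dataset`)
#' @param k_cal calibration constant (eV/pixel^2)
#' @param n_theta,freeze_beta4 see [pop_invert()]
#' @return list of energy-domain [pes()]
#' @export
invert_frames <- function(frames, k_cal, n_theta = 128,
                          freeze_beta4 = FALSE) {
  if (inherits(frames, "synthetic_dataset")) {
    k_cal <- frames$cfg$generator$k_cal
    frames <- frames$frames
  }
  lapply(frames, function(fr) {
    calibrate_energy(pop_invert(fr, n_theta = n_theta,
                                freeze_beta4 = freeze_beta4), k_cal)
  })
}

#' Full analysis of a time-resolved image stack
#'
#' The complete experimental analysis chain: per-frame polar onion peeling
#' and energy calibration, map assembly, pre-time-zero background
#' subtraction, normalisation, window integration, masked/smoothed
#' anisotropy map, transient fits (damped oscillation in the two moving
#' windows, long-delay exponential decay) and feature-averaged
#' anisotropies.
#'
#' @param ds a `synthetic_dataset` (or list of frames plus `cfg`)
#' @param cfg configuration; defaults to the dataset's own
#' @param fit_decay_tmin_fs long-delay fit start (default 2 ps)
#' @param osc_tmax_fs oscillation fits use delays up to this cutoff, so the
#'   slow population decay does not distort the damped-cosine model
#'   (default 2 ps)
#' @return list with `pes_list`, `maps` (raw and processed), `traces`,
#'   `fits`, `feature_betas`
#' @export
analyse_dataset <- function(ds, cfg = NULL, fit_decay_tmin_fs = 2000,
                            osc_tmax_fs = 2000) {
  if (inherits(ds, "synthetic_dataset")) {
    if (is.null(cfg)) cfg <- ds$cfg
    frames <- ds$frames
  } else {
    frames <- ds
    if (is.null(cfg)) stop("cfg required when passing a bare frame list")
  }
  delays <- vapply(frames, function(f) f$meta$delay_fs, 0)
  pes_list <- invert_frames(frames, cfg$generator$k_cal,
                            n_theta = cfg$inversion$n_theta,
                            freeze_beta4 = cfg$inversion$freeze_beta4)
  maps <- build_maps(pes_list, delays)
  sub <- subtract_background(maps$signal)
  norm <- normalise_map(sub)
  an <- cfg$analysis
  traces <- list(
    eps1 = integrate_window(sub, an$window_eps1[1], an$window_eps1[2],
                            label = "eps1"),
    eps2 = integrate_window(sub, an$window_eps2[1], an$window_eps2[2],
                            label = "eps2"),
    eps3 = integrate_window(sub, an$window_eps3[1], an$window_eps3[2],
                            label = "eps3"),
    total = total_signal(sub))
  irf <- cfg$generator$irf_fwhm_fs
  Tg <- cfg$generator$period_fs
  early <- function(tr) {
    sel <- tr$delays_fs <= osc_tmax_fs
    tr$delays_fs <- tr$delays_fs[sel]
    tr$s <- tr$s[sel]
    tr$err <- tr$err[sel]
    tr
  }
  fits <- list(
    osc_eps1 = fit_damped_oscillation(early(traces$eps1), irf,
                                      period_guess_fs = Tg),
    osc_eps2 = fit_damped_oscillation(early(traces$eps2), irf,
                                      period_guess_fs = Tg))
  if (sum(traces$eps2$delays_fs >= fit_decay_tmin_fs) >= 4) {
    fits$decay_eps2 <- fit_decay(traces$eps2, fit_decay_tmin_fs)
  }
  beta_masked <- mask_and_smooth(maps$beta, norm,
                                 threshold = an$mask_threshold,
                                 window = an$smooth_window)
  # feature-averaged beta2 at the delays closest to t = 0 and t = 1 ps
  i0 <- which.min(abs(delays - 0))
  i1 <- which.min(abs(delays - 1000))
  feature_betas <- list(
    eps1_t0 = feature_beta(pes_list[[i0]], an$window_eps1[1],
                           an$window_eps1[2]),
    eps2_t1ps = feature_beta(pes_list[[i1]], an$window_eps2[1],
                             an$window_eps2[2]))
  list(pes_list = pes_list, delays_fs = delays,
       maps = list(raw = maps$signal, subtracted = sub, normalised = norm,
                   beta = maps$beta, beta_masked = beta_masked),
       traces = traces, fits = fits, feature_betas = feature_betas)
}

#' Phase difference between two oscillation fits
#'
#' Circular distance between the fitted phases, in `[0, pi]`; the
#' out-of-phase signature of a wavepacket moving between two spectral
#' windows appears as a value near `pi`.
#'
#' @param fit1,fit2 `fit_result` objects from [fit_damped_oscillation()]
#' @return absolute phase difference (radians)
#' @export
phase_difference <- function(fit1, fit2) {
  stopifnot(!is.null(fit1$pars), !is.null(fit2$pars))
  d <- abs(fit2$pars[["phase_rad"]] - fit1$pars[["phase_rad"]]) %% (2 * pi)
  min(d, 2 * pi - d)
}
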