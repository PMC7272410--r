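mk_pes <- function(eps, S, b2 = rep(0, length(eps)), b2e = NULL) {
  pes(eps, S, beta2 = b2, domain = "energy", beta2_err = b2e)
}
mk_trace <- function(t, s) {
  structure(list(label = "w", bounds = c(0, 1), delays_fs = t, s = s,
                 err = rep(NA_real_, length(s))), class = "window_trace")
}

test_that("map assembly stacks spectra and validates the grids", {
  eps <- seq(0.1, 2, by = 0.1)
  p <- mk_pes(eps, dnorm(eps, 1, 0.3))
  maps <- build_maps(list(p, p, p), c(-100, 0, 100))
  expect_equal(dim(maps$signal$signal), c(3, length(eps)))
  expect_equal(maps$signal$signal[1, ], maps$signal$signal[3, ])

  one <- build_maps(list(p), 0)
  expect_equal(dim(one$signal$signal), c(1, length(eps)))

  expect_error(build_maps(list(p, p), c(100, -100)), "strictly increasing")
  p2 <- mk_pes(eps + 0.01, dnorm(eps, 1, 0.3))
  expect_error(build_maps(list(p, p2), c(0, 50)), "mismatch at delay 50")
})

test_that("background subtraction removes the pre-time-zero spectrum", {
  eps <- seq(0.1, 2, by = 0.1)
  bgshape <- exp(-eps)
  rows <- list(mk_pes(eps, bgshape), mk_pes(eps, bgshape),
               mk_pes(eps, bgshape + dnorm(eps, 1.4, 0.2)))
  maps <- build_maps(rows, c(-200, -100, 150))
  sub <- subtract_background(maps$signal)
  expect_true(sub$background_subtracted)
  expect_equal(sub$signal[1, ], 0 * eps)
  expect_equal(sub$signal[3, ], dnorm(eps, 1.4, 0.2))

  # map equal to its own background -> all-zero
  m2 <- subtract_background(build_maps(rows[c(1, 2)],
                                       c(-200, -100))$signal)
  expect_equal(max(abs(m2$signal)), 0)

  expect_error(subtract_background(build_maps(rows[3], 10)$signal),
               "no t < 0 frame")

  # fixture: the delay-independent probe-only background vanishes at all
  # delays after subtraction (noiseless dataset)
  cfg <- pck_fixture()
  cfg$generator$image_size <- 128
  cfg$generator$k_cal <- 5.6e-4
  cfg$generator$n_electrons <- 0
  cfg$generator$delays_fs <- c(-400, -300, 100, 600)
  ds <- generate_dataset(cfg)
  pl <- lapply(seq_along(ds$frames), function(i) {
    mk_pes(ds$energy, ds$spectra[i, ])
  })
  sub <- subtract_background(build_maps(pl, cfg$generator$delays_fs)$signal)
  # the probe-only frames contain nothing but the static background, so
  # they vanish identically after subtraction
  neg <- sub$delays_fs < 0
  expect_lt(max(abs(sub$signal[neg, ])), 1e-12 * max(sub$signal))
})

test_that("normalisation scales to unit maximum and is idempotent", {
  eps <- seq(0.1, 2, by = 0.1)
  maps <- build_maps(list(mk_pes(eps, 5 * dnorm(eps, 1, 0.3))), 0)
  nm <- normalise_map(maps$signal)
  expect_equal(max(nm$signal), 1)
  expect_equal(normalise_map(nm)$signal, nm$signal)
  neg <- maps$signal
  neg$signal <- -abs(neg$signal)
  expect_error(normalise_map(neg), "positive")
})

test_that("window integration is trapezoidal, additive, and propagates", {
  eps <- seq(0, 2, by = 0.05)
  unit <- build_maps(list(mk_pes(eps, rep(1, length(eps)))), 0)$signal
  tr <- integrate_window(unit, 0.5, 1.0)
  expect_equal(tr$s, 0.5)

  # full window equals the row trapezoid
  full <- integrate_window(unit, min(eps), max(eps))
  expect_equal(full$s, 2)

  # additive over adjacent windows (exact trapezoid identity)
  set.seed(5)
  rnd <- build_maps(list(mk_pes(eps, runif(length(eps)))), 0)$signal
  a <- integrate_window(rnd, 0.13, 0.77)$s
  b <- integrate_window(rnd, 0.77, 1.61)$s
  ab <- integrate_window(rnd, 0.13, 1.61)$s
  expect_equal(a + b, ab, tolerance = 1e-12)

  expect_error(integrate_window(unit, 3, 4), "overlap")
  expect_error(integrate_window(unit, 1.0, 0.5), "eps_lo < eps_hi")

  # total_signal equals a window covering the whole grid
  subbed <- unit
  subbed$background_subtracted <- TRUE
  expect_equal(total_signal(subbed)$s, full$s)
})

test_that("masking and smoothing respect the signal threshold", {
  eps <- seq(0.1, 2, length.out = 30)
  low <- build_maps(list(mk_pes(eps, rep(0.05, 30), rep(-0.3, 30))), 0)
  lown <- low$signal
  lown$normalised <- TRUE
  bm <- mask_and_smooth(low$beta, lown, threshold = 0.1, window = 5)
  expect_true(all(!bm$mask))
  expect_true(all(is.na(bm$beta2)))

  # constant beta2 is unchanged by smoothing
  co <- build_maps(list(mk_pes(eps, rep(1, 30), rep(-0.3, 30))), 0)
  con <- normalise_map(co$signal)
  bm2 <- mask_and_smooth(co$beta, con, 0.1, 5)
  expect_equal(bm2$beta2[1, ], rep(-0.3, 30))

  # alternating +-1 smooths to the 5-point mean at the centre
  alt <- build_maps(list(mk_pes(eps, rep(1, 30), rep(c(1, -1), 15))), 0)
  bm3 <- mask_and_smooth(alt$beta, normalise_map(alt$signal), 0.1, 5)
  expect_equal(bm3$beta2[1, 10], mean(rep(c(1, -1), 15)[8:12]))

  # raising the threshold never unmasks a point
  set.seed(9)
  sig <- build_maps(list(mk_pes(eps, runif(30), runif(30, -1, 2))), 0)
  sn <- normalise_map(sig$signal)
  m1 <- mask_and_smooth(sig$beta, sn, 0.2, 5)$mask
  m2 <- mask_and_smooth(sig$beta, sn, 0.5, 5)$mask
  expect_true(all(!m2 | m1))  # mask at 0.5 is a subset of mask at 0.2

  expect_error(mask_and_smooth(sig$beta, sn, 0.1, 4), "odd")
  expect_error(mask_and_smooth(sig$beta, sig$signal, 0.1, 5), "normalised")
})

test_that("feature anisotropy is the signal-weighted window mean", {
  eps <- seq(0.5, 1.5, by = 0.02)
  p <- mk_pes(eps, dnorm(eps, 1, 0.15), rep(-0.36, length(eps)),
              b2e = rep(0.02, length(eps)))
  fb <- feature_beta(p, 0.7, 1.3)
  expect_equal(fb$beta2, -0.36, tolerance = 1e-12)

  # beta2 linear in eps under a symmetric peak: mean = value at the centre
  b2lin <- -0.5 + 0.4 * (eps - 1)
  p2 <- mk_pes(eps, dnorm(eps, 1, 0.1), b2lin)
  fb2 <- feature_beta(p2, 0.6, 1.4)
  expect_equal(fb2$beta2, -0.5, tolerance = 1e-6)

  p3 <- mk_pes(eps, rep(0, length(eps)))
  expect_error(feature_beta(p3, 0.7, 1.3), "zero total weight")
})

test_that("damped-oscillation fitting recovers noiseless parameters", {
  # generate from the model family itself: exact recovery expected
  sigma <- 100 / (2 * sqrt(2 * log(2)))
  t <- seq(-300, 1700, by = 40)
  gq <- statmod::gauss.quad(40, kind = "legendre")
  conv_cos_ref <- function(ti, tau_d, T, phi) {
    lo <- max(0, ti - 6 * sigma)
    hi <- ti + 6 * sigma
    if (hi <= 0) return(0)
    x <- (hi + lo) / 2 + (hi - lo) / 2 * gq$nodes
    w <- (hi - lo) / 2 * gq$weights * dnorm(ti - x, 0, sigma)
    sum(w * exp(-x / tau_d) * cos(2 * pi * x / T - phi))
  }
  s <- vapply(t, conv_cos_ref, 0, tau_d = 500, T = 400, phi = 0.4) * 2 +
    1.5 * trpes:::irf_exp_decay(t, 5000, sigma) +
    0.7 * trpes:::irf_step(t, sigma)
  fit <- fit_damped_oscillation(mk_trace(t, s), 100, period_guess_fs = 300)
  expect_true(fit$converged)
  expect_equal(unname(fit$pars["period_fs"]), 400, tolerance = 1 / 400)
  expect_equal(unname(fit$pars["phase_rad"]), 0.4, tolerance = 0.02)
  expect_equal(unname(fit$pars["tau_d_fs"]), 500, tolerance = 0.02 * 500)

  # oscillation-free trace (constant excited signal under the IRF):
  # amplitude consistent with zero
  fitc <- fit_damped_oscillation(
    mk_trace(t, 2 * trpes:::irf_step(t, sigma)), 100,
    period_guess_fs = 300)
  expect_lt(abs(fitc$pars["a"]), 1e-3)

  expect_error(fit_damped_oscillation(mk_trace(t[1:8], s[1:8]), 100),
               "at least 12")
})

test_that("exponential decay fitting recovers the lifetime", {
  t <- c(seq(2000, 20000, by = 2000), seq(3e4, 4e5, length.out = 10))
  tau <- 120000
  s <- 3.2 * exp(-t / tau) + 0.1
  fit <- fit_decay(mk_trace(t, s), t_min_fs = 2000)
  expect_true(fit$converged)
  expect_equal(unname(fit$pars["tau_fs"]), tau, tolerance = 2000 / tau)

  # constant trace: lifetime unbounded, reported as NA
  fitc <- fit_decay(mk_trace(t, rep(1, length(t))), 2000)
  expect_true(fitc$lifetime_unbounded)
  expect_true(is.na(fitc$pars["tau_fs"]))

  # pure noise around zero: not converged
  set.seed(21)
  fitn <- fit_decay(mk_trace(t, rnorm(length(t), 0, 1)), 2000)
  expect_false(fitn$converged)

  expect_error(fit_decay(mk_trace(t[1:3], s[1:3]), 0), "fewer than 4")
})

test_that("moving peak conserves the total signal while windows oscillate", {
  cfg <- pck_fixture()
  cfg$generator$image_size <- 128
  cfg$generator$k_cal <- 5.6e-4
  cfg$generator$n_electrons <- 0
  ds <- generate_dataset(cfg)
  tr <- ds$truth
  dense <- tr$delay_fs >= 200 & tr$delay_fs <= 1200
  osc_amp <- function(x) {
    detr <- x - stats::fitted(stats::lm(x ~ poly(seq_along(x), 3)))
    diff(range(detr))
  }
  # oscillation of the total trace is < 5% of the eps1-window oscillation
  expect_lt(osc_amp(tr$total[dense]), 0.05 * osc_amp(tr$s_eps1[dense]))
})
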