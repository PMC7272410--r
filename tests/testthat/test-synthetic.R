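test_that("trajectory honours the phase convention and bounds", {
  cfg <- pck_fixture()
  T <- cfg$generator$period_fs
  expect_equal(trajectory(0, cfg), 0)
  # undamped limit: full excursion to SB at T/2, back at T
  cfg_inf <- cfg
  cfg_inf$generator$tau_damp_fs <- 1e12
  expect_equal(trajectory(T / 2, cfg_inf), 1, tolerance = 1e-9)
  expect_equal(trajectory(T, cfg_inf), 0, tolerance = 1e-9)
  expect_equal(trajectory(-50, cfg), 0)
  t <- seq(-200, 5000, by = 7)
  q <- trajectory(t, cfg)
  expect_true(all(q >= 0 & q <= 1))
  # damping settles the packet at the SB minimum, where the late-time peak sits
  expect_gt(trajectory(5 * cfg$generator$tau_damp_fs, cfg), 0.99)
})

test_that("model spectrum interpolates centre and anisotropy in q", {
  cfg <- pck_fixture()
  centre_of <- function(p) p$grid[which.max(p$S)]
  p0 <- model_pes(0, 300, cfg)
  p1 <- model_pes(1, 300, cfg)
  expect_equal(centre_of(p0), 1.4, tolerance = 0.02)
  expect_equal(centre_of(p1), 0.8, tolerance = 0.02)
  # beta2 at the moving peak is the linear interpolation of the endpoints
  phalf <- model_pes(0.5, 300, cfg)
  i <- which.min(abs(phalf$grid - 1.1))
  # remove dilution by the (beta = 0) background component
  peak_frac <- local({
    g <- cfg$generator
    peak <- dnorm(phalf$grid[i], 1.1, g$peak_width_ev) *
      irf_exp_decay(300, g$lifetime_ps * 1000, g$irf_fwhm_fs / 2.3548)
    bg <- g$bg_amp * exp(-phalf$grid[i] / g$bg_scale_ev) / g$bg_scale_ev
    peak / (peak + bg)
  })
  expect_equal(phalf$beta2[i] / peak_frac, (-0.36 + -0.11) / 2,
               tolerance = 1e-3)
  expect_error(model_pes(1.2, 0, cfg), "q must lie")
})

test_that("forward projection matches the closed-form shell profile", {
  # zero spectrum -> zero image
  p0 <- pes(1:50, rep(0, 50), domain = "radius")
  expect_equal(sum(abs(forward_project(p0, 128)$counts)), 0)

  # single isotropic shell: radial profile approximately R / sqrt(R^2 - r^2),
  # exactly the numeric line-of-sight integral of the unit-width shell
  R <- 40
  S <- rep(0, 50)
  S[R] <- 1
  img <- forward_project(pes(1:50, S, domain = "radius"), 128)
  cx <- img$centre[1]
  cy <- img$centre[2]
  iy <- round(cy) + 1
  ixs <- round(cx + c(5, 15, 25, 34, 38)) + 1
  rho <- sqrt((ixs - 1 - cx)^2 + (iy - 1 - cy)^2)
  px <- img$counts[cbind(iy, ixs)]
  oracle <- vapply(rho, abel_shell_num, 0, R = R)
  expect_equal(px, oracle, tolerance = 1e-3)
  # thin-shell closed form, away from the shell edge
  closed <- R / sqrt(R^2 - rho^2)
  expect_equal(px / px[1], closed / closed[1], tolerance = 0.02)

  # beta2 = +2 shell: cos^2 emission has a node in the image plane's
  # horizontal axis
  img2 <- forward_project(pes(1:50, S, beta2 = rep(2, 50),
                              domain = "radius"), 128)
  horiz <- img2$counts[round(cy) + 1, ]
  expect_lt(max(horiz) / max(img2$counts), 0.02)

  # image too small for the spectrum
  expect_error(forward_project(pes(1:80, c(rep(0, 79), 1),
                                   domain = "radius"), 64),
               "image too small")
})

test_that("forward projection conserves counts on random smooth spectra", {
  set.seed(101)
  for (i in 1:50) {
    p <- random_radial_pes(100)
    img <- forward_project(p, 224)
    expect_rel_equal(sum(img$counts), sum(p$S), 1e-3)
    # positivity for any beta2 in [-1, 2]
    expect_gt(min(img$counts), -1e-9 * max(img$counts))
  }
})

test_that("Poisson sampling is seeded, scaled, and unbiased", {
  S <- rep(0, 30)
  S[18] <- 1
  img <- forward_project(pes(1:30, S, domain = "radius"), 72)

  expect_equal(sum(sample_counts(img, 0, seed = 1)$counts), 0)
  a <- sample_counts(img, 2e4, seed = 7)
  b <- sample_counts(img, 2e4, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_false(identical(a$counts, sample_counts(img, 2e4, seed = 8)$counts))

  # mean of 200 replicates converges to the expectation (law of large
  # numbers) on pixels with >= 100 expected counts
  ex <- img$counts * (2e5 / sum(img$counts))
  acc <- matrix(0, nrow(ex), ncol(ex))
  for (s in 1:200) {
    acc <- acc + sample_counts(vmi_image(ex, img$centre), NULL,
                               seed = s)$counts
  }
  acc <- acc / 200
  hot <- ex >= 100
  expect_true(any(hot))
  expect_lt(mean(abs(acc[hot] - ex[hot]) / ex[hot]), 0.02)

  bad <- vmi_image(matrix(1, 4, 4) - 2 * diag(4), centre = c(1.5, 1.5))
  expect_error(sample_counts(bad, 10, seed = 1), "negative")
})

test_that("generated datasets are deterministic and IRF-limited", {
  cfg <- pck_fixture()
  cfg$generator$image_size <- 128
  cfg$generator$k_cal <- 5.6e-4
  cfg$generator$n_electrons <- 2e4
  cfg$generator$delays_fs <- seq(-200, 600, by = 50)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$frames[[5]]$counts, ds2$frames[[5]]$counts)
  expect_identical(ds1$truth, ds2$truth)

  # noiseless request yields expectation-valued frames
  cfg0 <- cfg
  cfg0$generator$n_electrons <- 0
  ds0 <- generate_dataset(cfg0)
  expect_false(all(ds0$frames[[8]]$counts == round(ds0$frames[[8]]$counts)))

  # ground-truth rise of the excited-state signal has the 10-90% width of a
  # 100 fs FWHM Gaussian step response (2.563 sigma = 109 fs)
  cfgr <- cfg0
  cfgr$generator$delays_fs <- c(-350, -300, seq(-250, 250, by = 10))
  dsr <- generate_dataset(cfgr)
  tr <- dsr$truth
  excited <- tr$total - mean(tr$total[tr$delay_fs <= -300])
  lvl <- excited / excited[length(excited)]
  t10 <- approx(lvl, tr$delay_fs, xout = 0.1, ties = "ordered")$y
  t90 <- approx(lvl, tr$delay_fs, xout = 0.9, ties = "ordered")$y
  sigma <- 100 / (2 * sqrt(2 * log(2)))
  expect_equal(t90 - t10, 2.563 * sigma, tolerance = 0.08)

  # at least two t < 0 frames are required
  cfg_bad <- cfg
  cfg_bad$generator$delays_fs <- c(-50, 0, 100)
  expect_error(generate_dataset(cfg_bad), "at least 2 frames")
})

test_that("undamped traces are periodic and fixture traces antiphase", {
  # tau_d, tau -> inf: window traces repeat exactly with period T
  cfg <- pck_fixture()
  cfg$generator$image_size <- 128
  cfg$generator$k_cal <- 5.6e-4
  cfg$generator$n_electrons <- 0
  cfg$generator$tau_damp_fs <- 1e12
  cfg$generator$lifetime_ps <- 1e12
  T <- cfg$generator$period_fs
  base <- seq(280, 640, by = 40)
  cfg$generator$delays_fs <- c(-200, -100, base, base + T)
  ds <- generate_dataset(cfg)
  tr <- ds$truth
  i1 <- match(base, tr$delay_fs)
  i2 <- match(base + T, tr$delay_fs)
  expect_equal(tr$s_eps1[i1], tr$s_eps1[i2], tolerance = 1e-6)
  expect_equal(tr$s_eps2[i1], tr$s_eps2[i2], tolerance = 1e-6)

  # fixture ground truth: eps1 and eps2 oscillate with a pi phase shift
  cfgf <- pck_fixture()
  cfgf$generator$image_size <- 128
  cfgf$generator$k_cal <- 5.6e-4
  cfgf$generator$n_electrons <- 0
  dsf <- generate_dataset(cfgf)
  trf <- dsf$truth
  mk <- function(s) structure(list(label = "w", bounds = c(0, 1),
                                   delays_fs = trf$delay_fs, s = s,
                                   err = rep(NA_real_, length(s))),
                              class = "window_trace")
  neg <- trf$delay_fs < 0
  f1 <- fit_damped_oscillation(mk(trf$s_eps1 - mean(trf$s_eps1[neg])), 100,
                               period_guess_fs = 400)
  f2 <- fit_damped_oscillation(mk(trf$s_eps2 - mean(trf$s_eps2[neg])), 100,
                               period_guess_fs = 400)
  expect_lt(abs(phase_difference(f1, f2) - pi), 0.2)
  # both windows see the generator period
  expect_equal(unname(f1$pars["period_fs"]), 400, tolerance = 0.1 * 400)
  expect_equal(unname(f2$pars["period_fs"]), 400, tolerance = 0.1 * 400)
})
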