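test_that("dihedral measurement follows the sign convention", {
  # planar trans 4-atom chain
  g <- geometry(rep("C", 4),
                rbind(c(0, 1, 0), c(0, 0, 0), c(1.4, 0, 0), c(1.4, -1, 0)))
  expect_equal(dihedral(g, 1, 2, 3, 4), 180)
  # perpendicular arrangement
  gp <- geometry(rep("C", 4),
                 rbind(c(0, 1, 0), c(0, 0, 0), c(1.4, 0, 0),
                       c(1.4, 0, 1)))
  expect_equal(abs(dihedral(gp, 1, 2, 3, 4)), 90)
  # mirror image flips the sign
  gg <- geometry(rep("C", 4),
                 rbind(c(0, 1, 0.3), c(0, 0, 0), c(1.4, 0, 0),
                       c(1.4, -1, 0.6)))
  gm <- geometry(gg$elements, gg$coords %*% diag(c(1, 1, -1)))
  expect_equal(dihedral(gm, 1, 2, 3, 4), -dihedral(gg, 1, 2, 3, 4))
  # collinear triple is an error naming the atoms
  gc <- geometry(rep("C", 4),
                 rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)))
  expect_error(dihedral(gc, 1, 2, 3, 4), "collinear")
})

test_that("internal coordinates round-trip through Cartesian space", {
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    P <- matrix(0, n, 3)
    for (i in 2:n) P[i, ] <- P[i - 1, ] + rnorm(3) * 0.35 + c(1.45, 0, 0)
    g <- geometry(rep("C", n), P)
    g2 <- from_internals(to_internals(g))
    expect_lt(align_rmsd(g, g2), 1e-6)
  }

  # butane-like gauche fixture: dihedral set to 60 reconstructs exactly
  ic <- to_internals(geometry(rep("C", 4),
                              rbind(c(0, 1.1, 0), c(0, 0, 0),
                                    c(1.53, 0, 0), c(2.1, 1.2, 0.4))))
  ic$dihedral[4] <- 60
  g3 <- from_internals(ic)
  expect_equal(dihedral(g3, 4, 3, 2, 1), 60, tolerance = 1e-9)
})

test_that("LIIC paths are endpoint-exact, affine, and wrap-aware", {
  set.seed(19)
  n <- 6
  P <- matrix(0, n, 3)
  for (i in 2:n) P[i, ] <- P[i - 1, ] + rnorm(3) * 0.3 + c(1.45, 0, 0)
  A <- geometry(rep("C", n), P, "A")
  Q <- P + 0.25 * matrix(rnorm(3 * n), n, 3)
  B <- geometry(rep("C", n), Q, "B")

  # n_points = 2 is exactly the endpoints
  p2 <- liic_path(A, B, 2)
  expect_identical(p2$geometries[[1]]$coords, A$coords)
  expect_identical(p2$geometries[[2]]$coords, B$coords)

  # every internal coordinate is affine in lambda
  p5 <- liic_path(A, B, 5)
  icA <- to_internals(A)
  icB <- to_internals(B)
  for (j in seq_along(p5$lambda)) {
    lam <- p5$lambda[j]
    expect_equal(p5$internals[[j]]$bond[-1],
                 ((1 - lam) * icA$bond + lam * icB$bond)[-1],
                 tolerance = 1e-9)
    expect_equal(p5$internals[[j]]$angle[3:n],
                 ((1 - lam) * icA$angle + lam * icB$angle)[3:n],
                 tolerance = 1e-9)
  }

  # dihedral interpolation: 0 -> 90 passes through 45; 170 -> -170 wraps
  # through 180 (shorter arc)
  mk <- function(d) {
    ic <- to_internals(A)
    ic$dihedral[4] <- d
    from_internals(ic)
  }
  mid <- function(d1, d2) {
    path <- liic_path(mk(d1), mk(d2), 3)
    dihedral(path$geometries[[2]], 4, 3, 2, 1)
  }
  expect_equal(mid(0, 90), 45, tolerance = 1e-9)
  expect_equal(abs(mid(170, -170)), 180, tolerance = 1e-9)

  expect_error(liic_path(A, geometry(rep("N", n), Q), 3), "incompatible")
})

test_that("the packaged pathway rotates the single bond only", {
  pm <- read_xyz(system.file("extdata", "pm_synthetic.xyz",
                             package = "trpes"))
  sb <- read_xyz(system.file("extdata", "sb_synthetic.xyz",
                             package = "trpes"))
  path <- liic_path(pm, sb, 15)
  phi_sb <- vapply(path$geometries, dihedral, 0, 1, 2, 3, 4)
  phi_db <- vapply(path$geometries, dihedral, 0, 2, 3, 4, 5)
  # single-bond dihedral sweeps monotonically from planar towards ~90
  expect_equal(phi_sb[1], 180, tolerance = 1e-6)
  expect_equal(phi_sb[15], 92, tolerance = 1e-6)
  expect_true(all(diff(phi_sb) < 0))
  # double-bond dihedral stays planar within 10 degrees
  expect_true(all(abs(phi_db) > 170))
})

test_that("photon-energy bookkeeping reproduces the printed limits", {
  model <- fixture_energetics()
  # eps_FC = hv_pump + hv_probe - VDE = 2.79 + 1.55 - 2.94 = 1.40
  expect_equal(epsilon_max_fc(model)$eps_fc, 1.40, tolerance = 1e-12)

  # the earlier experiment's 3.10 eV pump raises the limit to 1.71
  m2 <- energetics_model(3.10, 1.55, 2.94, model$geometries)
  expect_equal(epsilon_max_fc(m2)$eps_fc, 1.71, tolerance = 1e-12)

  # boundary: VDE equal to the photon sum closes the channel
  m3 <- energetics_model(1.5, 1.44, 2.94, model$geometries)
  expect_false(epsilon_max_fc(m3)$channel_open)

  # affine with unit coefficients in each argument (finite differences)
  d <- 0.07
  base <- epsilon_max_fc(model)$raw
  expect_equal(epsilon_max_fc(energetics_model(2.79 + d, 1.55, 2.94,
                                               model$geometries))$raw,
               base + d)
  expect_equal(epsilon_max_fc(energetics_model(2.79, 1.55 + d, 2.94,
                                               model$geometries))$raw,
               base + d)
  expect_equal(epsilon_max_fc(energetics_model(2.79, 1.55, 2.94 + d,
                                               model$geometries))$raw,
               base - d)

  # single-bond geometry: signal expected between 0.43 and 0.87 eV
  rng <- epsilon_range_geom(model, "SB")
  expect_equal(rng$eps_hi, 0.87, tolerance = 1e-12)
  expect_equal(rng$eps_lo, 0.43, tolerance = 1e-12)

  # no vibrational energy: the range collapses
  m4 <- energetics_model(2.79, 1.55, 2.94,
                         list(X = list(gap_d0_s1 = 0.68, e_s1 = 2.79)))
  r4 <- epsilon_range_geom(m4, "X")
  expect_equal(r4$eps_lo, r4$eps_hi)

  # gap equal to the probe closes the channel
  m5 <- energetics_model(2.79, 1.55, 2.94,
                         list(X = list(gap_d0_s1 = 1.55, e_s1 = 2.4)))
  expect_false(epsilon_range_geom(m5, "X")$channel_open)
})

test_that("assignment ranks candidates by energetics then anisotropy", {
  model <- fixture_energetics()
  features <- data.frame(
    label = c("eps1", "eps2"), centre_ev = c(1.4, 0.8),
    width_ev = c(0.3, 0.3), beta2 = c(-0.36, -0.11),
    beta2_unc = c(0.09, 0.12))
  candidates <- data.frame(
    label = c("DB", "FC", "PM", "SB"),
    beta2_model = c(0.04, -0.48, -0.40, -0.19))

  rep <- assign_features(features, candidates, model, delta_ev = 0.2)
  s <- rep$scores
  # the 0.8 eV feature is incompatible with the double-bond geometry
  # (its spectral maximum is expected below 0.21 eV)
  expect_false(s$compatible[s$feature == "eps2" & s$candidate == "DB"])
  # ... but compatible with the single-bond geometry
  expect_true(s$compatible[s$feature == "eps2" & s$candidate == "SB"])
  expect_identical(rep$ranking$eps2$candidate[1], "SB")
  # the 1.4 eV feature is compatible with both FC and PM
  expect_true(s$compatible[s$feature == "eps1" & s$candidate == "FC"])
  expect_true(s$compatible[s$feature == "eps1" & s$candidate == "PM"])

  # identical candidates: deterministic tie-break by label order
  cand2 <- data.frame(label = c("Z1", "A1"), beta2_model = c(-0.36, -0.36))
  m6 <- energetics_model(2.79, 1.55, 2.94,
                         list(A1 = list(gap_d0_s1 = 0.15, e_s1 = 2.79),
                              Z1 = list(gap_d0_s1 = 0.15, e_s1 = 2.79)))
  r2 <- assign_features(features[1, ], cand2, m6)
  expect_identical(r2$ranking$eps1$candidate, c("A1", "Z1"))
})
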