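# Independent numerical oracles used to freeze expected values.  These
# deliberately avoid the closed-form code paths they check.

# Legendre projection of an angular distribution f(theta) by adaptive
# quadrature: c_n = (2n+1)/2 int_{-1}^{1} f(acos x) P_n(x) dx
legendre_project_num <- function(f, n) {
  Pn <- function(x) {
    switch(as.character(n), "0" = rep(1, length(x)),
           "2" = 0.5 * (3 * x^2 - 1),
           "4" = 0.125 * (35 * x^4 - 30 * x^2 + 3))
  }
  (2 * n + 1) / 2 *
    stats::integrate(function(x) f(acos(x)) * Pn(x), -1, 1,
                     rel.tol = 1e-12)$value
}

# Line-of-sight projection of a finite-width isotropic shell (inner radius
# R - w/2, outer R + w/2, density 1/(4 pi r^2 w)) at in-plane radius rho,
# by numeric integration along the chord.
abel_shell_num <- function(rho, R, w = 1) {
  Rlo <- R - w / 2
  Rhi <- R + w / 2
  if (rho >= Rhi) return(0)
  xmax <- sqrt(Rhi^2 - rho^2)
  dens <- function(x) {
    r <- sqrt(rho^2 + x^2)
    ifelse(r >= Rlo & r <= Rhi, 1 / (4 * pi * r^2 * w), 0)
  }
  2 * stats::integrate(dens, 0, xmax, rel.tol = 1e-10,
                       subdivisions = 400)$value
}

# Plane-wave dipole matrix element by per-primitive 3-D Gauss-Hermite
# quadrature; the integrand (monomial x dipole x plane-wave phase) is
# evaluated as a black box on the grid.
matrix_element_num <- function(orb, k_vec, e_vec, n_gh = 28) {
  gh <- statmod::gauss.quad(n_gh, kind = "hermite")
  p <- orb$primitives
  M <- 0 + 0i
  for (i in seq_len(nrow(p))) {
    a <- p$alpha[i]
    C <- c(p$cx[i], p$cy[i], p$cz[i])
    u <- gh$nodes / sqrt(a)
    w <- gh$weights / sqrt(a)
    acc <- 0 + 0i
    for (ix in seq_len(n_gh)) {
      for (iy in seq_len(n_gh)) {
        rxy <- c(u[ix], u[iy])
        pre <- w[ix] * w[iy] * u[ix]^p$lx[i] * u[iy]^p$ly[i]
        if (pre == 0) next
        r <- cbind(rxy[1] + C[1], rxy[2] + C[2], u + C[3])
        f <- u^p$lz[i] * (r %*% e_vec) *
          exp(-1i * (r %*% k_vec))
        acc <- acc + pre * sum(w * f)
      }
    }
    M <- M + p$coeff[i] * acc
  }
  M
}

# random multi-centre orbital with s/p primitives (compact, small centres,
# so modest angular quadratures are converged)
random_orbital <- function(n_prim = 3) {
  ls <- matrix(0L, n_prim, 3)
  for (i in seq_len(n_prim)) {
    pick <- sample(0:3, 1)  # 0 = s, 1..3 = p_x/y/z
    if (pick > 0) ls[i, pick] <- 1L
  }
  dyson_orbital(data.frame(
    cx = runif(n_prim, -1.2, 1.2), cy = runif(n_prim, -1.2, 1.2),
    cz = runif(n_prim, -1.2, 1.2), lx = ls[, 1], ly = ls[, 2],
    lz = ls[, 3], alpha = runif(n_prim, 0.4, 1.2),
    coeff = runif(n_prim, -1, 1) + sign(runif(n_prim, -1, 1)) * 0.2))
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2],
                -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# smooth random spectrum (Gaussian mixture) on the integer radius grid
random_radial_pes <- function(n_r, n_peaks = 2) {
  r <- seq_len(n_r)
  S <- rep(0, n_r)
  for (i in seq_len(n_peaks)) {
    S <- S + runif(1, 0.3, 1) * dnorm(r, runif(1, 0.3, 0.8) * n_r,
                                      runif(1, 4, 12))
  }
  b2 <- runif(1, -1, 2) + (runif(1, -0.5, 0.5)) * sin(r / n_r * pi)
  b2 <- pmin(pmax(b2, -1), 2)
  pes(r, S * 1e5, beta2 = b2, domain = "radius")
}

expect_rel_equal <- function(x, y, tol) {
  testthat::expect_lt(abs(x - y) / max(abs(y), 1e-300), tol)
}
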