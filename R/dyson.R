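# Fourier integrals F_l(k; alpha) = int u^l exp(-i k u) exp(-alpha u^2) du
# via the recursion F_{l+1} = (-i k / 2 alpha) F_l + (l / 2 alpha) F_{l-1},
# F_0 = sqrt(pi/alpha) exp(-k^2 / 4 alpha).
fourier_F <- function(k, alpha, lmax) {
  out <- vector("list", lmax + 1)
  out[[1]] <- complex(real = sqrt(pi / alpha) * exp(-k^2 / (4 * alpha)))
  if (lmax >= 1) out[[2]] <- (-1i * k / (2 * alpha)) * out[[1]]
  if (lmax >= 2) {
    for (l in 2:lmax) {
      out[[l + 1]] <- (-1i * k / (2 * alpha)) * out[[l]] +
        ((l - 1) / (2 * alpha)) * out[[l - 1]]
    }
  }
  out
}

# Dipole-moment vectors V(k) = <e^{i k.r} | r | psi> for a whole matrix of
# k vectors (rows), evaluated in closed form: per primitive the Fourier
# transform factorises into 1-D integrals, with the centre entering through
# a phase factor and the split r = (r - R) + R.
orbital_moment_matrix <- function(orb, K) {
  p <- orb$primitives
  n <- nrow(K)
  V <- matrix(0i, n, 3)
  for (i in seq_len(nrow(p))) {
    a <- p$alpha[i]
    C <- c(p$cx[i], p$cy[i], p$cz[i])
    l <- c(p$lx[i], p$ly[i], p$lz[i])
    Fx <- fourier_F(K[, 1], a, l[1] + 1)
    Fy <- fourier_F(K[, 2], a, l[2] + 1)
    Fz <- fourier_F(K[, 3], a, l[3] + 1)
    f0x <- Fx[[l[1] + 1]]
    f0y <- Fy[[l[2] + 1]]
    f0z <- Fz[[l[3] + 1]]
    f1x <- Fx[[l[1] + 2]]
    f1y <- Fy[[l[2] + 2]]
    f1z <- Fz[[l[3] + 2]]
    base <- p$coeff[i] * exp(-1i * (K %*% C)[, 1])
    # component d: (F_{l_d + 1} + C_d F_{l_d}) * prod of the other two F_l
    V[, 1] <- V[, 1] + base * (f1x + C[1] * f0x) * f0y * f0z
    V[, 2] <- V[, 2] + base * f0x * (f1y + C[2] * f0y) * f0z
    V[, 3] <- V[, 3] + base * f0x * f0y * (f1z + C[3] * f0z)
  }
  V
}

orbital_moment_vector <- function(orb, k_vec) {
  orbital_moment_matrix(orb, matrix(k_vec, 1, 3))[1, ]
}

#' Plane-wave photodetachment dipole matrix element
#'
#' Evaluates `M = <exp(i k.r) | e.r | psi_D>` in closed form for a Dyson
#' orbital expanded in Cartesian Gaussians, treating the outgoing electron
#' as a plane wave (no interaction with the neutral core) and the dipole
#' operator in length gauge.
#'
#' @param orb a [dyson_orbital()]
#' @param k_vec photoelectron wavevector, molecular frame, atomic units
#' @param e_vec laser polarisation unit vector, molecular frame
#' @return complex amplitude
#' @export
matrix_element <- function(orb, k_vec, e_vec) {
  stopifnot(inherits(orb, "dyson_orbital"), length(k_vec) == 3,
            length(e_vec) == 3)
  if (abs(sqrt(sum(e_vec^2)) - 1) > 1e-8) {
    stop("polarisation vector must have unit length")
  }
  sum(e_vec * orbital_moment_vector(orb, k_vec))
}

# uniform-azimuth x Gauss-Legendre-polar unit-sphere quadrature
sphere_grid <- function(n_polar, n_az) {
  gl <- statmod::gauss.quad(n_polar, kind = "legendre")
  phi <- 2 * pi * (seq_len(n_az) - 0.5) / n_az
  ct <- rep(gl$nodes, each = n_az)
  st <- sqrt(pmax(0, 1 - ct^2))
  w <- rep(gl$weights, each = n_az) * (2 * pi / n_az)
  list(dirs = cbind(st * cos(phi), st * sin(phi), ct), w = w / (4 * pi))
}

# isotropic-orientation average at one energy via the k-frame route: for
# each molecular-frame emission direction khat, resolve |e.V|^2 into the
# components parallel (A) and perpendicular (B) to khat; the azimuthal
# average over polarisations at fixed angle theta to khat is analytic, so
# I_lab(theta) = <A> cos^2 + <B> sin^2 exactly.
beta_sigma_kframe <- function(orb, k, n_polar, n_az) {
  g <- sphere_grid(n_polar, n_az)
  V <- orbital_moment_matrix(orb, k * g$dirs)
  par2 <- Mod(rowSums(g$dirs * V))^2
  tot <- rowSums(Mod(V)^2)
  A <- sum(g$w * par2)
  B <- sum(g$w * (tot - par2) / 2)
  c0 <- (A + 2 * B) / 3
  list(sigma = 4 * pi * k * c0,
       beta2 = if (c0 > 0) 2 * (A - B) / (A + 2 * B) else 0,
       beta4 = 0, legendre_resid = 0)
}

# independent route: explicit SO(3) orientation average at fixed lab
# polarisation, followed by a numerical Legendre projection of the
# laboratory-frame angular distribution.
beta_sigma_so3 <- function(orb, k, n_alpha = 16, n_beta = 12,
                           n_gamma = 16, n_theta = 8) {
  glb <- statmod::gauss.quad(n_beta, kind = "legendre")
  alphas <- 2 * pi * (seq_len(n_alpha) - 0.5) / n_alpha
  gammas <- 2 * pi * (seq_len(n_gamma) - 0.5) / n_gamma
  glt <- statmod::gauss.quad(n_theta, kind = "legendre")
  e_lab <- c(0, 0, 1)
  rotz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3, 3)
  roty <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0,
                               sin(b), 0, cos(b)), 3, 3)
  # tabulate all rotations once: inverse-rotated lab vectors and weights
  nrot <- n_alpha * n_beta * n_gamma
  Kdir <- matrix(0, nrot, 3)
  Edir <- matrix(0, nrot, 3)
  wrot <- numeric(nrot)
  k_lab_unit <- function(ct) c(sqrt(max(0, 1 - ct^2)), 0, ct)
  I_theta <- numeric(n_theta)
  for (it in seq_len(n_theta)) {
    k_lab <- k * k_lab_unit(glt$nodes[it])
    row <- 0
    for (a in alphas) {
      Ra <- rotz(a)
      for (ib in seq_len(n_beta)) {
        Rab <- Ra %*% roty(acos(glb$nodes[ib]))
        for (gm in gammas) {
          R <- Rab %*% rotz(gm)
          row <- row + 1
          Kdir[row, ] <- crossprod(R, k_lab)
          Edir[row, ] <- crossprod(R, e_lab)
          wrot[row] <- glb$weights[ib]
        }
      }
    }
    V <- orbital_moment_matrix(orb, Kdir)
    M2 <- Mod(rowSums(Edir * V))^2
    I_theta[it] <- sum(wrot * M2) / (2 * n_alpha * n_gamma)
  }
  pl <- function(n, x) {
    switch(as.character(n), "0" = rep(1, length(x)),
           "2" = 0.5 * (3 * x^2 - 1),
           "4" = 0.125 * (35 * x^4 - 30 * x^2 + 3),
           "6" = (231 * x^6 - 315 * x^4 + 105 * x^2 - 5) / 16)
  }
  cn <- vapply(c(0, 2, 4, 6), function(n) {
    (2 * n + 1) / 2 * sum(glt$weights * pl(n, glt$nodes) * I_theta)
  }, 0)
  c0 <- cn[1]
  list(sigma = 4 * pi * k * c0,
       beta2 = if (c0 > 0) cn[2] / c0 else 0,
       beta4 = if (c0 > 0) cn[3] / c0 else 0,
       legendre_resid = if (c0 > 0) abs(cn[4]) / c0 else 0)
}

#' Cross-section and anisotropy of one-photon detachment at one energy
#'
#' Isotropic-orientation-averaged laboratory-frame photoelectron angular
#' distribution in the plane-wave Dyson-orbital model.  Two independent
#' averaging routes are provided: `"kframe"` (molecular-frame emission
#' directions with the analytic polarisation-azimuth average; the default)
#' and `"so3"` (explicit rotation average at fixed lab polarisation).  Both
#' must agree; the slower `so3` route is retained as a cross-check.
#'
#' @param orb a [dyson_orbital()]
#' @param eps_ev electron kinetic energy (eV, > 0)
#' @param averaging `"kframe"` or `"so3"`
#' @param n_polar,n_az quadrature orders over emission directions
#' @param check_convergence re-evaluate on a denser grid and error if the
#'   result moved by more than `1e-3`
#' @return list with `sigma` (arbitrary units, includes the
#'   density-of-states factor `k`), `beta2`, `beta4`, `legendre_resid`
#' @export
beta_sigma_at <- function(orb, eps_ev, averaging = c("kframe", "so3"),
                          n_polar = 20, n_az = 32,
                          check_convergence = FALSE) {
  averaging <- match.arg(averaging)
  stopifnot(eps_ev > 0)
  k <- ekin_to_k(eps_ev)
  res <- if (averaging == "kframe") {
    beta_sigma_kframe(orb, k, n_polar, n_az)
  } else {
    beta_sigma_so3(orb, k)
  }
  if (check_convergence && averaging == "kframe") {
    res2 <- beta_sigma_kframe(orb, k, n_polar + 8, 2 * n_az)
    dsig <- abs(res2$sigma - res$sigma) / max(res$sigma, 1e-300)
    if (abs(res2$beta2 - res$beta2) > 1e-3 || dsig > 1e-3) {
      stop(sprintf(
        "angular quadrature not converged (delta beta2 = %.2g); %s",
        abs(res2$beta2 - res$beta2),
        "increase n_polar / n_az"))
    }
  }
  res
}

#' Anisotropy and cross-section curves over an energy grid
#'
#' @param orb a [dyson_orbital()]
#' @param eps_grid positive energies (eV); any order, result is sorted
#' @param ... passed to [beta_sigma_at()]
#' @return object of class `pad_result` with fields `eps_ev`, `k_au`,
#'   `sigma`, `beta2` and metadata
#' @export
beta_curve <- function(orb, eps_grid, ...) {
  stopifnot(all(eps_grid > 0))
  o <- order(eps_grid)
  eps <- eps_grid[o]
  vals <- lapply(eps, function(e) beta_sigma_at(orb, e, ...))
  structure(list(eps_ev = eps, k_au = ekin_to_k(eps),
                 sigma = vapply(vals, `[[`, 0, "sigma"),
                 beta2 = vapply(vals, `[[`, 0, "beta2"),
                 beta4 = vapply(vals, `[[`, 0, "beta4"),
                 orbital = orb$label),
            class = "pad_result")
}

#' @export
print.pad_result <- function(x, ...) {
  cat(sprintf("<pad_result>%s %d energies [%.3g, %.3g] eV\n",
              if (nzchar(x$orbital)) paste0(" ", x$orbital, ",") else "",
              length(x$eps_ev), min(x$eps_ev), max(x$eps_ev)))
  invisible(x)
}

#' Window-averaged model anisotropy
#'
#' Averages a computed `beta2(eps)` curve over the same energy window as an
#' experimental feature, for direct comparison with [feature_beta()].
#'
#' @param pad a `pad_result`
#' @param eps_lo,eps_hi window bounds (eV)
#' @param weighting `"uniform"` or `"sigma"` (cross-section weighted)
#' @return scalar `beta2`
#' @export
window_average_beta <- function(pad, eps_lo, eps_hi,
                                weighting = c("uniform", "sigma")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(pad, "pad_result"), eps_lo < eps_hi)
  sel <- pad$eps_ev >= eps_lo & pad$eps_ev <= eps_hi
  if (!any(sel)) stop("window contains no grid points")
  w <- if (weighting == "sigma") pad$sigma[sel] else rep(1, sum(sel))
  sum(w * pad$beta2[sel]) / sum(w)
}
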