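#' Signed dihedral angle
#'
#' IUPAC sign convention: looking down the j->k bond, the angle from the
#' i-j bond to the k-l bond, positive clockwise, in `(-180, 180]` degrees.
#' A mirror image flips the sign.
#'
#' @param g a [geometry()]
#' @param i,j,k,l 1-based atom indices (distinct)
#' @return dihedral in degrees
#' @export
dihedral <- function(g, i, j, k, l) {
  stopifnot(inherits(g, "geometry"), length(unique(c(i, j, k, l))) == 4)
  P <- g$coords
  b1 <- P[j, ] - P[i, ]
  b2 <- P[k, ] - P[j, ]
  b3 <- P[l, ] - P[k, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    stop(sprintf("collinear atoms among (%d, %d, %d, %d): %s", i, j, k, l,
                 "dihedral undefined"))
  }
  ang <- atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  deg <- ang * 180 / pi
  if (deg <= -180) deg <- deg + 360
  deg
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

bond_angle <- function(P, i, j, k) {
  v1 <- P[i, ] - P[j, ]
  v2 <- P[k, ] - P[j, ]
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Z-matrix style connectivity
#'
#' Row `i` names the reference atoms of atom `i`: bond partner `j`, angle
#' reference `k`, dihedral reference `l` (NA where not applicable: atom 1
#' has none, atom 2 only `j`, atom 3 `j` and `k`).  The default chains each
#' atom to its three predecessors.
#'
#' @param n atom count
#' @return data frame with columns `j`, `k`, `l`
#' @export
chain_connectivity <- function(n) {
  data.frame(j = c(NA, seq_len(n - 1))[seq_len(n)] - 0L,
             k = c(NA, NA, seq_len(max(0, n - 2)))[seq_len(n)],
             l = c(NA, NA, NA, seq_len(max(0, n - 3)))[seq_len(n)])
}

#' Cartesian to internal coordinates
#'
#' @param g a [geometry()]
#' @param connectivity a Z-matrix connectivity (see [chain_connectivity()]);
#'   default: sequential chain
#' @return object of class `internal_coords`: the connectivity plus, per
#'   atom, bond length (Angstrom), bond angle and dihedral (degrees)
#' @export
to_internals <- function(g, connectivity = NULL) {
  stopifnot(inherits(g, "geometry"))
  n <- length(g$elements)
  if (n < 2) stop("need at least 2 atoms")
  con <- if (is.null(connectivity)) chain_connectivity(n) else
    as.data.frame(connectivity)
  P <- g$coords
  bond <- rep(NA_real_, n)
  angle <- rep(NA_real_, n)
  dihed <- rep(NA_real_, n)
  for (i in 2:n) {
    j <- con$j[i]
    if (is.na(j) || j >= i) stop("connectivity must reference earlier atoms")
    bond[i] <- sqrt(sum((P[i, ] - P[j, ])^2))
    if (bond[i] <= 0) stop("zero bond length at atom ", i)
    if (i >= 3) {
      k <- con$k[i]
      angle[i] <- bond_angle(P, i, j, k)
      if (angle[i] < 1e-6 || angle[i] > 180 - 1e-6) {
        stop(sprintf("collinear angle reference at atoms (%d, %d, %d)",
                     i, j, k))
      }
    }
    if (i >= 4) {
      dihed[i] <- dihedral(g, i, con$j[i], con$k[i], con$l[i])
    }
  }
  structure(list(elements = g$elements, connectivity = con, bond = bond,
                 angle = angle, dihedral = dihed, label = g$label),
            class = "internal_coords")
}

#' Internal coordinates to Cartesian (NeRF placement)
#'
#' Rebuilds Cartesian coordinates in a canonical frame: atom 1 at the
#' origin, atom 2 on +x, atom 3 in the xy-plane.  The result reproduces the
#' input of [to_internals()] up to rigid rotation/translation.
#'
#' @param ic an `internal_coords`
#' @return a [geometry()]
#' @export
from_internals <- function(ic) {
  stopifnot(inherits(ic, "internal_coords"))
  n <- length(ic$elements)
  P <- matrix(0, n, 3)
  con <- ic$connectivity
  if (n >= 2) P[2, ] <- c(ic$bond[2], 0, 0)
  if (n >= 3) {
    j <- con$j[3]
    k <- con$k[3]
    th <- ic$angle[3] * pi / 180
    dirjk <- (P[k, ] - P[j, ])
    dirjk <- dirjk / sqrt(sum(dirjk^2))
    # rotate dirjk by the bond angle within the xy-plane
    perp <- c(-dirjk[2], dirjk[1], 0)
    P[3, ] <- P[j, ] + ic$bond[3] * (cos(th) * dirjk + sin(th) * perp)
  }
  if (n >= 4) {
    for (i in 4:n) {
      j <- con$j[i]
      k <- con$k[i]
      l <- con$l[i]
      b <- ic$bond[i]
      th <- ic$angle[i] * pi / 180
      ph <- ic$dihedral[i] * pi / 180
      bc <- P[j, ] - P[k, ]
      bc <- bc / sqrt(sum(bc^2))
      ab <- P[k, ] - P[l, ]
      nv <- cross3(ab, bc)
      nn <- sqrt(sum(nv^2))
      if (nn < 1e-9) stop("collinear reference atoms in NeRF placement")
      nv <- nv / nn
      mv <- cross3(nv, bc)
      d2 <- c(-b * cos(th), b * sin(th) * cos(ph), b * sin(th) * sin(ph))
      P[i, ] <- P[j, ] + d2[1] * bc + d2[2] * mv + d2[3] * nv
    }
  }
  geometry(ic$elements, P, ic$label)
}

# shorter-arc difference d2 - d1 wrapped into (-180, 180]
dihedral_arc <- function(d1, d2) {
  delta <- (d2 - d1) %% 360
  ifelse(delta > 180, delta - 360, delta)
}

wrap_deg <- function(x) {
  y <- x %% 360
  ifelse(y > 180, y - 360, ifelse(y <= -180, y + 360, y))
}

#' Linear interpolation in internal coordinates (LIIC)
#'
#' Interpolates every internal coordinate linearly between two endpoint
#' geometries that share one connectivity; dihedrals follow the shorter
#' angular arc with wrap-around at 180 degrees.  No geometry
#' reoptimisation is performed, so the pathway is a direct geometric
#' interpolation, not a minimum-energy path.  The endpoint frames are the
#' input geometries exactly.
#'
#' @param geomA,geomB endpoint [geometry()] objects (same atoms, same order)
#' @param n_points number of frames including the endpoints (>= 2)
#' @param connectivity optional shared connectivity
#' @param direction optional named vector of forced arc directions for
#'   dihedrals near the 180-degree ambiguity: names are atom indices (as
#'   character), values `+1` (increasing) or `-1`
#' @return object of class `liic_path`: `geometries` (list), `lambda`
#'   (fractions in `[0, 1]`), `internals` (list of `internal_coords`)
#' @export
liic_path <- function(geomA, geomB, n_points, connectivity = NULL,
                      direction = NULL) {
  stopifnot(inherits(geomA, "geometry"), inherits(geomB, "geometry"),
            n_points >= 2)
  if (length(geomA$elements) != length(geomB$elements) ||
      !all(geomA$elements == geomB$elements)) {
    stop("endpoint geometries have incompatible atom counts or ordering")
  }
  icA <- to_internals(geomA, connectivity)
  icB <- to_internals(geomB, connectivity)
  lambda <- seq(0, 1, length.out = n_points)
  darc <- dihedral_arc(icA$dihedral, icB$dihedral)
  if (!is.null(direction)) {
    for (nm in names(direction)) {
      i <- as.integer(nm)
      if (!is.na(darc[i]) && sign(darc[i]) != sign(direction[[nm]])) {
        darc[i] <- darc[i] - sign(darc[i]) * 360
      }
    }
  }
  internals <- lapply(lambda, function(lm) {
    ic <- icA
    ic$bond <- (1 - lm) * icA$bond + lm * icB$bond
    ic$angle <- (1 - lm) * icA$angle + lm * icB$angle
    ic$dihedral <- wrap_deg(icA$dihedral + lm * darc)
    ic$label <- sprintf("LIIC lambda=%.4f", lm)
    ic
  })
  geoms <- lapply(internals, from_internals)
  geoms[[1]] <- geomA
  geoms[[n_points]] <- geomB
  structure(list(geometries = geoms, lambda = lambda,
                 internals = internals,
                 labels = c(geomA$label, geomB$label)),
            class = "liic_path")
}

#' RMSD between two geometries after optimal rigid alignment
#'
#' Kabsch superposition (rotation restricted to det +1, so enantiomers do
#' not align) after centring both structures.
#'
#' @param gA,gB [geometry()] objects with the same atom count
#' @return root-mean-square deviation in Angstrom
#' @export
align_rmsd <- function(gA, gB) {
  stopifnot(inherits(gA, "geometry"), inherits(gB, "geometry"),
            length(gA$elements) == length(gB$elements))
  A <- sweep(gA$coords, 2, colMeans(gA$coords))
  B <- sweep(gB$coords, 2, colMeans(gB$coords))
  s <- svd(crossprod(B, A))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((A - B %*% R)^2)))
}

#' @export
print.liic_path <- function(x, ...) {
  cat(sprintf("<liic_path> %d frames: %s -> %s\n", length(x$lambda),
              x$labels[1], x$labels[2]))
  invisible(x)
}
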