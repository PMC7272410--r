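#' Dyson orbital as a Cartesian Gaussian expansion
#'
#' The Dyson orbital is the effective one-electron wavefunction of the
#' photodetached electron.  It is represented here as a sum of primitive
#' Cartesian Gaussians
#' \deqn{c \, (x-X)^{l_x} (y-Y)^{l_y} (z-Z)^{l_z} e^{-\alpha |r-R|^2}}
#' with centres in bohr and exponents in bohr^-2.
#'
#' @param primitives data frame with columns `cx, cy, cz` (centre, bohr),
#'   `lx, ly, lz` (non-negative integer Cartesian angular exponents),
#'   `alpha` (> 0) and `coeff` (real coefficient)
#' @param label optional character label (e.g. "SB")
#' @return object of class `dyson_orbital`; the field `norm` holds
#'   `sqrt(<psi|psi>)` computed by analytic Gaussian overlap
#' @export
dyson_orbital <- function(primitives, label = "") {
  p <- as.data.frame(primitives)
  need <- c("cx", "cy", "cz", "lx", "ly", "lz", "alpha", "coeff")
  if (!all(need %in% names(p))) {
    stop("primitives must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(p) < 1) stop("orbital must contain at least one primitive")
  if (any(p$alpha <= 0)) stop("all Gaussian exponents alpha must be > 0")
  if (any(p[, c("lx", "ly", "lz")] < 0) ||
      any(p[, c("lx", "ly", "lz")] != round(p[, c("lx", "ly", "lz")]))) {
    stop("angular exponents lx, ly, lz must be non-negative integers")
  }
  orb <- structure(list(primitives = p[need], norm = NA_real_,
                        label = as.character(label)[1]),
                   class = "dyson_orbital")
  orb$norm <- orbital_norm(orb)
  if (!is.finite(orb$norm) || orb$norm <= 0) {
    stop("orbital norm must be finite and positive")
  }
  orb
}

#' @export
print.dyson_orbital <- function(x, ...) {
  cat(sprintf("<dyson_orbital> %d primitives, norm %.6g%s\n",
              nrow(x$primitives), x$norm,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

# 1-D Obara-Saika overlap <(u-A)^l1 e^{-a(u-A)^2} | (u-B)^l2 e^{-b(u-B)^2}>
# including the Gaussian prefactor for this dimension.
overlap1d <- function(l1, l2, A, B, a, b) {
  p <- a + b
  mu <- a * b / p
  P <- (a * A + b * B) / p
  S <- matrix(0, l1 + 1, l2 + 1)
  S[1, 1] <- sqrt(pi / p) * exp(-mu * (A - B)^2)
  if (l1 >= 1) {
    S[2, 1] <- (P - A) * S[1, 1]
    if (l1 >= 2) {
      for (i in 2:l1) {
        S[i + 1, 1] <- (P - A) * S[i, 1] + (i - 1) / (2 * p) * S[i - 1, 1]
      }
    }
  }
  if (l2 >= 1) {
    for (j in 1:l2) {
      for (i in 0:l1) {
        S[i + 1, j + 1] <- (P - B) * S[i + 1, j] +
          (if (i >= 1) i / (2 * p) * S[i, j] else 0) +
          (if (j >= 2) (j - 1) / (2 * p) * S[i + 1, j - 1] else 0)
      }
    }
  }
  S[l1 + 1, l2 + 1]
}

# overlap of two primitive Cartesian Gaussians (unit coefficients)
primitive_overlap <- function(p1, p2) {
  overlap1d(p1$lx, p2$lx, p1$cx, p2$cx, p1$alpha, p2$alpha) *
    overlap1d(p1$ly, p2$ly, p1$cy, p2$cy, p1$alpha, p2$alpha) *
    overlap1d(p1$lz, p2$lz, p1$cz, p2$cz, p1$alpha, p2$alpha)
}

#' Norm of a Dyson orbital by analytic Gaussian overlap
#'
#' @param orb a [dyson_orbital()] (or a bare primitive table)
#' @return `sqrt(<psi|psi>)`
#' @export
orbital_norm <- function(orb) {
  p <- if (inherits(orb, "dyson_orbital")) orb$primitives else as.data.frame(orb)
  n <- nrow(p)
  s2 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s2 <- s2 + p$coeff[i] * p$coeff[j] *
        primitive_overlap(p[i, ], p[j, ])
    }
  }
  sqrt(s2)
}

# expand (w1 x + w2 y + w3 z)^l into monomials; returns data.frame(lx,ly,lz,c)
expand_linear_power <- function(w, l) {
  terms <- data.frame(lx = 0L, ly = 0L, lz = 0L, c = 1)
  if (l == 0) return(terms)
  for (rep in seq_len(l)) {
    new <- do.call(rbind, lapply(seq_len(nrow(terms)), function(i) {
      data.frame(
        lx = terms$lx[i] + c(1L, 0L, 0L),
        ly = terms$ly[i] + c(0L, 1L, 0L),
        lz = terms$lz[i] + c(0L, 0L, 1L),
        c = terms$c[i] * w)
    }))
    terms <- stats::aggregate(c ~ lx + ly + lz, new, sum)
  }
  terms[terms$c != 0, , drop = FALSE]
}

#' Apply a rigid rotation to a Dyson orbital
#'
#' Rotates both the primitive centres and the Cartesian angular parts, i.e.
#' returns the expansion of `psi(R^T r)` for a rotation matrix `R`.  The norm
#' and any orientation-averaged observable are invariant under this map.
#'
#' @param orb a [dyson_orbital()]
#' @param R 3x3 orthogonal rotation matrix
#' @return rotated [dyson_orbital()]
#' @export
rotate_orbital <- function(orb, R) {
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8) {
    stop("R must be orthogonal")
  }
  p <- orb$primitives
  out <- list()
  for (i in seq_len(nrow(p))) {
    centre <- as.numeric(R %*% c(p$cx[i], p$cy[i], p$cz[i]))
    # (R^T r)_d = sum_j R[j, d] r_j
    ex <- expand_linear_power(R[, 1], p$lx[i])
    ey <- expand_linear_power(R[, 2], p$ly[i])
    ez <- expand_linear_power(R[, 3], p$lz[i])
    for (a in seq_len(nrow(ex))) {
      for (b in seq_len(nrow(ey))) {
        for (d in seq_len(nrow(ez))) {
          out[[length(out) + 1]] <- data.frame(
            cx = centre[1], cy = centre[2], cz = centre[3],
            lx = ex$lx[a] + ey$lx[b] + ez$lx[d],
            ly = ex$ly[a] + ey$ly[b] + ez$ly[d],
            lz = ex$lz[a] + ey$lz[b] + ez$lz[d],
            alpha = p$alpha[i],
            coeff = p$coeff[i] * ex$c[a] * ey$c[b] * ez$c[d])
        }
      }
    }
  }
  prim <- do.call(rbind, out)
  prim <- stats::aggregate(coeff ~ cx + cy + cz + lx + ly + lz + alpha,
                           prim, sum)
  dyson_orbital(prim, label = orb$label)
}

# normalisation constant of a primitive Cartesian Gaussian
gto_norm_const <- function(alpha, lx, ly, lz) {
  dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))
  L <- lx + ly + lz
  (2 * alpha / pi)^0.75 * (4 * alpha)^(L / 2) /
    sqrt(dfact(2 * lx - 1) * dfact(2 * ly - 1) * dfact(2 * lz - 1))
}

#' Read a Dyson orbital
#'
#' Two dialects are supported.  `"json"` is a plain list of primitives:
#' `{"label": ..., "primitives": [{"centre": [x,y,z] (bohr), "l": [lx,ly,lz],
#' "alpha": ..., "coeff": ...}, ...]}`.  `"molden_subset"` is a restricted
#' Molden file with `[Atoms]`, `[GTO]` and `[MO]` sections, Cartesian s/p/d
#' shells only, from which one MO is selected by index; each Cartesian
#' component is normalised individually and d components are ordered
#' xx, yy, zz, xy, xz, yz.
#'
#' @param path file path
#' @param dialect `"json"` or `"molden_subset"`
#' @param mo_index which MO to take from a Molden file (default 1)
#' @return a [dyson_orbital()]
#' @export
read_orbital <- function(path, dialect = c("json", "molden_subset"),
                         mo_index = 1L) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    prims <- obj$primitives
    if (is.null(prims) || length(prims) == 0) {
      stop("orbital file contains zero primitives")
    }
    p <- do.call(rbind, lapply(prims, function(q) {
      data.frame(cx = q$centre[[1]], cy = q$centre[[2]], cz = q$centre[[3]],
                 lx = q$l[[1]], ly = q$l[[2]], lz = q$l[[3]],
                 alpha = q$alpha, coeff = q$coeff)
    }))
    dyson_orbital(p, label = if (is.null(obj$label)) "" else obj$label)
  } else {
    read_molden_subset(path, mo_index)
  }
}

#' Write a Dyson orbital in the JSON dialect
#' @param orb a [dyson_orbital()]
#' @param path output path
#' @export
write_orbital_json <- function(orb, path) {
  p <- orb$primitives
  prims <- lapply(seq_len(nrow(p)), function(i) {
    list(centre = c(p$cx[i], p$cy[i], p$cz[i]),
         l = c(p$lx[i], p$ly[i], p$lz[i]),
         alpha = p$alpha[i], coeff = p$coeff[i])
  })
  jsonlite::write_json(list(label = orb$label, primitives = prims), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_molden_subset <- function(path, mo_index) {
  lines <- readLines(path, warn = FALSE)
  secline <- grepl("^\\s*\\[", lines)
  secname <- tolower(gsub(".*\\[(.*)\\].*", "\\1", lines))
  find_sec <- function(name) {
    hits <- which(secline & secname == name)
    if (length(hits) == 0) stop(sprintf("Molden file missing [%s] section",
                                        name))
    hits[1]
  }
  sec_body <- function(start) {
    nxt <- which(secline & seq_along(lines) > start)
    end <- if (length(nxt)) min(nxt) - 1 else length(lines)
    lines[seq(start + 1, end)]
  }
  atoms_start <- find_sec("atoms")
  unit <- if (grepl("au", tolower(lines[atoms_start]))) 1 else
    1 / BOHR_ANGSTROM  # convert Angstrom to bohr
  atoms <- lapply(sec_body(atoms_start), function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(tok) < 6) stop("malformed [Atoms] line: ", l)
    list(idx = as.integer(tok[2]), xyz = as.numeric(tok[4:6]) * unit)
  })
  centres <- lapply(atoms, `[[`, "xyz")
  names(centres) <- vapply(atoms, function(a) as.character(a$idx), "")

  # [GTO]: blocks "atom_index 0", then "shell nprim 1.00", then prim rows
  gto <- sec_body(find_sec("gto"))
  gto <- gto[nzchar(trimws(gto))]
  shells <- list()
  i <- 1
  while (i <= length(gto)) {
    tok <- strsplit(trimws(gto[i]), "\\s+")[[1]]
    atom <- as.integer(tok[1])
    i <- i + 1
    while (i <= length(gto)) {
      tok <- strsplit(trimws(gto[i]), "\\s+")[[1]]
      if (length(tok) >= 2 && grepl("^[A-Za-z]+$", tok[1])) {
        type <- tolower(tok[1])
        nprim <- as.integer(tok[2])
        if (!type %in% c("s", "p", "d")) {
          stop(sprintf("unsupported shell type '%s': only Cartesian s/p/d %s",
                       type, "shells are handled"))
        }
        rows <- gto[i + seq_len(nprim)]
        expo <- t(vapply(rows, function(l) {
          as.numeric(strsplit(trimws(gsub("[dD]", "e", l)), "\\s+")[[1]][1:2])
        }, numeric(2)))
        shells[[length(shells) + 1]] <- list(atom = atom, type = type,
                                             alpha = expo[, 1],
                                             contr = expo[, 2])
        i <- i + 1 + nprim
      } else if (length(tok) >= 1 && grepl("^[0-9]+$", tok[1])) {
        break  # next atom block
      } else {
        i <- i + 1
      }
    }
  }
  if (length(shells) == 0) stop("Molden file contains zero primitives")

  cart_components <- list(
    s = list(c(0L, 0L, 0L)),
    p = list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)),
    d = list(c(2L, 0L, 0L), c(0L, 2L, 0L), c(0L, 0L, 2L),
             c(1L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 1L)))

  # [MO]: take the mo_index-th "Occup=" block's coefficient list
  mo <- sec_body(find_sec("mo"))
  coef_starts <- grep("occup", tolower(mo))
  if (length(coef_starts) < mo_index) {
    stop(sprintf("Molden file has %d MOs, requested index %d",
                 length(coef_starts), mo_index))
  }
  from <- coef_starts[mo_index] + 1
  to <- if (mo_index < length(coef_starts)) {
    # back up over the next MO's header lines (Sym=/Ene=/Spin=/Occup=)
    hdr <- grep("=", mo)
    min(hdr[hdr > from & hdr <= coef_starts[mo_index + 1]]) - 1
  } else length(mo)
  rows <- mo[seq(from, to)]
  rows <- rows[grepl("^\\s*[0-9]+\\s", rows)]
  mo_coef <- vapply(rows, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2])
  }, 0)

  prim <- list()
  ib <- 0
  for (sh in shells) {
    ctr <- centres[[as.character(sh$atom)]]
    if (is.null(ctr)) stop("GTO block references unknown atom ", sh$atom)
    for (comp in cart_components[[sh$type]]) {
      ib <- ib + 1
      if (ib > length(mo_coef)) {
        stop("MO coefficient list shorter than the basis")
      }
      if (mo_coef[ib] == 0) next  # basis function absent from this MO
      for (ip in seq_along(sh$alpha)) {
        a <- sh$alpha[ip]
        nrm <- gto_norm_const(a, comp[1], comp[2], comp[3])
        prim[[length(prim) + 1]] <- data.frame(
          cx = ctr[1], cy = ctr[2], cz = ctr[3],
          lx = comp[1], ly = comp[2], lz = comp[3], alpha = a,
          coeff = mo_coef[ib] * sh$contr[ip] * nrm)
      }
    }
  }
  dyson_orbital(do.call(rbind, prim), label = sprintf("MO%d", mo_index))
}
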