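#' Photon-energy and state-gap bookkeeping for feature assignment
#'
#' Collects the pump and probe photon energies, the vertical detachment
#' energy at the Franck-Condon geometry, and per-geometry energetics: the
#' vertical D0-S1 gap (which bounds the electron kinetic energy available
#' to the probe) and the S1 energy relative to S0 at the Franck-Condon
#' point (which fixes the vibrational energy left above each local
#' minimum).
#'
#' @param hv_pump,hv_probe photon energies (eV, > 0)
#' @param vde vertical detachment energy at the FC geometry (eV, > 0)
#' @param geometries named list; each entry a list with `gap_d0_s1` and
#'   `e_s1` (eV)
#' @return object of class `energetics_model`
#' @export
energetics_model <- function(hv_pump, hv_probe, vde, geometries) {
  stopifnot(hv_pump > 0, hv_probe > 0, vde > 0, length(geometries) >= 1,
            !is.null(names(geometries)))
  for (nm in names(geometries)) {
    gg <- geometries[[nm]]
    if (is.null(gg$gap_d0_s1) || is.null(gg$e_s1)) {
      stop("each geometry entry needs gap_d0_s1 and e_s1 (eV)")
    }
  }
  structure(list(hv_pump = hv_pump, hv_probe = hv_probe, vde = vde,
                 geometries = geometries),
            class = "energetics_model")
}

#' Energetics model of the packaged fixture configuration
#' @param cfg configuration list (its `energetics` section is used)
#' @return an [energetics_model()]
#' @export
fixture_energetics <- function(cfg = pck_fixture()) {
  e <- cfg$energetics
  energetics_model(e$hv_pump, e$hv_probe, e$vde, e$geometries)
}

#' Maximum electron kinetic energy for two-photon detachment at the
#' Franck-Condon geometry
#'
#' `eps_FC = hv_pump + hv_probe - VDE`.  If the photon energies do not
#' exceed the detachment energy the two-photon channel is closed and the
#' result is flagged.
#'
#' @param model an [energetics_model()]
#' @return list with `eps_fc` (eV) and `channel_open` flag
#' @export
epsilon_max_fc <- function(model) {
  stopifnot(inherits(model, "energetics_model"))
  eps <- model$hv_pump + model$hv_probe - model$vde
  list(eps_fc = max(eps, 0), channel_open = eps > 0,
       raw = eps)
}

#' Predicted photoelectron energy range for a critical-point geometry
#'
#' The probe maps the S1 population at a geometry onto D0, so signal
#' extends to `eps_hi = hv_probe - gap(geometry)`.  Because the potential
#' energy at a local minimum lies below the initial excitation energy, the
#' spectral maximum is shifted down by up to the available vibrational
#' energy `E_vib = hv_pump - E_S1(geometry)`, giving
#' `eps_lo = max(eps_hi - E_vib, 0)`.  A gap exceeding the probe photon
#' energy closes the channel.
#'
#' @param model an [energetics_model()]
#' @param label geometry label present in the model
#' @return list with `eps_lo`, `eps_hi` (eV), `e_vib` and `channel_open`
#' @export
epsilon_range_geom <- function(model, label) {
  stopifnot(inherits(model, "energetics_model"))
  gg <- model$geometries[[label]]
  if (is.null(gg)) {
    stop(sprintf("no energetics entry for geometry '%s' (have: %s)", label,
                 paste(names(model$geometries), collapse = ", ")))
  }
  eps_hi <- model$hv_probe - gg$gap_d0_s1
  e_vib <- model$hv_pump - gg$e_s1
  if (eps_hi <= 0) {
    return(list(eps_lo = 0, eps_hi = 0, e_vib = e_vib,
                channel_open = FALSE))
  }
  list(eps_lo = max(eps_hi - max(e_vib, 0), 0), eps_hi = eps_hi,
       e_vib = e_vib, channel_open = TRUE)
}

#' Assign measured photoelectron features to candidate geometries
#'
#' A feature is energetically compatible with a candidate geometry when its
#' measured peak centre lies within the candidate's predicted energy range
#' widened by the calculation uncertainty `delta_ev` on both sides.  Among
#' candidates, the ranking is lexicographic: energetic compatibility first,
#' then the anisotropy deviation `|beta2_meas - beta2_model|` divided by
#' the combined uncertainty; ties break deterministically by candidate
#' label order.
#'
#' @param features data frame with columns `label`, `centre_ev`,
#'   `width_ev`, `beta2`, `beta2_unc`
#' @param candidates data frame with columns `label`, `beta2_model` and
#'   optionally `beta2_model_unc` (defaults 0); energy ranges are taken
#'   from `model`
#' @param model an [energetics_model()]
#' @param delta_ev compatibility margin (eV), the stated uncertainty of
#'   the electronic-structure energies
#' @return object of class `assignment_report`: per-pair score table and
#'   per-feature ranked assignment
#' @export
assign_features <- function(features, candidates, model, delta_ev = 0.2) {
  stopifnot(nrow(features) >= 1, nrow(candidates) >= 1,
            inherits(model, "energetics_model"))
  if (is.null(candidates$beta2_model_unc)) candidates$beta2_model_unc <- 0
  rows <- list()
  for (fi in seq_len(nrow(features))) {
    f <- features[fi, ]
    for (ci in seq_len(nrow(candidates))) {
      cd <- candidates[ci, ]
      rng <- epsilon_range_geom(model, cd$label)
      compatible <- rng$channel_open &&
        f$centre_ev >= rng$eps_lo - delta_ev &&
        f$centre_ev <= rng$eps_hi + delta_ev
      comb <- sqrt(f$beta2_unc^2 + cd$beta2_model_unc^2)
      dev <- abs(f$beta2 - cd$beta2_model) / max(comb, 1e-12)
      rows[[length(rows) + 1]] <- data.frame(
        feature = f$label, candidate = cd$label,
        centre_ev = f$centre_ev, eps_lo = rng$eps_lo, eps_hi = rng$eps_hi,
        compatible = compatible, beta2_meas = f$beta2,
        beta2_model = cd$beta2_model, beta2_deviation = dev)
    }
  }
  scores <- do.call(rbind, rows)
  ranking <- lapply(split(scores, scores$feature), function(d) {
    d[order(!d$compatible, d$beta2_deviation, d$candidate), ]
  })
  structure(list(scores = scores, ranking = ranking, delta_ev = delta_ev),
            class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  for (nm in names(x$ranking)) {
    top <- x$ranking[[nm]][1, ]
    cat(sprintf(
      "feature %-8s -> %-4s (%s, beta2 dev %.2f sigma)\n", nm,
      top$candidate,
      if (top$compatible) "energetically compatible" else "NO compatible match",
      top$beta2_deviation))
  }
  invisible(x)
}
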