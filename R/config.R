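#' Default run configuration
#'
#' Nested list with `generator`, `inversion`, `analysis` and `energetics`
#' sections.  The defaults are the packaged `pck_fixture` world: a wavepacket
#' with a 400 fs period and 400 fs coherence damping, a 120 ps S1 population
#' lifetime, the moving photoelectron peak travelling from 1.4 eV (planar
#' minimum, PM) to 0.8 eV (single-bond rotated minimum, SB), endpoint
#' anisotropies beta2 = -0.36 (PM) and -0.11 (SB), a static low-energy
#' channel near 0.1 eV, a 100 fs FWHM Gaussian instrument response, Poisson
#' counting noise and a delay-independent background present at t < 0.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    generator = list(
      period_fs = 400,          # wavepacket period T
      tau_damp_fs = 400,        # coherence damping; one visible oscillation
      lifetime_ps = 120,        # S1 population lifetime
      eps_pm_centre = 1.4,      # moving-peak centre at the PM geometry (eV)
      eps_sb_centre = 0.8,      # moving-peak centre at the SB geometry (eV)
      peak_width_ev = 0.17,     # Gaussian sigma of the moving peak
      beta2_pm = -0.36,         # endpoint anisotropy at PM
      beta2_sb = -0.11,         # endpoint anisotropy at SB
      eps3_centre = 0.10,       # static low-energy channel centre (eV)
      eps3_width_ev = 0.045,
      eps3_rel_amp = 0.12,      # area relative to the moving peak at t = 0
      bg_amp = 0.08,            # t < 0 background area, same relative scale
      bg_scale_ev = 0.30,       # background spectral decay constant
      irf_fwhm_fs = 100,
      k_cal = 1.4e-4,           # energy calibration (eV / pixel^2)
      image_size = 256,
      n_electrons = 5e5,        # electrons in the brightest frame
      seed = 20200604,
      delays_fs = NULL          # NULL = pck_delays()
    ),
    inversion = list(
      n_theta = 128,
      r_max = NULL,             # NULL = largest radius inside the image
      freeze_beta4 = FALSE
    ),
    analysis = list(
      window_eps1 = c(1.15, 1.65),
      window_eps2 = c(0.55, 1.05),
      window_eps3 = c(0.02, 0.25),
      mask_threshold = 0.1,
      smooth_window = 5
    ),
    energetics = list(
      hv_pump = 2.79,
      hv_probe = 1.55,
      vde = 2.94,
      delta_ev = 0.2,           # compatibility margin (calc. uncertainty)
      geometries = list(
        FC = list(gap_d0_s1 = 0.15, e_s1 = 2.79),
        PM = list(gap_d0_s1 = 0.21, e_s1 = 2.73),
        SB = list(gap_d0_s1 = 0.68, e_s1 = 2.35),
        DB = list(gap_d0_s1 = 1.34, e_s1 = 2.55)
      )
    )
  )
}

#' Delay grid of the packaged fixture
#'
#' 40 dense delays from -0.3 to 1.2 ps; optionally extended with 12 sparse
#' frames from 5 to 400 ps (log-spaced) for lifetime extraction.
#'
#' @param long include the sparse long-delay frames
#' @return numeric vector of delays in fs, strictly increasing
#' @export
pck_delays <- function(long = FALSE) {
  dense <- seq(-300, 1200, length.out = 40)
  if (!long) return(dense)
  c(dense, exp(seq(log(5000), log(4e5), length.out = 12)))
}

#' The packaged fixture configuration
#'
#' @param long_delays include sparse long delays in the generator delay list
#' @return configuration list (see [default_config()])
#' @export
pck_fixture <- function(long_delays = FALSE) {
  cfg <- default_config()
  cfg$generator$delays_fs <- pck_delays(long = long_delays)
  cfg
}

config_key_paths <- function(x, prefix = character(0)) {
  out <- character(0)
  for (nm in names(x)) {
    here <- c(prefix, nm)
    out <- c(out, paste(here, collapse = "."))
    if (is.list(x[[nm]]) && !is.null(names(x[[nm]])) && nm != "geometries") {
      out <- c(out, config_key_paths(x[[nm]], here))
    }
  }
  out
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected with a suggestion of the closest valid key;
#' missing keys are filled with the [default_config()] values, so an empty
#' file yields the all-defaults configuration.
#'
#' @param path YAML file path
#' @return fully-resolved configuration list
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(default_config())
  defaults <- default_config()
  valid <- config_key_paths(defaults)
  check <- function(x, prefix = character(0)) {
    for (nm in names(x)) {
      key <- paste(c(prefix, nm), collapse = ".")
      if (!key %in% valid) {
        sug <- agrep(key, valid, max.distance = 0.3, value = TRUE)
        stop(sprintf("unknown configuration key '%s'%s. Valid keys: %s", key,
                     if (length(sug)) paste0(" (did you mean '", sug[1], "'?)")
                     else "",
                     paste(valid, collapse = ", ")))
      }
      if (is.list(x[[nm]]) && !is.null(names(x[[nm]])) &&
          !identical(nm, "geometries")) {
        check(x[[nm]], c(prefix, nm))
      }
    }
  }
  check(user)
  merge_cfg <- function(def, usr) {
    for (nm in names(usr)) {
      if (is.list(usr[[nm]]) && !is.null(names(usr[[nm]])) &&
          is.list(def[[nm]])) {
        def[[nm]] <- merge_cfg(def[[nm]], usr[[nm]])
      } else {
        def[[nm]] <- usr[[nm]]
      }
    }
    def
  }
  cfg <- merge_cfg(defaults, user)
  # YAML sequences arrive as lists; flatten the numeric-vector keys
  if (!is.null(cfg$generator$delays_fs)) {
    cfg$generator$delays_fs <- as.numeric(unlist(cfg$generator$delays_fs))
  }
  for (w in c("window_eps1", "window_eps2", "window_eps3")) {
    cfg$analysis[[w]] <- as.numeric(unlist(cfg$analysis[[w]]))
  }
  cfg
}
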