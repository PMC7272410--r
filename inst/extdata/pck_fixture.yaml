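# Packaged fixture: synthetic stand-in for the published pump-probe
# photoelectron imaging experiment on the PYP chromophore anion.
# All values are the package defaults; this file exists so that
# read_config() on the packaged configuration loads without edits.
generator:
  period_fs: 400          # wavepacket period
  tau_damp_fs: 400        # coherence damping (single visible oscillation)
  lifetime_ps: 120        # S1 population lifetime
  eps_pm_centre: 1.4      # early-time peak centre (eV)
  eps_sb_centre: 0.8      # late-time peak centre (eV)
  peak_width_ev: 0.17
  beta2_pm: -0.36         # early-time feature anisotropy
  beta2_sb: -0.11         # late-time feature anisotropy
  eps3_centre: 0.10
  eps3_width_ev: 0.045
  eps3_rel_amp: 0.12
  bg_amp: 0.08
  bg_scale_ev: 0.30
  irf_fwhm_fs: 100        # instrument response (FWHM)
  k_cal: 1.4e-4           # eV per pixel^2
  image_size: 256
  n_electrons: 5.0e5
  seed: 20200604
inversion:
  n_theta: 128
  freeze_beta4: false
analysis:
  window_eps1: [1.15, 1.65]
  window_eps2: [0.55, 1.05]
  window_eps3: [0.02, 0.25]
  mask_threshold: 0.1
  smooth_window: 5
energetics:
  hv_pump: 2.79
  hv_probe: 1.55
  vde: 2.94
  delta_ev: 0.2
  geometries:
    FC: {gap_d0_s1: 0.15, e_s1: 2.79}
    PM: {gap_d0_s1: 0.21, e_s1: 2.73}
    SB: {gap_d0_s1: 0.68, e_s1: 2.35}
    DB: {gap_d0_s1: 1.34, e_s1: 2.55}
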