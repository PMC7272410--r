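---
title: "Models and numerical choices in trpes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in trpes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`trpes` implements the analysis chain of a pump-probe photoelectron
velocity-map imaging (VMI) experiment on an isolated model chromophore
anion of the photoactive yellow protein, whose S1 excited state isomerises
by rotation about a single bond.  The package covers five connected
pieces: (i) a synthetic VMI image-stack generator driven by a 1-D
wavepacket model, (ii) polar onion peeling inversion of the 2-D
projections with Legendre angular decomposition, (iii) assembly and
quantification of time/energy-resolved spectral and anisotropy maps,
(iv) a plane-wave Dyson-orbital model of photoelectron angular
distributions (PADs), and (v) linear interpolation in internal
coordinates (LIIC) with the photon-energy bookkeeping used to assign
spectral features to molecular geometries.  Electronic-structure theory
itself (CASSCF/XMCQDPT2/EOM-CCSD) is out of scope; its outputs enter only
as data (state gaps, fixture orbitals).

# The angular model

One-photon detachment with linearly polarised light produces the
laboratory-frame distribution

$$I(\varepsilon,\theta) = \frac{\sigma}{4\pi}\left[1 +
\beta_2(\varepsilon) P_2(\cos\theta) + \beta_4(\varepsilon)
P_4(\cos\theta)\right],$$

with $\theta$ measured from the polarisation axis.  $\beta_2 = +2$
corresponds to emission parallel to the polarisation, $-1$ to
perpendicular, $0$ to isotropic.  `legendre_fit()` performs the weighted
least-squares projection onto $\{P_0, P_2, P_4\}$; `pop_invert()` applies
it ring by ring.

# The wavepacket world of the synthetic generator

The generator's defaults are the stated conditions of the experiment it
emulates, not tuning knobs:

| parameter | default | origin |
|---|---|---|
| period `T` | 400 fs | observed oscillation period |
| coherence damping `tau_d` | 400 fs | "a single oscillation" is visible; free choice, documented |
| S1 lifetime `tau` | 120 ps | observed decay of the late-time peak |
| peak centres | 1.4 -> 0.8 eV | observed early/late peak positions |
| endpoint `beta2` | -0.36 / -0.11 | measured feature-averaged anisotropies |
| IRF FWHM | 100 fs | instrument response |
| low-energy channel `eps3` | 0.10 eV, rel. amplitude 0.12 | phenomenological; amplitude is a free choice set so the moving peak remains the global maximum of the map, as in the measured spectra |
| background | exp(-eps/0.3 eV), rel. amplitude 0.08 | probe-only counts present at all delays; free choice |
| peak width | 0.17 eV (sigma) | consistent with the ~5 % energy resolution and the measured widths |
| calibration `k_cal` | 1.4e-4 eV/px^2, 256 px images | places the 2 eV window inside the detector with ~0.02 eV/px at 0.8 eV |
| electrons/frame | 5e5 | stated synthetic-benchmark scale |

The reaction coordinate is dimensionless: $q = 0$ at the planar S1
minimum (PM), $q = 1$ at the single-bond rotated minimum (SB),

$$q(t) = 1 - \cos^2(\pi t/T)\,e^{-t/\tau_d}, \qquad t \ge 0 .$$

In the undamped limit this is $\sin^2(\pi t/T)$: the packet leaves PM at
$t=0$, reaches SB at $T/2$ and returns at $T$.  With damping it settles
at the SB minimum, which is what the experiment shows: the photoelectron
peak moves from 1.4 eV to 0.8 eV and stays there while the S1 population
decays over ~120 ps.  (A damped $\sin^2$ form that returned the packet to
PM would contradict the observed late-time spectrum and make the lifetime
invisible in the 0.55-1.05 eV window; this is the one deliberate design
deviation in the package, made in favour of the observed phenomenology.)

The spectrum at coordinate $q$ is a Gaussian peak at
$(1-q)\,1.4 + q\,0.8$ eV whose anisotropy interpolates linearly between
the endpoint values — the adiabatic assumption that the electronic
structure follows the nuclear coordinate instantaneously.  All
time-dependent amplitudes (population, coherence, low-energy channel) are
convolved with the Gaussian IRF at the amplitude level; images themselves
are never blurred, because pump-probe delay is the only time axis.
Counting noise is Poisson per pixel with a per-frame seed derived from the
configured seed, so a configuration is bit-reproducible.

# Forward projection and polar onion peeling

Each energy bin is a spherical shell at radius $r = \sqrt{\varepsilon /
k_\mathrm{cal}}$.  A shell of unit content occupying $[R-\tfrac12,
R+\tfrac12]$ px has the closed-form line-of-sight projection

$$P(\rho, z) = \frac{1}{2\pi}\,[1 + \beta_2 P_2(z/R) + \beta_4
P_4(z/R)]\;\frac{1}{\rho}\left[\arccos\frac{\rho}{R+\frac12} -
\arccos\frac{\rho}{\max(R-\frac12,\rho)}\right],$$

which integrates to exactly one over the image plane; discretisation on
pixel centres conserves counts to ~1e-3.  The inversion resamples the
image onto a polar grid (bilinear, four-quadrant averaged, 128 angular
bins over $[0, \pi/2]$, 1 px radial steps) and peels from the outermost
ring inward: fit the residual ring with $\{P_0,P_2,P_4\}(\cos\theta)$,
record $(S, \beta_2, \beta_4)$, subtract the shell's own projection from
all interior rings using the same closed-form basis.  Negative shell
intensities are clipped at zero (the clip fraction is logged) because
unbounded negative shells corrupt all interior rings under noise.
Round-trip accuracy on noiseless 512 px images is
$\mathrm{MAE}(\beta_2) < 10^{-3}$ where the signal exceeds 10 % of its
maximum — comfortably inside the 0.05 contract the tests enforce.

# Transient fitting

Window traces are fitted with

$$s(t) = \left[a\,e^{-t/\tau_d}\cos(2\pi t/T - \phi) + c_1 e^{-t/\tau} +
c_0\right]\Theta(t) \otimes G_\mathrm{IRF},$$

using variable projection: for each trial of the nonlinear parameters
$(\tau_d, T, \tau)$ the four linear amplitudes are solved exactly, with a
multi-start over eight period guesses.  The exponential and step terms
are convolved with the Gaussian analytically, the oscillatory term by
Gauss-Legendre quadrature.  A vanishing ridge (~1e-9 relative) on the
oscillation amplitudes selects the zero-amplitude solution when the
cosine is degenerate with the exponential terms (oscillation-free
traces).  Oscillation fits use delays up to 2 ps so the slow population
decay cannot distort the damped-cosine model; the lifetime is fitted
separately on the sparse long delays as a single exponential plus offset.
Uncertainties come from the numerical Jacobian at the optimum.  Because
the window response to the moving peak is not perfectly sinusoidal, the
recovered period carries a small systematic (~4-5 % low on the packaged
fixture), well inside the 10 % contract.

# Plane-wave Dyson-orbital PADs

The Dyson orbital — the one-electron wavefunction of the detached
electron — is a sum of Cartesian Gaussians.  With the outgoing electron
treated as a plane wave and the dipole in length gauge, the matrix
element $M = \langle e^{i\mathbf{k}\cdot\mathbf{r}}|\hat e \cdot
\mathbf{r}|\Psi_D\rangle$ is evaluated in closed form (1-D Fourier
integrals of Gaussians by recursion; a real-space quadrature oracle
verifies them in the tests).  For isotropic orientations the lab-frame
PAD is obtained by resolving $|\hat e\cdot\mathbf{V}(\mathbf{k})|^2$ into
components parallel and perpendicular to $\hat k$, whose azimuthal
average over polarisation directions is analytic, giving
$I(\theta) = \langle A\rangle \cos^2\theta + \langle B\rangle
\sin^2\theta$ exactly — hence $\beta_2 \in [-1, 2]$ and $\beta_4 = 0$ by
construction.  The remaining average over emission directions uses a
Gauss-Legendre (polar) x uniform (azimuth) product grid; no Lebedev
tables are available in the target environment, and the product rule
integrates these band-limited integrands exactly, with tolerance-driven
refinement available (`check_convergence`).  An independent explicit
SO(3) rotation average (`averaging = "so3"`) agrees with the default
route to 1e-6 and serves as the cross-check.  Energies use atomic units
with $\varepsilon = k^2/2$; the cross-section includes the
density-of-states factor $k$, which leaves $\beta_2$ untouched.

The packaged fixture orbitals are *synthetic stand-ins* (the published
EOM-CCSD Dyson orbitals are not printed in any source available to the
package): a three-centre out-of-plane p-combination with a +/-/+ node
pattern as the planar pi-like orbital, and two perpendicular p functions
on separated centres as the twisted, delocalised one.  They reproduce the
qualitative discrimination — planar pi gives $\beta_2 < 0$ over
0.2-1.5 eV, twisted gives $|\beta_2| \le 0.15$ — not the published
per-geometry values.

# LIIC and energetic assignment

Geometries interconvert with internal (Z-matrix) coordinates by NeRF
placement; linear interpolation acts on bonds, angles, and dihedrals,
the latter along the shorter angular arc with wrap at 180 degrees (an
explicit direction override exists for near-ambiguous arcs).  No
reoptimisation is performed, so pathways are geometric interpolations,
not minimum-energy paths.  The packaged PM/SB endpoint files are
synthetic six-atom stand-ins for the chromophore tail on which the
single-bond dihedral sweeps 180 -> 92 degrees while the double-bond
dihedral stays planar within 3 degrees.

Energetics: with pump/probe photon energies $h\nu_1, h\nu_2$ and the
vertical detachment energy VDE, the two-photon limit is
$\varepsilon_{FC} = h\nu_1 + h\nu_2 - \mathrm{VDE}$ (1.40 eV for the
packaged table).  Per geometry, signal extends to $\varepsilon_{hi} =
h\nu_2 - \Delta(D_0 - S_1)$ and the maximum is displaced down by at most
the vibrational energy $E_\mathrm{vib} = h\nu_1 - E_{S_1}$ available
above the local minimum — the natural reading of the published bound
derivation, which the source states only qualitatively.  Since absolute
multireference energies are not published, the packaged table stores the
printed photon energies, VDE and kinetic-energy limits with gaps
back-derived from them; the table is data, not computation.  Feature
assignment is lexicographic: energetic compatibility within the stated
0.2 eV calculation uncertainty first, then the anisotropy deviation in
combined standard errors, with deterministic label-order tie-breaks.

# What a green test establishes (and what it does not)

The generator emulates the *statistical structure* of the measured data:
peak positions and motion, antiphase window oscillations, IRF-limited
rise, Poisson noise, a static background, and a phenomenological
low-energy channel.  It does not model autodetachment, the D1 channel's
electronic structure, double-bond-pathway dynamics, vibrational
structure, or detector artefacts.  End-to-end recovery therefore
validates the analysis chain — inversion, windowing, fitting,
anisotropy averaging — against a known ground truth at realistic counting
statistics; it does not re-derive the published physics from raw data.
Similarly, the plane-wave PAD model ignores the electron-neutral
interaction (the neutral core has a large dipole moment, so computed
anisotropies are trends rather than exact predictions), and the packaged
orbital and geometry fixtures are labelled synthetic stand-ins
throughout.

# Numerical choices

* Lengths: bohr for orbital mathematics, Angstrom in geometry files
  (0.52917721067 A/bohr); energies in eV externally, hartree internally
  (27.211386 eV/hartree).
* Image convention: pixel (0,0) top-left, x rightward, y downward,
  polarisation along the image vertical, fractional centres allowed.
* IRF convolutions: analytic for exponential/step terms, 24-40 node
  Gauss-Legendre for oscillatory/composite integrands over a +/-5 sigma
  window.
* Background estimate: mean of all t < 0 frames (at least two required).
* Config: YAML with defaults filled; unknown keys rejected with a
  closest-match suggestion.  Image stacks: HDF5, one group per delay.
* Degenerate inputs: all-zero angular slices are flagged rather than
  thrown; traces without resolvable decay report an unbounded-lifetime
  flag instead of a number; channel-closed energetics are flagged.
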