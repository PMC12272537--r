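---
title: "Modeling kinesin-driven de-mixing in actin-microtubule composites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling kinesin-driven de-mixing in actin-microtubule composites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Active composites of actin filaments and microtubules restructured by kinesin
motor clusters display a striking coupling between structure and mechanics:
motors contract microtubules into dense aggregates, actin is squeezed into
the interstitial space, and the composite's resistance to local deformation
peaks at intermediate motor concentration. `composim` implements the
computational side of that story: a lattice-gas kinetic Monte Carlo (KMC)
simulator, structural pair-correlation and heterogeneity statistics,
in-silico bead microrheology, optical-tweezers force-trace analysis, and a
Kelvin-Voigt circuit model, plus synthetic-data generators so the whole
pipeline is testable without laboratory data.

## The lattice-gas model

Space is a two-dimensional triangular (hexagonally coordinated) lattice on a
periodic torus, 100 x 100 um by default with spacing a = 1.25 um. Each site
holds at most one filament *center* (actin or microtubule); rigid 5-um
filaments interact with neighbours within four grid points (5 um, one
filament length). The default composition mirrors a 45:55 actin:tubulin
molar composite with equal filament lengths: total occupancy 0.35, split
f_A = 0.1575 / f_M = 0.1925. Total occupancy is a design choice (no printed
value exists); 0.35 produces visually percolated but mobile networks and is
overridable in `lattice_params()`.

Kinesin clusters act only between microtubule pairs (kinesin walks on
microtubules; actin feels excluded volume and passive diffusion only). The
concentration mapping goes through the experimental motor ratio
R = c_k / (4 c_T): each microtubule pair within reach carries an engaged
motor with probability `min(5 R, 1)`, refreshed every 0.5 s of simulated
time (motor turnover) and resampled locally whenever a filament moves. An
engaged motor exerts a 5 pN force along the pair's centre-to-centre line and
acts as a crosslink, adding 0.5 pN s/um to the filament's drag.

**Quenched motor polarity.** Whether an engaged motor pulls a given pair
together or pushes it apart is decided once per run and per pair (a salted
hash of the pair id; pull probability 0.5 by default). The sign is a proxy
for the pair's relative polarity, which is fixed for rigid filaments. This
choice matters: if the sign is redrawn at every engagement, pushes and pulls
cancel and no net restructuring occurs at any motor concentration. With
quenched signs, pulling pairs ratchet into contact and stay crosslinked
while pushing pairs separate beyond reach and stop interacting, which is
what produces de-mixing and its monotone growth with c_k.

**Dynamics.** Filament hops to empty nearest-neighbour sites are a Markov
jump process with first-passage drift-diffusion rates

    k = D / a^2 + max(F_par, 0) / (zeta a),    D = k_B T / zeta,

where F_par is the net-force component along the hop and
zeta = zeta_0 + zeta_xl n_crosslinks. Defaults: k_B T = 4.11e-3 pN um (room
temperature), zeta_0 = 0.1 pN s/um (a 5-um rod in a dilute mesh, giving
D ~ 0.04 um^2/s), zeta_xl = 0.5 pN s/um per engaged crosslink. Events are
executed with the Gillespie algorithm (exponential waiting times with mean
1/total rate), so the 5-minute duration is honest simulated clock time, and
crosslink friction progressively arrests aggregates into the quasi-steady
state. Orientation is bookkeeping: a filament aligns with its net force when
that force exceeds 0.1 pN and otherwise performs small random rotations
(0.05 rad per update); orientation does not feed back on the forces, which
act centre-to-centre.

Fully jammed states (no admissible hop anywhere) advance the clock with a
warning rather than failing, so aggregated end states can still be analysed.

## Structural statistics

`pair_distribution()` computes g_ij(r) = N_i(r) / (f_i N(r)) around
reference filaments of kind j, where N(r) is the *exact* per-bin site count
of the lattice geometry (no continuum approximation) and f_i excludes the
reference filament for like pairs, so an ideal random configuration gives
g = 1 in expectation at every r. Distances are binned on a uniform grid of
one lattice spacing; the first bin is r0 = 1.25 um and analysis runs to
25 um. `trajectory_delta_g()` averages g over the final 10% of snapshots
(the quasi-steady tail) and subtracts the t = 0 curve.

Correlation lengths follow two rules shared by the lattice and image
pipelines (`correlation_lengths()`, `sia_lengths()`): l0 is the linearly
interpolated first zero crossing, and the second length is the first strict
sign change of the discrete derivative beyond l0 (ties toward smaller r) —
a local minimum (lmin) for like-pair curves, a maximum (lmax) for unlike
pairs. Curves with no crossing report missing values rather than guesses.

Heterogeneity statistics use the coefficient of variation per tile:
delta = sigma/mean of filament force magnitudes in 20-um hexagonal tiles
(`force_heterogeneity()`), or of pixel intensities in 20 x 20 um square
tiles (`tile_heterogeneity()`). Local heterogeneity h is the mean of delta
over tiles, global heterogeneity H its standard deviation, and patchiness
p = H/h: near zero for well-mixed fields, above one for fields de-mixed on
the tile scale. Tiles with fewer than two filaments are excluded (sigma is
undefined), edge tiles smaller than the full tile size are discarded, and
the force metrics refuse motor-free composites where every force is zero.

## In-silico microrheology

A probe bead (radius 0.625 um) is placed at a uniformly random vacancy of a
quasi-steady composite and forced sinusoidally, F(t) = F0 sin(2 pi f t) with
F0 = 100 pN at f in {0.25, 0.5, 1} Hz for 20 periods. The bead-network
coupling is the package's mechanical closure (the underlying force law is
not observable): linear springs to every filament within the interaction
reach, with stiffness kappa_i = 1 pN/um x (1 + n_crosslinks,i), elastoplastic
slip when an attachment is stretched beyond 2 um (detach/re-anchor, the
dissipation channel), and bead drag 2 pN s/um plus 0.05 pN s/um per unit of
attached stiffness weight. The overdamped dynamics are integrated with an
exponential stepper (exact for the linearized relaxation with the drive
frozen at substep midpoints; substeps chosen automatically for stability),
started on the linear steady-state orbit so no transient contaminates the
spectral estimates.

Displacement amplitude and phase are read off the discrete Fourier component
at the forcing frequency (records are integer numbers of periods; the first
two periods are discarded), and the moduli use the probe-response convention
printed with the study: G' = (F0/x) cos(phi) / r_sph,
G'' = (F0/x) sin(phi) / r_sph, with relative elasticity the inverse loss
tangent G'/G'' normalized by the motor-free value.

## Force-trace analysis and the circuit model

Optical-tweezers recordings (time, stage position, force) are restricted to
the first forward stroke (`segment_first_pull()`): the first contiguous
region of positive stage velocity, rebased to start at zero, with the last
1% of the 20-um stroke (0.2 um) trimmed because the stage reversal is not
instantaneous. Classification (`classify_response()`) smooths the force with
a 1%-of-samples moving average and compares secant stiffnesses over an early
window (10-30% of the stroke, past the <50 ms trap re-equilibration
transient) and a late window (70-100%): the ratio rho = k_late/k_early
labels the trace stiffening above 1.5, yielding below 0.5, elastic between.
The thresholds are declared defaults — no quantitative rule is printed
anywhere — and are exposed as arguments. Classification is exactly invariant
under force rescaling because rho is a stiffness ratio.

Ensembles are averaged on a common 200-point grid over [0, 19.8] um with
linear interpolation; Fmax is the terminal mean force normalized by the
motor-free curve.

The circuit model is two Kelvin-Voigt elements in series: the optical trap
(stiffness k_OT = 68 pN/um, known from calibration, never fitted) and the
network (spring kappa, dashpot gamma). With trap centre x1 = v t and probe
position x2(0) = 0, the force balance
gamma dx2/dt + (kappa + k_OT) x2 = k_OT v t gives

    F(x1) = [k_OT kappa / (k_OT + kappa)] x1
          + [gamma v k_OT^2 / (k_OT + kappa)^2]
            (1 - exp(-(k_OT + kappa) x1 / (gamma v))).

This form was re-derived from the stated circuit because the printed
equation is typographically corrupted; it reproduces every stated
phenomenological feature — initial slope k_OT (trap re-equilibration, time
constant gamma/(kappa + k_OT), under 50 ms at realistic parameters), a
second elastic regime with the series-spring slope, and a viscous plateau
gamma v in the fluid limit — and matches direct numerical integration of the
force balance to better than 1e-6 relative error (a tested property).
`fit_circuit()` does weighted (inverse-SEM) nonlinear least squares over
(kappa, gamma) via Levenberg-Marquardt, initialized from the terminal slope
m (kappa_0 = k_OT m / (k_OT - m), with a coarse grid search fallback when
m >= k_OT) and reports Wald 95% confidence intervals from the parameter
covariance.

## Image analysis

Spatial image autocorrelation (`sia()`) transforms the *mean-subtracted*
intensity field by FFT, takes the squared modulus, inverse transforms, and
normalizes by the squared mean intensity before radial averaging on annular
one-pixel bins. Subtracting the mean is a deliberate corrected reading: the
raw-intensity normalization cannot produce the decay to zero and the
negative depletion minima that the analysis relies on. Consequences that are
tested: g_I is exactly invariant under intensity gain, and an additive
offset c rescales it by (mean/(mean+c))^2. Boundary handling is periodic (no
padding or windowing), matching the standard SIA recipe; pixel size is
per-stack metadata (the instruments involved use different magnifications),
never a constant.

`intensity_distribution()` histograms all pixels with detected peak
locations (bimodality is the signature of coexisting dense bundles and
depleted zones at high c_k); `tile_heterogeneity()` is described above.

## Synthetic data

The generators exist so every analysis stage has a ground-truth input:

* `gen_image_stack()` — isotropic Gaussian blobs (periodically wrapped) over
  a uniform background with Poisson or Gaussian noise. Blobs are a
  sufficient stand-in for fluorescent filament clusters because every
  downstream statistic is intensity-statistical, not morphological. The
  autocovariance of a sigma-blob field decays on 2 sigma, which is the
  ground truth the SIA length tests check against (within 20%).
* `gen_force_trace()` — the circuit closed form (with known kappa, gamma),
  a saturating plateau (yielding), or a quadratic (stiffening), plus
  Gaussian noise; the truth travels with the object.
* `gen_kv_response()` — the exact analytic Kelvin-Voigt oscillation, the
  oracle for the moduli-extraction path.

What passing these tests does *not* show: the generators contain no filament
morphology, no photobleaching or camera artifacts, no drift, and the
simulated composite is 2D with monodisperse rigid filaments, so agreement
here does not certify behaviour on raw microscopy stacks or hardware traces.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full study geometry
(100 x 100 um, 5 simulated minutes, ~2,600 filaments). Replicate counts are
the package's choices for a desk-scale build: 5-6 seeds for the structural
null, one run per kinesin concentration for correlation lengths, and 3
replicate composites x 8 beads for relative elasticity (the study-scale
ensemble is 3 x 10; the smaller bead count changes only the noise). The KMC
engine is compiled (Rcpp) with a Fenwick tree over per-filament rates and
local force updates, so a 5-minute, 1.4-million-event run takes tens of
seconds.

Tolerances worth knowing: g(r) bins with no sites at that exact lattice
distance are dropped rather than reported as 0/0; the Fourier extraction
requires at least two full periods after the discarded transient; the
oscillation integrator refuses explicitly requested substeps that violate
stability.

## Known limitations

* The simulation is 2D, monodisperse, and rigid-rod; experimental actin is
  semiflexible and 3D, and measured correlation lengths in experiments are
  an order of magnitude larger than the simulation box allows.
* The bead-network coupling is a quasi-static closure: springs anchor to a
  frozen snapshot of the composite, so inter-cluster connectivity (which
  softens strongly de-mixed composites in the real system) enters only
  through local crosslink counts and attachment depletion. In practice the
  relative elasticity exceeds the motor-free value at every c_k and peaks
  at intermediate c_k at 1 Hz, but at 0.25 Hz it saturates monotonically
  instead of peaking — a known gap of the closure, not of the moduli
  extraction, which is oracle-tested.
* Motor force magnitudes, drags, and friction constants are declared
  defaults (the source values live in supplementary material that is not
  part of the main text); absolute G'/G'' and kappa/gamma magnitudes are
  therefore not comparable to printed values, only normalized and
  qualitative behaviour is.
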