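---
title: "Methods: dual-polarity MT protocol optimization and tract-specific MTR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-polarity MT protocol optimization and tract-specific MTR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dualmt` implements two connected pieces of machinery for co-encoded
magnetization-transfer (MT) diffusion MRI: a steady-state simulator of a
pulsed, dual-polarity MT preparation used to optimize sequence parameters for
MTR efficiency, and a global streamline-weight fitter that turns a pair of
MT-on / MT-off diffusion acquisitions into tract-specific MTR values. This
vignette documents the models, the tunable parameters, the numerical choices,
and what the synthetic phantom does and does not establish.

## The two-pool saturation model

Tissue is modeled as a free water pool (observable, transverse relaxation
`T2a`) exchanging with a macromolecular bound pool (fraction `M0b`, not
directly observable, `T2b` of order microseconds), with a dipolar-order
reservoir attached to the bound pool. The state advanced by the integrator is
`(Mxa, Mya, Mza, Mzb, beta)`:

* free pool: full Bloch equations with off-resonance precession, `T2a`
  relaxation, and longitudinal recovery at the intrinsic rate `Ra`;
* bound pool: longitudinal relaxation `1/T1b`, exchange (`k_f = R * M0b`
  toward the bound pool, `k_r = R` back, with `M0a = 1`), and RF saturation
  at the rate `W = pi * omega1^2 * G(offset)`, where `G` is the bound-pool
  absorption lineshape (super-Lorentzian by default);
* dipolar order: `dbeta/dt = W * (2*pi*offset/omega_loc^2) *
  (Mzb - 2*pi*offset*beta) - beta/T1d`, and the same bracket reduces the
  bound-pool saturation term. A constant offset sign pumps `beta` up and
  makes saturation progressively less effective; alternating the offset sign
  between pulses (dual irradiation) cancels the pumping term, which is why
  the alternating preparation saturates at least as well and the two
  polarities coincide in the `T1d -> 0` limit.

Default tissue values are the white-matter set used for the optimization:
`M0b = 0.1`, `T1b = 1` s, `T2b = 1` µs, `T1d = 3` ms, `T2a = 60` ms,
`R = 26` s⁻¹, observed `T1 = 0.85` s. The intrinsic rate `Ra` is not a free
parameter: `derive_intrinsic_ra()` finds the value whose free-pool
inversion-recovery mode matches the observed T1. The local dipolar field
`omega_loc` is rarely tabulated; the default uses the lineshape
second-moment relation `omega_loc = 1/(sqrt(15) * T2b)` and the field is
exposed on `two_pool_tissue()` for users with a measured value.

Numerical scheme: the coupled system is affine with piecewise-constant
coefficients over each RF waveform segment (64 segments per Gaussian pulse,
truncated at ±2.5σ with σ = τ/5 and renormalized to the exact flip angle),
so each segment is advanced by one matrix exponential — exact for the
segmented waveform, with no step-size tuning. The steady state over the
per-slice cycle (pulse train, spoiler, free relaxation filling `TR_MT`) is
reached by fixed-point iteration from thermal equilibrium, stopping when the
signal proxy `Mza` changes by less than 1e-8 between cycles (cap 500); a
closed-form fixed point is deliberately avoided because polarity alternation
breaks per-pulse periodicity.

Two deliberate modeling choices deserve emphasis. First, direct saturation
of the free pool is obtained by integrating the full Bloch equations within
each pulse rather than by a lineshape approximation, which keeps the model
valid at offsets as low as ~1 kHz. Second, free-pool transverse coherence is
*not* carried from one pulse to the next: the spoiler between pulses models
the B0-dispersion dephasing of the tiny off-resonant `Mxy` at multi-kHz
offsets. Tracking it instead couples the polarity comparison to an
unphysical coherent pathway that survives only in a perfectly homogeneous
voxel. The EPI readout, excitation/refocusing pulses and multi-slice
cross-talk are not simulated; `T_exc` / `T_ref` are carried as metadata.

## MTR efficiency and the SAR model

The contrast of interest is the *macromolecular* MTR: the usual
`1 - S_on/S_off` computed for the full tissue, minus the same quantity for a
free-pool-only tissue (`M0b = 0`), so that direct water saturation — present
in both acquisitions — is subtracted out. The optimization objective is MTR
efficiency, MTR per unit total scan time, with the dual acquisition lasting
`TR_MT * slices * (directions + b0) * 2`.

SAR is modeled relatively: energy per `TR_MT` is quadratic in the MT flip
angle at fixed pulse shape and duration, plus a fixed term for the non-MT
pulses. Because only the constraint geometry matters for the optimization,
the default calibration pins the scale at an operating point: the optimal
preparation (3 kHz, 7 × 1 ms pulses, alternating) at `TR_MT = 90` ms reaches
97% of the 3.2 W/kg head limit at `FA_MT = 596°`. Everything else follows in
closed form; at `TR_MT = 110` ms the SAR-matched flip angle evaluates to
≈659°, within 2% of the 656° operating point used in vivo. With zero fixed
energy the SAR-matched flip angle scales exactly as `sqrt(TR_MT)`.

One property of the model worth knowing: the subtracted (macromolecular) MTR
is *not* monotone in `FA_MT` all the way up. The bound pool is close to
fully saturated by a few hundred degrees per pulse, while direct water
saturation keeps growing quadratically, so the subtracted MTR peaks (near
~350° for the default preparation) and declines slowly beyond; the raw,
unsubtracted MTR keeps growing. The efficiency optimum over `TR_MT` is
unaffected — at the SAR-matched flip angle, efficiency decreases
monotonically over 90–150 ms and the grid argmax is the minimal `TR_MT`.

## The global tract-specific MTR estimator

The fitter follows the convex microstructure-informed tractography recipe:
every streamline contributes an axially symmetric "zeppelin" response
(default `D_par = 1.7e-3`, `D_perp = 0.6e-3` mm²/s), rotated along each
voxel segment and scaled by the segment length, with one non-negative weight
per streamline (signal per unit length, constant along the streamline); each
fitted voxel additionally carries a "ball" free-water compartment
(`D_iso = 3e-3` mm²/s). Per voxel and q-space sample,

```
S(q) / S(b=0, MT_off) = sum_i x_i^zeppelin * R_i^zeppelin(q) + x^ball * R^ball(q)
```

The MT-on and MT-off problems share the identical operator and both are
normalized by the MT-off b0, so saturation maps proportionally onto the
weights. The observations are normalized per voxel, and the operator rows
carry the same per-voxel normalization — equivalently, the fit is a
row-weighted least squares in absolute signal units — so generation and
fitting share one forward model exactly and noiseless self-generated data
are recovered to solver precision. b = 0 rows are kept in the system (they
anchor the total signal fraction), the fitted mask is the set of
streamline-traversed voxels (optional dilation), and voxels without
streamlines get no ball column. Segment directions are used exactly rather
than quantized to a direction dictionary: at desk scale, exactness beats
speed.

The solver is Nesterov-accelerated projected gradient with step `1/L` (`L`
from power iteration), restarted onto a guaranteed-descent plain projected
step whenever acceleration would increase the objective, so the objective
trace is non-increasing; initialization is `x = 0` (the problem is convex),
the stop rule is relative objective change below 1e-10 (cap 5000 iterations
by default; the noiseless phantom tests raise the cap to reach machine-level
recovery). No regularization is applied by default, matching the plain
non-negative formulation.

Streamlines with positive weight in *both* fits are grouped by the node pair
they connect (weights below 1e-12 of the maximum count as zero; streamlines
not connecting two distinct nodes are discarded), and the bundle MTR is

```
MTR_bundle = 1 - sum_j L_j x_j_on / sum_j L_j x_j_off
```

with `L_j` the full arc length inside the grid, consistent with the forward
tracing (not a voxel count). The ratio is invariant to global weight
rescaling, and a homogeneous bundle returns every member streamline's
implied MTR. Undefined connectome edges are stored as `NaN`, distinct from a
true 0.

## The conventional tractometry baseline

The comparison method projects a scalar MTR map onto streamlines: the
diffusion-weighted MTR map (`mtr_dw_map()`) is `1 - mean(S_on)/mean(S_off)`
over b > 0 volumes only. The ratio-of-means convention is the default and a
mean-of-ratios option is provided, since either reading is defensible; the
two differ only at second order in the angular variation. The map is sampled
at streamline vertices with trilinear interpolation (nearest-neighbor
optional), the median is taken along each streamline, and bundle values are
means of medians. The single-fiber reference selects traversed voxels above
an FA threshold (default 0.6, from a log-linear tensor fit) and averages the
map there weighted by tract density (segment counts per voxel). On the
default phantom the ball background keeps single-fiber FA near 0.5, so
phantom analyses pass a threshold of ~0.45 instead; the 0.6 default is the
in vivo convention.

## The synthetic phantom: what it shows and what it cannot

`make_crossing_phantom()` builds two orthogonal straight bundles (true MTR
0.30 and 0.40, 40 streamlines each by default) crossing at the center of a
20×20×20 grid of 2 mm voxels, with box node regions at the tube ends.
Streamlines are tube-confined jittered copies of the centerline (radial
Gaussian displacement, sd = radius/2, truncated at the radius) resampled at
0.5 mm. A uniform isotropic ball background at 30% of the mean in-bundle b0
signal (ball MTR 0) is included by default: the isotropic compartment is the
partial-volume contaminant the tract-specific method is designed to reject,
and without it an ideal two-tube phantom read by a median-along-streamline
would show no tractometry bias at all. Signals follow the zeppelin-ball
forward model above; Rician noise (`sqrt((S+n1)^2 + n2^2)`) is available at
a configurable SNR referenced to the mean in-bundle b0.

The phantom establishes internal correctness — exact noiseless recovery of
weights and bundle MTRs, the partial-volume advantage over tractometry, the
robustness of bundle ranking to the assumed zeppelin FA (0.4–0.8), and
scan-rescan repeatability under Rician noise. It does not emulate curved or
dispersing anatomy, fiber-orientation estimation or tractography errors
(streamlines are supplied, not reconstructed), susceptibility/motion
artifacts, spatially varying receive fields, or exchange between MT contrast
and the diffusion encoding. Passing phantom tests therefore validates the
estimator given a faithful tractogram, not the full in vivo pipeline.

## Problem sizes and runtimes

The shipped analyses are sized for a desk run: steady-state simulations use
64 RF segments per pulse and converge in well under a second per protocol;
the TR_MT sweep evaluates 7 protocols. The default phantom fit solves two
NNLS problems of roughly 10,000 equations by ~430 unknowns in a few seconds
each. All randomness (streamline jitter, noise) flows through explicit
integer seeds, and rerunning any deterministic stage reproduces its outputs
bit-identically.

## Known limitations

* The SAR model is relative; absolute W/kg values require a hardware
  calibration point, and only the constraint geometry is meaningful.
* The simulator's signal proxy is `Mza` at excitation; echo attenuation,
  fat suppression and multi-slice MT cross-talk are outside the model.
* A single zeppelin shape is shared by all streamlines; the FA-robustness
  analysis bounds, but does not remove, the resulting bias.
* The t-test helper assumes paired, approximately normal bundle values; it
  flags zero-variance (degenerate) pairings rather than reporting infinite
  statistics.
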