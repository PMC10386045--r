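---
title: "Methods: AACID CEST-MRI pH mapping on digital phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AACID CEST-MRI pH mapping on digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the forward model
and its assumptions, the processing chain, the parameters that matter and
why their defaults were chosen, the numerical decisions, and what the
passing test suite does — and does not — establish about real data.

## 1. The forward model

### Bloch-McConnell equations

The simulator treats each voxel as a set of exchanging proton pools:
bulk water plus an amide pool at +3.5 ppm and an amine pool at +2.75 ppm
(an optional broad magnetization-transfer pool is off by default, one
fewer unconstrained component). Under a continuous-wave saturation pulse
the coupled magnetization obeys a linear ODE, `dM/dt = A M + b`, in the
frame rotating at the saturation frequency; exchange couples every solute
to water with rate `k_s` and back-rate `f_s k_s` (detailed balance, with
`f_s` the solute proton fraction). Two solvers share the matrix builder:

* `bm_steady_state()` solves the fixed point `A M = -b`; for a single
  water pool it reproduces the Lorentzian closed form exactly, which the
  test suite uses as an analytic oracle.
* `bm_evolve()` propagates the finite pulse with the exact
  matrix-exponential solution `M(t) = Mss + expm(A t)(M0 - Mss)`
  (`Matrix::expm`, Ward's scaling-and-squaring Padé method — robust for
  these stiff matrices, where naive Padé overflows). The tests
  cross-check it against an independent stiff ODE integration
  (`deSolve::lsoda`) and against the steady state at long saturation.

Exchange rates follow base catalysis,

```
k(pH) = k_ref * 10^(slope * (pH - 7)),
```

the mechanism that makes amide/amine CEST pH-sensitive in the
physiological range.

### Default pools

The study protocol reports no tissue exchange or relaxation parameters,
so the defaults are literature-plausible stand-ins, not fitted values:

| pool  | shift (ppm) | T1 (s) | T2 (ms) | fraction | k at pH 7 (1/s) | pH slope |
|-------|------------:|-------:|--------:|---------:|----------------:|---------:|
| water |           0 |    2.0 |      60 |        1 |               — |        — |
| amide |        +3.5 |    1.0 |      10 |     7e-4 |              30 |      1.0 |
| amine |       +2.75 |    1.0 |       5 |     5e-4 |            1500 |      1.0 |

Water T1/T2 are brain-like values at 9.4 T; solute T1 of 1.0 s is a
typical small-metabolite value. The rates place amide exchange in the
slow regime (effect grows with pH) and amine exchange fast/intermediate
(effect shrinks with pH above its optimum), which is exactly what makes
the AACID ratio decrease as tissue becomes more alkaline. With these
defaults the simulated AACID is strictly decreasing over pH 6.2–7.6 and
locally linear (R² > 0.95) — verified by the test suite, not assumed.
All pool parameters are overridable (`pool()`, `pool_system()`).

The water resonance is 400.22 MHz (42.5764 MHz/T × 9.4 T); this constant
also fixes the ppm-to-Hz conversion of the 1-Hz evaluation grid.

## 2. The acquisition being emulated

* CEST: 55 offsets, 1.2 to 6.6 ppm in 0.1-ppm steps, plus reference
  acquisitions at −1000 and +1000 ppm (57 frames), continuous-wave
  saturation at 1.5 µT for 4 s.
* WASSR: 41 offsets, −0.6 to +0.6 ppm in 0.03-ppm steps, 0.2 µT for
  100 ms, no reference frames of its own (normalized against the CEST
  reference image).
* Three repeats of each, averaged during processing.
* 96 × 96 matrix at 0.4 mm in-plane, 2 mm slice for the CEST grid;
  anatomical masks for volume measurements use 0.2 mm / 1 mm voxels.

`generate_phantom()` renders per-voxel spectra with the voxel's
pH-resolved exchange rates, shifted by the voxel's B0 offset and scaled
by its B1 factor. For speed, each tissue class is simulated once on a
dense 0.005-ppm master grid and voxels interpolate it at
`offset − B0(voxel)`; at that spacing the interpolation error is orders
of magnitude below the noise floor. Reference frames carry the
unsaturated-level signal; air voxels carry zero signal before noise.

**Noise.** Magnitude-MRI noise is Rician:
`v -> sqrt((v + g1)^2 + g2^2)`, `g1, g2 ~ N(0, sigma)`, with `sigma`
expressed relative to the unsaturated signal (default 0.02, i.e. SNR 50
per acquisition — a realistic preclinical operating point). The sample
mean of the noisy signal is validated against a quadrature integral of
the Rice density.

**B0 field.** A smooth low-order polynomial surface (default amplitude
about ±0.1 ppm, clamped at ±0.3 ppm) so the ±0.6 ppm WASSR window always
brackets the water minimum.

**Seeding.** One master seed per phantom; per-repeat noise streams are
derived deterministically, so a fixed spec reproduces bit-identical
stacks. Library code saves and restores the caller's RNG state.

## 3. The processing chain and its numerical decisions

Order of operations: normalize each repeat by its reference frames,
average the repeats, fit the per-voxel spline, then WASSR-correct. (The
alternative — correcting each repeat before averaging — matters only if
B0 drifts between repeats, which the simulator does not model; the
chosen order is the simpler reading of the protocol.)

* **Air masking.** Magnitude noise gives air voxels a strictly positive
  "reference" signal, so a pure zero test is not enough; voxels below
  20% of the bright (99th-percentile) reference signal are flagged
  invalid. Invalid voxels are always carried as masks, never zero-filled.
* **1-Hz grid.** The continuous spectrum is read at integer-Hz points
  (about 0.0025 ppm at 400.22 MHz), endpoints snapped inside the sampled
  domain; `sample_mz()` returns the grid point nearest the requested
  offset. At this spacing the nearest-point error is negligible compared
  with every other error source.
* **WASSR B0 estimate.** The spline-interpolated minimum over the
  sampled window; among minima within 1e-4 of the global one, the
  closest to 0 ppm wins (tie-break), and a minimum attained at the
  window edge flags the voxel invalid (shift not bracketed) rather than
  returning a boundary value.
* **Sign convention.** A voxel whose water center appears at +d ppm gets
  shift +d, and its corrected spectrum is `corrected(w) = original(w + d)`;
  the round-trip test (simulate with known B0, estimate, correct,
  compare AACID with the unshifted run) pins this convention down.
* **Degenerate inputs.** Zero/negative reference signal, boundary WASSR
  minima, B0 shifts that push 2.75/3.5/6.0 ppm out of the corrected
  domain, and AACID's undefined denominators (`Mz(2.75) = 0`,
  `Mz(6.0) = Mz(3.5)`) all flag the voxel invalid; maps never carry NaN.

### Smoothing: a calibrated choice

The protocol says only that a smoothing spline generated the continuous
Z-spectrum; the smoothing strength is genuinely open, and it matters:

* GCV-selected smoothing flattens the narrow amine/amide dips and biases
  AACID upward substantially at this sampling density.
* A pure interpolating spline is unbiased on noiseless data but pushes
  the full per-offset noise through the AACID ratio, whose small
  denominator `Mz(6.0) − Mz(3.5)` makes the ratio upward-biased under
  noise (a classic ratio-estimator effect).
* A fixed moderate smoothing, `spar = 0.4`, minimizes the per-voxel
  readout root-mean-square error at the protocol noise level (three
  averaged repeats at SNR 50) in a simulation calibration, and is the
  package default for the CEST readout. The WASSR fit keeps GCV: its
  single deep dip (depth ~0.8 vs noise ~0.01) is robust to smoothing,
  which helps the minimum search.

Both controls are exposed (`smoothing`, `wassr_smoothing`) and every
noiseless test uses exact interpolation.

One related caveat: a 41-point WASSR acquisition cannot be interpolated
to pointwise accuracy near its very sharp direct-saturation dip (the dip
is only ~2 samples wide); the shoulders are accurate and the minimum
*location* — the only quantity WASSR is used for — is recovered to
within 0.003 ppm noiselessly, with bias below 0.005 ppm at sigma 0.01.

## 4. Mapping and ROI analysis

`make_maps()` applies the readout per voxel: spline, B0 shift, Mz at
2.75/3.5/6.0 ppm, AACID, then the affine calibration
`pHi = −4·AACID + 12.8` (mouse-brain constants; overridable, and no
recalibration is attempted). ROI statistics run over valid voxels only
and report SEM (matching the field's error bars); time courses attach
percent change versus baseline and the ΔpH implied by the calibration
slope. Percent changes are computed per subject and then averaged,
matching the repeated-measures structure of the statistics. Tumor volume
is voxel count times voxel volume on the anatomical grid.

## 5. Statistics

`rm_anova_gg()` implements the fully within-subject one- or two-factor
repeated-measures ANOVA with each effect tested against its own
subject-interaction error term. Sphericity is never assumed: effects
with more than one numerator df are Greenhouse-Geisser corrected, with
epsilon computed from the covariance of the orthonormalized
within-subject contrasts (the standard sample estimator; a 2-level
factor has epsilon exactly 1). The implementation is validated against
`car::Anova` to 1e-6 on randomized tables. Tukey post-hoc comparisons
use the studentized range with the factor-by-subject error term (the
k = 2 case reduces exactly to the paired t-test, which is also the
closed form used when only one denominator df is available).
Shapiro-Wilk and the paired t-test wrap their `stats` implementations.

Two calibration facts the test suite establishes, and their limits:

* On the study-sized design (10 subjects, 2 sides, 3 timepoints) the
  GG-corrected time effect has null rejection rate within [0.03, 0.07]
  at nominal 0.05 (500-replicate simulation).
* With many levels and few subjects (e.g. 9 timepoints, 6 subjects) the
  epsilon estimator degenerates (the contrast covariance cannot reach
  full rank) and the corrected test becomes severely conservative. This
  is a known small-sample property of the Greenhouse-Geisser correction,
  not an implementation artifact; interpret long-time-course ANOVAs
  accordingly.

## 6. What the phantoms do and do not show

The synthetic data reproduce: the offset schedules and pulse parameters,
pH-dependent multi-pool saturation physics, smooth B0 inhomogeneity,
Rician noise, repeat structure, and disjoint tissue classes with
scripted pH time courses (a drug challenge is "scripted pH", not a
pharmacokinetic model). They do **not** reproduce: k-space/readout
effects, motion, B0 drift between repeats, partial-volume mixtures,
semisolid MT (unless enabled), B1 maps beyond a static scale factor,
inter-animal anatomical variability, or manual segmentation (truth masks
stand in for it).

Consequently, passing tests show the *pipeline* is correct and
self-consistent: a scripted pH step is recovered to within 0.02 pH
noiselessly and 0.1 pH at SNR 50 — but "recovered" means recovering the
AACID change implied by the simulator's own AACID-pH response read out
the same way, converted through the fixed calibration slope. The default
pools are not calibrated to make that response match the in-vivo
calibration's slope; absolute pH values from phantom runs are therefore
not comparable to in-vivo numbers, and nothing here validates the
calibration constants themselves in any particular tissue.

## 7. Problem sizes used by the tests

Unit and acceptance tests run on reduced grids (14×14 to 32×32 phantoms,
two or three tissue classes, up to 6 subjects and 3 repeats, 500-replicate
statistical simulations) — sizes chosen so the whole suite exercises every
code path, including the end-to-end recovery scenario, in under a minute
on one core. The full 96×96 protocol grid runs through exactly the same
code (`default_phantom_spec()` uses it) and is exercised by the demo
configuration.

## 8. Known limitations

* The AACID ratio is upward-biased at low SNR even with the calibrated
  smoothing; region means inherit a small residual bias (the tests bound
  its effect on recovered ΔpH at 0.1 pH under the protocol conditions).
* The WASSR estimator is the spline argmin; the maximum-symmetry-center
  variant from the WASSR literature is out of scope.
* No motion/registration, no B1 correction (the emulated protocol found
  none necessary), no outlier-rejection rule (the study mentions one
  without specifying it, so none is implemented).
* Greenhouse-Geisser conservativeness with many within-subject levels,
  as discussed above.
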