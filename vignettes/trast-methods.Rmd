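---
title: "Models and methods behind trastkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trastkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trastkit)
```

This vignette is the package's own account of what it computes and why the
numerical and design choices were made the way they were. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The electronic-state model

TRAST (transient-state) monitoring infers dark-state kinetics of a
fluorophore from how its *time-averaged* fluorescence responds to the
duration `w` of rectangular excitation pulses. For NADH the package uses a
six-state model:

* `ground` (⁰NADH) and `singlet` (¹NADH), coupled by excitation `k01` and
  the combined radiative/non-radiative decay `k10`;
* `triplet` (ᵀNADH), populated by intersystem crossing `kisc` and decaying
  at `kT = kT0 + kQT_O2·[O2]` (oxygen quenching is the dominant decay
  channel in aerated solution);
* `radical` (·NADH⁺), formed by photo-induced electron ejection `kee` from
  the singlet. It either returns to the ground state by taking up an
  electron (`kred = kred0 + kQred_O2·[O2] + kQred_Asc·[Asc]`; the O₂
  coefficient is *negative* — molecular oxygen competes for solvated
  electrons) or deprotonates irreversibly toward NAD⁺
  (`kdeprot = kdeprot0 + kQdeprot·[TRIS, H2O2, OH]`);
* two non-fluorescent `NAD⁺` pools (`oxRadial`, `oxAxial`). On TRAST time
  scales photo-oxidized molecules only reappear through diffusion of fresh
  molecules into the detection volume; the two pools with separate recovery
  rates approximate the different influx time scales along the short radial
  and long axial axes of the focus.

Units everywhere: rates in µs⁻¹, second-order coefficients in mM⁻¹µs⁻¹,
concentrations in mM, times in µs (lifetimes in ns).

Two constraints are built in rather than left to the user:

* **Lifetime constraint.** `k10` is never set directly; it is derived as
  `k10 = 1/tauF − kisc − kee` so that the combined singlet decay always
  reproduces the 0.4 ns fluorescence lifetime. Under the alternative
  "ejection from the triplet" model variant only `kisc` is subtracted.
* **No clamping.** A composed rate that goes negative at the supplied
  concentrations (possible because `kQred_O2 < 0`) raises an error naming
  the offending rate. Silent clamping would hide unphysical extrapolation
  of the linear quencher model.

The higher excited singlet reached under intense illumination is *not* an
explicit state: its lifetime is far below every observable time scale, so
under two-photon excitation the two ejection pathways are folded into one
effective rate `k'ee` that may scale with irradiance
(`trastModel(eeIexp = 1)`), which is also how the fitting presets treat it.

### Defaults and their provenance

`rateParams()` defaults to the solution-phase rate constants for NADH under
355 nm one-photon excitation (kisc 0.93, kT0 0.021, kQT_O2 1.6, kee 5.3,
kred0 2.8, kQred_O2 −1.6, kQred_Asc 0.25, kdeprot0 3.9, kQdeprot_TRIS
0.012, kQdeprot_H2O2 0.4, kQdeprot_OH 0.16; τF 0.4 ns). Three groups of
values are *implementation defaults*, not literature facts, and are stated
as such:

* **Atmosphere → [O₂]**: air 0.27 mM, pure oxygen 1.3 mM, argon 0 mM —
  standard aqueous solubilities at room temperature; only relative effects
  matter for the package's tests, and the mapping is configurable.
* **Recovery pools**: `fRadial = 0.5`, `krecRadial = 1e-3`,
  `krecAxial = 1e-4` µs⁻¹, i.e. recovery on the 1–10 ms scale, consistent
  with diffusional replenishment of a ~µm-scale focal volume. They are
  fittable but held fixed in all provided analyses (their values do not
  affect relative changes between conditions).
* **Collection efficiency function (CEF)**: a Gaussian weight of radius
  2× the beam waist, reflecting a nearly open pinhole.

## Excitation and the scanned-beam equivalence

One-photon: `k01 = σ·I·λ/(hc)` (σ = 2×10⁻¹⁷ cm² at 355 nm). Two-photon:
each femtosecond pulse is treated as rectangular of its nominal width, so
`k01 = σ₂·Φ_pk²·f·τp` with the peak flux `Φ_pk = (I_avg/(f·τp))·λ/(hc)` —
exactly quadratic in the time-averaged irradiance (σ₂ = 0.4 GM at 735 nm,
76 MHz, 150 fs).

A scanned beam excites each molecule with a smooth Gaussian passage rather
than a rectangle. The package adopts the integral-preserving rectangular
equivalent: a pass at speed `v` becomes a rectangle of the pass-peak
amplitude whose duration preserves the time-integral of `k01` (one-photon)
or of the squared-Gaussian excitation profile (two-photon):
`w_eff = √(π/2)·ω/v` and `(√π/2)·ω/v` respectively. The exact
pulse-equivalence convention used by the original instrument software is
not public; the integral-preserving choice is this package's documented
decision, and `speedForDwell()` is its exact inverse.

**Spatial averaging.** The detected signal integrates the singlet
population over the focal volume weighted by the CEF. The radial Gaussian
profile is discretized into `nShells` annuli of equal detected-signal
probability (measure ∝ I^m·CEF, m = 1 or 2 by mode). Each shell carries its
CEF mass as weight and a representative irradiance that preserves the
CEF-weighted mean of I^m within the shell, which makes the low-saturation
signal exact at *any* shell count and leaves only the nonlinearity of the
dark-state buildup to converge (measured in the tests: < 0.5% between 32
shells and the 256-shell limit). `nShells = 1` degenerates to a single
evaluation at the CEF-averaged irradiance. Default: 16 shells.

## The TRAST curve engine

For each shell, the generator matrix `M` is assembled and the pulse average
of the singlet population over `[0, w]` is computed in closed form from the
eigendecomposition: with `p(t) = V e^{Λt} V⁻¹ p₀`, the average is
`Σ_m c_m (e^{λ_m w} − 1)/(λ_m w)`. This replaces time-grid quadrature
entirely — it is exact, and fast enough (an Armadillo kernel) for global
fitting; a dense-grid propagation path remains as fallback and as the test
oracle (a 10 ps explicit-Euler reference, evaluated by binary powering of
the step matrix, agrees to < 10⁻⁶ per state over a millisecond horizon).

**Initial condition.** Pulses start from the singlet-equilibrated bright
manifold (`p ∝ (k_S, k01)` on ground/singlet) rather than the pure ground
state. The nanosecond singlet rise is thereby excluded from the average —
the quasi-steady-state singlet approximation, exact to O(τF/w) and
justified because every observable `w` (≥ 500 ns) exceeds τF by three
orders of magnitude. It also makes the no-dark-state limit exactly flat,
which the normalization convention (curve ≡ 1 at the shortest duration)
requires.

**Pulse trains.** All pulses of a stationary train are assumed identical
(low duty cycle, full recovery in between). The simulator warns when the
slowest recovery rate times the inter-pulse dead time at the longest `w`
falls below 5.

## Global fitting

`globalFit()` minimizes summed squared residuals of simulated versus
observed normalized curves over all curves simultaneously with a bounded
Levenberg–Marquardt trust region (minpack). Choices that matter:

* **Log scale** for strictly positive parameters (the rates span four
  decades); sign-free coefficients (`kQred_O2`) stay linear.
* **Initial trust region** `stepFactor = 1` instead of minpack's usual 100.
  The landscape has strongly correlated directions, and large first steps
  reproducibly slam parameters into their box bounds, where the projected
  trust region can stall at a constrained stationary point. Small early
  steps cost iterations (the cap is 400) but avoid this failure mode.
* **Per-curve normalization** (`perCurveNorm = TRUE`): each measured curve
  is normalized by its shortest-duration point, so that point's noise is a
  common-mode error of the whole curve. A per-curve multiplicative scale,
  profiled out in closed form at every residual evaluation, absorbs it.
  The profiled scales are counted as free parameters in AIC/BIC.
* **Confidence intervals** are linearized (t-quantiles on the internal
  scale from the Jacobian at the optimum), i.e. they reflect specifically
  the least-squares uncertainty.
* **Residual weighting** is uniform by default; `weights = "sd"` uses the
  per-point standard deviations when the curves carry them.
* **Multi-start** (`nStarts > 1`, Latin hypercube over the bounded box) is
  available but not the default: the provided experiments start from
  stated initial values, and random starts mostly land in the degenerate
  basins described next.

### Identifiability and the recovery protocol

The solution-phase experiment (`opeRecoveryExperiment()`) is a synthetic
re-run of the rate determination: the 53-curve design — an irradiance
series (10–81 kW/cm², air), oxygen and argon atmospheres at five
irradiances, and ascorbate, TRIS, hydroxide and peroxide titrations — is
simulated from the known rates at 1% multiplicative noise and refit.

Two structural degeneracies of the model shape the protocol. First, a
common rescaling of *all* radical-pathway rates (`kred0`, `kdeprot0` and
their quencher coefficients) preserves every branching ratio at every
concentration; its only observable is the radical residence time
(~0.15 µs), just below the shortest pulse durations, so the data contain
essentially no information about it (rescaling by 4× changes the noiseless
residual sum by < 10⁻⁶). Second, the triplet pair (`kisc`, `kT0`) is
constrained mainly by its ratio (the small argon-atmosphere plateau).
A fully free fit therefore drifts arbitrarily along these directions once
noise is present. The recovery protocol restores identifiability the way a
practitioner would: the second-order coefficients of the three *reference*
quenchers (O₂ on the triplet, ascorbate on reduction, hydroxide on
deprotonation — quantities available from independent calibration) and the
zero-quencher triplet decay are held fixed, while all first-order rates of
interest plus the remaining coefficients (`kisc`, `kee`, `kred0`,
`kQred_O2`, `kdeprot0`, `kQdeprot_TRIS`, `kQdeprot_H2O2`) are fitted,
starting at twice their generating values. Under this protocol the
noiseless round trip is exact to < 10⁻⁸ and the noisy recovery is verified
in the acceptance tests. The fitted standard error of `kisc` (~0.19 µs⁻¹)
shows it remains the most weakly determined rate; occasional excursions of
order one standard error are expected.

**Problem sizes.** The provided experiments use 34 pulse durations per
curve (500 ns–1 ms, 10 per decade — a typical acquisition density), 53
curves, and 60 replicates for the model-selection experiment; these are the
package's chosen study sizes.

### Model selection

`modelSelection()` ranks fits of *identical data* by
`AIC = n·ln(SSR/n) + 2k` and `BIC = n·ln(SSR/n) + k·ln(n)` (Gaussian
residual likelihood, `k` counting free parameters), with relative
likelihoods `exp(−ΔAIC/2)`. `eeModelSelectionExperiment()` uses it to
discriminate the electron-ejection mechanism: data generated with
irradiance-independent ejection from the singlet are fit by that model, by
ejection from the triplet, and by an irradiance-proportional (quadratic)
variant; the generating mechanism is expected to rank first in ≥ 95% of
replicates, which the acceptance test checks.

## FLIM analysis

TCSPC histograms are modeled as wrapped exponentials over one laser period
(13.16 ns at 76 MHz), circularly convolved with the IRF (synthetic Gaussian
of 0.3 ns FWHM by default; measured IRFs can be supplied as vectors), plus
an optional uniform background. Defaults use 256–4096 bins; per-pixel
statistics, not bin width, limit the estimators.

* The pooled two-exponential fit maximizes the Poisson likelihood over both
  lifetimes, the amplitude split and (optionally) the background, with the
  overall amplitude profiled out. Nearly equal fitted lifetimes trigger an
  identifiability warning.
* The per-pixel estimator holds the lifetime pair fixed (0.4/2.4 ns) and
  maximizes the likelihood over the bound-photon fraction on the *closed*
  interval [0, 1]: no logit transform, so exact boundary estimates are
  reachable. Pixels under 50 photons are flagged; empty pixels are NA.
  The image version (`boundFractionMap()`) solves the same score equation
  by vectorized bisection (the likelihood is concave in the fraction).
* `brightnessCorrect()` converts photon to molecular fractions assuming
  quantum yields proportional to lifetimes; `boundPhotonFraction()` is its
  exact inverse, which the generator uses.

**Known limitation — lifetime mis-specification.** The per-pixel estimate
is *not* insensitive to the assumed bound lifetime: re-analyzing the same
data with τ_bound set anywhere in [2, 3] ns moves the brightness-corrected
bound fraction by about 0.1 at realistic operating points (tests quantify
the envelope). Claims of near-invariance over this range are not supported
by the exact Poisson MLE; users comparing conditions should fix one
lifetime pair across all data, in which case only the common scale, not
the contrast, is affected.

## Imaging pipeline

`analyzeCellField()` chains: per-frame drift correction (the repeated fast
frames act as bleaching references; frame totals are regressed linearly and
rescaled to the trend start), sub-pixel alignment (cross-correlation on a
10× oversampled grid, computed by zero-padding the cross-power spectrum —
identical to correlating sinc-interpolated images; featureless pairs fall
back to zero shift with a warning), constant background subtraction
estimated from the unlabeled region, the per-pixel amplitude
`A = (F_f − F_s)/F_f` with pixels under 20 background-subtracted fast
counts set to NA (ratio variance explodes below that), optional per-pixel
FLIM, and per-cell/per-region means. Cells are averaged per pixel by
default; a count-sum mode (amplitudes from summed region counts) is
provided because the published averaging convention is ambiguous — the two
agree on homogeneous regions and the pixel mean is the default.

The default geometry is 128×128 pixels over 90×90 µm with dwell times
12/600 µs and 50 fast repeats (dose matching 50·w_f = w_s is checked and
warned about). Shifts are reported as (dy, dx) in pixels, row-major.

## Synthetic cell fields

`genCellField()` emulates the two-condition scan experiment: elliptical
cells (axes 8–15 µm, a purely structural choice) with concentric nuclei
(40–60% of the cell axes) are rejection-placed without overlap, at most 12
per field of view; requests for more cells produce multiple fields with
globally unique labels. Per cell, nuclear and cytosolic dark-state
occupancies θ and bound fractions β are drawn from truncated normals around
the condition presets with between-cell SDs 0.02 and 0.01 (read from the
spread of the reported condition means). Expected counts: fast-sum budget
per in-cell pixel (default 500), slow counts reduced by (1−θ), uniform
background in both, optional linear bleaching across the fast frames and an
optional injected sub-pixel offset of the slow frame; all counts Poisson.
Micro-times are drawn per pixel from the two-exponential+IRF mixture with
the photon fraction implied by β (default 1000 photons per in-cell pixel).

The condition presets place the region truths so that at the expected
nuclear area fraction (~0.25) the pixel-weighted cell means reproduce the
reported condition averages (A_TRAST 0.43/0.52/0.36 with nuclear 0.38 and
cytosolic 0.45 in the control; A_bound 0.20/0.18/0.21). What the generator
deliberately does *not* emulate: PSF blur, scanner distortion, intra-region
texture, autofluorescent species other than NAD(P)H, and detector dead
time. Passing round trips therefore demonstrate estimator correctness and
calibration, not robustness to those real-data effects.

## Classification

`trainEval()` repeats plain random 80/20 train/test splits (stratified
splitting available as an option), fits a 500-tree depth-4 random forest
per run (ranger), and averages held-out accuracy and confusion counts over
runs; splits that lose a class from the training set are resampled.
`voteAccuracy()` turns the single-cell probability matrix into the exact
N-cell majority-vote accuracy by multinomial enumeration; tied votes count
as failures (the strictest reading of "more votes than either
alternative"), and the three classes are equally likely a priori. The
real-cell accuracies themselves depend on the real feature distributions
and are not reproducible from synthetic data; the tests instead verify the
structural claim that joint A_TRAST + A_bound features outperform either
alone on matched synthetic distributions, the closed-form limits, and
agreement with a Monte-Carlo voting oracle.

## Interfaces

Rate parameters and environments serialize to flat JSON/YAML configs
(`writeRateParams()`); curves to CSV (`w_us, F_norm, sd`) with JSON
sidecars; maps and label masks to TIFF (maps quantized to 32-bit samples
over the fixed range [−1, 2] with the range maximum as the missing-pixel
sentinel — the plain-TIFF route does not carry native floats). Vendor
TCSPC formats (PTU/SPC) and HDF5 containers are out of scope. A thin
command-line front end lives in `inst/scripts/trast.R`.
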