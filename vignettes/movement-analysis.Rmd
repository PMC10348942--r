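---
title: "Movement kinematics, posturography and 1D SPM: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement kinematics, posturography and 1D SPM: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

motorlab analyses a within-subject experiment in which people perform a
self-paced aiming movement — golf putting — under a real-world condition
and two virtual-reality conditions (`Real`, `VR`, `VRHaptic`), with the
clubhead instrumented by a triaxial accelerometer and the performer
standing on a pressure plate.  This vignette explains the models behind
each stage, the tunable parameters, and the design decisions taken where
the analysis recipe left genuine freedom.  It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The pipeline at a glance

```{r}
library(motorlab)
cfg <- study_config(seed = 1)     # 21 participants x 3 conditions x 20 putts
report <- run_all(cfg)            # generate -> process -> model -> SPM
report$model_table                # twelve Table-style outcome rows
report$spm$transverse$omnibus     # SPM{F} over the swing continuum
```

Every stage is also exported on its own (`generate_swing_trace()`,
`process_swing()`, `posture_metrics()`, `spm_compare_conditions()`,
`fit_lmm()`, ...), and `run_all()`/`validate_inputs()` are the
programmatic entry points; there is no shell executable because the
package's users drive it from R.

## Swing kinematics

Raw accelerometer recordings are resampled to a uniform 1125 Hz grid
(linear interpolation), and analysis channels are low-pass filtered at
3 Hz with a 2nd-order Butterworth filter applied forward and backward.
Zero-phase filtering avoids phase lag that would shift the apparent
impact instant; the price is that the effective attenuation is the
squared single-pass magnitude response, which the filter tests assert
explicitly.  `signal::butter()` supplies the coefficients; the
forward-backward pass itself is initialized with the filter's
steady-state response to the first sample and padded by odd reflection
(the classic filtfilt algorithm), because a zero-state pass corrupts
hundreds of milliseconds at each end of a 3 Hz / 1125 Hz filter.

Each putt is found as a spike in the **raw** vertical channel: the
3 Hz filter would smear a 20 ms impact transient into invisibility, so
detection runs unfiltered, with a robust baseline (median and MAD) and a
`threshold_k = 6` multiplier.  The pre-contact phase is then extracted
by backtracking from impact to the movement onset: the last sample at
which the smoothed transverse magnitude stays below 5% of its pre-impact
peak for at least 150 ms.  Two details of this rule are deliberate
deviations from the obvious first guess:

* the onset smoother is a **10 Hz** low-pass, not the 3 Hz analysis
  filter — a zero-phase 3 Hz pass spreads movement energy roughly 50 ms
  ahead of the true onset, biasing onsets early by about that much;
* the hold is **150 ms**, not 50 ms — the transverse acceleration of a
  low-amplitude swing dips below the 5% threshold for up to ~100 ms at
  the mid-backswing zero crossing, and a 50 ms hold can lock onto that
  dip instead of the true onset.

Per-putt metrics are read from the filtered channels: transverse and
sagittal acceleration at the impact sample, the sample variance of the
sagittal channel over the segment, and mean |jerk| per plane with
`jerk = diff(acc) / dt`.  Mean jerk is computed on magnitudes because a
signed mean over a near-symmetric swing cancels toward zero and cannot
produce the positive summaries this metric is meant to carry.  Finally
each segment is linearly re-sampled onto 101 nodes (0-100% of the
pre-contact swing), the standard registration for curve-level analysis.

Outlier screening for the scalar outcomes uses a 3 SD z-score with a
Winsorized replacement: an outlier becomes a value 1% more extreme than
the next most extreme non-outlying value on its side (`1.01 * v` /
`0.99 * v` on positive scales, sign-consistent for negatives).  The rule
is applied per outcome on the pooled vector across conditions; applying
it per condition instead is a one-line change, but pooled screening is
the default because the model residuals, not the condition cells, are
what the screen protects.

## Posturography

Centre-of-pressure (COP) traces (300 Hz, mm, `x` sagittal / `y`
transverse) are filtered at 5 Hz (2nd-order zero-phase Butterworth) and
segmented to the putt window: from the foot-lift preceding the putt plus
a 0.5 s settling margin, to the next foot-lift or the end of the
recording.  The foot-lift is taken from event markers when present;
`detect` mode instead finds the largest sustained excursion of COP speed
(estimated over a 50 ms lag — per-sample differences measure noise, not
movement) above 150 mm/s for more than 100 ms.

Four outcome families are computed on the window:

* **RMS sway** per axis about the mean position;
* **sample entropy** per axis after decimation to 100 Hz, with
  `m = 2` and `r = 0.2 * SD` of the analysed (decimated) series — the
  canonical SampEn parameterization, with Chebyshev template distance
  and self-matches excluded.  `SampEn = -ln(A/B)`; `A = 0` yields an
  `Inf` sentinel with a warning rather than a silent drop;
* **path length**, the summed consecutive-sample displacement of the
  filtered 2D trace;
* the **95% prediction ellipse**, from the eigen-decomposition of the
  2x2 position covariance: area `pi * 5.991 * sqrt(l1 * l2)` with
  `5.991 = qchisq(0.95, 2)` and an `n - 1` covariance denominator.

A note on entropy scales: a clean sinusoid sampled at ~45 samples per
cycle has a SampEn floor near 0.2 (its continuous phase spreads template
edges), against ~2.2 for white noise, so "near-zero entropy for a fully
regular signal" means an order of magnitude below the noise level, not
numerically zero.  The per-axis 1D treatment (rather than a 2D norm) is
a documented interpretation choice.

## 1D statistical parametric mapping

The swing continua are compared with a pointwise repeated-measures
one-way ANOVA (subject as blocking factor; sphericity assumed, no
correction — a documented limitation), giving an SPM{F} curve, and with
paired-t curves for each condition pair.  Each subject contributes the
mean of their 20 time-normalized trials per condition; whether trials or
subject means enter the maps is genuinely open, and subject means were
chosen because they match the repeated-measures F used for inference.

Family-wise error is controlled with random field theory.  Field
smoothness (FWHM, in nodes) is estimated from the node-wise-standardized
residual curves via the mean squared gradient,
`fwhm = sqrt(4 log 2 / mean(grad^2))`.  The critical height solves
`E[EC](u) = alpha` by bisection, with
`E[EC](u) = P0(u) + resels * rho1(u)` and `resels = (n_nodes - 1)/fwhm`.
The 1D EC density for the t field is the standard
`sqrt(4 log 2)/(2 pi) * (1 + u^2/nu)^(-(nu - 1)/2)`.  Published forms of
the F-field density disagree in their `2 pi` prefactor; the
implementation pins it down by requiring the exact excursion-set
identity `EC{F(1, nu) > u} = 2 EC{t(nu) > sqrt(u)}`, and both densities
are validated by Monte Carlo: simulated smooth Gaussian null fields
(2000 replicates in the test suite) must cross the threshold in 3.5-6.5%
of replicates at `alpha = 0.05`.  This simulation-based validation
stands in for a cross-check against an external 1D-SPM implementation,
which is not a dependency of the package.

Supra-threshold clusters use integer node boundaries (no interpolated
crossings — simpler and conservative) with extents in resels.  Cluster
p-values use the expected-cluster approximation: with expected cluster
count `E_c = E[EC](u)` and mean extent `eta = resels * P0(u) / E_c`,
`P(extent >= k) = exp(-pi k^2 / (4 eta^2))` and
`p = 1 - exp(-E_c * P(extent >= k))`.  Pairwise t maps are two-tailed by
default and are not alpha-adjusted across the three pairs (each map is
reported on its own); both choices are arguments.  The bisection bracket
starts at `[uncorrected critical value, +20]` and grows geometrically
when needed — heavy-tailed F fields with few denominator degrees of
freedom (tiny pilot designs) can need thresholds far above +20.

## Mixed-effects condition models

Each scalar outcome is modelled as
`outcome ~ condition + (1 | participant)`, `Real` as reference, fitted
by REML (`lmerTest`).  The jerk outcomes additionally get random
condition slopes; sagittal variance and ellipse area are modelled on the
log scale; the two entropy outcomes use a Gamma GLMM with log link
(`lme4::glmer` — the link is a choice, the family is given).  Model
structure is taken as fixed; no model selection is re-enacted.

Variance explained follows the fixed/random/residual decomposition:
marginal `R2 = var_f / (var_f + var_r + var_e)` and conditional (total)
`R2` adds `var_r` to the numerator, with `var_f` the variance of the
fixed-effect predictor, `var_r` the mean diagonal of `Z Sigma Z'` (so
random slopes are handled), and `var_e` the residual variance — for the
Gamma log link, the trigamma-based latent-scale variance
`trigamma(1/phi)`.  Standardized betas default to
`beta * SD(dummy) / SD(response)` on the modelling scale; dividing by
the response SD alone is available as `std_convention = "response"`
since the convention in use elsewhere is often unstated.  Labels follow
`|beta| < 0.2` weak, `0.2-0.5` moderate (inclusive), `> 0.5` strong.
Pairwise contrasts come from estimated marginal means with
`p_adj = min(1, 3p)` applied exactly.

The six 5-point conscious-movement items are summarized per participant
and condition; both the item mean (range 1-5) and the item sum (range
6-30) are supported, the sum being the pipeline default because
condition-level questionnaire intercepts around 20 arise on that scale.
The scoring mode travels with the value.

## The synthetic study generator

The generator exists so that every downstream stage is testable against
recorded ground truth; it emulates the statistical structure the
analysis assumes, not putting physiology.

**Swing traces.**  The transverse channel is built from two opposed
minimum-jerk acceleration lobes: a 0.75 s backswing whose braking peak
lands at 50% of the pre-contact swing, and a slower downswing whose
rising lobe peaks exactly at impact, scaled so the value at the impact
sample equals the trial's true impact acceleration (this identity is
exact before sensor noise and is what the recovery tests lean on).  The
vertical channel carries a 20 ms half-cosine spike of 40 m/s^2 at
impact; the sagittal channel is a band-limited (0.2-1 Hz) fluctuation
scaled to the trial's true SD plus a smooth impact-locked component
pinning the sagittal impact value.  Condition effects enter three ways:
impact-instant accelerations (defaults from the transverse row
3.69 / -1.47 / -0.42 m/s^2 and sagittal row 0.95 / +0.90 / +0.78),
log sagittal variance (-2.21 / +1.20 / +0.95), and localized swing-shape
bumps — compactly supported raised cosines at 50% and 76% of the swing,
identical for the two VR conditions.  Compact support matters: a
Gaussian bump's tail, smeared by the 3 Hz filter, reaches the impact
sample and corrupts the recovery identity by a few hundredths of m/s^2.
True impact accelerations are floored at 0.5 m/s^2: a putt must strike
the ball moving forward, and unbounded Gaussian tails otherwise produce
physically meaningless near-stationary "swings".

**COP traces.**  Each axis is a slow quasi-periodic drift (4 sinusoids
in 0.1-0.5 Hz, amplitude set per condition: 10 / +4 / +3 mm, sagittal
1.2x) plus a regularity mixture
`lambda * sine(2.2 Hz) + (1 - lambda) * white noise` rescaled so its
**in-band** (below 5 Hz) SD is 2.5 mm — most white-noise power lies
above the plate filter, so calibrating the raw SD would leave the
regularity dial invisible downstream.  `lambda` defaults to
0.35 / +0.35 / +0.30, so VR sway is more regular (lower SampEn) while
amplitude outcomes stay drift-dominated.  The foot-lift is written both
as an event timestamp and as a 40 mm, 0.4 s excursion so segmentation is
testable in marker and detection mode.  One caveat is measured rather
than assumed: SampEn's decrease in `lambda` is strict through the
analysis chain, but the first grid step (0 to 0.25) is small, so the
grid test uses 30 s mixtures to keep estimator noise below the step.

**Design and scores.**  Condition order follows a cycled 3x3 Latin
square; participant random intercepts are drawn once per outcome per
participant from seeds derived from the root seed, so every trace and
table of a study sees identical draws regardless of generation order.
Questionnaire items are a discretized latent normal (defaults put the
6-item sum near 20 for `Real`, lower in VR) clamped to 1-5.

**What the generator does not emulate** — and hence what green tests do
not show about laboratory data: physiologically realistic sway spectra
or swing variability, order/learning effects across the Latin-square
blocks, subject-by-condition interaction in the swing continua, missing
data mechanisms beyond file deletion, and any relation between movement
and putting outcome.  In particular, because trace-level condition
effects scale the whole swing profile, SPM maps computed from fully
processed traces show broad amplitude differences; the localized
two-cluster pattern is asserted on `generate_curve_set()`, whose curves
carry condition differences only in the injected shape bumps (subject
amplitudes are condition-independent there by design).

## Numerical choices and degenerate inputs

* Per-trace RNG streams are derived by hashing (root seed, participant,
  condition, trial); identical configuration and seed reproduce every
  output byte for byte.
* The SampEn tolerance is per-series (`0.2 * SD` of the analysed
  series); constant series return 0 when `r` is supplied and error on
  the degenerate `r <= 0` default.
* Rank-deficient COP clouds give ellipse area 0 with a warning;
  zero-variance nodes are excluded from FWHM estimation; an all-flat
  curve set raises an error rather than returning an F map of NaNs.
* Cluster p-values are floored at 1e-300 to avoid reporting exactly 0
  after underflow.
* Singular mixed-model fits (expected when random slopes are requested
  for outcomes simulated without slope variance) are flagged in the
  result, never hidden.

## Problem sizes used by the tests

The suite validates the full default design (21 x 3 x 20 = 1260 trials)
end to end once, parameter recovery on 100 direct simulations of the
1260-row outcome table, family-wise error on 2000 simulated null fields
of 20 curves x 101 nodes, and entropy/ellipse closed forms on series of
1000-10000 samples.  These sizes were chosen to make Monte Carlo
tolerances meaningful (binomial SE ~0.005 at 2000 replicates for the
FWE check) while keeping a full run of the suite in the low minutes on
one core.

## Known limitations

* Sphericity is assumed in the repeated-measures F; no
  Greenhouse-Geisser style correction is applied.
* The cluster-extent p-value is an asymptotic approximation known to be
  conservative for low thresholds and short fields.
* SampEn at 100 Hz of 5 Hz-limited signals compresses the dynamic range
  of the regularity dial; between-condition entropy differences are
  reliable in direction but not calibrated to any physiological scale.
* The generator's effect sizes for posturographic outcomes are
  direction-calibrated, not magnitude-calibrated, to published values.
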