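# motorlab

Movement-analysis pipeline for within-subject real-versus-virtual motor
experiments: clubhead-IMU swing kinematics, centre-of-pressure (COP)
posturography, one-dimensional statistical parametric mapping (SPM) over
swing continua, and mixed-effects condition contrasts — with a synthetic
study generator that makes every stage testable against known ground
truth.

It is written for movement scientists comparing how a self-paced aiming
skill (the motivating task is golf putting) is executed in a real
environment versus virtual-reality conditions with and without haptic
contact (`Real`, `VR`, `VRHaptic`), measuring both the effector (putter
swing) and postural control.

## What it computes

**Swing kinematics** (per putt, from a triaxial clubhead accelerometer):
resampling to 1125 Hz, zero-phase 2nd-order 3 Hz Butterworth filtering,
impact detection from vertical-channel spikes, movement-onset
backtracking, then transverse/sagittal acceleration at impact, sagittal
variance over the pre-contact swing, mean |jerk| per plane
(jerk = dAcc/dt), and 101-node time-normalized continua.  Outliers
beyond 3 SD are Winsorized to 1% beyond the next most extreme value.

**Posturography** (per putt, from a 300 Hz pressure plate): 5 Hz
zero-phase filtering, foot-lift-based putt segmentation (markers or
detection), RMS sway per axis, sample entropy per axis
(SampEn(m = 2, r = 0.2 SD) on 100 Hz-decimated data,
`SampEn = -ln(A/B)` with Chebyshev matching and self-matches excluded),
COP path length, and the 95% prediction ellipse from the principal
components of the position cloud:
`area = pi * 5.991 * sqrt(lambda_1 * lambda_2)`.

**1D SPM**: pointwise repeated-measures SPM{F} and paired SPM{t}
continua over the 0-100% swing, with random-field-theory thresholds
(`E[EC](u) = P0(u) + resels * rho1(u)` solved for the critical height,
resels from residual-based FWHM estimation) and supra-threshold cluster
p-values from the expected-cluster-extent approximation.

**Mixed models**: per outcome,
`outcome ~ condition + (1 | participant)` by REML (random condition
slopes for jerk; log scale for sagittal variance and ellipse area;
Gamma/log GLMM for entropy), standardized betas with weak / moderate /
strong labels, marginal and conditional R² from the
fixed/random/residual variance decomposition, and Bonferroni pairwise
contrasts (`p_adj = min(1, 3p)`).

## Worked example

```r
library(motorlab)

cfg <- study_config(seed = 1)   # 21 participants x 3 conditions x 20 putts

## one synthetic putt through the swing chain
sw <- generate_swing_trace(cfg, participant = 1, condition = "Real", trial = 1)
process_swing(sw$trace)$metrics
#>  acc_impact_transverse acc_impact_sagittal var_sagittal jerk_mean_transverse
#>                   5.56               0.555        0.122                 16.9
#>  jerk_mean_sagittal n_samples
#>                 2.5      1336

## the same trial's postural outcomes
cp <- generate_cop_trace(cfg, 1, "Real", 1)
posture_metrics(cp$trace)
#>  rms_t rms_s sampen_t sampen_s path_length_mm ellipse_area_mm2
#>   6.14  7.44    0.229    0.185            374              852

## SPM over subject-mean swing continua
cs <- generate_curve_set(cfg, "transverse")
spm_compare_conditions(cs, alpha = 0.05)$omnibus
#> <spm1d_result> SPM{F} over 101 nodes
#>   df = (2, 40), FWHM = 10.67 nodes, resels = 9.37
#>   z* = 7.265 at alpha = 0.05
#>   clusters:
#>  start_node end_node extent_nodes extent_resels max_stat      p_value
#>          44       58           15      1.405698 277.6225 1.151569e-06
#>          70       83           14      1.311985 621.2898 4.560734e-06
```

The first trial's transverse impact acceleration is 5.56 m/s² (this
participant swings faster than the 3.69 m/s² population intercept); its
sway entropy near 0.2 per axis sits an order of magnitude below the
white-noise level of ~2.2, reflecting partly regular sway.  The SPM{F}
map finds exactly two supra-threshold clusters, spanning nodes 44-58 and
70-83 of the swing — the loci where the generator injects VR-specific
shape differences (backswing reversal at ~50%, downswing at ~76%) — each
with p < 1e-5 under the random-field null.

The full chain — generation, per-trial processing, Winsorizing, twelve
mixed models with contrasts, SPM per plane, and a JSON/CSV report — is
one call:

```r
report <- run_all(cfg, out_dir = "results/run1")
report$model_table
report$contrasts
```

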