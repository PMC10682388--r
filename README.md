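# propriolearn

Scoring and causal analysis of a proprioceptive learning battery: how do
proprioceptive **acuity** and proprioceptive **short-term memory** shape how
much a person learns when a robot passively guides their limb along a
movement they must later reproduce?

The package is aimed at motor-learning and psychophysics researchers who
want a complete, testable implementation of this pipeline — from trial-level
task data to a causal graph over per-participant measures — plus a
calibrated synthetic-cohort generator that stands in for human data in
validation, power analysis and methods work.

## What it computes

**Recognition memory (signal detection).** Hits/misses/false
alarms/correct rejections from 60 present/absent trials over elbow angles,
then

- sensitivity = hit/(hit + miss), precision = hit/(hit + false alarm),
- d′ = Z(hit rate) − Z(false-alarm rate), extreme rates replaced by 1/(2n),
- per-serial-position sensitivity and the memory-preference index
  (position 3 − position 1; negative = better memory for older items).

**Acuity (2AFC).** Maximum-likelihood cumulative-Gaussian fit
P(larger | Δ) = Φ((Δ − μ)/σ) to the 80-trial judgment task, and

&nbsp;&nbsp;&nbsp;&nbsp;JND = (x₇₅ − x₂₅)/2 = σ·Φ⁻¹(0.75) ≈ 0.6745 σ.

**Trajectory learning.** Peak normalized cross-correlation (a per-lag
Pearson correlation maximized over temporal shifts, FFT-accelerated)
between the 10-s, 250-Hz target and each reproduction; improvement =
mean(post) − mean(pre) over 5 + 5 trials; zero-lag RMSE as the
timing-sensitive complement.

**Causal stage.** DirectLiNGAM over the standardized triple
(JND, sensitivity, improvement) for the linear non-Gaussian model
xᵢ = Σⱼ bᵢⱼ xⱼ + eᵢ: greedy causal-order search by residual independence
(nonlinear-moment entropy approximation), adaptive-LASSO pruning (BIC,
OLS refit on the support), bootstrap edge/graph probabilities, HSIC and
Shapiro–Wilk assumption checks, and an ML SEM re-fit of the selected path
model with z tests and CFI/TLI/RMSEA/SRMR.

**Synthetic cohort.** `simulate_cohort()` generates trial-level data for
all three tasks from latent traits A (acuity), M (memory), L (learning)
linked by a standardized structural model (defaults: A→M = −0.39,
M→L = 0.70, no direct A→L path, uniform disturbances), with mechanistic
trait-to-parameter links calibrated so the scored cohort reproduces the
reference cohort means (sensitivity 0.84, precision 0.68, d′ 1.39,
JND 4.24°, improvement 0.14). See the vignette
(`vignettes/proprioceptive-learning.Rmd`) for the model and calibration
rationale.

## Worked example

```r
library(propriolearn)

co  <- simulate_cohort(cohort_config(n_participants = 40, seed = 2))
m   <- compute_participant_metrics(co)

mean(m$sensitivity); mean(m$jnd); mean(m$improvement)
paired_t_test(m$pre_mean_r, m$post_mean_r)

Z   <- scale(as.matrix(m[, c("jnd", "sensitivity", "improvement")]))
fit <- direct_lingam(Z)
fit
fit_path_model(Z, fit)
```

Output:

```
mean sensitivity 0.888 | precision 0.703 | d-prime 1.73
mean JND 4.43 deg | improvement 0.143
pre vs post: t(39) = 11.54, p = 3.8e-14
DirectLiNGAM causal graph
  causal order: sensitivity -> improvement -> jnd
  sensitivity -> improvement : +0.344
  exogenous: jnd, sensitivity
Path model (ML)
  sensitivity -> improvement : +0.344 (se 0.150, z = 2.29, p = 0.022)
  chi^2(2) = 3.088 | CFI 0.783 | TLI 0.674 | RMSEA 0.118 | SRMR 0.129
```

Reading this: passive guidance clearly improved reproduction (pre/post
paired t), memory sensitivity carries a positive path to improvement, and
no direct acuity (JND) → improvement edge survives pruning.  At n = 40 the
measured-variable graph is noisy — the acuity → memory edge is weak and the
causal order unstable across resamples — which is exactly what
`bootstrap_paths()` quantifies; the latent-trait recovery checks in the
test suite use n = 2000, where the default structural model is recovered
essentially always.

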