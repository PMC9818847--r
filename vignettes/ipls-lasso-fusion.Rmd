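---
title: "Interval-PLS member models fused by the Lasso: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval-PLS member models fused by the Lasso: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iplslasso)
```

## The problem

Egg freshness is conventionally graded by the Haugh unit (HU), a logarithmic
index of thick-albumen height $H$ (mm) and egg weight $W$ (g):

$$\mathrm{HU} = 100 \cdot \log_{10}\!\left(H - 1.7\,W^{0.37} + 7.57\right).$$

Measuring $H$ requires cracking the egg. A non-destructive alternative is to
calibrate HU against visible/short-wave-NIR semi-transmittance spectra
(%T over roughly 550–985 nm), where freshness-related changes — water loss
through the shell, protein-structure changes in the albumen — shift the
depths of absorption valleys near 645, 770, 880 and 970 nm. The calibration
problem is classic chemometrics: a few dozen reference samples against
thousands of collinear spectral variables.

`iplslasso` implements a two-stage strategy for this problem:

1. **Interval PLS (iPLS) member models.** The wavelength axis (p variables)
   is partitioned into $n$ contiguous intervals of equal width ($\lfloor p/n
   \rfloor$, the first $p \bmod n$ intervals receiving one extra variable).
   A mean-centred NIPALS PLS1 model is fitted per interval, its
   latent-variable (LV) count chosen by cross-validation (minimum RMSECV,
   ties to the smaller count).
2. **Lasso selection-and-fusion.** The members' *cross-validated* outputs
   form a samples × $n$ matrix $Z$, and HU is regressed on $Z$ with an
   L1 penalty:
   $$\hat\beta = \arg\min_\beta \frac{1}{2N}\sum_i \Big(y_i - \beta_0 -
   \textstyle\sum_j z_{ij}\beta_j\Big)^2 + \lambda \sum_j |\beta_j|.$$
   Members with exactly-zero coefficients are discarded; the survivors
   define the selected spectral intervals. The penalty is chosen by 5-fold
   cross-validation (minimum mean MSE over a 100-point log grid from
   $\lambda_{\max}$ down to $10^{-4}\lambda_{\max}$, ties to the larger,
   sparser $\lambda$). In the unscaled objective
   $\sum_i(\cdot)^2 + \lambda_u\sum_j|\beta_j|$ the equivalent penalty is
   $\lambda_u = 2N\lambda$.

The division count $n$ is swept over $1..40$. With $n = 1$ there is a
single member — the full-spectrum PLS model — and the fusion is defined as
the identity on it, so the sweep's first row *is* the PLS baseline.

Crucially, $Z$ holds out-of-fold predictions, never in-sample fits:
stacking on in-sample fits would leak training information into the fusion
weights and overstate member quality.

## Choosing the division

RMSECV (fusion applied to the cross-validated member outputs) tends to keep
falling as $n$ grows, while RMSEP on the held-out prediction set
deteriorates once the many narrow members start overfitting. `sweep_divisions()`
therefore recommends `best_n` as the division with the lowest RMSEP *among
those whose RMSECV is within 5% of the global minimum* (`cv_margin`,
configurable). This operationalizes the qualitative rule that predictive
performance must be weighed alongside cross-validation performance when
picking the fusion model.

Two stacked comparators bracket the fusion:

* **PLS-s1** — one PLS model on the concatenated columns of the selected
  intervals (the selected-interval combination used directly, without
  optimizing the combination);
* **PLS-s2** — the unpenalized OLS stack of *all* $n$ member outputs plus
  intercept, solved minimum-norm (SVD pseudoinverse, with a warning) when
  rank deficient.

## Protocol defaults and the knobs that matter

| knob | default | why |
|---|---|---|
| split ratio | 2:1, round-half-up | 103 samples give 69 calibration / 34 prediction |
| outlier `alpha` | 0.05 | two-sided 5% significance on both tests |
| fold scheme | 5-fold, one seeded shuffle, contiguous blocks | reused across LV selection, member CV and Lasso CV so all stages see identical splits |
| `max_lv` | 20, capped at `min(20, interval width, training fold − 2)` | standard chemometric ceiling |
| pretreatments | none / SNV / MSC / SG 1st derivative (5 pts, degree 2) | the four-way comparison for the PLS baseline |
| `n_max` | 40 | sweep range of the division count |
| `cv_margin` | 0.05 | near-minimal-RMSECV band for `best_n` |

Pretreatment notes: SNV uses the $n-1$ denominator (configurable); MSC
regresses each spectrum on the calibration mean spectrum and stores that
reference so prediction-set spectra are corrected against the *calibration*
reference; the SG derivative is per-index (the axis is treated as evenly
spaced; pass `delta` to rescale per nm) with polynomial-fit edge handling so
the column count is preserved.

Outlier screening is a standard chemometric stand-in, since only a
significance level is conventionally reported: spectral outliers by
Mahalanobis distance of PCA scores (components retaining ≥ 99% variance)
against a $\chi^2_{1-\alpha}$ cutoff, reference outliers by two-sided
z-score. Both thresholds are configurable; the choice of statistic is a
design decision, not a reconstruction of any particular study's procedure.

## The synthetic study

No public egg-spectra archive accompanies this problem, so the package
ships a generator (`sim_config()`, `generate_cohort()`,
`generate_spectra()`) whose defaults define the study conditions used by
the tests and the acceptance script:

* 105 eggs in equal batches over storage days {1, 3, 5, 7, 9, 11, 13};
* arrival weight from a normal with SD 4.095 g truncated to
  [49.095, 69.514] g — the underlying mean is solved numerically (closed-form
  truncated-normal mean + `uniroot`) so the *truncated* mean is exactly
  57.53 g, since naive truncation at these bounds would shift it by ~0.18 g;
* per-egg HU starting near 85 (SD 4), declining gently to ~79 by day 7,
  dropping to ~70 by day 9, then easing to ~62 by day 13, plus egg-level
  noise, clipped to [56, 91]; albumen height is back-solved from the HU
  formula so `haugh_unit()` reproduces the assigned HU exactly;
* weight-loss rate increasing and yolk coefficient decreasing with day,
  shape index centred at 1.273 (SD 0.037);
* spectra on 550–985 nm with 2041 points: a smooth transmittance baseline
  (attenuated ~1.2%/day) minus Gaussian valleys at 645/770/880/970 nm whose
  depths are affine in HU and day plus a per-egg jitter; three replicate
  readings per egg with log-normal multiplicative scatter, additive offset
  and iid noise.

The HU→valley-depth link is a Beer–Lambert-style surrogate: the real
literature gives band assignments, not a quantitative link, so the affine
coefficients are a stand-in. Valley depth also depends on storage day
independently of HU, emulating the partially decoupled water-loss dynamics.
The per-egg band-depth jitter is the knob that sets the attainable
calibration error; it was calibrated once so that the full-spectrum PLS
baseline lands near the 5–6 HU RMSEP scale typical of short-wave-NIR egg
calibrations, and is a calibration knob, not a claim about any instrument.
The absolute %T level of the baseline is likewise arbitrary.

What passing tests on this generator do show: the pipeline recovers planted
interval-confined signal, the fusion's selection keeps informative members
and drops noise members, and every stage's bookkeeping (splits, folds,
out-of-fold outputs, serialization) is exact. What they cannot show:
performance on real egg spectra, whose noise structure (detector drift,
shell-colour variation, temperature effects) the generator does not model.
One consequence is worth stating plainly: because the generator's
freshness link runs through four broad bands *and* a storage-correlated
baseline trend, nearly the whole synthetic spectrum is informative, so the
full-spectrum PLS baseline is close to the oracle model on this data. On
acceptance-script runs the fusion therefore clearly beats its own best
single member and the unpenalized stack, and roughly matches — but does
not systematically beat — the full-spectrum PLS at the prediction stage.
An advantage *over* full-spectrum PLS requires spectra in which informative
bands sit among uninformative or interference-dominated regions, which is
a property of real eggs the generator does not claim to reproduce.

`plant_interval_signal()` is the sharper oracle for selection tests: iid
noise columns everywhere except a contiguous band (fraction `span`, default
0.2) centred in each designated interval, whose columns share a latent
factor (band value = factor + independent column noise). The shared factor
matters: real absorption-band wavelengths rise and fall together, and that
collinearity is what lets an interval's PLS member extract the band cleanly.
An earlier uniform-independent-column variant made members far weaker than
any realistic band signal and is not what the helper should emulate. The
response adds each band's column average, so `y` remains an exact linear
function of the signal intervals' columns.

## Numerical choices

* **NIPALS PLS1** deflates both `X` and `y`; the regression vector is
  recovered as $B = W (P^\top W)^{-1} q$ (triangular backsolve), and the
  per-LV vectors $B_1..B_K$ are kept so cross-validation evaluates every
  LV count from one fit per fold. If deflation exhausts the covariance
  (weight norm < 1e−12) the component sequence is truncated and higher
  counts reuse the last valid $B$; a response entirely orthogonal to `X`
  yields $B = 0$ and mean-prediction.
* **Lasso coordinate descent** runs in compiled code (covariance-form
  updates with active-set iteration, as production Lasso solvers do),
  standardizes $Z$ internally (population variance), leaves the intercept
  unpenalized, and back-scales coefficients; back-scaled magnitudes below
  1e−10 are reported as exact zeros. Convergence is a three-rule ladder:
  maximum coefficient change < 1e−7; global KKT violation < 1e−8 (which
  certifies exactly-duplicated members, whose optimum is a whole segment);
  and, only after 1000 sweeps, per-sweep guaranteed objective decrease
  < 1e−9 · var(y). The last rule matters at high divisions, where adjacent
  narrow intervals inside one absorption band produce member outputs
  correlated beyond 0.999: the coefficient split between near-duplicates
  is then ill-conditioned and wanders along an almost-flat valley long
  after the fitted values have converged, so meaningful objective
  progress — not coefficient identity — is the right criterion. Ordinary
  problems always stop on the first rule at full precision. Constant
  columns are excluded from the active set.
* **Ties** break conservatively everywhere: smallest LV count, largest
  (sparsest) $\lambda$, first minimum in the division sweep.
* **Rounding**: the calibration share rounds half-up, so 103 samples at
  2:1 give 69, matching the arithmetic a 2:1 split is expected to print.
* **Serialization**: model bundles are JSON with 17 significant digits, so
  reloaded models predict bit-identically.
* Intervals are 0-width-safe by construction (`n ≤ p` enforced); reports
  use 1-based "k/n" labels while column indexing is internal.

## Problem sizes used by the test suite

Unit and property tests run on small synthetic problems (tens of samples,
p ≤ 200). The study-scale checks use the full spectral width: planted-signal
recovery at p = 2041 with 100 samples (20 seeds for interval recovery and
fusion support coverage, 10 paired seeds for the fusion-vs-member
comparison), and the acceptance script executes the complete protocol —
replicate averaging, outlier removal, 2:1 split, four-way pretreatment
comparison, divisions 1..40, both stacked comparators — on the default
105-egg study. These sizes are the package's chosen validation conditions.

## Known limitations

* PLS1 only (single response); no PLS2, kernel or nonlinear variants.
* Equal-width contiguous intervals only: no moving windows, no
  backward/forward interval elimination, no genetic-algorithm or true
  synergy-interval search over interval combinations.
* The Lasso is plain L1 — no elastic net, adaptive or group penalties —
  so among highly correlated members the particular survivor is somewhat
  arbitrary even though the fused prediction is stable.
* The outlier statistics are a defensible convention, not a reconstruction.
* The generator is phenomenological; conclusions about real instruments
  require real spectra.

## A minimal run

```{r example, eval = FALSE}
study <- simulate_study(sim_config(seed = 1))
flags <- detect_outliers(study$spectra)
ds <- remove_outliers(study$spectra, flags)
sp <- split_calibration(ds, ratio = c(2, 1), seed = 2)
folds <- make_folds(n_samples(sp$calibration), k = 5, seed = 3)

sweep <- sweep_divisions(sp$calibration, sp$prediction,
                         n_max = 40, folds = folds)
glance(sweep)
autoplot(sweep)

best <- attr(sweep, "best_model")
tidy(best)
plot_predictions(best, sp$prediction)
```

The same protocol, including the pretreatment comparison and the stacked
comparators, is available end to end as `run_simulate()` → `run_fit()` →
`run_predict()`, with a thin command-line wrapper in
`inst/cli/iplslasso.R`.
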