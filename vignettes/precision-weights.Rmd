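---
title: "Bootstrap precision weights for label-fusion volumetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap precision weights for label-fusion volumetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasboot)
```

## The statistical model

A volumetric study measures, for each of $n$ subjects, an ROI volume
$Y_i$ (mm³) by fusing the labels of $m$ registered atlases on the
subject's target image $T_i$. We model

$$Y_i = X_i^t \beta + \varepsilon_i, \qquad
\mathbb{E}[\varepsilon_i] = 0, \qquad
\operatorname{Cov}(\varepsilon_i, \varepsilon_j \mid T_1,\dots,T_n) =
\begin{cases} \sigma_i^2 & i = j\\ 0 & i \neq j,\end{cases}$$

where $X_i$ collects the covariates (an intercept, age, intracranial
volume, a group indicator). The essential departure from the textbook
linear model is that the $\sigma_i^2$ differ by subject: the error is
dominated by the segmentation procedure, and targets that align poorly
with the atlas set are segmented less reproducibly. Conditional on the
targets, the atlases are the source of randomness, and errors are taken
uncorrelated across subjects — each subject is segmented independently.

Under this model the weighted least-squares estimator
$\hat\beta = (X^tWX)^{-1}X^tWY$ with $W = \operatorname{diag}(w_i)$ is
unbiased for any positive weights, and by the Aitken theorem its
coefficient variances are minimised at $w_i = 1/\sigma_i^2$ — the
subject's *precision*. The package verifies this empirically rather than
formally: on simulated cohorts with known $\sigma_i^2$, the variance of
the group-effect estimate under inverse-variance weights is checked to be
strictly below the unit-weight and inverse-CV alternatives (2000
replicates at 160 subjects in the shipped tests), and both weightings are
checked to be unbiased within Monte Carlo error.

## Estimating the conditional variance: the atlas bootstrap

$\sigma_i^2 = \operatorname{Var}(Y_i \mid T_i)$ describes variability of
the volume estimate under hypothetical re-draws of the atlas collection,
with the target fixed. No closed form is available for a fusion pipeline,
so the package estimates it by bootstrapping the atlases: draw $B$
collections of size $m$ with replacement from the atlas pool, fuse each
collection, extract the ROI volume, and take the unbiased sample variance
(divisor $B-1$) of the $B$ replicate volumes. The precision weight is its
reciprocal; the inverse-CV weight — kept as a comparison scheme — is the
reciprocal of (sd / mean) of the same replicates.

Choices worth stating explicitly:

* **$B$ (default 300), $m$ = pool size.** The
  `running_variance_curve()` diagnostic tracks the variance of the first
  $n$ replicates as $n$ grows; the shipped tests check on phantom scenes
  that the value at $B = 300$ sits within 20% of the $B = 1000$ value for
  at least 9 of 10 seeds, which is the stabilisation behaviour the default
  relies on. Replicate order is generation order, so the curve is
  meaningful.
* **Degenerate collections are kept.** A resample in which one atlas
  fills all $m$ slots is a legitimate bootstrap draw; excluding such
  collections would bias the variance downward.
* **Floors.** Identical replicates (possible only in noise-free synthetic
  unanimity) give variance exactly 0; `precision_weight()` caps the weight
  at `1/variance_floor` (default floor $10^{-9}$ mm⁶) and the record is
  flagged `variance_floored`, so degenerate inputs are visible rather than
  infinite. `cv_weight()` uses an analogous floor of $10^{-6}$.
* **Reproducibility.** Each subject's replicate stream derives from the
  global seed and the subject's identifier, so a cohort can be processed
  in any order, or in parallel, with identical output.
* **Fusion-agnosticism.** The bootstrap needs only "fuse a collection,
  measure a volume". Two engines ship for desk-scale work — majority vote
  and a patch-similarity locally weighted vote — and any external fusion
  tool can be used instead by supplying its replicate volumes as a CSV
  (`weights_from_replicates()`).

## The fusion engines

Both engines are deterministic, so re-fusing a collection is exactly
reproducible, and both break voting ties in favour of the smallest label
id — an arbitrary but platform-stable rule.

*Majority vote* labels each voxel with the label endorsed by the most
atlases in the collection (duplicates from resampling count once per
slot).

*Locally weighted vote* weights atlas $a$ at voxel $v$ by
$\exp(-\mathrm{SSD}_a(v) / (h\,|P(v)|))$, where $\mathrm{SSD}_a(v)$ is the
sum of squared intensity differences between target and atlas over the
cubic patch $P(v)$ of radius 1 voxel (3×3×3 by default) centred at $v$.
Patches are clipped at the image border and the SSD is normalised by the
clipped patch size $|P(v)|$, which avoids any padding convention. The
bandwidth $h$ defaults to the sample variance of the target intensities,
making the kernel scale-free under intensity rescaling; both radius and
bandwidth are overridable. With identical target and atlas intensities
all weights coincide and the engine reduces exactly to majority vote.

ROI volume is voxel count × physical voxel volume, with voxel dimensions
carried from the NIfTI header zooms; an empty ROI is legal and yields 0
mm³, which the weight layer then flags via the variance floor rather than
erroring.

## Weighted permutation inference

Since the weights are estimated from the same images being analysed, the
parametric WLS t reference is not trusted; p-values come from permutation.

The primary scheme residualises the predictor of interest $x$ (the group
label) against the nuisance design $Z$ (intercept, age, ICV) by WLS with
the same weights, and permutes those residuals $e$ to build surrogate
predictors $x^* = \pi(e)$. For each of `n_perm` permutations the full
weighted model of $y$ on $[x^*, Z]$ is refitted and the t-statistic of
$x^*$ recorded. The raw (not re-weighted) residuals of the weighted fit
are what gets permuted. The secondary Freedman–Lane scheme instead
permutes the residuals of $y$ on $Z$ and adds them back to the reduced
fit before refitting the full model; under the null both are valid and
the tests agree within Monte Carlo error.

Numerical and counting choices:

* The two-sided p-value pools the observed statistic with the permuted
  ones: $p = (\#\{|t^*| \ge |t_{\mathrm{obs}}|\} + 1)/(n_{\mathrm{perm}}+1)$.
  Inclusive counting of ties is deliberate: it guarantees
  $p \ge 1/(n_{\mathrm{perm}}+1)$ and test validity, where strict
  exceedance could produce $p = 0$. Strict counting is available behind
  the `strict` flag for comparison.
* `n_perm` defaults to 999, so 1000 statistics enter the pooled
  proportion.
* Permutations are drawn uniformly with replacement from the permutation
  group (not guaranteed distinct), seed-reproducibly. The shipped tests
  check the Monte Carlo p against exhaustive enumeration of all 120
  permutations at $n = 5$.
* Internally each permutation refit uses the Frisch–Waugh–Lovell
  residualised form against the pre-computed weighted QR of $Z$, which is
  algebraically identical to the full refit (asserted in the tests against
  explicit `wls_fit()` calls) and makes a 1000-permutation test on 160
  subjects a few matrix products.
* Rescaling all weights by a positive constant leaves coefficients,
  t-statistics and p-values exactly unchanged, so only relative precision
  matters.

With unit weights the primary scheme is the standard unweighted
residual-permutation (Smith) method. Its finite-sample validity is
asymptotic rather than exact, which is why the package ships null
calibration experiments rather than assuming it.

## The simulation experiments

`type1_experiment()` draws, per replicate, $2n$ subjects *without*
replacement from a null pool, assigns artificial 0/1 labels at random
($n$ per group), and tests the label effect under each weighting scheme;
the fraction of p-values strictly below $\alpha$ (default 0.05, matching
the convention of counting p-values $< 0.05$) estimates the type I error.
`power_experiment()` draws $n$ subjects *with* replacement from each of
two pools; resampled duplicates are treated as distinct observations, as
a resampling design implies. Covariates, volumes and weights travel
together in every draw — they belong to the subject. Within a replicate
all schemes share one permutation sequence, so scheme comparisons are
paired and, under homoskedasticity (constant weights), precision and
identity schemes give identical p-values replicate by replicate.

The shipped calibration uses 1000 replicates of 160-subject null cohorts
with 999 permutations (a few minutes on one CPU); the power comparison
uses a sparse grid ($n = 40, 160$ per group) with 300 replicates. Grid
endpoints mirror common study sizes ($n$ up to 80 per group for the null
sweep, 160 for power) and are configurable.

## What the synthetic generators emulate — and what they do not

**Phantom scenes** stand in for registered atlas sets. Truth is a
voxelised ellipsoid (default semi-axes 6×5×4 mm on a 24³ 1 mm grid);
the target intensity is box-smoothed truth plus Gaussian noise; each
atlas is the truth translated by a per-axis Normal(0, `shift_sd`)
displacement rounded to whole voxels (nearest-voxel resampling keeps
labels integral), with boundary labels flipped at `label_flip_rate` and
an intensity channel rebuilt from its own labels. Rigid translation plus
boundary noise is deliberately minimal: it reproduces the phenomenology
that matters to the method — atlases disagree more when alignment is
poor, so bootstrap variance grows with `shift_sd` (checked over 20 seeds
on a 3-point misalignment grid) — without modelling deformable
registration, correlated atlas errors, bias fields or motion artifacts.
Passing tests on phantoms therefore validate the bootstrap and inference
machinery, not the realism of any particular registration pipeline.

**Cohort tables** are drawn from exactly the heteroskedastic model above:
age uniform on 55–95 years, ICV Normal(1.4×10⁶, 1.2×10⁵) mm³, volume
$7400 + 10(\mathrm{age}-75) + 0.001\,\mathrm{ICV}$ mm³ plus the group
effect, with $\sigma_i = 100 \times \mathrm{LogNormal}(0, 0.5)$ mm³.
The intercept calibrates mean volume to the 7.4 cm³ centre of typical
atlas hippocampal volumes, and the age window matches the usual range of
aging-study cohorts. Hidden truth columns (`true_sigma2`, `outlier`)
support parameter-recovery tests; the `precision_weight` column is the
oracle $1/\sigma_i^2$, with an optional noisy variant in which the
estimated variance is a scaled $\chi^2_{B-1}$ draw ($B = 300$ by
default), emulating bootstrap estimation error. The outlier model — a
per-group flag rate, an additive volume shift and a multiplicative
variance inflation — reproduces the structure in which a case group
contributes mostly *high* outlying, low-precision volume estimates. The
shipped power experiment uses a modest atrophy effect of −150 mm³ with a
10% outlier rate, +1500 mm³ shift and 100× variance inflation in the case
group: the outliers cancel the effect in the unweighted analysis, which
is precisely the regime where precision weighting recovers power (the
tests require a gain of at least 0.1 at the largest sample size).

## Known limitations

* The bootstrap estimates the variance *given the target image*; scan-
  rescan variability of the same subject is invisible to it and is not
  modelled.
* Errors are assumed uncorrelated across subjects; generalised least
  squares with off-diagonal covariance (e.g. shared-scanner effects, or
  the cross-ROI covariance the bootstrap could also estimate) is out of
  scope.
* The desk-scale engines are deliberately simple; correlated-error
  weighting (joint label fusion) and deformable registration are not
  reimplemented, and the CSV replicate route exists so production
  pipelines can plug in their own fusion.
* Stochastic acceptance checks are seeded; a fixed-seed run of a
  statistical test at a sharp significance cutoff can land on the wrong
  side by ordinary sampling fluctuation, which is why the calibration
  checks state binomial error bounds rather than point targets.
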