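---
title: "Health space models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Health space models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthspace)
```

# The problem

Population cohorts routinely carry an *ordered* health-status outcome —
here four groups: healthy (0), one metabolic risk factor (1), two risk
factors (2), metabolic syndrome or an oxidative-stress-related disease (3)
— together with clinical covariates that are biologically tied to two broad
stress processes: oxidative stress (age, sex, smoking, white blood cell
count, ALT) and metabolic stress (age, sex, BMI, triglycerides, HDL,
fasting glucose). A health space (HS) model embeds each individual at a
2-D point, one coordinate per stress axis, such that the ordered groups
separate visibly. The embedding is a *visualization and separation*
problem, not a classification problem: AUC or accuracy would reward sharp
decision boundaries, whereas what matters here is that the group clouds
occupy distinct, ordered regions of the plane. That is why model quality
is measured by the ellipse-overlap Health Space Index and clustering
validity indices rather than by classification metrics.

# The ordinal network

For one axis with covariates $x \in \mathbb{R}^p$ the model is

$$\log \frac{\Pr(Y > j \mid x)}{\Pr(Y \le j \mid x)} = \alpha_j + f(x)^\top
\beta, \qquad j = 0, \dots, J-2,$$

with $f$ a stack of dense ReLU layers (default widths 32 and 16), a single
coefficient vector $\beta$ shared by all thresholds, and per-threshold
intercepts $\alpha_j$. Sharing $\beta$ is what makes the $J-1$ cumulative
classifiers *consistent*: all thresholds see the same 1-D score
$s = f(x)^\top \beta$, and only the intercept moves. The health score is
$s$ itself — the quantity plotted — and is unaffected by the intercepts.

The loss is the sum over samples and thresholds of the binary
cross-entropies of the exceedance indicators $y^{(j)} = I(y > j)$:

$$-\sum_i \sum_{j=0}^{J-2} \left\{ y_i^{(j)} \log \sigma(s_i + \alpha_j) +
(1 - y_i^{(j)}) \log \big(1 - \sigma(s_i + \alpha_j)\big) \right\}.$$

It is computed in the standard logits form
$\max(z,0) - zy + \log(1+e^{-|z|})$, which is exact and finite for logits
of any magnitude; at all-zero logits it equals $(J-1)\ln 2$ per sample.
With $J = 2$ it is exactly the logistic-regression deviance, and with zero
hidden layers the model *is* logistic regression — the test suite verifies
that a zero-hidden-layer fit matches an IRLS oracle to within 0.01 in
predicted probability.

## Training and its tunable parameters

* **Optimizer**: Adam, learning rate 0.001, batch size 100, up to 150
  epochs — the reference training regime for cohort-scale data. Gradients
  are averaged within a batch for learning-rate stability; the logged loss
  is the summed form.
* **Early stopping**: a 10% random validation split, patience 10 epochs,
  best-epoch weights restored. The split, initialization and batch order
  all derive from the `seed` argument, so fits are bit-reproducible.
* **Standardization**: covariates are z-scored with training-set statistics
  inside `donn()`; the constants are stored and reused when scoring new
  data. This stabilizes optimization and costs nothing in generality.
* **Initialization**: He-scaled normal weights for ReLU layers;
  intercepts start at a small decreasing ramp.
* **Intercept ordering** is *not* enforced during training — the plain
  formulation is kept — but the fitted model records an `alpha_ordered`
  diagnostic; on separable data the ordering emerges by itself.
* **Identifiability**: $(f, \beta)$ are only identified up to scale and
  rotation of the last hidden layer, so recovery is asserted at the level
  of predicted probabilities and the *rank* of the health score (Spearman
  correlation with the true latent score), never on raw network weights.

Degenerate inputs are rejected with named errors: a category absent from
the training split, non-finite losses (with the epoch index), covariate
width mismatches at prediction time.

The four binary variants (`0 vs 3` on the extreme-group subset;
`0 vs 1+2+3`, `0+1 vs 2+3`, `0+1+2 vs 3` on relabelled full data) reuse the
identical network, optimizer and hyperparameters, so comparisons isolate
the value of the ordinal information. The proportional odds baseline is
delegated to `MASS::polr` and remapped to the same $Y > j$
parameterization ($\alpha_j = -\zeta_j$).

# From scores to the health space

`health_space()` pairs one fitted model per axis. Because the raw score
$\hat W \hat\beta$ is unbounded while the plotted scores should live on
$[0,1]$, two normalizers are offered; which transformation the original
construction used is not fixed by its description, so both are documented
and the choice is recorded in the output:

* **min–max** (default): training scores are mapped so their minimum is
  exactly 0 and maximum exactly 1; external cohorts reuse the frozen
  constants and are clamped, with a logged count of clamped points.
* **sigmoid**: $\sigma(s + \bar\alpha)$, which never clamps but does not
  attain the endpoints.

Axis orientation is normalized so larger always means worse: if a fitted
axis score has negative Spearman correlation with the group rank the sign
is flipped and recorded. External cohorts are scored with the frozen
models, flips and constants — never refitted — mirroring external
validation.

# The Health Space Index

The HSI construction here is a faithful but independent implementation of
the ellipse-overlap idea; the original's exact confidence level, covariance
estimator and overlap algorithm are not published alongside it, so numeric
parity with previously printed values is not claimed. Choices, all
configurable:

* per-group ellipse: sample mean and sample covariance, region
  $(z-c)^\top \Sigma^{-1} (z-c) \le \chi^2_2(0.95)$; singular covariances
  are ridged by $10^{-8}$ (with a warning) instead of excluding the group,
  so the pairwise table stays complete;
* overlap: Jaccard index of the two elliptical regions, integrated either
  on a 512×512 grid over the 5%-padded union bounding box (error
  $O(1/\text{resolution})$; disjoint bounding boxes short-circuit to 0
  exactly) or by uniform Monte-Carlo sampling (200,000 points, fixed
  seed); the two integrators agree within 0.01 and both match the
  closed-form circle-lens area within 0.005 in the tests;
* orientation: $\text{HSI} = 1 - \text{Jaccard}$ per pair, so higher is
  better; the model summary is the unweighted mean over the
  $J(J-1)/2 = 6$ pairs.

Because Jaccard is a ratio of areas, applying one common affine map to all
points leaves every pairwise HSI unchanged (areas scale by the same
determinant) — a property the acceptance tests verify within grid
tolerance. Groups with fewer than three points cannot carry an ellipse and
are reported as missing pairs.

The three clustering indices (silhouette, Davies–Bouldin,
Calinski–Harabasz) are computed on the 2-D scores with the given group
labels, Euclidean metric throughout. Singleton-cluster silhouette is set
to 0, the common convention; coincident centroids (Davies–Bouldin) and
zero within-dispersion (Calinski–Harabasz) are surfaced rather than
silently patched. Each implementation is checked against an independent
brute-force oracle to $10^{-10}$.

# Bootstrap comparison

`bootstrap_hsi()` resamples the training cohort with replacement, refits
the chosen model on both axes per replicate (the faithful, expensive
default; score-only resampling is available via `refit = FALSE`),
recomputes the average HSI, and summarizes B replicates by their mean and
2.5/97.5 percentiles. Evaluation on the replicate itself is the default —
the variability being quantified is that of the *training data* — with
out-of-bag evaluation as an option, since the original procedure does not
state which was used. Replicates missing a category are redrawn (at most
10 times). The reference replicate count is B = 200; worked examples and
tests use B = 20–50, which already stabilizes the percentile interval at
these cohort sizes.

# The synthetic cohort generator

`generate_cohort()` emulates the *statistical structure* the HS models
assume, not any real population: two covariate blocks of widths 5 and 6
whose first two columns (age and sex analogues) are shared draws,
continuous covariates standard normal, binary covariates (sex, smoking
analogues) Bernoulli(1/2), and labels drawn from

$$\Pr(Y > j \mid x) = \sigma\!\big((\alpha_j + g(x)) / s\big),$$

where $g$ is linear in the true block coefficients plus an optional
quadratic ($c\,x_1^2$) or interaction ($c\,x_1 x_2$) term, and $s$ is the
latent logistic noise scale (`noise_scale`, default 1, which reduces to
the plain cumulative-logit model). Labels are sampled by inverse CDF with
one uniform draw per row — $y_i = \sum_j I\{u_i < \Pr(Y_i > j)\}$ — which
is exact, $O(nJ)$ and reproducible. Defaults: $\alpha = (1, 0, -1)$,
moderate mixed-sign coefficients on both blocks, nonlinearity coefficient
1. The quadratic regime exists to give the network a relationship a linear
model cannot represent; on such cohorts (n = 5,000) the ordinal network
beats the proportional odds baseline in average HSI on every seed tested.

What the generator does **not** emulate: realistic covariate marginals or
correlations of any actual survey, the clinical diagnosis-based group
assignment, missingness, or measurement error. Passing tests therefore
demonstrate correctness of the machinery and qualitative behaviour under
known ground truth — not performance on real cohort data, which is
access-restricted and out of scope.

# Problem sizes and numerical tolerances

The analyses shipped with the package use sizes chosen to make every
experiment exact enough to be conclusive while remaining desk-scale:
parameter recovery of the proportional odds baseline at n = 20,000
(every parameter within 0.1 of truth; mean bias below 0.03 over 20
replicates), score-rank recovery of the network at n = 20,000 (Spearman
> 0.95), the six-model comparison at n = 5,000 with 60-epoch fits, and
bootstrap B = 50 in the acceptance script. Monte-Carlo label-frequency
checks run at n = 50,000 within 3 binomial standard errors.

# Known limitations

* The network health score is interpretable only up to monotone
  transformation; feature-level attribution is not provided (the linear
  POM baseline is the interpretable fallback).
* Two axes only; extending to a third (e.g. inflammation) would require
  generalizing the ellipse overlap to ellipsoids, which is deliberately
  not implemented since all reference results are 2-D.
* Min–max normalization is sensitive to extreme training scores; the
  sigmoid normalizer is the robust alternative.
* Training determinism holds for a fixed seed on a fixed BLAS/threading
  configuration, as with any floating-point minibatch optimizer.
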