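---
title: "Methods: the acute mediastinitis recovery scale and its machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the acute mediastinitis recovery scale and its machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amprog)
```

## The prognostic model

The scale summarizes eight admission parameters into three latent
factors and turns them into a recovery/death prediction. Formally, for
a patient with raw parameter vector $x$ (order: HGB, total protein,
coexisting diseases, WBC, age, albumin, CRP, PCT),

$$z_i = \frac{x_i - \mu_i}{\sigma_i}, \qquad F_j = \sum_{i=1}^{8} w_{ij}\, z_i,$$

where $\mu, \sigma$ are the derivation cohort's means and sample
(n−1) standard deviations (`am_reference()`) and $W = (w_{ij})$ is the
varimax-rotated weight matrix (`am_weights()`). The factors have
clinical readings: $F_1$ *proteinic status* (high = well-nourished,
predicts recovery), $F_2$ *inflammatory status* and $F_3$ *general
risk* (high values of either predict death).

Each factor votes "recovery" by a strict inequality —
$F_1 > -1.4$, $F_2 < 1.0$, $F_3 < 0.4$ — and the default prediction is
the 2-of-3 majority of votes. Two alternative combination rules are
exposed because the derivation study is ambiguous about how the
factors were combined: `f1_only` (which reproduces the study's
per-case classification column exactly, 44/44, with 7
misclassifications) and `unanimous`. Majority is the default because
it is the only simple rule that reproduces the study's *overall*
sensitivity of 90% and specificity of 64% on the printed scores, while
the per-case column follows factor 1 alone; both facts are checked in
the test suite.

Assumptions worth stating plainly: the weights are applied to
standardized values as-is (the derivation study uses the rotated
matrix entries verbatim as score coefficients, and the printed factor
SDs of roughly 2.98/1.50/1.52 — far from 1 — are consistent only with
that convention). The textbook regression estimator
($R^{-1}W$ applied to $z$) is available as
`factor_scores(..., method = "regression")` for methodological
comparison, but it is *not* what reproduces the published scores.

## Scoring conventions and edge cases

* A score exactly at a cutoff votes **non-recovery**. This is the
  conservative direction (toward predicting death, hence toward more
  aggressive treatment); no published score sits on a cutoff, so the
  choice does not affect reproduction.
* Sensitivity `snc = 100*tp/(tp+fn)` and specificity
  `spc = 100*tn/(tn+fp)` are kept at full precision and rounded only
  for display; a zero denominator yields `NA`, never 0.
* `derive_thresholds(method = "youden")` searches the midpoints of
  adjacent sorted observed scores and maximizes SNC/100 + SPC/100 − 1;
  the recovery side is the side of the recovery-group mean, and ties
  are broken toward the lowest cutoff. This is an explicit extension:
  the original cutoffs were read off density traces by eye, and indeed
  the Youden optimum for factor 1 on the published scores (−1.508) is
  close to, but not equal to, the published −1.4.

## The factor-analysis pipeline

`derive_scale()` re-creates the derivation path on any cohort with
more patients than parameters:

1. **Correlation.** Pearson correlations of the raw parameters
   (`correlation_matrix()`); constant columns are refused by name.
2. **Extraction.** Principal components of the correlation matrix
   (initial communalities fixed at 1); unrotated loading $j$ is
   $v_j\sqrt{\lambda_j}$. Retention is the strict Kaiser rule
   $\lambda > 1$: an eigenvalue of exactly 1 (the identity-matrix edge
   case) is not retained.
3. **Rotation.** Varimax with Kaiser row normalization (rows scaled to
   unit communality during rotation), implemented as pairwise Jacobi
   sweeps with the closed-form quartic angle per pair; convergence
   when the criterion gain per sweep drops below `tol = 1e-10`, with a
   hard cap of 1000 sweeps (exceeding it is an error that reports the
   last gain, not a silent return). Row communalities are preserved to
   machine precision. Output is made deterministic by sorting columns
   by explained variance and signing each so its largest-magnitude
   loading is positive — the orientation of the published matrix,
   where each factor's dominant markers load positively. The
   implementation is cross-checked in the tests against
   `stats::varimax` and against a brute-force rotation-angle grid
   (10^-4 rad) in the two-factor case.
4. **Thresholds.** Youden search on the resulting scores (above).

Degenerate inputs fail loudly: derivation is refused for $n \le 8$
(singular correlation), while *scoring* with a fixed external scale
has no such restriction.

## Validation statistics

`describe()` reports the usual moments plus *standardized* skewness
and kurtosis: the adjusted Fisher–Pearson statistics $G_1, G_2$
divided by $\sqrt{6/n}$ and $\sqrt{24/n}$. This is the convention of
the major desktop statistics packages and is the one that reproduces
the published summary table (e.g. standardized skewness −1.88, 2.64,
0.26 for the three factors); the unadjusted moment variants do not.

For the two-outcome comparison, `compare_groups()` runs one-way ANOVA
(`stats::oneway.test`, equal variances; for two groups $F = t^2$),
Levene's test (`car::leveneTest`) and Kruskal–Wallis
(`stats::kruskal.test`), and recommends ANOVA when Levene's $p \ge
0.05$ and Kruskal–Wallis otherwise. **Levene centering defaults to the
median** (Brown–Forsythe). The derivation study does not say which
variant it used, but median centering reproduces all three published
Levene statistics to the printed precision (4.0978; 8.9967; 0.0001
with $p = 0.9929$) whereas mean centering does not (4.18 for the
first); both variants are computed in the reproduction report.

## The synthetic cohort generator

`simulate_cohort()` draws patients from the minimal generative model
consistent with a loadings-based factor analysis: latent
$f \sim N(0, I_k)$, standardized observations
$z = \Lambda f + \Psi^{1/2}\varepsilon$ with
$\Psi = I - \mathrm{diag}(\Lambda\Lambda^\top)$, raw values
$x = \mu + \sigma z$. Defaults are the published loadings and moments,
so the implied correlation structure is $\Lambda\Lambda^\top + \Psi$
and parameter recovery against $\Lambda$ is meaningful. Outcomes are
linked to the latent structure either by applying the published
thresholds and majority rule to the scores $W^\top z$ (with an
optional independent label-flip probability), or by a logistic model
$P(\text{death}) = \mathrm{logit}^{-1}(a + b(-f_1 + f_2 + f_3))$ whose
defaults $a = -0.9, b = 1$ give roughly the one-third mortality of the
clinical series.

Raw values are forced onto their natural ranges: the comorbidity count
is rounded to a non-negative integer, strictly positive parameters are
floored at small positive values, and CRP/PCT at 0. Under the
published moments about 3.4% of cells are affected — almost all of
them procalcitonin, whose mean (2.93) is smaller than its SD (3.92),
so a normal marginal is left-truncated. The generator reports clip
rates above 1% and keeps the pre-adjustment standardized matrix as an
attribute; convergence of the generated correlations to
$\Lambda\Lambda^\top + \Psi$ is tested on that matrix, since
truncation attenuates the PCT row of the raw-scale correlations by
construction.

What the generator does **not** emulate: skewed or heavy-tailed
marginals (real CRP/PCT are log-normal-ish, not truncated normal),
covariate dependence beyond the three-factor structure, missingness,
or cohort heterogeneity (etiology, referral delay). Passing
parameter-recovery tests therefore shows the pipeline recovers a known
linear-Gaussian structure at realistic $n$ — not that three factors
are the truth about mediastinitis.

## Problem sizes and reproducibility

The recovery experiment used in the tests runs 20 seeded cohorts of
n = 2000; it retains three factors by the Kaiser rule in ≥ 95% of
seeds and attains mean aligned Tucker congruence ≥ 0.98 against the
generating loadings (alignment = best column permutation and sign,
enumerated exactly for k ≤ 6). Convergence of the generated
correlation structure is checked at n = 20000 averaged over 5 seeds,
because a single cohort's Frobenius distance sits at the sampling
floor (≈ 0.045). All simulation entry points take an explicit seed,
use one RNG stream per cohort and restore the caller's RNG state.

## Known limitations

* The scale's constants come from a single-centre series of 44
  consecutive patients; the package reproduces that scale, it cannot
  revalidate it. External validation would need new cohort data.
* The raw 44 × 8 parameter table behind the published scale was never
  released, so the original rotation cannot be re-derived bit-for-bit;
  the factor-score table, constants and weight matrix are embedded and
  every downstream statistic is recomputed from them.
* Units are not converted or checked beyond positivity: inputs must
  arrive in the units of the derivation cohort (conventional clinical
  units for the printed magnitudes; after standardization the
  arithmetic is unit-agnostic, but a unit mismatch silently shifts
  z-scores).
* With 8 parameters, three factors explain ~69% of variance; the
  remaining variance is irreducible at this design, which is why
  mutually overlapping score distributions (and hence FP/FN cases) are
  expected even in the derivation data.
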