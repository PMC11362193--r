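---
title: "Four statistical indices of masculinity-femininity: models, assumptions, and measurement error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four statistical indices of masculinity-femininity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(mfindex)
library(dplyr)
```

## The problem

Researchers studying sex-related individual differences often want to place
multivariate trait profiles — body measurements, personality scales, brain
morphometry components — on a single masculinity-femininity continuum,
anchored to the empirical male and female trait distributions. There is more
than one defensible way to do this, and the alternatives can disagree: the
same profile can be on the masculine side of one index and the feminine side
of another. `mfindex` computes four complementary indices from the same
fitted model so that their agreement (or disagreement) becomes part of the
analysis rather than an accident of method choice.

## The common z-space

Everything happens in a standardized space. Let the sample contain males and
females measured on `p` numeric traits. Each trait is centered on the
*unweighted* mean of the male and female trait means — the midpoint between
the two centroids, deliberately not the grand mean, so that unequal group
sizes do not shift the origin — and divided by its pooled within-sex SD
(two-group pooling, denominator `n_M + n_F - 2`). In this z-space:

* `d` is the vector of Cohen's d values, `d_j = (mean_M - mean_F) / sd_pooled`,
  with positive values meaning higher male means; the male and female
  centroids sit at `+d/2` and `-d/2`;
* `R` is the pooled within-sex correlation matrix, obtained by centering
  each sex at its own mean, concatenating the residuals and taking the
  cross-product with denominator `n - 2`. Computed this way its diagonal is
  exactly 1 (the z columns have pooled variance 1 by construction), which in
  turn makes several exactness guarantees below hold to machine precision
  rather than approximately.

## The four indices

**Sex-directionality** projects a profile on the centroid axis:
`mfd = z'd / ||d||`. Each trait contributes independently, weighted by its
own univariate sex difference; correlations between traits play no role.
`||d||` is the standardized Euclidean distance between the centroids, and
normalizing by it puts directionality on a scale comparable with
typicality.

**Sex-typicality** projects on the discriminant axis, the direction that
maximizes the statistical separation between the sexes under equal
within-sex covariance matrices: `a = R^-1 d`, and `mft = z'a / c`. The
normalizer `c` is chosen so that the pooled within-sex variance of the
scores equals 1 on the training sample. Because the within-sex variance of
`z'a` is `a'Ra = d'R^-1 d = D_M^2`, that normalizer is `c = sqrt(a'Ra) =
D_M`, the Mahalanobis distance between the centroids. (A normalizer of the
form `1/sqrt(a'R^-1 a)` circulates in the literature; it does not satisfy
the unit-within-sex-variance contract, which is the property the package
honors and unit-tests. Users comparing numbers across implementations
should check which normalizer was used — the two differ by a constant
factor, so correlations and discordance classifications are unaffected.)

**Sex-probability** is the estimated probability of being male under equal
priors: `mfp = plogis(z'a)` with the *un-normalized* discriminant score.
It is an exact monotone (logistic) function of typicality — for the linear
discriminant fit, `mfp = plogis(D_M * mft)` — so it can never disagree with
typicality in direction, but it compresses the tails: when the sexes are
well separated, most profiles pile up near 0 and 1.

**Sex-centrality** compares a profile's Mahalanobis distances to the two
centroids: `mfc = (D(z, f) - D(z, m)) / D(m, f)`, with metric `R^-1` and
`m = d/2`, `f = -d/2`. The male centroid scores exactly +1, the female
centroid exactly -1, and the zero contour coincides with the classification
boundary, so centrality always agrees with typicality in sign while
diverging from it toward the extremes. In high-dimensional trait sets most
of the probability mass lies far from both centroids, so even strongly
sex-central profiles are not "near" a centroid; centrality scores should be
interpreted with that caveat when `p` is large.

A profile whose directionality and typicality have strictly opposite signs
is **discordant** — it lies between the directional boundary (equal
Euclidean distance to the centroids) and the classification boundary (equal
Mahalanobis distance). Exact zeros lie *on* a boundary; they are neither
male- nor female-anything and are counted as concordant (the zero set has
probability zero under continuous data, so the convention is
inconsequential in practice but makes the classification total).

```{r}
R <- matrix(c(1, -0.5, -0.5, 1), 2)
prof <- simulate_population(R, d_true = c(0.8, -0.6), n = 1000, seed = 7)
fit <- fit_mf(prof)
glance(fit)
scores <- mf_scores(fit)
summarize_indices(scores)
```

The `summary_plot()` / `autoplot()` display mirrors the standard reporting
format: per-sex densities on the diagonal, scatterplots with discordant
regions shaded below it, and both whole-sample correlations `r` and partial
correlations `r_p` controlling for sex above it. The partial correlations
are the more informative comparison, because all four indices share the
mean sex difference and whole-sample correlations are inflated by it.

## Fitting choices

* **Discriminant vs logistic.** The default fit solves `R a = d` in closed
  form (a linear solve, not an explicit inversion — the two agree to 1e-10
  in the test suite, but the solve is better conditioned). `method =
  "logistic"` instead fits sex on the standardized traits by maximum
  likelihood, which drops the multivariate-normality assumption; its raw
  linear predictor takes the role of the un-normalized discriminant score
  in the probability index and is rescaled by its pooled within-sex SD
  (`sqrt(b'Rb)`) for the typicality analogue. Directionality and centrality
  are unaffected by the choice. Under approximate normality the two methods
  agree very closely; with separable data the logistic fit warns and its
  probabilities saturate.
* **Near-singular `R`** (condition number above 1e10) is a hard error with
  advice to aggregate or drop collinear traits, rather than a silent ridge
  fix: a silently regularized discriminant would change every
  typicality-family score without any visible trace in the output.
* **Scoring new individuals** uses the frozen training standardization
  (midpoint and pooled SDs from the fit), so a new profile's scores do not
  depend on who else is being scored. Refitting on the combined sample is
  the alternative when the new individuals are meant to update the norms.

## Measurement error and its correction

Classical measurement error leaves means alone but inflates within-sex
variances, which attenuates both standardized sex differences and trait
correlations. As reliability falls, the observed `R` drifts toward the
identity, the discriminant axis rotates onto the centroid axis, typicality
collapses toward directionality, and discordant profiles vanish — a bias
that more data cannot fix, since it is driven by the error model rather
than sampling noise.

Given per-trait reliabilities `rel_j` (the true-score share of observed
variance), `fit_mf(..., reliabilities = )` corrects the data before
fitting:

1. the observed pooled within-sex correlation is disattenuated,
   `r*_ij = r_ij / sqrt(rel_i rel_j)`, clipped to `[-1, 1]` and projected
   back to a valid correlation matrix if needed (eigenvalue floor 1e-8,
   diagonal renormalized);
2. the within-sex deviations are rotated by `R_obs^(-1/2) R*^(1/2)`
   (symmetric square roots), which makes the pooled correlation of the
   corrected data equal `R*` exactly;
3. each trait's deviations are then shrunk by `sqrt(rel_j)`, restoring the
   true-score variance, while sex-mean differences stay untouched in trait
   units — so the refitted Cohen's d values grow by `1/sqrt(rel_j)` and the
   centroid distance rises, as it should when attenuation is removed.

This deterministic whitening/recoloring construction reduces exactly to the
identity at perfect reliability. Because it operates on within-sex
deviations it is defined only for the sample it was fitted on; corrected
models refuse to score new data. Reliabilities must come from outside the
package (test-retest, internal consistency); estimating them from item-level
data is out of scope, as are SIMEX-style and latent-variable error models.
Correction trades bias for variance — corrected estimates have wider
sampling error — so it is most advisable in large samples.

## The synthetic-data generator and the validity study

`simulate_population()` draws males from `MVN(+d/2, R)` and females from
`MVN(-d/2, R)` — multivariate normal, equal covariance matrices, unit
within-sex variances — and `add_measurement_error()` adds independent
Gaussian noise with variance `(1 - rel)/rel`, so the nominal reliability is
realized exactly in expectation. Random correlation matrices come from a
C-vine construction in which every partial correlation is drawn as
`2 Beta(beta, beta) - 1`; with the default `beta = 4` the mean absolute
off-diagonal correlation lands around .20–.25 for 5 to 30 traits, a
realistic level for psychological and morphological batteries. This
emulates the covariance structure and error model of real trait data but
none of its other features — no skewness, floor/ceiling effects, missing
data, or sex-specific covariance — so passing simulation checks supports
the statistical machinery, not any claim about a particular empirical
domain.

`run_validity_experiment()` crosses replicates with reliability levels. Per
replicate a fresh `R` and `d ~ N(0, d_sd^2)` are drawn (redrawn each
replicate, so the boxplot spread propagates design uncertainty, not just
sampling noise), the error-free sample is fitted to produce each
individual's *true* scores, and each noisy version is refitted from scratch
— validity is the correlation between an index computed on noisy data and
on the same individuals' error-free data, with the model re-estimated both
times, mirroring what a real analyst could and could not observe. The
reference designs pair `p = 5/10/30` with `d_sd = 0.70/0.50/0.05`
(centroid distances averaging roughly 2/3/4 and above) at `N = 2000`, 50%
females, 100 replicates. The test suite runs a scaled-down profile — 20
replicates at `n = 1000` — which reproduces every qualitative conclusion in
a few seconds; `scripts/acceptance.R` runs the full 100-replicate design.
The qualitative findings are robust across both scales:

* validity of every index decreases with error, but typicality, centrality
  and (usually) probability degrade much faster than directionality, and
  the gap widens with the number of traits;
* as reliability falls, directionality and typicality become more highly
  correlated — the observed data *overstate* the redundancy of the indices;
* the concordant/discordant classification is extremely noise-sensitive:
  its phi coefficient against the true classification drops steeply and is
  well below 1 even at reliability .90, so discordance analyses require
  very precisely measured traits;
* applying the data-matrix correction with the generating reliabilities
  raises the corrected-data centroid distance in every replicate, improves
  median validity of all four indices, and moves the
  directionality-typicality partial correlation back toward its true-score
  value, while the concordance classification improves only modestly.

```{r}
res <- run_validity_experiment(validity_config(
  p = 5, n = 500, d_sd = 0.70, reliabilities = c(0.5, 0.9),
  n_reps = 5, seed = 42))
res |>
  group_by(reliability) |>
  summarise(across(starts_with("validity"), median))
```

## Numerical conventions

* Pooled SD and pooled correlation both use denominator `n - 2`; this
  consistency is what makes the unit-within-sex-variance property of
  typicality exact rather than asymptotic.
* The bias-corrected centroid distance uses the standard unbiased estimator
  of the squared Mahalanobis distance,
  `D_Mu^2 = ((n - p - 3)/(n - 2)) D_M^2 - p(1/n_M + 1/n_F)`, floored at 0.
* Probability scores are clamped to the open unit interval so that logits
  of reported scores stay finite.
* Zero index scores are treated as concordant; constant traits, zero `d`
  vectors, and groups below 2 individuals are errors, not warnings.

## Worked-example drivers

`replicate_example()` wires the pieces together for three dataset shapes:
anthropometry with circumference measures residualized on BMI before
analysis (pooled single-slope regression by default; sex-specific
residualization is available via `residualize_on(by_sex = TRUE)`),
an already-reduced component table (any upstream dimension reduction such
as PCA with rotation is performed outside the package), and personality
scales with optional reliability-based correction. No dataset is bundled
and nothing is downloaded; callers supply their own files. The package's
tests exercise these drivers end-to-end on synthetic stand-ins with known
parameters and check that the drivers are pure composition of the exported
building blocks.

## Limitations

Two sex categories only; complete-case filtering with no imputation;
numeric traits only; equal within-sex covariance matrices assumed
throughout (the generator enforces it, the discriminant fit relies on it);
no nonlinear discriminants or machine-learning probability variants; and
the error correction requires externally supplied reliabilities and assumes
the classical error model (independent, additive, homoscedastic noise).
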