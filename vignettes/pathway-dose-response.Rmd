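---
title: "Pathway-level dose-response modeling with pathbmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level dose-response modeling with pathbmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathbmd)
```

## Motivation

Classical benchmark-dose (BMD) analysis of omics data fits a dose-response
model to each gene separately and aggregates the resulting BMDs afterwards.
That discards the shared structure within a biological pathway: genes in the
same gene set tend to respond to the exposure with a common trend, differing
mainly in baseline and amplitude. `pathbmd` models a whole gene set at once
with mixed-effects models — the pathway trend is a fixed effect, gene-specific
deviations are random effects — and derives the pathway's benchmark dose and
trend-change doses directly from the fitted set-level curve.

## The model

For gene $j$ in the set, sample $i$ with modeling-scale dose $d_i$, the
response $y_{ij}$ (log-CPM for counts, the given values for log-intensity
data) is described by one of four nested candidates, all fitted by maximum
likelihood (`REML = FALSE`) with `lme4::lmer`:

* **null**: $y_{ij} = \beta_0 + b_j + \varepsilon_{ij}$ — a gene-specific
  baseline, no dose effect.
* **linear_mixed**: adds a fixed slope in dose and an uncorrelated random
  slope per gene.
* **nonlinear_fixed**: replaces the linear term with a cubic B-spline in
  dose (fixed effect only), keeping the random intercept.
* **nonlinear_mixed**: additionally gives each gene random spline
  coefficients, with either a diagonal covariance (default) or an
  unstructured one (`cov_structure = "full"`).

When counts are supplied, the preprocessing step estimates a
negative-binomial dispersion, transforms to log-CPM, and attaches
inverse-variance precision weights that are passed to `lmer` as prior
weights.

### The spline basis and identifiability

The cubic basis is clamped at the boundary doses, with an interior knot at
*every* non-boundary dose level, so the curve can flex at each tested
concentration. With $K$ interior knots the basis has $K + 4$ functions but
only $K + 2$ distinct dose levels, so the raw coefficients are not
identifiable: the likelihood constrains the curve only at the observed
doses. The fixed spline term is therefore regressed on an orthonormal basis
of the identifiable subspace (the right singular vectors of the dose-level
basis matrix), which makes the fit well-posed without changing the model
space.

To report a single curve on a fine grid, the package chooses among all
equal-likelihood spline representations the *smoothest* one: the coefficient
vector that interpolates the fitted dose-level values while minimizing the
integrated squared second derivative $\int g''(x)^2\,dx$. This removes the
between-knot ringing that an arbitrary (e.g. minimum-norm) representative
can exhibit, and for collinear fitted values it reproduces a straight line
exactly. The roughness matrix is computed exactly with two-point
Gauss-Legendre quadrature per knot interval (the integrand is piecewise
quadratic for cubic splines).

## Model selection

Each non-null candidate is compared to the null by a likelihood-ratio test.
For the mixed candidates the statistic is referred to a $\chi^2$ distribution
with degrees of freedom equal to the difference in parameter count; because
variance components lie on the boundary of the parameter space under the
null, this reference is conservative. For `nonlinear_fixed` — a pure
fixed-effects enlargement in the Gaussian model — the LRT statistic is
transformed to its exact finite-sample F form instead, which removes the
anti-conservativeness of the asymptotic $\chi^2$ reference at realistic
sample sizes. Candidates whose test is not significant at `alpha` (default
0.05) are discarded; among the survivors (and the null) the model with the
lowest AIC is selected, with ties going to the model with fewer parameters.
P-values are adjusted across pathways by Benjamini-Hochberg.

## Benchmark and trend-change doses

From the selected pathway curve evaluated on a 200-point grid:

* the **BMD** is the first dose (by linear interpolation between grid
  points) at which the curve leaves the band $y_0 \pm z\,\hat\sigma$, where
  $y_0$ is the curve value at the lowest dose, $\hat\sigma$ is the residual
  standard deviation and $z$ defaults to 1;
* the **TCDs** are the doses where the analytic first derivative of the
  spline changes sign (maxima/minima) and where the second derivative
  changes sign (inflections). Linear fits have none.

Uncertainty is quantified by bootstrap: `n_boot` (default 1000)
dose-stratified subsamples of `boot_fraction` (default 0.6) of the samples,
drawn without replacement, are refitted with the selected model kind, and
percentile confidence intervals are formed from the resulting BMDs and from
TCDs matched by type.

## Pre-filters and clustering

Optional pathway pre-filters (off by default, `use_filters = TRUE` to
enable) drop sets that are unlikely to carry a coherent dose signal or whose
signal is degenerate: sets dominated by low-variance genes, sets with mostly
negatively correlated gene pairs, and sets whose first principal component
explains more than 70% of the within-set variance. The filters were designed
for large curated collections; on small focused studies they can be
aggressive (a strongly coherent responsive set *is* PC1-dominated), which is
why they are opt-in.

Within-pathway clustering (`clustering = TRUE`) groups the genes by their
fitted dose-profile features with k-means (25 restarts), choosing the number
of clusters by average silhouette width subject to a floor; each cluster is
then refitted as a derived sub-pathway. This separates, for example, the up-
and down-going halves of an antagonistic set whose mean trend cancels.

## Synthetic data generator

`simulation_spec()` / `simulate_dataset()` generate studies with known
ground truth for validation: gene sets with flat, linear, sigmoid, bell,
U-shaped or antagonistic (mixed-sign) trends on a normalized log10-dose
axis, gene-level random intercepts and amplitudes, Gaussian noise, and
optionally negative-binomial counts with log-normal library-size factors.
`true_bmd_log10()` returns the closed-form BMD of the noiseless true curve,
independently of the estimator, so generator and estimator cross-check each
other. The generator does not attempt to emulate real RNA-seq beyond these
ingredients — no batch effects, no realistic library-size heterogeneity.

## Worked example

```{r example}
sim <- simulate_dataset(simulation_spec(
  genesets = list(
    list(name = "responsive", n_genes = 10L, shape = "sigmoid",
         effect_size = 2),
    list(name = "unaffected", n_genes = 10L, shape = "flat",
         effect_size = 0)),
  sigma = 0.3, seed = 1L))

cfg <- run_config(dataset = sim$dataset, genesets = sim$genesets,
                  log10_dose = TRUE, n_boot = 100L, seed = 1L)
res <- run_pipeline(cfg)
res$table[, c("geneset", "best_model", "adj_p", "significant",
              "bmd", "bmd_lo", "bmd_hi", "n_tcds")]
```

The responsive pathway is detected with a spline model and a benchmark dose
inside the tested range; the flat pathway stays on the null model with no
BMD.

## Numerical choices and limitations

* All candidates are fitted with `REML = FALSE` so likelihoods are
  comparable across fixed-effect structures.
* Singular fits (zero variance components) are accepted and flagged rather
  than failed: on the boundary they are still valid ML solutions.
* The BMD grid has 200 points over the tested dose range; reported doses are
  accurate to roughly half a grid step, which bounds the achievable
  precision regardless of sample size.
* The bootstrap refits only the selected model kind; model-selection
  uncertainty is not propagated into the confidence intervals.
* The $\chi^2$ reference for mixed candidates is conservative near the
  boundary; the F reference is exact only for `nonlinear_fixed`.
* Doses must be positive when `log10_dose = TRUE`; a zero control dose
  should be recoded to a small positive surrogate by the user, which
  affects the modeling scale and therefore the estimated BMD.
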