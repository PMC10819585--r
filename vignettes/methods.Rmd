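---
title: "Methods: index systems, layer comparison and risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: index systems, layer comparison and risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalrisk)
```

This vignette is the package's own account of the methods it implements:
the model behind each computation, the defaults and why they were chosen,
what the synthetic generator does and does not emulate, and the known
limitations.

## The assessment problem

A small farmland survey measures seven regulated metals (Cr, Ni, Cu, Zn,
As, Cd, Pb; mg/kg) at a handful of sites in two depth layers. The surface
layer (`APMS`, 0–10 cm) integrates atmospheric deposition and human
activity on top of the soil background; the deep layer (`SOIL`, 10–20 cm)
is closer to the local geochemical baseline. The questions are: how
polluted is each layer, on which grading scale; do the layers differ; and
which variables carry the total ecological risk.

## Reference constants: two maps, not one

Every index divides a concentration by a per-metal constant, but two
different constants are in play:

* **Screening values** `S` — regulatory farmland limits; denominator of
  the single-factor index `Pi = C/S` and hence of the risk indices.
* **Background values** `B` — geochemical baselines; denominator of the
  geoaccumulation index and the load index.

The shipped screening set is \{Cr 250, Ni 190, Cu 100, Zn 300, As 25,
Cd 0.6, Pb 170\} mg/kg. Only six of the seven values were available as a
printed list; the alignment to Ni…Pb is the one that reproduces the
published per-metal mean risk indices to better than 0.5 %, and Cr = 250
is back-calculated from the published mean Cr concentration and mean Cr
risk index (2 × 54.62 / 0.437 ≈ 250), coinciding with the national
farmland screening value at pH > 7.5.

The true local backgrounds were never published. The shipped defaults are
reconstructed by inverting the surface-layer mean geoaccumulation indices,
`B = C/(1.5 · 2^Igeo)`, from the published surface-layer means. They
round-trip the surface-layer mean `Igeo` within 0.05 but are
approximations and are flagged as such (`?default_background_set`); the
deep layer, which played no part in the inversion, agrees only loosely
(within ~0.15), because a per-sample mean of a concave transform is not
the transform of the mean. Users with real jurisdictional backgrounds
should supply them via `load_reference_set()`.

## Grading

Each index has an ascending cut-point scheme (`default_schemes()`). A
value exactly equal to a cut point falls in the **higher** class — so a
single-metal risk index of exactly 40 already grades "moderate risk".
This matches how the published class statements read, and is configurable
(`boundary = "lower"`). Classification is exhaustive and monotone:
increasing a value never lowers its class.

Two star conventions coexist deliberately: correlation displays use the
three-tier \*, \*\*, \*\*\* scheme at 0.05/0.01/0.001, while model
coefficient tables add a 0.1 "marginal" dot tier. They are separate
constants (`sig_stars(..., scheme =)`), never mixed.

## Naming the comprehensive indices

Three "overall pollution" statistics circulate under confusingly similar
names. The package computes all three under unambiguous names:

* `PI_mean` — plain average of the seven `Pi`;
* `PN` — Nemero index `sqrt((mean(Pi)² + max(Pi)²)/2)`;
* `PLI` — geometric mean of the seven `C/B` ratios.

In the survey this package emulates, the summary row labelled "PI"
(mean 1.448 in the surface layer) is numerically the **Nemero** index —
the plain average of the `Pi` implied by the same means is ≈ 0.806 — and
the row labelled "PLI" is the background-referenced geometric-mean load
index. The pipeline reports all three and leaves the mapping explicit
rather than choosing silently.

## Layer comparison

`describe()` reports per-layer Q1/median/Q3 (type-7 linear interpolation,
the convention the quartiles depend on), mean, sample SD (n−1) and n.
`layer_test()` always computes **both** an exact Wilcoxon rank-sum p and
a Welch t p, with the exact rank test as the default primary. Rationale:
with n = 8 per layer an exact rank test is robust to the strong skew of
concentration data, and its p-values are invariant under strictly
monotone per-metal transforms — which is exactly the observed pattern
where a metal, its geoaccumulation index and its risk index share one
p-value. Identical groups yield p = 1 (ties handled by the normal
approximation without continuity correction); two constant groups give a
Welch p of 1 (equal) or 0 (unequal) by convention, since the statistic is
0/0. No multiple-testing correction is applied, matching per-pair star
reporting.

## Multivariate exploration

All multivariate inputs are standardized (`standardize()`, mean 0/SD 1,
invertible). PCA is computed by SVD; a deterministic sign convention
(largest-magnitude loading per component made positive) removes the SVD
sign ambiguity so runs are comparable. Degenerate rank yields fewer
components, not an error. Contribution of a variable to an axis is its
squared loading — over an orthonormal column these sum to 1 and read as
shares (`top_contributors()`). The PCA input is the full standardized
variable set (metals + geoaccumulation + risk families + pollution
indices), so "the most influencing variable" is judged across families.

`supervised_embedding()` wraps label-supervised UMAP (via `uwot`).
Hyperparameters are unstated in the source analysis; defaults are fixed
at `n_neighbors = 5` (groups of n = 8 leave no room for more),
`min_dist = 0.1`, and a mandatory seed with a single-threaded optimizer
so identical calls are bit-identical. The 90 % confidence ellipse is the
normal-theory ellipse of the embedded coordinates (sample mean and
covariance, chi-square(2) quantile radius) — the source display never
defines its ellipse, so the package picks the standard construction and
records it. Ellipse area shrinks monotonically with the coverage level,
and on the shipped fixture the deep layer embeds with the smaller
ellipse, matching its smaller dispersions.

## The stepwise model suite

The response is the total risk `TEI`, pooled over layers (n = sites × 2).
Four candidate structures are fitted: metals only (model 0); metals +
geoaccumulation family (model 1); metals + single-metal risk family
(model 2); metals + Nemero and load indices (model 3). Choices the source
leaves open, fixed here and recorded in each fit's metadata:

* **Search**: bidirectional stepwise minimizing AIC from the
  intercept-only model, OLS at each step (`stats::step` semantics; ties
  broken by lower AIC then earlier candidate order, so the path is
  deterministic).
* **Collinearity**: before the search, iterative VIF pruning at the
  conventional cutoff 10, removal order logged; if survivors still reach
  n − 1 the cutoff is halved with a warning.
* **Importance**: LMG (average sequential R² increment over all predictor
  orderings), computed by the exact subset-weighted closed form — chosen
  for order invariance; shares are normalized to sum to 1.
* **Criteria**: AIC/BIC in the full-likelihood convention of
  `stats::AIC`.

One structural fact shapes everything: `TEI` is *identically*
`Σ Tr·C/S`, an exact linear function of the seven concentrations. Any
candidate set that spans the concentrations (or their risk transforms)
therefore saturates: R² = 1 up to rounding, and the AIC search reliably
finds it. On real surveys sub-unity fits arise when collinearity
elimination removes dominant metals (for strongly inter-correlated field
data) before the search; with the fixture's moderate correlations (0.5)
VIFs stay below 2 and nothing is pruned, so all four models saturate and
differences between them are numerical noise. The suite reproduces the
*mechanism* — forced-in full sets give R² = 1; selection on noisy
candidates gives less — rather than any particular published
coefficient path, which is not reproducible without the raw survey data.
A generalized linear mixed model with a random layer term is deliberately
out of scope (it was reported indistinguishable from the stepwise fits);
`model_data()` returns everything needed to fit one externally.

## The synthetic generator

`generate_samples()` emulates the survey design: per layer, a Gaussian
copula with the layer's 7 × 7 correlation matrix drives marginal draws
with the target mean/SD — lognormal by default (concentrations are
positive and right-skewed; parameters solved from mean and SD), truncated
normal as a sensitivity alternative. `moment_matched` mode then affinely
rescales each (layer, metal) column so the *sample* mean and SD equal the
targets exactly (< 1e−9). An affine rescale of a high-dispersion metal
(surface Cu has CV ≈ 0.6) can cross zero for an unlucky draw; the layer
is then redrawn deterministically (up to 50 rejections) before the
targets are declared infeasible with a pointer to the lognormal family.

The default targets (`profile_targets()`) are the fourteen per-layer
mean/SD pairs of the emulated survey; the default correlation pattern is
a uniform 0.5 block with Pb–Cd raised to 0.9 in the deep layer, echoing
the strong Pb–Cd association observed there. These correlations are
stand-ins — the survey published significance stars, not r values.

What passing tests on this fixture do **not** show about real data: the
generator matches first and second moments and broad correlation
structure only. Quartiles are not matched (published quartiles serve only
as loose reconciliation); there is no spatial autocorrelation between
sites, no censoring at detection limits, no measurement-replicate error,
and inter-metal correlations are schematic. Layer-mean index values and
all algebraic identities transfer to real data; significance patterns and
embedding geometries need not.

## Numerical conventions and degenerate inputs

* Quantiles: type 7. SDs: n − 1. Pearson p: t distribution, n − 2 df;
  |r| = 1 maps to p = 0.
* Zero-variance variables: errors in `standardize()` (named), flagged
  `NA` (not dropped) in correlation output.
* Sample validation rejects non-positive concentrations (with row
  numbers), unknown metals/layers (naming the valid sets), duplicates,
  and incomplete metal panels.
* All randomness flows from a user seed; the report runner expands it by
  fixed offsets per stage (simulation +1, embedding +2).

Problem sizes used by the shipped tests were chosen to keep every check
sharp but quick: exact Wilcoxon enumeration at 8 + 8, copula calibration
at n = 5000, law-of-large-numbers checks at n = 10 000, LMG oracle
enumeration up to 5 predictors (120 orderings), and 200-replicate
stepwise null simulations at n = 16.

## Known limitations

* Shipped backgrounds are reconstructions; load-index and
  geoaccumulation output against them should be read as approximate
  (~5 % on the load index).
* The exact-identity saturation above means stepwise model comparisons
  on synthetic data discriminate structure, not predictive power.
* No speciation/bioavailability adjustment, no enrichment-factor or
  source-apportionment indices, no pH-dependent screening logic, no GIS
  layer.
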