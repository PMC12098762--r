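---
title: "Trait contrasts between locally dominant and rare tree species: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait contrasts between locally dominant and rare tree species: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domrare)
```

## The question and the statistic

Within a forest plot, a handful of species carry most of the stems and
many species are represented by one or two individuals. `domrare` asks
whether the locally dominant species are a functionally biased draw
from the community — and whether that bias strengthens or weakens along
temperature and water-availability gradients.

The unit of analysis is the plot. Per plot, species are ranked by stem
count; the extremes of that rank-abundance curve define the **dominant
set** and the **rare set** (top-2/bottom-2 in plots of 6–19 species,
the top and bottom 10 % — `k = floor(S/10)`, floored at 2 — in richer
plots). The per-plot statistic for trait $j$ is

$$D_j = \mathrm{median}\,z_j(\text{dominants}) -
        \mathrm{median}\,z_j(\text{rares}),$$

where $z_j$ is the natural-log trait value standardized over the pooled
tree-level population (all species-by-plot occurrences of the filtered,
classified data). The log tempers trait outliers; the shared z-scale
makes $D$ comparable across traits and biomes; the median makes the
statistic insensitive to unequal group sizes. Medians are contrasted
(not means): group sizes are small and trait distributions are skewed,
so the median is the natural robust choice; a mean-based variant exists
only inside the null-model stage, where the two are compared directly.

### Assumptions

* Stem count is the abundance currency. Basal-area ranking is exposed
  (`basis = "basal_area"`) but not the default, because basal area is
  itself a function of size-related traits and would entangle the
  classifier with the response.
* Plots are treated as independent sampling units in all tests. This is
  the field's convention for inventory compilations; it is also the one
  assumption the synthetic generator is explicitly engineered to
  satisfy (see *Lottery assembly* below).
* A plot whose rarest species still holds more than 10 % of the stems
  has no meaningful abundance extremes and is excluded before any
  contrast is computed.

## Quality filters

`apply_filters()` retains plots with area in [0.02, 2] ha (below
0.02 ha rare species are not sampled reliably; above 2 ha plots are
outliers in inventory compilations), census year ≥ 1990, stand age ≥ 25
years (early succession reshuffles dominance), and at least six species
(so "top 2 vs bottom 2" never overlaps). Boundaries are inclusive at
the stated values and the thresholds are arguments, not constants; the
attrition report records the four steps in this fixed order. The
0.02-ha bound is hard-coded rather than recomputed as an empirical
quantile of each dataset, so the filter is a fixed, portable rule.

## Tie handling in the classifier

Abundance ties are ubiquitous (every singleton ties with every other
singleton), and they sit exactly where the rare set is selected. Two
design rules deal with them:

* One **total order** — (stems decreasing, tie key, species id) — is
  built per plot, and the dominant set is read off its head, the rare
  set off its tail. Reading both ends of a single order keeps the sets
  disjoint even when one run of tied counts spans both selection
  boundaries.
* The **tie key is a plot-keyed hash** (`tie_hash()`), deterministic
  and platform-stable, but varying from plot to plot. A global
  convention such as alphabetical order would select the same species
  at every tie across thousands of plots and thereby attach that
  species' trait values — a single random draw — to the rare group
  everywhere, which measurably inflates the variance of biome-level
  mean contrasts. The hash mixes the plot id multiplicatively (an
  additive mix would only rotate one fixed species order within each
  plot and re-create the same problem).

## Inference

**Wilcoxon signed-rank per biome.** For each of 13 responses (ten
traits, gymnosperm percentage, PC1 and PC2 scores) and each biome, the
paired test of dominant vs rare plot medians. Exact zeros are dropped
and counted. For $n \le 25$ tie-free pairs the exact null is used; the
large-sample branch uses a normal approximation whose second and fourth
cumulants come from the realized midranks (this subsumes the classical
tie correction), a continuity correction, and an Edgeworth kurtosis
term — without the Edgeworth term the approximation misses the exact
two-sided p by slightly more than 0.01 at $n = 15$; with it the error
is a few $10^{-4}$. The tropical conifer biome is not tested by
default: any biome under `min_n` plots (default 200) is flagged and
skipped, because with so few plots the standard error of the mean
contrast makes the grid entry uninformative. P-values are reported raw,
as is standard for this kind of descriptive battery; a Holm adjustment
can be applied downstream by the user.

**PCA.** `fit_pca()` decomposes the correlation matrix (the traits are
already z-scored; the correlation basis keeps any residual scale
differences out of the spectrum). The main analysis uses one row per
plot-by-group median vector; the species-level PCA is a secondary mode
of the same function. Component signs are arbitrary in any PCA, so each
component is oriented to make its largest-magnitude loading positive
and the anchoring trait is recorded. Note one mathematical caveat: the
spectrum of a *correlation* matrix is not invariant under orthogonal
rotation of the rows (rotation changes column variances), so
rotation-invariance properties are only tested in the covariance basis,
which `basis = "covariance"` exposes.

**Climate-response models.** For each response,

$$D \sim t + t^2 + w + w^2 + t\cdot w +
  \text{plot size} + \text{age} + \text{elevation} + \text{biome},$$

by ordinary least squares, with every continuous predictor z-scored
*before* squaring (so the quadratic terms are squares of the scaled
variables and the linear coefficients stay directly comparable; the
raw-square-then-scale alternative is not fitted). The interaction is
the single product $z_t z_w$. Biome enters as dummies with the
most-plot-rich biome as reference. Water availability is always fitted
with its quadratic term; `delta_aic_water_linear` reports when the
linear-water form wins by AIC instead of hard-coding a per-variable
functional form.

Curve geometry — the roots and vertex of the fitted quadratic in each
climate variable, with the other climate variable at its mean,
covariates at their means, and biome at its observed mix — is mapped
back to native units (°C, WAI) through the stored scaling constants. A
fit whose climate response never crosses zero inside the observed range
reports `NA` roots; that is information, not an error.

**Grouped LMG importance.** `lmg_importance()` decomposes the model
$R^2$ into per-group shares by Shapley averaging of incremental $R^2$
over all $2^G$ subsets with factorial order weights; $t$ with $t^2$
form one group, $w$ with $w^2$ another, the interaction and each
covariate their own, and all biome dummies one group. Shares are
non-negative and sum to the full $R^2$ to machine precision; the
implementation is checked against an explicit all-orderings oracle. A
guard refuses more than 20 groups ($2^{20}$ subsets).

**Temperature vs water importance.** The 13 temperature shares are
compared with the 13 water shares by a pooled-variance two-sample t
statistic *and* a variance-ratio F statistic, both reported. Published
summaries of this comparison have labelled a mean comparison with an F
value; reporting both surfaces the ambiguity instead of silently
resolving it. Whether the 13 pairs should be treated as paired is
equally unstated in that tradition; the two-sample form is the default.

## Null models

`fixed_margin_randomize()` draws a random plot-by-species stem matrix
with both margins fixed (trees per plot, individuals per species) via
the sequential conditional algorithm (`stats::r2dtable`, Patefield's
algorithm). The resulting law is the multivariate hypergeometric null —
every assignment of individual stems to cells consistent with the
margins equally likely — which is the standard community-ecology null
for this constraint, and the one the uniformity tests check against by
exact fiber enumeration. `null_ensemble()` re-runs the classifier on
each replicate (plots dropping below six species are excluded by the
standard rule and counted), aggregates each group's traits under mean,
median, and IQR, and reports pairwise overlapping coefficients of the
three statistics' replicate distributions from pooled histograms. Mean
and median summaries overlap almost completely under the null; the IQR
lives on a different (dispersion) scale and is reported for
completeness, not expected to overlap the location statistics.

## The synthetic forest generator

`generate_forest()` is first-class, tested code: it defines the
conditions under which the pipeline is validated.

What it emulates: plot areas log-normal with mean ≈ 0.07 ha truncated
to [0.02, 2] ha; censuses 1990–2015; stand ages ≥ 25 yr (gamma-tailed,
mean ≈ 53 yr); six biomes with their own temperature and
water-availability ranges, species-pool sizes and richness (speciose
tropics, species-poor boreal); log-series regional abundance structure;
a gymnosperm occupancy advantage growing below 4 °C and above WAI 1.8;
ten log-normal traits built from two latent axes (a stem-strategy axis
separating the gymnosperm syndrome, and a leaf-economics axis) plus
climate-dependent intraspecific variation; and a weak negative rank
correlation between temperature and water availability. The within-
biome copula targets Spearman ρ = −0.09, and the biome water ranges
were set, once, so that the pooled realized correlation also lands near
−0.09 under the default biome mixture (the pooled value is dominated by
between-biome structure, not by the copula).

**Lottery assembly.** Local abundance structure follows a log-series
weight vector, but the weights are assigned to species by a fresh
random permutation per plot (plus lognormal noise, `assembly_sd`).
Which species dominates a plot is therefore pure lottery unless a
coupling tilts it. This choice is what makes the package's null
calibration meaningful: if the same regional ranking decided dominance
everywhere, the handful of permanently dominant species — with their
single random trait draws — would make plot contrasts strongly
dependent across plots, and a signed-rank test over plots would reject
far above its nominal level even with no trait–dominance link. With the
lottery, a fully neutral configuration (`neutral = TRUE`: coupling off
*and* occupancy flattened — the occupancy curve is itself a
trait–dominance link, since division predicts traits) yields a 13 × 5
Wilcoxon grid rejecting at the nominal 5 %.

**The coupling.** Per trait, a log-abundance multiplier
$\beta(t, w) = b_0 + b_t t + b_{tt} t^2 + b_w w + b_{ww} w^2$ applied
as $\exp(\beta \cdot z)$ to the pool-standardized species baseline when
sampling the community. `quadratic_temperature_coupling(roots, peak)`
builds the hump-shaped special case from its zero crossings. Defaults:
height hump-shaped in temperature (roots 5 and 25 °C, peak 0.5),
rooting-depth advantage increasing with temperature, and
climate-independent wood-density and seed-mass advantages — a caricature
of dominance being trait-selective where climate is limiting.

What the generator does **not** emulate: spatial autocorrelation
between plots, demographic dynamics through time, regionally persistent
dominance identity (by design, see above), non-log-normal trait
distributions, or correlated trait--climate measurement error. Passing
tests on this generator therefore show the *machinery* is correct and
calibrated under the stated structure; they do not show that real
inventory data satisfy the independence assumptions.

## Numerical and procedural choices

* Determinism: every stochastic stage derives per-unit substreams from
  one master seed (`derive_seed()`, 32-bit safe), so identical
  (config, seed) pairs give byte-identical outputs including the run
  manifest, which deliberately records no clock state.
* Trees unresolved even at genus level (no species match, no congeneric
  trait rows) are dropped and counted, never imputed as zeros.
  Genus-level trees take the mean of congeners present in the trait
  table.
* Standardization is global (all biomes pooled) so $D$ is in one common
  s.d. unit across biomes; a per-biome population can be supplied
  through the `population` argument for sensitivity analyses.
* Zero-variance traits, non-positive raw trait values, unknown config
  keys, malformed tables and inconsistent groups raise typed
  conditions; validation never silently coerces.
* The temperate-biome subsample (when configured) is a seeded uniform
  draw whose ids are recorded; `bootstrap_subsample_check()` verifies
  the subsample reproduces the full-set mean contrasts within central
  95 % bootstrap intervals.

## Validation experiment sizes

The shipped tests validate the pipeline at sizes chosen to give each
check sharp power: the classifier is compared with a brute-force oracle
on 10,000 random plots (6–60 species, engineered ties and boundary
shares); signed-rank exactness is checked against full $2^n$
enumeration on 500 small vectors; margin conservation on 1,000 random
matrices plus exact fiber-law goodness of fit; LMG on 200 random
designs against the factorial oracle; parameter recovery on twenty
5,000-plot single-biome datasets with the quadratic coupling planted at
roots 5/25 °C (speciose, large, dense plots — richness ≈ 60, ≈ 0.75 ha
— so the classifier sees enough stems for the ±1 °C recovery tolerance);
and the neutral rejection rate on a 13 × 5 grid pooled over five
generator replicates, since one grid's 65 cells estimate a 5 % rate
with a ±2.7 % binomial error, wider than the ±2 % band being checked.

## Known limitations

* LMG shares depend on the grouping; regrouping (e.g. splitting $t$
  from $t^2$) changes the decomposition. The default grouping treats a
  variable and its square as one concept.
* The climate models are fixed-effects OLS; no spatial or hierarchical
  error structure is available, matching the analysis tradition the
  package implements rather than improving on it.
* With heavy ties at small $n$ the smooth signed-rank approximation
  tracks the lumpy conditional null only to a few percent; such cells
  are rare in practice because the auto rule prefers the exact branch
  whenever it is defined.
* The overlapping coefficient uses pooled-range histograms (30 bins);
  it is a descriptive diagnostic, not an estimator with standard
  errors.
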