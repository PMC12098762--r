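# domrare

Functional-trait contrasts between locally dominant and locally rare
tree species across forest biomes, and how those contrasts move along
temperature and water-availability gradients.

## The scientific problem

In almost every forest plot a few species contribute most of the stems
while many species are rare. Whether the locally dominant species are a
functionally distinct subset — taller, denser-wooded, heavier-seeded —
and whether that distinctiveness grows or shrinks with climate, is a
question about community assembly: competitive dominance should leave a
trait signature where the environment is limiting, and a weak or absent
signature where assembly is closer to a lottery.

`domrare` implements a complete, reusable pipeline for this question on
plot-based forest-inventory data:

* **Plot quality filters** — area within 0.02–2 ha, census year ≥ 1990,
  forest age ≥ 25 yr, ≥ 6 species; per-step attrition report.
* **Dominance classification** — per plot, species are ranked by stem
  count; the top and bottom 10 % form the dominant and rare sets
  (top-2/bottom-2 in plots of 6–19 species, `k = floor(S/10)`, at least
  2, otherwise; 5 % and 15 % variants for sensitivity). Plots whose
  rarest species still holds > 10 % of stems are excluded.
* **Trait contrast** — ten traits (height, rooting depth, SLA, conduit
  diameter, crown diameter, wood density, bark thickness, leaf N,
  leaf N/P, seed mass) are ln-transformed and z-scored over the pooled
  tree-level population; per plot the statistic is
  `D = median(z, dominants) − median(z, rares)` in pooled s.d. units.
* **Multivariate structure** — correlation-basis PCA over the ten
  traits of the plot-level group median vectors (PC1 separates the
  gymnosperm stem syndrome, PC2 the leaf-economics axis).
* **Inference** — per-biome Wilcoxon signed-rank tests (exact
  enumeration for small n, tie-corrected normal approximation
  otherwise) over 13 responses (10 traits, gymnosperm %, PC1, PC2);
  Pearson/Spearman trait–climate correlations; second-order polynomial
  models `D ~ t + t² + w + w² + t·w + plot size + age + elevation +
  biome` on z-scored predictors, with grouped LMG (Shapley)
  R²-decomposition and the roots/vertex of the fitted climate response
  in °C / WAI units.
* **Null models** — Patefield fixed-margin randomization of the
  plot × species stem matrix (row sums = trees per plot, column sums =
  individuals per species), re-classification, and comparison of mean,
  median and IQR group summaries by overlapping coefficient.
* **Synthetic forest generator** — biome-structured plots (log-series
  pools, lottery assembly, gymnosperm occupancy rising below 4 °C and
  above WAI 1.8, weakly negatively correlated climate fields, two-latent-
  axis trait model, intraspecific variation) with a configurable
  trait–dominance coupling `β(trait, t, w)` whose truth is recoverable,
  so every stage of the pipeline can be validated end to end.

## Worked example

```r
library(domrare)

run <- run_pipeline(list(generator = forest_config(), min_n = 40),
                    seed = 11)
print(run)
#> domrare pipeline run (seed 11 )
#>   plots: 800 input -> 753 filtered -> 749 classified
#>   PCA: PC1 43%, PC2 19.7%
#>   Wilcoxon battery rows: 65 | climate fits: 13

print(run$climate_fits[["D_height"]])
#> Climate-response model for D_height (n = 749 , R^2 = 0.064 )
#> LMG importance: temperature 0.031 | water 0.004 | interaction 0.002
#> Temperature curve: roots -0.95, 20 degC; vertex 9.53 degC
```

Reading the output: 800 synthetic plots survive the quality filters
almost intact (they are generated inside the filter envelope except for
sampling tails); every retained plot yields a dominant and a rare
species set and one row of trait contrasts. PC1 takes 43 % of the trait
variance and aligns with the angiosperm–gymnosperm syndrome. The
default generator couples height to dominance with a hump-shaped
temperature response, so the height-contrast model finds a concave
climate curve with temperature carrying roughly ten times the
explained variance of water availability; at this modest plot count
the fitted zero crossings are still noisy, which is exactly what the
package's larger recovery experiment quantifies.

Fit the generator's planted quadratic and recover its geometry:

```r
cfg <- forest_config(
  n_plots = c(temperate = 5000),
  coupling = list(height = quadratic_temperature_coupling(c(5, 25), 0.5)),
  plot_size_mean = 0.75,
  biome_overrides = list(temperate = list(
    mat_lo = -10, mat_hi = 30, wai_lo = 0.5, wai_hi = 2.5,
    richness_mean = 60, pool_size = 250, gym_frac = 0)))
# generate -> filter -> classify -> standardize -> contrast -> fit:
# the fitted roots land near 5 and 25 degC, the vertex near 15 degC.
```

A thin command-line wrapper (`inst/scripts/domrare.R`) exposes
`simulate`, `run` and `sensitivity` subcommands over YAML configs.

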