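#' Apply forest-inventory quality filters
#'
#' Applies, in a fixed order, the plot-level quality filters used before
#' any dominance classification: plot area within `[area_min, area_max]`
#' hectares, census year at or after `year_min`, forest age at least
#' `age_min` years, and species richness of at least `richness_min`.
#' Boundaries are inclusive at the stated thresholds (a 0.02-ha, 1990,
#' 25-year, 6-species plot is retained). Richness is counted as distinct
#' `species` values in the abundance table.
#'
#' @param plots Plot table (see [read_forest_tables()]).
#' @param trees Abundance table; used for the richness step.
#' @param area_min,area_max,year_min,age_min,richness_min Thresholds;
#'   defaults 0.02 ha, 2 ha, 1990, 25 yr, 6 species.
#' @return A list with `plots` (the retained rows) and `report`, a data
#'   frame of per-step attrition (`filter`, `n_before`, `n_after`,
#'   `fraction_removed`) in the order area, year, age, richness.
#' @examples
#' g <- generate_forest(forest_config(n_plots = 20), seed = 1)
#' apply_filters(g$plots, g$trees)$report
#' @export
apply_filters <- function(plots, trees,
                          area_min = 0.02, area_max = 2,
                          year_min = 1990, age_min = 25,
                          richness_min = 6) {
  steps <- list(
    area = function(p) p$area_ha >= area_min & p$area_ha <= area_max,
    year = function(p) p$year >= year_min,
    age = function(p) p$age >= age_min,
    richness = function(p) {
      rich <- tapply(trees$species, trees$plot_id,
                     function(s) length(unique(s)))
      r <- rich[match(p$plot_id, names(rich))]
      r[is.na(r)] <- 0L
      r >= richness_min
    })
  report <- data.frame(filter = names(steps),
                       n_before = NA_integer_, n_after = NA_integer_,
                       fraction_removed = NA_real_,
                       stringsAsFactors = FALSE)
  cur <- plots
  for (i in seq_along(steps)) {
    n0 <- nrow(cur)
    keep <- if (n0) steps[[i]](cur) else logical(0)
    cur <- cur[keep, , drop = FALSE]
    report$n_before[i] <- n0
    report$n_after[i] <- nrow(cur)
    report$fraction_removed[i] <- if (n0) 1 - nrow(cur) / n0 else 0
  }
  rownames(cur) <- NULL
  list(plots = cur, report = report)
}
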