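pipeline_config_keys <- c("generator", "input_dir", "pct", "basis",
                          "filters", "temperate_subsample_n", "min_n",
                          "null_reps", "null_biomes", "pca_basis")

hash_config <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full dominant-versus-rare analysis pipeline
#'
#' Orchestrates one reproducible run: obtain data (either the synthetic
#' generator or a directory of interchange TSVs), apply the plot quality
#' filters, classify dominant and rare species per plot, standardize
#' traits over the filtered classified tree-level population, build
#' plot-level contrasts with PCA scores, run the per-biome Wilcoxon
#' battery, fit the climate-response models with grouped LMG importance
#' for every response, compare temperature against water importance,
#' and (optionally) run fixed-margin null ensembles per biome. All stage
#' outputs are returned and, when `out_dir` is given, written as TSV/JSON
#' together with a run manifest (config hash, seed, per-stage row
#' counts); the manifest contains no clock state, so identical
#' (config, seed) runs are byte-identical.
#'
#' @param config Named list; recognised keys: `generator` (arguments for
#'   [forest_config()], or an already-built config), `input_dir`
#'   (directory of TSVs; overrides `generator`), `pct`, `basis`,
#'   `filters` (named list of [apply_filters()] thresholds),
#'   `temperate_subsample_n`, `min_n` (Wilcoxon battery), `null_reps`
#'   (default 0 = skip), `null_biomes`.
#' @param seed Integer master seed for every stochastic stage.
#' @param out_dir Optional output directory.
#' @return Object of class `domrare_run` with elements `data`,
#'   `filtered`, `dominance`, `std`, `contrasts`, `pca`, `wilcoxon`,
#'   `climate_fits`, `importance_test`, `nulls`, `manifest`.
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir = NULL) {
  bad <- setdiff(names(config), pipeline_config_keys)
  if (length(bad))
    stop_domrare(paste0("unknown config key(s): ",
                        paste(bad, collapse = ", ")),
                 "domrare_config_error")
  seed <- as.integer(seed)

  if (!is.null(config$input_dir)) {
    data <- read_forest_tables(config$input_dir)
    data$truth <- NULL
  } else {
    gcfg <- config$generator %||% forest_config()
    if (!inherits(gcfg, "forest_config"))
      gcfg <- do.call(forest_config, gcfg)
    data <- generate_forest(gcfg, seed = seed)
  }

  filt <- do.call(apply_filters,
                  c(list(plots = data$plots, trees = data$trees),
                    config$filters %||% list()))
  trees_f <- data$trees[data$trees$plot_id %in% filt$plots$plot_id, ,
                        drop = FALSE]

  subs <- if (!is.null(config$temperate_subsample_n))
    list(n = config$temperate_subsample_n, seed = derive_seed(seed, 91L))
  else NULL
  dset <- classify_all(trees_f, plots = filt$plots,
                       pct = config$pct %||% 10,
                       basis = config$basis %||% "stems",
                       temperate_subsample = subs)

  retained <- names(Filter(function(a) !a$excluded, dset$assignments))
  pop_rows <- if ("plot_id" %in% names(data$traits))
    which(data$traits$plot_id %in% retained) else NULL
  std <- standardize_traits(data$traits, population = pop_rows)

  contrasts <- plot_contrasts(std, dset, filt$plots, trees_f, pca = TRUE)
  pca <- attr(contrasts, "pca")

  wil <- biome_test_battery(contrasts, min_n = config$min_n %||% 200)

  responses <- paste0("D_", c(trait_names(), "gym_pct", "pc1", "pc2"))
  responses <- intersect(responses, names(contrasts))
  fits <- list()
  for (resp in responses) {
    fits[[resp]] <- tryCatch(fit_climate_model(contrasts, resp),
                             domrare_error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), fits)
  imp_test <- if (length(fits) >= 2) {
    tshare <- vapply(fits, function(f) f$importance["temperature"],
                     numeric(1))
    wshare <- vapply(fits, function(f) f$importance["water"], numeric(1))
    compare_importance(tshare, wshare)
  } else NULL

  nulls <- NULL
  if ((config$null_reps %||% 0) >= 1) {
    nb <- config$null_biomes %||% main_biomes()
    nulls <- list()
    for (b in nb) {
      ids <- filt$plots$plot_id[filt$plots$biome == b]
      ids <- intersect(ids, retained)
      tb <- trees_f[trees_f$plot_id %in% ids, , drop = FALSE]
      if (!nrow(tb)) next
      nulls[[b]] <- null_ensemble(tb, std, n_reps = config$null_reps,
                                  seed = derive_seed(seed, match(b, nb)),
                                  pct = config$pct %||% 10)
    }
  }

  manifest <- list(
    package = "domrare",
    version = as.character(utils::packageVersion("domrare")),
    seed = seed,
    config_hash = hash_config(config),
    n_plots_input = nrow(data$plots),
    n_plots_filtered = nrow(filt$plots),
    n_plots_classified = length(retained),
    n_plots_excluded = nrow(dset$exclusions),
    n_contrasts = nrow(contrasts),
    n_trees_dropped_no_traits = attr(contrasts, "n_dropped") %||% 0L,
    n_climate_fits = length(fits),
    temperate_subsample = if (is.null(subs)) NULL else
      length(dset$subsampled_ids))

  run <- structure(list(data = data, filtered = filt, dominance = dset,
                        std = std, contrasts = contrasts, pca = pca,
                        wilcoxon = wil, climate_fits = fits,
                        importance_test = imp_test, nulls = nulls,
                        manifest = manifest),
                   class = "domrare_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wr(run$filtered$plots, "plots_filtered.tsv")
  wr(run$filtered$report, "filter_report.tsv")
  asn <- run$dominance$assignments
  asn_df <- do.call(rbind, lapply(asn, function(a) {
    if (a$excluded)
      return(data.frame(plot_id = a$plot_id, species = NA_character_,
                        class = paste0("excluded_", a$exclusion_reason),
                        stringsAsFactors = FALSE))
    data.frame(plot_id = a$plot_id,
               species = c(a$dominant_set, a$rare_set),
               class = rep(c("dominant", "rare"),
                           c(a$k_dom, a$k_rare)),
               stringsAsFactors = FALSE)
  }))
  wr(asn_df, "assignments.tsv")
  cdf <- as.data.frame(run$contrasts)
  wr(cdf, "contrasts.tsv")
  if (!is.null(run$pca)) {
    wr(data.frame(trait = rownames(run$pca$loadings),
                  run$pca$loadings, stringsAsFactors = FALSE),
       "pca_loadings.tsv")
    wr(data.frame(component = colnames(run$pca$loadings),
                  explained_fraction = run$pca$explained_fraction),
       "explained.tsv")
  }
  wr(run$wilcoxon, "wilcoxon.tsv")
  if (length(run$climate_fits)) {
    wr(do.call(rbind, lapply(run$climate_fits, climate_fit_row)),
       "climate_fits.tsv")
  }
  if (!is.null(run$importance_test))
    jsonlite::write_json(unclass(run$importance_test),
                         file.path(out_dir, "importance_test.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(run$nulls)) {
    ov <- do.call(rbind, lapply(names(run$nulls), function(b)
      cbind(biome = b, run$nulls[[b]]$overlap)))
    jsonlite::write_json(ov, file.path(out_dir, "overlap_report.json"),
                         digits = NA)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

climate_fit_row <- function(f) {
  cf <- f$coefficients
  g <- function(nm) if (nm %in% names(cf)) unname(cf[nm]) else NA_real_
  data.frame(response = f$response, n = f$n, r_squared = f$r_squared,
             coef_t = g("t"), coef_t2 = g("t2"), coef_w = g("w"),
             coef_w2 = g("w2"), coef_t_x_w = g("t_x_w"),
             lmg_temperature = unname(f$lmg["temperature"]),
             lmg_water = unname(f$lmg["water"]),
             lmg_interaction = unname(f$lmg["interaction"]),
             root_t_lo = f$geometry$temperature$roots[1],
             root_t_hi = f$geometry$temperature$roots[2],
             vertex_t = f$geometry$temperature$vertex,
             root_w_lo = f$geometry$water$roots[1],
             root_w_hi = f$geometry$water$roots[2],
             vertex_w = f$geometry$water$vertex,
             delta_aic_water_linear = f$delta_aic_water_linear,
             stringsAsFactors = FALSE)
}

#' @export
print.domrare_run <- function(x, ...) {
  m <- x$manifest
  cat("domrare pipeline run (seed", m$seed, ")\n")
  cat("  plots: ", m$n_plots_input, " input -> ", m$n_plots_filtered,
      " filtered -> ", m$n_plots_classified, " classified\n", sep = "")
  if (!is.null(x$pca))
    cat("  PCA: PC1 ", round(100 * x$pca$explained_fraction[1], 1),
        "%, PC2 ", round(100 * x$pca$explained_fraction[2], 1),
        "%\n", sep = "")
  cat("  Wilcoxon battery rows:", nrow(x$wilcoxon),
      "| climate fits:", length(x$climate_fits), "\n")
  invisible(x)
}

#' Sensitivity suite over classification and age thresholds
#'
#' Re-runs filter + classification + contrasts under variant settings of
#' the selection percentage (5, 10, 15) and of the minimum forest age
#' (25, 30, 35 years), on one generated dataset, and reports the
#' retained plot count and per-trait mean contrast for every variant.
#' Stricter percentages select more extreme ends of the rank-abundance
#' curve, so for a trait with a genuine dominance coupling the absolute
#' mean contrast should not decrease as the percentage tightens.
#'
#' @param config As for [run_pipeline()] (generator settings are used).
#' @param seed Integer seed (one dataset is shared by all variants).
#' @param pct_variants,age_variants Settings to sweep.
#' @return Data frame: `variant`, `setting`, `n_plots`, then
#'   `mean_D_<trait>` columns.
#' @export
sensitivity_suite <- function(config = list(), seed = 1,
                              pct_variants = c(5, 10, 15),
                              age_variants = c(25, 30, 35)) {
  gcfg <- config$generator %||% forest_config()
  if (!inherits(gcfg, "forest_config"))
    gcfg <- do.call(forest_config, gcfg)
  data <- generate_forest(gcfg, seed = seed)
  one <- function(pct, age_min) {
    filt <- apply_filters(data$plots, data$trees, age_min = age_min)
    trees_f <- data$trees[data$trees$plot_id %in% filt$plots$plot_id, ,
                          drop = FALSE]
    dset <- classify_all(trees_f, plots = filt$plots, pct = pct)
    retained <- names(Filter(function(a) !a$excluded, dset$assignments))
    pop <- which(data$traits$plot_id %in% retained)
    std <- standardize_traits(data$traits, population = pop)
    ctr <- plot_contrasts(std, dset, filt$plots, trees_f, pca = FALSE)
    md <- colMeans(as.matrix(ctr[, paste0("D_", trait_names())]),
                   na.rm = TRUE)
    c(list(n_plots = nrow(ctr)),
      stats::setNames(as.list(md), paste0("mean_", names(md))))
  }
  rows <- list()
  for (p in pct_variants)
    rows[[length(rows) + 1L]] <-
      c(list(variant = "pct", setting = p), one(p, 25))
  for (a in age_variants)
    rows[[length(rows) + 1L]] <-
      c(list(variant = "age_min", setting = a), one(10, a))
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}
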