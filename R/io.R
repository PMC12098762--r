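#' Read forest-inventory interchange tables
#'
#' Reads the three delimited text tables used throughout the package: a tree
#' abundance table (`trees.tsv`: plot_id, species, stems, division), a plot
#' table (`plots.tsv`: plot_id, lat, lon, area_ha, year, age, elevation_m,
#' biome, mat_c, wai) and a trait table (`traits.tsv`: species, optional
#' plot_id, the ten trait columns, division). All tables are tab-separated
#' with headers and "." as the decimal mark.
#'
#' Validation is total: every malformed input raises a typed condition
#' (`domrare_schema_error` for a missing column, `domrare_validation_error`
#' for an invariant violation naming the offending row) rather than being
#' silently coerced. Species that appear in the abundance table but not in
#' the trait table are flagged in the returned `unknown_species` attribute.
#'
#' @param dir Directory containing `trees.tsv`, `plots.tsv`, `traits.tsv`.
#' @param trees,plots,traits Optional explicit file paths overriding `dir`.
#' @return A list with elements `plots`, `trees`, `traits` (data frames) and
#'   attribute `unknown_species`.
#' @seealso [write_forest_tables()]
#' @export
read_forest_tables <- function(dir = NULL, trees = NULL, plots = NULL,
                               traits = NULL) {
  trees <- trees %||% file.path(dir, "trees.tsv")
  plots <- plots %||% file.path(dir, "plots.tsv")
  traits <- traits %||% file.path(dir, "traits.tsv")
  for (f in c(trees, plots, traits)) {
    if (!file.exists(f)) stop_domrare(paste0("file not found: ", f),
                                      "domrare_io_error")
  }
  rd <- function(f) utils::read.table(f, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE, dec = ".",
                                      check.names = FALSE)
  tr <- rd(trees); pl <- rd(plots); tt <- rd(traits)
  validate_trees(tr)
  validate_plots(pl)
  validate_traits(tt)
  unknown <- setdiff(unique(tr$species), unique(tt$species))
  out <- list(plots = pl, trees = tr, traits = tt)
  attr(out, "unknown_species") <- unknown
  out
}

require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_domrare(paste0(what, " table is missing required column(s): ",
                        paste(miss, collapse = ", ")),
                 "domrare_schema_error")
}

validate_trees <- function(tr) {
  require_cols(tr, c("plot_id", "species", "stems", "division"), "trees")
  bad <- which(!is.finite(tr$stems) | tr$stems < 1 | tr$stems != floor(tr$stems))
  if (length(bad))
    stop_domrare(paste0("trees: stems must be a positive integer; bad row(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")),
                 "domrare_validation_error")
  dup <- duplicated(tr[c("plot_id", "species")])
  if (any(dup))
    stop_domrare(paste0("trees: duplicate (plot_id, species) at row(s): ",
                        paste(utils::head(which(dup), 5), collapse = ", ")),
                 "domrare_validation_error")
  bad <- which(!tr$division %in% c("angiosperm", "gymnosperm"))
  if (length(bad))
    stop_domrare(paste0("trees: division must be angiosperm|gymnosperm; row(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")),
                 "domrare_validation_error")
  invisible(tr)
}

validate_plots <- function(pl) {
  require_cols(pl, c("plot_id", "lat", "lon", "area_ha", "year", "age",
                     "elevation_m", "biome", "mat_c", "wai"), "plots")
  bad <- which(!is.finite(pl$area_ha) | pl$area_ha <= 0)
  if (length(bad))
    stop_domrare(paste0("plots: area_ha must be > 0; bad row(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")),
                 "domrare_validation_error")
  bad <- which(!is.finite(pl$wai) | pl$wai < 0)
  if (length(bad))
    stop_domrare(paste0("plots: wai must be >= 0; bad row(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")),
                 "domrare_validation_error")
  bad <- which(!is.finite(pl$age) | pl$age < 0)
  if (length(bad))
    stop_domrare(paste0("plots: age must be >= 0; bad row(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")),
                 "domrare_validation_error")
  bad <- which(!pl$biome %in% biome_levels())
  if (length(bad))
    stop_domrare(paste0("plots: unknown biome label; bad row(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")),
                 "domrare_validation_error")
  if (anyDuplicated(pl$plot_id))
    stop_domrare("plots: duplicate plot_id", "domrare_validation_error")
  invisible(pl)
}

validate_traits <- function(tt) {
  require_cols(tt, c("species", trait_names(), "division"), "traits")
  for (tn in trait_names()) {
    v <- tt[[tn]]
    bad <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    if (length(bad))
      stop_domrare(paste0("traits: ", tn,
                          " must be positive (log-transformable); bad row(s): ",
                          paste(utils::head(bad, 5), collapse = ", ")),
                   "domrare_validation_error")
  }
  invisible(tt)
}

#' Write forest-inventory interchange tables
#'
#' Writes `plots.tsv`, `trees.tsv` and `traits.tsv` under `dir` in the
#' canonical column order, so that `write_forest_tables(read_forest_tables(d))`
#' round-trips byte-identically.
#'
#' @param tables A list as returned by [read_forest_tables()] or
#'   [generate_forest()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_forest_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, dec = ".")
  wr(canonical_order(tables$plots,
                     c("plot_id", "lat", "lon", "area_ha", "year", "age",
                       "elevation_m", "biome", "mat_c", "wai")), "plots.tsv")
  wr(canonical_order(tables$trees,
                     c("plot_id", "species", "stems", "division")), "trees.tsv")
  tcols <- c("species",
             intersect("plot_id", names(tables$traits)),
             trait_names(), "division")
  wr(canonical_order(tables$traits, tcols), "traits.tsv")
  invisible(dir)
}

canonical_order <- function(df, cols) {
  df <- df[, c(cols, setdiff(names(df), cols)), drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Map raw species names through a synonym table
#'
#' Standardises raw species names against a user-supplied synonym map (a
#' named character vector, `raw name -> accepted name`). Names without an
#' entry pass through unchanged; nothing is dropped. The fraction of names
#' that were remapped is attached as attribute `mapped_fraction`.
#'
#' @param raw_names Character vector of names as recorded.
#' @param synonym_map Named character vector; may be empty.
#' @return Character vector of resolved names with attribute
#'   `mapped_fraction`.
#' @export
resolve_names <- function(raw_names, synonym_map = character()) {
  stopifnot(is.character(raw_names))
  if (length(synonym_map) && is.null(names(synonym_map)))
    stop_domrare("synonym_map must be a named character vector",
                 "domrare_parameter_error")
  hit <- raw_names %in% names(synonym_map)
  out <- raw_names
  out[hit] <- unname(synonym_map[raw_names[hit]])
  attr(out, "mapped_fraction") <-
    if (length(raw_names)) mean(hit) else 0
  out
}
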