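#' Deterministic plot-keyed tie-break key
#'
#' Hash of (plot id, species id) used to order species with tied
#' abundance: reproducible across runs and platforms, but varying from
#' plot to plot so no fixed species is systematically favoured at ties.
#'
#' @param species Character vector of species ids.
#' @param plot_id Plot id (scalar, recycled).
#' @return Numeric hash values in `[0, 1000003)`.
#' @export
tie_hash <- function(species, plot_id = NA_character_) {
  # multiplicative mix: an additive combination would merely rotate one
  # fixed species order within each plot, re-favouring the same species
  a <- roll_hash(as.character(plot_id)[1]) + 1
  (a * (roll_hash(species) + 1)) %% 1000003
}

.hash_cache <- new.env(parent = emptyenv())

roll_hash <- function(strings) {
  out <- numeric(length(strings))
  for (i in seq_along(strings)) {
    s <- strings[i]
    h <- .hash_cache[[s]]
    if (is.null(h)) {
      v <- utf8ToInt(s)
      h <- 0
      for (c in v) h <- (h * 131 + c) %% 1000003
      .hash_cache[[s]] <- h
    }
    out[i] <- h
  }
  out
}

#' Classify the dominant and rare species of one plot
#'
#' Ranks a plot's species by abundance and selects the extremes of the
#' rank-abundance curve: in plots with 6--19 species the top two and
#' bottom two species are dominant and rare respectively; in plots with
#' 20 or more species the top and bottom `pct` percent are taken, with
#' `k = floor(S * pct / 100)` floored at 2. A plot whose rarest species
#' still holds more than 10 percent of the total stems is excluded
#' (reason `rarest_gt_10pct`), since its rare species are not clearly
#' separated in abundance from its dominants; plots with fewer than six
#' species are excluded defensively (reason `too_few_species`).
#'
#' Ties at a rank boundary are broken deterministically but without a
#' global species order: all species are placed in one total order by
#' (abundance decreasing, plot-keyed hash of the species id, species
#' id); the dominant set is the first `k` of that order and the rare set
#' the last `k`. Using one total order keeps the two sets disjoint even
#' when a run of tied abundances spans both boundaries, and keying the
#' hash by plot prevents any fixed species (e.g. the alphabetically
#' last) from being picked at every tie across thousands of plots, which
#' would couple persistent species identity -- and hence that species'
#' trait values -- to the rare group.
#'
#' @param abund Data frame with columns `species` and `stems` (one plot),
#'   plus optional `basal_area` when `basis = "basal_area"`.
#' @param pct Selection percentage for plots with >= 20 species
#'   (default 10; 5 and 15 supported for sensitivity analyses).
#' @param basis Abundance measure used for ranking, `"stems"` (default)
#'   or `"basal_area"`. The >10-percent-rarest exclusion is always
#'   evaluated on stem shares.
#' @param plot_id Optional id carried into the result.
#' @return A `dominance_assignment` list: `plot_id`, `dominant_set`,
#'   `rare_set`, `k_dom`, `k_rare`, `excluded`, `exclusion_reason`.
#' @examples
#' classify_plot(data.frame(species = LETTERS[1:6],
#'                          stems = c(10, 8, 5, 3, 2, 1)))
#' @export
classify_plot <- function(abund, pct = 10, basis = c("stems", "basal_area"),
                          plot_id = NA_character_) {
  basis <- match.arg(basis)
  if (!all(c("species", "stems") %in% names(abund)))
    stop_domrare("abundance table needs species and stems columns",
                 "domrare_schema_error")
  S <- nrow(abund)
  res <- function(dom, rare, excluded, reason)
    structure(list(plot_id = plot_id,
                   dominant_set = dom, rare_set = rare,
                   k_dom = length(dom), k_rare = length(rare),
                   excluded = excluded, exclusion_reason = reason),
              class = "dominance_assignment")
  if (S < 6)
    return(res(character(0), character(0), TRUE, "too_few_species"))
  # exclusion is checked first, always on stem shares
  if (min(abund$stems) / sum(abund$stems) > 0.10)
    return(res(character(0), character(0), TRUE, "rarest_gt_10pct"))
  a <- if (basis == "stems") abund$stems else abund$basal_area
  if (basis == "basal_area" && is.null(a))
    stop_domrare("basis = basal_area requires a basal_area column",
                 "domrare_schema_error")
  k <- if (S <= 19) 2L else max(2L, as.integer(floor(S * pct / 100)))
  ord <- order(-a, tie_hash(abund$species, plot_id), abund$species)
  res(abund$species[ord[seq_len(k)]],
      abund$species[rev(ord)[seq_len(k)]],
      FALSE, "none")
}

#' Classify every plot in an abundance table
#'
#' Runs [classify_plot()] over all plots, optionally first drawing a
#' seeded uniform subsample of the temperate-biome plots (the device used
#' to balance an otherwise temperate-heavy dataset). Plots of other
#' biomes are never subsampled.
#'
#' @param trees Abundance table (plot_id, species, stems).
#' @param plots Plot table; required when `temperate_subsample` is set.
#' @param pct,basis Passed to [classify_plot()].
#' @param temperate_subsample Optional list `list(n = , seed = )`; at most
#'   `n` temperate plots are kept, sampled with the given seed.
#' @return A list of class `dominance_set`: `assignments` (named list of
#'   `dominance_assignment`), `subsampled_ids` (NULL or the retained
#'   temperate ids), and `exclusions`, a data frame of excluded plots.
#' @export
classify_all <- function(trees, plots = NULL, pct = 10,
                         basis = c("stems", "basal_area"),
                         temperate_subsample = NULL) {
  basis <- match.arg(basis)
  keep_ids <- unique(trees$plot_id)
  subsampled <- NULL
  if (!is.null(temperate_subsample)) {
    if (is.null(plots))
      stop_domrare("temperate subsampling needs the plot table",
                   "domrare_parameter_error")
    temp_ids <- plots$plot_id[plots$biome == "temperate"]
    temp_ids <- intersect(temp_ids, keep_ids)
    n <- temperate_subsample$n
    if (!is_count(n) || n < 1)
      stop_domrare("temperate_subsample$n must be a positive integer",
                   "domrare_parameter_error")
    if (length(temp_ids) > n) {
      set.seed(temperate_subsample$seed %||% 1L)
      subsampled <- sort(sample(temp_ids, n))
      keep_ids <- c(setdiff(keep_ids, temp_ids), subsampled)
    } else subsampled <- temp_ids
  }
  keep_ids <- keep_ids[order(keep_ids)]
  idx <- split(seq_len(nrow(trees)), trees$plot_id)
  assignments <- lapply(keep_ids, function(pid)
    classify_plot(trees[idx[[pid]], , drop = FALSE], pct = pct,
                  basis = basis, plot_id = pid))
  names(assignments) <- keep_ids
  excl <- vapply(assignments, `[[`, logical(1), "excluded")
  exclusions <- data.frame(
    plot_id = keep_ids[excl],
    reason = vapply(assignments[excl], `[[`, character(1),
                    "exclusion_reason"),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(assignments = assignments,
                 subsampled_ids = subsampled,
                 exclusions = exclusions,
                 pct = pct, basis = basis),
            class = "dominance_set")
}

#' @export
print.dominance_assignment <- function(x, ...) {
  if (x$excluded) {
    cat("Plot", x$plot_id, "excluded:", x$exclusion_reason, "\n")
  } else {
    cat("Plot", x$plot_id, "- dominant:",
        paste(x$dominant_set, collapse = ", "),
        "| rare:", paste(x$rare_set, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.dominance_set <- function(x, ...) {
  n <- length(x$assignments)
  cat("Dominance classification of", n, "plots (pct =", x$pct,
      ", basis =", x$basis, ")\n")
  cat("  excluded:", nrow(x$exclusions), "\n")
  if (!is.null(x$subsampled_ids))
    cat("  temperate subsample:", length(x$subsampled_ids), "plots\n")
  invisible(x)
}

#' Bootstrap check that a subsample represents the full biome
#'
#' Compares per-trait mean contrasts from a full set of plot contrasts
#' with the bootstrap distribution obtained by resampling the subsample's
#' plots with replacement: for each trait, reports whether the full-set
#' mean difference lies inside the central 95 percent bootstrap interval.
#'
#' @param full_contrasts,sub_contrasts Contrast tables (see
#'   [plot_contrasts()]); only the `D_<trait>` columns are used.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return Data frame with one row per trait: full-set mean, bootstrap
#'   interval bounds, and a `covered` flag.
#' @export
bootstrap_subsample_check <- function(full_contrasts, sub_contrasts,
                                      B = 200, seed = 1) {
  if (!is_count(B) || B < 1)
    stop_domrare("B must be a positive integer", "domrare_parameter_error")
  dcols <- paste0("D_", trait_names())
  dcols <- intersect(dcols, names(full_contrasts))
  if (!nrow(full_contrasts) || !nrow(sub_contrasts))
    stop_domrare("contrast sets must be nonempty", "domrare_parameter_error")
  set.seed(seed)
  n <- nrow(sub_contrasts)
  boot <- matrix(NA_real_, B, length(dcols),
                 dimnames = list(NULL, dcols))
  for (b in seq_len(B)) {
    ix <- sample.int(n, n, replace = TRUE)
    boot[b, ] <- colMeans(sub_contrasts[ix, dcols, drop = FALSE],
                          na.rm = TRUE)
  }
  full_mean <- colMeans(full_contrasts[, dcols, drop = FALSE], na.rm = TRUE)
  lo <- apply(boot, 2, stats::quantile, 0.025, na.rm = TRUE)
  hi <- apply(boot, 2, stats::quantile, 0.975, na.rm = TRUE)
  data.frame(trait = sub("^D_", "", dcols),
             full_mean = as.vector(full_mean),
             boot_lower = as.vector(lo), boot_upper = as.vector(hi),
             covered = full_mean >= lo & full_mean <= hi,
             row.names = NULL, stringsAsFactors = FALSE)
}
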