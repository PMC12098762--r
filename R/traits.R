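#' Log-transform and z-score a trait table
#'
#' Builds the three trait layers used by the analysis: the raw layer
#' (native units, strictly positive), the natural-log layer, and the
#' z-score layer `(log - mean) / sd` with the mean and standard deviation
#' of each trait computed over a stated standardization population and
#' stored with the result. The log transform tempers trait outliers; the
#' pooled z-scoring puts all ten traits on one common s.d. scale so that
#' contrasts are comparable across traits and biomes.
#'
#' @param traits Trait table with `species`, optional `plot_id`, the ten
#'   trait columns and `division`.
#' @param population Optional logical or integer index selecting the rows
#'   over which standardization constants are computed (default: all
#'   rows). Typically the tree-level occurrences of the filtered,
#'   classified dataset.
#' @return An object of class `std_traits`: list with `raw`, `log`,
#'   `zscore` data frames (same keys), and `constants` (trait, mean, sd
#'   of the log layer).
#' @export
standardize_traits <- function(traits, population = NULL) {
  tn <- trait_names()
  require_cols(traits, c("species", tn), "traits")
  pop <- if (is.null(population)) seq_len(nrow(traits)) else population
  logdf <- traits
  for (t in tn) {
    v <- traits[[t]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      stop_domrare(paste0("trait ", t, " non-positive for species ",
                          traits$species[bad[1]], " (row ", bad[1], ")"),
                   "domrare_validation_error")
    logdf[[t]] <- log(v)
  }
  const <- data.frame(trait = tn, mean = NA_real_, sd = NA_real_,
                      stringsAsFactors = FALSE)
  zdf <- logdf
  for (i in seq_along(tn)) {
    lv <- logdf[[tn[i]]][pop]
    m <- mean(lv, na.rm = TRUE)
    s <- stats::sd(lv, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop_domrare(paste0("trait ", tn[i],
                          " has zero variance in the standardization ",
                          "population"), "domrare_validation_error")
    const$mean[i] <- m; const$sd[i] <- s
    zdf[[tn[i]]] <- (logdf[[tn[i]]] - m) / s
  }
  structure(list(raw = traits, log = logdf, zscore = zdf,
                 constants = const), class = "std_traits")
}

#' @export
print.std_traits <- function(x, ...) {
  cat("Standardized trait table:", nrow(x$raw), "rows,",
      length(trait_names()), "traits (raw/log/zscore layers)\n")
  print(x$constants, digits = 3)
  invisible(x)
}

# Precomputed lookup structure over the z layer: species-by-plot keys,
# species-level means, genus-level means (for trees resolved to genus only).
build_trait_lookup <- function(std) {
  z <- std$zscore
  tn <- trait_names()
  zmat <- as.matrix(z[, tn, drop = FALSE])
  has_plot <- "plot_id" %in% names(z) && any(!is.na(z$plot_id))
  key <- if (has_plot) paste(z$species, z$plot_id, sep = "\r") else NULL
  sp_mean <- rowsum(zmat, z$species, na.rm = TRUE)
  sp_n <- rowsum((!is.na(zmat)) + 0, z$species)
  sp_mean <- sp_mean / pmax(sp_n, 1)
  sp_mean[sp_n == 0] <- NA_real_
  genus <- sub("[ _].*$", "", rownames(sp_mean))
  g_mean <- rowsum(ifelse(is.na(sp_mean), 0, sp_mean), genus)
  g_n <- rowsum((!is.na(sp_mean)) + 0, genus)
  g_mean <- g_mean / pmax(g_n, 1)
  g_mean[g_n == 0] <- NA_real_
  list(zmat = zmat, key = key, has_plot = has_plot,
       sp_mean = sp_mean, g_mean = g_mean)
}

# column-wise medians by group key; size-1/2 NA-free groups (the
# overwhelmingly common case, k = 2) go through rowsum, the rest loop
group_col_medians <- function(z, key) {
  f <- factor(key)
  li <- split(seq_along(f), f)
  sizes <- lengths(li)
  row_na <- rowSums(is.na(z)) > 0
  grp_na <- vapply(li, function(ix) any(row_na[ix]), logical(1))
  out <- matrix(NA_real_, length(li), ncol(z),
                dimnames = list(names(li), colnames(z)))
  easy <- sizes <= 2 & !grp_na
  if (any(easy)) {
    s <- rowsum(z, as.integer(f))
    out[easy, ] <- s[easy, , drop = FALSE] / sizes[easy]
  }
  for (g in which(!easy)) {
    zz <- z[li[[g]], , drop = FALSE]
    out[g, ] <- apply(zz, 2, function(v) stats::median(v[!is.na(v)]))
  }
  out
}

# z-values for a set of species in one plot, with species-level and
# genus-level fallback; rows of all-NA correspond to unresolvable trees.
lookup_z <- function(lk, species, plot_id) {
  n <- length(species)
  out <- matrix(NA_real_, n, ncol(lk$zmat),
                dimnames = list(species, colnames(lk$zmat)))
  if (lk$has_plot) {
    m <- match(paste(species, plot_id, sep = "\r"), lk$key)
    hit <- !is.na(m)
    out[hit, ] <- lk$zmat[m[hit], , drop = FALSE]
  } else hit <- rep(FALSE, n)
  todo <- which(!hit)
  if (length(todo)) {
    m <- match(species[todo], rownames(lk$sp_mean))
    hit2 <- !is.na(m)
    out[todo[hit2], ] <- lk$sp_mean[m[hit2], , drop = FALSE]
    todo <- todo[!hit2]
  }
  if (length(todo)) {
    g <- sub("[ _].*$", "", species[todo])
    m <- match(g, rownames(lk$g_mean))
    hit3 <- !is.na(m)
    out[todo[hit3], ] <- lk$g_mean[m[hit3], , drop = FALSE]
  }
  out
}

#' Median z-scored trait of one plot's dominant or rare group
#'
#' Aggregates a group's species-by-plot z-values to a single number per
#' trait with the median, so that unequal dominant and rare group sizes
#' cannot bias the contrast.
#'
#' @param std A [standardize_traits()] result.
#' @param assignment A `dominance_assignment` for the plot.
#' @param group `"dominant"` or `"rare"`.
#' @param trait One of [trait_names()].
#' @return The median z-value (NA when every group member lacks the
#'   trait).
#' @export
group_median <- function(std, assignment, group = c("dominant", "rare"),
                         trait) {
  group <- match.arg(group)
  stopifnot(trait %in% trait_names())
  members <- if (group == "dominant") assignment$dominant_set else
    assignment$rare_set
  if (!length(members))
    stop_domrare("group is empty for this plot", "domrare_parameter_error")
  lk <- build_trait_lookup(std)
  z <- lookup_z(lk, members, rep(assignment$plot_id, length(members)))
  stats::median(z[, trait], na.rm = TRUE)
}

#' Plot-level dominant-minus-rare trait contrasts
#'
#' For every retained plot, computes the dominant-group and rare-group
#' median z-value per trait, their difference
#' `D = dom_median - rare_median` (in pooled s.d. units), the percentage
#' of each group's species that are gymnosperms, and (optionally) the
#' groups' scores on the first two axes of a traits PCA fitted to the
#' plot-by-group median vectors.
#'
#' @param std A [standardize_traits()] result.
#' @param dset A `dominance_set` from [classify_all()].
#' @param plots Plot table (for biome/climate covariates).
#' @param trees Abundance table (for per-plot division flags).
#' @param pca `TRUE` (fit a PCA to the group median vectors and attach
#'   PC1/PC2 scores), `FALSE`, or an existing [fit_pca()] result to
#'   project onto.
#' @return A data frame of class `plot_contrasts` with one row per
#'   retained plot: covariates, `dom_<trait>`, `rare_<trait>`,
#'   `D_<trait>`, `gym_pct_dom`, `gym_pct_rare`, and `pc1_dom`,
#'   `pc1_rare`, `pc2_dom`, `pc2_rare`, `D_gym_pct`, `D_pc1`, `D_pc2`.
#'   The fitted PCA (if any) is attached as attribute `pca`; the count of
#'   trees dropped for lacking any trait data as attribute `n_dropped`.
#' @export
plot_contrasts <- function(std, dset, plots, trees, pca = TRUE) {
  tn <- trait_names()
  lk <- build_trait_lookup(std)
  asn <- Filter(function(a) !a$excluded, dset$assignments)
  if (!length(asn))
    return(structure(data.frame(), class = c("plot_contrasts",
                                             "data.frame")))
  np <- length(asn)
  pids <- vapply(asn, `[[`, character(1), "plot_id")
  k_dom <- vapply(asn, `[[`, integer(1), "k_dom")
  k_rare <- vapply(asn, `[[`, integer(1), "k_rare")
  # one long member table for all plots and both groups, looked up and
  # aggregated in a single pass
  mem <- data.frame(
    plot = rep(rep(pids, 2), c(k_dom, k_rare)),
    gidx = rep(rep(seq_len(np), 2), c(k_dom, k_rare)),
    group = rep(rep(c("dominant", "rare"), c(np, np)),
                c(k_dom, k_rare)),
    species = c(unlist(lapply(asn, `[[`, "dominant_set")),
                unlist(lapply(asn, `[[`, "rare_set"))),
    stringsAsFactors = FALSE)
  zmem <- lookup_z(lk, mem$species, mem$plot)
  n_dropped <- sum(rowSums(!is.na(zmem)) == 0)
  gkey <- paste(mem$group, mem$gidx)
  med_all <- group_col_medians(zmem, gkey)
  dk <- paste("dominant", seq_len(np))
  rk <- paste("rare", seq_len(np))
  med_d <- med_all[match(dk, rownames(med_all)), , drop = FALSE]
  med_r <- med_all[match(rk, rownames(med_all)), , drop = FALSE]
  dimnames(med_d) <- dimnames(med_r) <- list(NULL, tn)

  div_key <- paste(trees$plot_id, trees$species, sep = "\r")
  mem$division <- trees$division[match(paste(mem$plot, mem$species,
                                             sep = "\r"), div_key)]
  gshare <- tapply(mem$division == "gymnosperm", gkey,
                   mean, na.rm = TRUE)
  gym <- 100 * cbind(as.vector(gshare[dk]), as.vector(gshare[rk]))
  m <- match(pids, plots$plot_id)
  out <- data.frame(plot_id = pids,
                    plots[m, c("biome", "mat_c", "wai", "area_ha",
                               "age", "elevation_m")],
                    stats::setNames(as.data.frame(med_d),
                                    paste0("dom_", tn)),
                    stats::setNames(as.data.frame(med_r),
                                    paste0("rare_", tn)),
                    stats::setNames(as.data.frame(med_d - med_r),
                                    paste0("D_", tn)),
                    gym_pct_dom = gym[, 1], gym_pct_rare = gym[, 2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$D_gym_pct <- out$gym_pct_dom - out$gym_pct_rare

  pca_fit <- NULL
  if (isTRUE(pca) || inherits(pca, "trait_pca")) {
    dom_mat <- as.matrix(out[, paste0("dom_", tn)])
    rare_mat <- as.matrix(out[, paste0("rare_", tn)])
    colnames(dom_mat) <- colnames(rare_mat) <- tn
    stacked <- rbind(dom_mat, rare_mat)
    complete <- stats::complete.cases(stacked)
    pca_fit <- if (inherits(pca, "trait_pca")) pca else
      fit_pca(stacked[complete, , drop = FALSE])
    sc <- matrix(NA_real_, nrow(stacked), 2)
    sc[complete, ] <- stats::predict(pca_fit,
                                     stacked[complete, , drop = FALSE])[, 1:2]
    n <- nrow(out)
    out$pc1_dom <- sc[seq_len(n), 1]
    out$pc2_dom <- sc[seq_len(n), 2]
    out$pc1_rare <- sc[n + seq_len(n), 1]
    out$pc2_rare <- sc[n + seq_len(n), 2]
    out$D_pc1 <- out$pc1_dom - out$pc1_rare
    out$D_pc2 <- out$pc2_dom - out$pc2_rare
  }
  structure(out, class = c("plot_contrasts", "data.frame"),
            pca = pca_fit, n_dropped = n_dropped)
}

#' Mean absolute trait contrast of a biome
#'
#' The mean of `|D|` pooled over the ten traits and all of a biome's
#' plots: a single-number summary of how strongly dominants and rares
#' diverge in that biome, in pooled s.d. units.
#'
#' @param contrasts A [plot_contrasts()] table.
#' @param biome Biome label.
#' @return Mean absolute difference (NA when the biome has no plots).
#' @export
biome_mean_absolute_difference <- function(contrasts, biome) {
  sub <- contrasts[contrasts$biome == biome, paste0("D_", trait_names()),
                   drop = FALSE]
  if (!nrow(sub)) return(NA_real_)
  mean(abs(as.matrix(sub)), na.rm = TRUE)
}
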