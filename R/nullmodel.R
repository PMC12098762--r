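#' Randomize a plot-by-species matrix holding both margins fixed
#'
#' Draws a random nonnegative integer matrix with exactly the observed
#' row sums (total stems per plot) and column sums (total individuals
#' per species), uniformly over all such tables, using the sequential
#' conditional (Patefield-type) algorithm provided by
#' [stats::r2dtable()]. This breaks the link between which species is
#' abundant where, while conserving every plot's stem total and every
#' species' regional total.
#'
#' @param mat Nonnegative integer matrix (plots x species).
#' @param seed Integer seed; draws are deterministic given it.
#' @return A matrix of the same dimensions and dimnames with identical
#'   row and column sums.
#' @export
fixed_margin_randomize <- function(mat, seed = 1) {
  mat <- as.matrix(mat)
  if (!length(mat)) return(mat)
  if (any(mat < 0) || any(mat != floor(mat)))
    stop_domrare("matrix must contain nonnegative integers",
                 "domrare_validation_error")
  rs <- rowSums(mat); cs <- colSums(mat)
  if (nrow(mat) == 1L || ncol(mat) == 1L) return(mat)  # fully constrained
  set.seed(seed)
  out <- stats::r2dtable(1, rs, cs)[[1]]
  dimnames(out) <- dimnames(mat)
  out
}

plot_species_matrix <- function(trees) {
  if (!nrow(trees)) return(matrix(0L, 0, 0))
  p <- factor(trees$plot_id)
  s <- factor(trees$species)
  m <- matrix(0L, nlevels(p), nlevels(s),
              dimnames = list(levels(p), levels(s)))
  m[cbind(as.integer(p), as.integer(s))] <- as.integer(trees$stems)
  m
}

matrix_to_trees <- function(mat, division_by_species) {
  ix <- which(mat > 0, arr.ind = TRUE)
  sp <- colnames(mat)[ix[, 2]]
  data.frame(plot_id = rownames(mat)[ix[, 1]],
             species = sp,
             stems = mat[ix],
             division = unname(division_by_species[sp]),
             stringsAsFactors = FALSE)
}

# overlapping coefficient of two samples from pooled-range histograms
overlap_coefficient <- function(a, b, bins = 30) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  rng <- range(c(a, b))
  if (diff(rng) == 0) return(1)
  brk <- seq(rng[1], rng[2], length.out = bins + 1)
  fa <- tabulate(findInterval(a, brk, rightmost.closed = TRUE), bins)
  fb <- tabulate(findInterval(b, brk, rightmost.closed = TRUE), bins)
  sum(pmin(fa / sum(fa), fb / sum(fb)))
}

#' Null-model ensemble for one biome
#'
#' Repeatedly randomizes a biome's plot-by-species stem matrix with
#' [fixed_margin_randomize()], re-runs the dominance classification on
#' each randomized community (plots whose richness falls below six
#' species in a replicate are excluded by the standard rule and
#' counted), and summarizes each group's z-scored traits under three
#' plot-level aggregation statistics: mean, median, and interquartile
#' range. Trait values travel with the species (species-by-plot rows are
#' re-looked-up after randomization), so the null severs the
#' abundance--trait link while conserving both margins.
#'
#' The ensemble records, per replicate, statistic and group, the
#' across-plot average of each trait's plot-level summary, plus the
#' pairwise overlapping coefficients of the three statistics' replicate
#' distributions per group.
#'
#' @param trees Abundance table for one biome's plots.
#' @param std A [standardize_traits()] result covering those species.
#' @param n_reps Number of randomizations (default 100).
#' @param seed Integer master seed.
#' @param pct Selection percentage for the classifier.
#' @return Object of class `null_ensemble`: `summaries` (long data
#'   frame: rep, statistic, group, trait, value), `overlap` (pairwise
#'   overlap coefficients per group), `n_excluded` per replicate.
#' @export
null_ensemble <- function(trees, std, n_reps = 100, seed = 1, pct = 10) {
  if (!is_count(n_reps) || n_reps < 1)
    stop_domrare("n_reps must be a positive integer",
                 "domrare_parameter_error")
  mat <- plot_species_matrix(trees)
  div <- tapply(trees$division, trees$species, `[`, 1)
  lk <- build_trait_lookup(std)
  tn <- trait_names()
  stats_fun <- list(
    mean = function(v) mean(v, na.rm = TRUE),
    median = function(v) stats::median(v, na.rm = TRUE),
    IQR = function(v) stats::IQR(v, na.rm = TRUE))

  res <- vector("list", n_reps)
  n_excluded <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    rmat <- fixed_margin_randomize(mat, seed = derive_seed(seed, r))
    rtrees <- matrix_to_trees(rmat, div)
    rich <- table(rtrees$plot_id)
    keep <- names(rich)[rich >= 6]
    n_excluded[r] <- nrow(mat) - length(keep)
    rtrees <- rtrees[rtrees$plot_id %in% keep, , drop = FALSE]
    if (!nrow(rtrees)) next
    dset <- classify_all(rtrees, pct = pct)
    acc <- list()
    for (a in dset$assignments) {
      if (a$excluded) next
      for (grp in c("dominant", "rare")) {
        mem <- if (grp == "dominant") a$dominant_set else a$rare_set
        z <- lookup_z(lk, mem, rep(a$plot_id, length(mem)))
        for (sname in names(stats_fun)) {
          acc[[paste(grp, sname)]] <-
            rbind(acc[[paste(grp, sname)]],
                  apply(z, 2, stats_fun[[sname]]))
        }
      }
    }
    rows <- lapply(names(acc), function(k) {
      gs <- strsplit(k, " ")[[1]]
      data.frame(rep = r, statistic = gs[2], group = gs[1],
                 trait = tn, value = colMeans(acc[[k]], na.rm = TRUE),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    res[[r]] <- do.call(rbind, rows)
  }
  summaries <- do.call(rbind, res)

  pairs <- list(c("mean", "median"), c("mean", "IQR"), c("median", "IQR"))
  ov <- list()
  for (grp in c("dominant", "rare")) {
    for (pr in pairs) {
      va <- summaries$value[summaries$group == grp &
                              summaries$statistic == pr[1]]
      vb <- summaries$value[summaries$group == grp &
                              summaries$statistic == pr[2]]
      ov[[length(ov) + 1L]] <- data.frame(
        group = grp, stat_a = pr[1], stat_b = pr[2],
        overlap = overlap_coefficient(va, vb),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(summaries = summaries,
                 overlap = do.call(rbind, ov),
                 n_excluded = n_excluded,
                 n_reps = n_reps, seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Null-model ensemble:", x$n_reps, "fixed-margin randomizations\n")
  cat("  mean plots excluded per replicate (<6 species):",
      round(mean(x$n_excluded), 1), "\n")
  print(x$overlap, digits = 3)
  invisible(x)
}
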