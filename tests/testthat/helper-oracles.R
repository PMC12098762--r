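# Independent brute-force oracles used across the suite.

# rank-abundance classifier: full sort and explicit slicing, sharing only
# the tie-key convention with the implementation
oracle_classify <- function(abund, pct = 10, plot_id = NA_character_) {
  S <- nrow(abund)
  if (S < 6)
    return(list(excluded = TRUE, reason = "too_few_species"))
  if (min(abund$stems) / sum(abund$stems) > 0.10)
    return(list(excluded = TRUE, reason = "rarest_gt_10pct"))
  k <- if (S >= 20) max(2, floor(S * pct / 100)) else 2
  key <- tie_hash(abund$species, plot_id)
  o <- order(-abund$stems, key, abund$species)
  ranked <- abund$species[o]
  list(excluded = FALSE,
       dom = sort(ranked[seq_len(k)]),
       rare = sort(ranked[S + 1 - seq_len(k)]))
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wdist <- as.vector(signs %*% r)
  p_le <- mean(Wdist <= W)
  p_ge <- mean(Wdist >= W)
  min(1, 2 * min(p_le, p_ge))
}

# LMG by explicit averaging over all orderings of groups
oracle_lmg <- function(x, y, groups) {
  G <- length(groups)
  r2_of <- function(cols) {
    if (!length(cols)) return(0)
    f <- lm.fit(cbind(1, x[, cols, drop = FALSE]), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  shares <- setNames(numeric(G), names(groups))
  allp <- perms(seq_len(G))
  for (p in allp) {
    have <- character(0)
    for (g in p) {
      r2_before <- r2_of(have)
      have <- c(have, groups[[g]])
      shares[g] <- shares[g] + (r2_of(have) - r2_before)
    }
  }
  shares / length(allp)
}

# all nonnegative integer matrices with the given margins, with their
# Patefield (multivariate hypergeometric) probabilities
oracle_fiber <- function(rs, cs) {
  nr <- length(rs); nc <- length(cs); N <- sum(rs)
  stopifnot(N == sum(cs))
  tables <- list()
  rec <- function(rows, rem) {
    i <- length(rows) + 1
    if (i > nr) {
      if (all(rem == 0))
        tables[[length(tables) + 1]] <<- do.call(rbind, rows)
      return(invisible())
    }
    for (row in enum_comp(rs[i], nc, rem))
      rec(c(rows, list(row)), rem - row)
  }
  rec(list(), cs)
  probs <- vapply(tables, function(tb)
    exp(sum(lfactorial(rs)) + sum(lfactorial(cs)) -
          lfactorial(N) - sum(lfactorial(tb))), numeric(1))
  list(tables = tables, probs = probs)
}

enum_comp <- function(total, parts, caps) {
  if (parts == 1) {
    if (total <= caps[1]) return(list(total)) else return(list())
  }
  out <- list()
  for (v in 0:min(total, caps[1])) {
    for (rest in enum_comp(total - v, parts - 1, caps[-1]))
      out[[length(out) + 1]] <- c(v, rest)
  }
  out
}

# small synthetic interchange fixture: 3 plots, 8 species
tiny_tables <- function() {
  plots <- data.frame(
    plot_id = c("p1", "p2", "p3"),
    lat = c(45.1, 46.2, 47.3), lon = c(7.5, 8.5, 9.5),
    area_ha = c(0.05, 0.10, 0.07),
    year = c(2000L, 2005L, 2010L),
    age = c(60, 40, 80),
    elevation_m = c(300, 500, 700),
    biome = c("temperate", "temperate", "boreal"),
    mat_c = c(9.5, 8.0, 1.5), wai = c(1.2, 1.4, 1.1),
    stringsAsFactors = FALSE)
  sp <- c("Fagus sylvatica", "Picea abies", "Abies alba", "Quercus robur",
          "Betula pendula", "Pinus sylvestris", "Acer pseudoplatanus",
          "Sorbus aucuparia")
  trees <- data.frame(
    plot_id = rep(c("p1", "p2", "p3"), c(3, 3, 2)),
    species = sp,
    stems = c(12L, 5L, 2L, 20L, 7L, 3L, 9L, 1L),
    division = ifelse(sp %in% c("Picea abies", "Pinus sylvestris",
                                "Abies alba"),
                      "gymnosperm", "angiosperm"),
    stringsAsFactors = FALSE)
  traits <- data.frame(species = sp, stringsAsFactors = FALSE)
  set.seed(99)
  for (tn in trait_names()) traits[[tn]] <- exp(rnorm(8))
  traits$division <- trees$division[match(traits$species, trees$species)]
  list(plots = plots, trees = trees, traits = traits)
}

# tiny standardized trait set over explicit z-values for contrast tests
std_from_z <- function(zvals, species, plot_id) {
  # builds a std_traits object whose zscore layer holds the given values
  tn <- trait_names()
  df <- data.frame(species = species, plot_id = plot_id,
                   stringsAsFactors = FALSE)
  for (t in tn) df[[t]] <- exp(zvals)
  std <- standardize_traits(df)
  for (t in tn) std$zscore[[t]] <- zvals
  std
}
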