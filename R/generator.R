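#' Default configuration for the synthetic forest-inventory generator
#'
#' Builds the configuration list consumed by [generate_forest()]. The
#' defaults emulate the statistical structure of a filtered global
#' forest-inventory compilation: plot sizes log-normal with mean about
#' 0.07 ha truncated to 0.02--2 ha, censuses from 1990 on, forest ages of
#' 25 years and older, biome-structured richness (speciose tropics,
#' species-poor boreal), log-series regional species pools, a gymnosperm
#' occupancy advantage below 4 degrees C and above a water-availability
#' index of 1.8, weakly negatively correlated temperature and
#' water-availability fields (target Spearman rho -0.09), and
#' climate-dependent intraspecific trait variation.
#'
#' Species log-traits are built from two latent axes -- a stem-strategy
#' axis separating the gymnosperm syndrome (narrow conduits, thick bark,
#' low SLA) from the angiosperm syndrome, and a leaf-economics axis --
#' plus independent residuals, so that a PCA over the ten traits recovers
#' the two-axis structure by construction.
#'
#' The trait--dominance coupling `coupling` is the generator's synthesis
#' knob: per trait, a log-abundance multiplier
#' `beta(mat, wai) = b0 + bt*mat + btt*mat^2 + bw*wai + bww*wai^2`
#' applied to a species' standardized baseline trait when sampling the
#' community, so `beta = 0` for every trait reproduces a neutral forest
#' with no trait--dominance link. Defaults give dominants a modest
#' climate-independent advantage in height, wood density and seed mass.
#'
#' @param n_plots Named integer vector of plots per biome (names from
#'   [biome_levels()]); unnamed scalar recycles over all six biomes.
#' @param n_total Alternative to `n_plots`: total plot count, allocated
#'   over biomes in the default proportions.
#' @param rho Target rank correlation between temperature and water
#'   availability within each biome.
#' @param coupling Named list of per-trait coefficient lists
#'   `list(b0, bt, btt, bw, bww)`; missing traits mean no coupling.
#' @param stem_density Expected stems per hectare used to set plot totals.
#' @param richness_mean Optional named vector overriding per-biome mean
#'   species richness.
#' @param intraspecific_sd Residual s.d. of the plot-level trait deviation
#'   on the log scale.
#' @param plot_size_mean Median plot area in hectares of the log-normal
#'   plot-size law (default 0.055, giving a truncated mean of about
#'   0.07 ha).
#' @param assembly_sd S.d. (natural-log scale) of the per-plot,
#'   per-species lognormal multiplier on sampling weights. This models
#'   compositional turnover between plots -- dispersal, microhabitat and
#'   assembly stochasticity -- so that different species dominate
#'   different plots of the same biome; without it the same few
#'   high-weight pool species would dominate every plot and their
#'   particular trait draws would masquerade as a trait--dominance
#'   signal.
#' @param biome_overrides Named list (by biome) of named lists overriding
#'   that biome's law columns, e.g.
#'   `list(temperate = list(mat_lo = -10, mat_hi = 30, gym_frac = 0))`.
#' @param neutral If TRUE, switch off every trait--dominance link: the
#'   coupling is emptied and the gymnosperm occupancy curve flattened, so
#'   species identity is exchangeable with respect to traits and the
#'   dominant and rare groups differ only by sampling noise.
#' @return A `forest_config` list.
#' @export
forest_config <- function(n_plots = NULL, n_total = NULL, rho = -0.09,
                          coupling = NULL, stem_density = 600,
                          richness_mean = NULL, intraspecific_sd = 0.10,
                          plot_size_mean = 0.055, assembly_sd = 1.5,
                          biome_overrides = NULL, neutral = FALSE) {
  biomes <- data.frame(
    biome = biome_levels(),
    n_plots = c(150L, 100L, 30L, 250L, 120L, 150L),
    mat_lo = c(20, 20, 15, 5, 0, -10),
    mat_hi = c(28, 30, 25, 16, 12, 2),
    wai_lo = c(1.0, 0.2, 0.8, 0.8, 0.75, 0.65),
    wai_hi = c(3.5, 1.05, 2.0, 2.0, 2.9, 2.4),
    richness_mean = c(24, 14, 10, 11, 9, 8),
    pool_size = c(400L, 200L, 80L, 250L, 100L, 50L),
    logseries_x = c(0.995, 0.99, 0.97, 0.99, 0.97, 0.95),
    gym_frac = c(0.05, 0.05, 0.35, 0.15, 0.50, 0.50),
    stringsAsFactors = FALSE)
  if (!is.null(n_total)) {
    if (!is.null(n_plots))
      stop_domrare("give n_plots or n_total, not both",
                   "domrare_config_error")
    biomes$n_plots <- as.integer(round(
      biomes$n_plots * n_total / sum(biomes$n_plots)))
  }
  if (!is.null(n_plots)) {
    if (is.null(names(n_plots))) {
      biomes$n_plots <- rep_len(as.integer(n_plots), nrow(biomes))
    } else {
      idx <- match(names(n_plots), biomes$biome)
      if (anyNA(idx))
        stop_domrare("n_plots names must be biome labels",
                     "domrare_config_error")
      biomes$n_plots[idx] <- as.integer(n_plots)
      biomes$n_plots[-idx] <- 0L
    }
  }
  if (!is.null(richness_mean)) {
    idx <- match(names(richness_mean), biomes$biome)
    if (anyNA(idx))
      stop_domrare("richness_mean names must be biome labels",
                   "domrare_config_error")
    biomes$richness_mean[idx] <- as.numeric(richness_mean)
  }
  if (!is.null(biome_overrides)) {
    bad <- setdiff(names(biome_overrides), biomes$biome)
    if (length(bad))
      stop_domrare(paste0("biome_overrides names unknown biome(s): ",
                          paste(bad, collapse = ", ")),
                   "domrare_config_error")
    for (b in names(biome_overrides)) {
      ov <- biome_overrides[[b]]
      bad <- setdiff(names(ov), setdiff(names(biomes), "biome"))
      if (length(bad))
        stop_domrare(paste0("unknown biome law field(s): ",
                            paste(bad, collapse = ", ")),
                     "domrare_config_error")
      i <- match(b, biomes$biome)
      for (f in names(ov)) biomes[i, f] <- ov[[f]]
    }
  }
  if (abs(rho) >= 1)
    stop_domrare("|rho| must be < 1", "domrare_config_error")
  if (any(biomes$richness_mean > biomes$pool_size))
    stop_domrare("richness_mean exceeds regional pool size",
                 "domrare_config_error")

  traits <- trait_names()
  mu_angio <- c(height = log(18), rooting_depth = log(3.0), sla = log(15),
                conduit_diameter = log(60), crown_diameter = log(6),
                wood_density = log(0.55), bark_thickness = log(5),
                leaf_n = log(20), leaf_np = log(14), seed_mass = log(50))
  mu_gymno <- c(height = log(20), rooting_depth = log(2.5), sla = log(6),
                conduit_diameter = log(12), crown_diameter = log(4.5),
                wood_density = log(0.45), bark_thickness = log(9),
                leaf_n = log(12), leaf_np = log(16), seed_mass = log(20))
  # latent axis 1: stem strategy (high = gymnosperm syndrome)
  l1 <- c(height = 0.10, rooting_depth = 0.08, sla = -0.15,
          conduit_diameter = -0.40, crown_diameter = 0.08,
          wood_density = -0.12, bark_thickness = 0.30,
          leaf_n = -0.12, leaf_np = 0.06, seed_mass = 0.00)
  # latent axis 2: leaf economics (high = acquisitive)
  l2 <- c(height = -0.05, rooting_depth = 0.00, sla = 0.30,
          conduit_diameter = 0.05, crown_diameter = 0.05,
          wood_density = -0.20, bark_thickness = -0.05,
          leaf_n = 0.30, leaf_np = -0.15, seed_mass = -0.25)
  # intraspecific plasticity per 10 degC of temperature / per WAI unit
  p_t <- c(height = 0.05, rooting_depth = 0.35, sla = 0.05,
           conduit_diameter = 0.10, crown_diameter = 0.03,
           wood_density = 0.02, bark_thickness = 0.00,
           leaf_n = -0.02, leaf_np = 0.02, seed_mass = 0.05)
  p_w <- c(height = 0.05, rooting_depth = -0.05, sla = 0.05,
           conduit_diameter = 0.05, crown_diameter = 0.02,
           wood_density = -0.02, bark_thickness = 0.00,
           leaf_n = 0.02, leaf_np = -0.02, seed_mass = 0.02)
  stopifnot(identical(names(mu_angio), traits))

  # dominants are taller where climate is benign (hump-shaped in
  # temperature), deeper-rooted toward warm climates, and modestly
  # denser-wooded and heavier-seeded everywhere
  default_coupling <- list(
    height = quadratic_temperature_coupling(c(5, 25), 0.5),
    rooting_depth = list(bt = 0.02),
    wood_density = list(b0 = 0.10),
    seed_mass = list(b0 = 0.10))
  coupling <- coupling %||% default_coupling
  if (neutral) coupling <- list()
  coupling <- normalize_coupling(coupling)
  occ_strength <- if (neutral) c(k_t = 0, k_w = 0) else
    c(k_t = 1.0, k_w = 0.5)

  structure(list(
    biomes = biomes, rho = rho, coupling = coupling,
    stem_density = stem_density, assembly_sd = assembly_sd,
    trait_model = list(mu_angio = mu_angio, mu_gymno = mu_gymno,
                       l1 = l1, l2 = l2, p_t = p_t, p_w = p_w,
                       latent_sd = 1, species_resid_sd = 0.20,
                       gym_axis_shift = 2.0,
                       intraspecific_sd = intraspecific_sd),
    gym_occupancy = list(mat_mid = 4, mat_scale = 5,
                         wai_mid = 1.8, wai_scale = 0.5,
                         k_t = unname(occ_strength["k_t"]),
                         k_w = unname(occ_strength["k_w"])),
    plot_size = list(meanlog = log(plot_size_mean), sdlog = 0.60,
                     min_ha = 0.02, max_ha = 2),
    age = list(min_yr = 25, shape = 2, scale = 14),
    year = list(min = 1990, max = 2015)
  ), class = "forest_config")
}

normalize_coupling <- function(coupling) {
  if (!length(coupling)) return(list())
  bad <- setdiff(names(coupling), trait_names())
  if (length(bad))
    stop_domrare(paste0("coupling names unknown trait(s): ",
                        paste(bad, collapse = ", ")),
                 "domrare_config_error")
  lapply(coupling, function(b) {
    full <- list(b0 = 0, bt = 0, btt = 0, bw = 0, bww = 0)
    full[names(b)] <- b
    full
  })
}

#' Quadratic-in-temperature coupling from its roots and peak
#'
#' Convenience constructor for a coupling term
#' `beta(mat) = peak * (mat - r1) * (r2 - mat) / ((v - r1) * (r2 - v))`
#' with `v = (r1 + r2) / 2`, i.e. a downward parabola crossing zero at the
#' two stated temperatures and reaching `peak` at the vertex midway.
#'
#' @param roots Length-2 numeric, zero crossings in degrees C.
#' @param peak Coupling strength at the vertex.
#' @return A coefficient list usable inside `coupling`.
#' @export
quadratic_temperature_coupling <- function(roots = c(5, 25), peak = 0.3) {
  r1 <- min(roots); r2 <- max(roots)
  v <- (r1 + r2) / 2
  a <- peak / ((v - r1) * (r2 - v))
  # peak*(x-r1)(r2-x)/norm = -a x^2 + a (r1+r2) x - a r1 r2
  list(b0 = -a * r1 * r2, bt = a * (r1 + r2), btt = -a)
}

coupling_beta <- function(coef, mat, wai) {
  coef$b0 + coef$bt * mat + coef$btt * mat^2 +
    coef$bw * wai + coef$bww * wai^2
}

build_pool <- function(cfg, brow, seed) {
  set.seed(seed)
  J <- brow$pool_size
  tm <- cfg$trait_model
  abbrev <- paste0(substr(strsplit(brow$biome, "_")[[1]], 1, 2),
                   collapse = "")
  species <- sprintf("%s_sp%04d", abbrev, seq_len(J))
  division <- ifelse(stats::runif(J) < brow$gym_frac,
                     "gymnosperm", "angiosperm")
  w <- brow$logseries_x ^ seq_len(J) / seq_len(J)
  w <- w / sum(w)
  f1 <- stats::rnorm(J, sd = tm$latent_sd) +
    ifelse(division == "gymnosperm", tm$gym_axis_shift, 0)
  f2 <- stats::rnorm(J, sd = tm$latent_sd)
  traits <- trait_names()
  mu <- rbind(angiosperm = tm$mu_angio, gymnosperm = tm$mu_gymno)
  base <- mu[division, , drop = FALSE] +
    outer(f1, tm$l1) + outer(f2, tm$l2) +
    matrix(stats::rnorm(J * length(traits), sd = tm$species_resid_sd),
           J, length(traits))
  dimnames(base) <- list(species, traits)
  # pool-standardized baselines drive the dominance coupling
  zbase <- scale(base)
  list(species = species, division = division, weight = w,
       base = base, zbase = zbase[, , drop = FALSE],
       f1 = f1, f2 = f2)
}

#' Generate a synthetic forest-inventory dataset
#'
#' Draws plots, communities and species-by-plot trait values under a
#' [forest_config()]. Per plot: climate comes from the biome's law (a
#' Gaussian copula links temperature and water availability at the
#' configured rank correlation); species are drawn without replacement
#' from the biome's log-series regional pool with sampling weights
#' multiplied by the gymnosperm occupancy curve and by
#' `exp(sum_trait beta(mat, wai) * z_trait)`; stems follow a weighted
#' multinomial over a plot total proportional to area times stem density;
#' and each selected species' trait values are its baseline plus
#' climate-dependent plasticity plus noise.
#'
#' All randomness derives from `seed` through per-plot sub-streams, so a
#' given (config, seed) pair is byte-reproducible.
#'
#' @param config A [forest_config()].
#' @param seed Integer master seed.
#' @return A list with `plots`, `trees`, `traits` data frames and a
#'   `truth` record of the generating parameters.
#' @export
generate_forest <- function(config = forest_config(), seed = 1) {
  stopifnot(inherits(config, "forest_config"))
  seed <- as.integer(seed)
  biomes <- config$biomes[config$biomes$n_plots > 0, , drop = FALSE]
  pools <- lapply(seq_len(nrow(biomes)), function(i)
    build_pool(config, biomes[i, ], derive_seed(seed, i)))
  names(pools) <- biomes$biome

  plot_rows <- vector("list", sum(biomes$n_plots))
  tree_rows <- vector("list", sum(biomes$n_plots))
  trait_rows <- vector("list", sum(biomes$n_plots))
  tm <- config$trait_model
  gp <- config$gym_occupancy
  rho <- config$rho
  gidx <- 0L

  for (bi in seq_len(nrow(biomes))) {
    brow <- biomes[bi, ]
    pool <- pools[[bi]]
    beta_traits <- names(config$coupling)
    zb <- if (length(beta_traits))
      pool$zbase[, beta_traits, drop = FALSE] else NULL
    for (pi in seq_len(brow$n_plots)) {
      gidx <- gidx + 1L
      set.seed(derive_seed(seed, 1000L + gidx))
      plot_id <- sprintf("plot_%05d", gidx)

      # climate: Gaussian copula at the target rank correlation
      z1 <- stats::rnorm(1)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
      mat <- brow$mat_lo + (brow$mat_hi - brow$mat_lo) * stats::pnorm(z1)
      wai <- brow$wai_lo + (brow$wai_hi - brow$wai_lo) * stats::pnorm(z2)

      ps <- config$plot_size
      u <- stats::runif(1, stats::plnorm(ps$min_ha, ps$meanlog, ps$sdlog),
                        stats::plnorm(ps$max_ha, ps$meanlog, ps$sdlog))
      area <- stats::qlnorm(u, ps$meanlog, ps$sdlog)
      year <- sample(config$year$min:config$year$max, 1)
      age <- config$age$min_yr +
        stats::rgamma(1, shape = config$age$shape, scale = config$age$scale)
      elev <- stats::rgamma(1, shape = 1.5, scale = 300)
      lat <- switch(brow$biome,
                    tropical_moist = stats::runif(1, -15, 15),
                    tropical_dry = stats::runif(1, -20, 20),
                    tropical_conifer = stats::runif(1, 10, 25),
                    temperate = stats::runif(1, 35, 50),
                    temperate_conifer = stats::runif(1, 40, 55),
                    boreal = stats::runif(1, 50, 65))
      lon <- stats::runif(1, -180, 180)

      # community: log-series local abundance structure, allocated to
      # species by lottery (arrival-order/priority effects), then tilted
      # by the occupancy curve and the trait coupling. The lottery makes
      # local dominance identity exchangeable with respect to traits, so
      # a zero coupling really carries no trait--dominance signal.
      w <- sample(pool$weight)
      if (config$assembly_sd > 0)
        w <- w * exp(stats::rnorm(length(w), sd = config$assembly_sd))
      gym <- pool$division == "gymnosperm"
      if (any(gym)) {
        mult <- exp(gp$k_t * (gp$mat_mid - mat) / gp$mat_scale +
                      gp$k_w * (wai - gp$wai_mid) / gp$wai_scale)
        w[gym] <- w[gym] * mult
      }
      if (!is.null(zb)) {
        betas <- vapply(config$coupling, coupling_beta, numeric(1),
                        mat = mat, wai = wai)
        w <- w * exp(drop(zb %*% betas))
      }
      n_stems <- max(1L, stats::rpois(1, area * config$stem_density))
      S <- min(max(2L, stats::rpois(1, brow$richness_mean)),
               length(pool$species), n_stems)
      sel <- sample.int(length(pool$species), S, prob = w)
      extra <- if (n_stems > S)
        stats::rmultinom(1, n_stems - S, prob = w[sel])[, 1]
      else integer(S)
      stems <- 1L + extra

      plot_rows[[gidx]] <- list(plot_id = plot_id, lat = lat, lon = lon,
                                area_ha = area, year = year, age = age,
                                elevation_m = elev, biome = brow$biome,
                                mat_c = mat, wai = wai)
      tree_rows[[gidx]] <- list(plot_id = rep(plot_id, S),
                                species = pool$species[sel],
                                stems = as.integer(stems),
                                division = pool$division[sel])
      tv <- pool$base[sel, , drop = FALSE] +
        outer(rep(1, S), tm$p_t) * (mat - 15) / 10 +
        outer(rep(1, S), tm$p_w) * (wai - 1.5) +
        matrix(stats::rnorm(S * 10, sd = tm$intraspecific_sd), S, 10)
      trait_rows[[gidx]] <- list(species = pool$species[sel],
                                 plot_id = rep(plot_id, S),
                                 values = exp(tv),
                                 division = pool$division[sel])
    }
  }

  plots <- do.call(rbind, lapply(plot_rows, as.data.frame))
  trees <- data.frame(
    plot_id = unlist(lapply(tree_rows, `[[`, "plot_id")),
    species = unlist(lapply(tree_rows, `[[`, "species")),
    stems = unlist(lapply(tree_rows, `[[`, "stems")),
    division = unlist(lapply(tree_rows, `[[`, "division")),
    stringsAsFactors = FALSE)
  vals <- do.call(rbind, lapply(trait_rows, `[[`, "values"))
  traits <- data.frame(
    species = unlist(lapply(trait_rows, `[[`, "species")),
    plot_id = unlist(lapply(trait_rows, `[[`, "plot_id")),
    vals,
    division = unlist(lapply(trait_rows, `[[`, "division")),
    stringsAsFactors = FALSE, row.names = NULL)
  truth <- list(seed = seed, coupling = config$coupling,
                rho = config$rho,
                trait_model = config$trait_model,
                gym_occupancy = config$gym_occupancy,
                pools = lapply(pools, function(p)
                  list(species = p$species, division = p$division,
                       f1 = p$f1, f2 = p$f2)))
  list(plots = plots, trees = trees, traits = traits, truth = truth)
}

#' Summarize the realism of a generated dataset
#'
#' Reports the realized plot-size mean, per-biome species richness,
#' gymnosperm stem share against temperature and water availability, and
#' the shape of the pooled rank-abundance curve (mean within-plot stem
#' share of the most abundant species and of the rarest species). Used to
#' validate generator defaults against the structure they emulate.
#'
#' @param dataset A list with `plots` and `trees`, e.g. from
#'   [generate_forest()].
#' @return A list with `plot_size`, `richness`, `gymnosperm`, and
#'   `rank_abundance` summaries; all empty when the dataset is empty.
#' @export
summarize_realism <- function(dataset) {
  plots <- dataset$plots; trees <- dataset$trees
  if (is.null(plots) || !nrow(plots)) {
    return(list(plot_size = numeric(0),
                richness = data.frame(),
                gymnosperm = data.frame(),
                rank_abundance = data.frame()))
  }
  rich <- tapply(trees$species, trees$plot_id, function(s) length(unique(s)))
  rich_df <- data.frame(plot_id = names(rich),
                        richness = as.vector(rich),
                        stringsAsFactors = FALSE)
  rich_df$biome <- plots$biome[match(rich_df$plot_id, plots$plot_id)]
  rich_by_biome <- stats::aggregate(richness ~ biome, rich_df, mean)

  gym_stems <- tapply(trees$stems * (trees$division == "gymnosperm"),
                      trees$plot_id, sum)
  tot_stems <- tapply(trees$stems, trees$plot_id, sum)
  gdf <- data.frame(plot_id = names(tot_stems),
                    gym_share = as.vector(gym_stems) / as.vector(tot_stems),
                    stringsAsFactors = FALSE)
  m <- match(gdf$plot_id, plots$plot_id)
  gdf$biome <- plots$biome[m]; gdf$mat_c <- plots$mat_c[m]
  gdf$wai <- plots$wai[m]
  gym_by_biome <- stats::aggregate(gym_share ~ biome, gdf, mean)

  shares <- tapply(seq_len(nrow(trees)), trees$plot_id, function(ix) {
    s <- trees$stems[ix]
    c(top = max(s), bottom = min(s)) / sum(s)
  })
  sh <- do.call(rbind, shares)
  list(
    plot_size = c(mean = mean(plots$area_ha),
                  min = min(plots$area_ha), max = max(plots$area_ha)),
    richness = rich_by_biome,
    gymnosperm = gym_by_biome,
    gymnosperm_plots = gdf,
    rank_abundance = data.frame(mean_top_share = mean(sh[, "top"]),
                                mean_bottom_share = mean(sh[, "bottom"]))
  )
}
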