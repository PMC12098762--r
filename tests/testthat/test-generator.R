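test_that("generation is deterministic given seed and config", {
  cfg <- forest_config(n_plots = 30)
  g1 <- generate_forest(cfg, seed = 9)
  g2 <- generate_forest(cfg, seed = 9)
  expect_identical(g1$plots, g2$plots)
  expect_identical(g1$trees, g2$trees)
  expect_identical(g1$traits, g2$traits)
  g3 <- generate_forest(cfg, seed = 10)
  expect_false(identical(g1$trees, g3$trees))
})

test_that("generated data satisfy the interchange invariants", {
  g <- generate_forest(forest_config(n_plots = 25), seed = 14)
  expect_silent(validate_plots <- read_forest_tables(
    write_forest_tables(g, file.path(tempdir(), "genio"))))
  expect_true(all(g$trees$stems >= 1))
  expect_true(all(g$plots$area_ha >= 0.02 & g$plots$area_ha <= 2))
  expect_true(all(g$plots$year >= 1990))
  expect_true(all(g$plots$age >= 25))
  expect_true(all(g$traits[, trait_names()] > 0))
})

test_that("realized structure matches the emulated inventory", {
  g <- generate_forest(forest_config(), seed = 15)
  s <- summarize_realism(g)
  expect_gt(s$plot_size["mean"], 0.05)
  expect_lt(s$plot_size["mean"], 0.09)
  rich <- setNames(s$richness$richness, s$richness$biome)
  expect_gt(rich["tropical_moist"], rich["boreal"])
  gym <- setNames(s$gymnosperm$gym_share, s$gymnosperm$biome)
  expect_gt(gym["boreal"], gym["tropical_moist"])
  expect_gt(s$rank_abundance$mean_top_share,
            s$rank_abundance$mean_bottom_share)

  empty <- summarize_realism(list(plots = data.frame(),
                                  trees = data.frame()))
  expect_equal(nrow(empty$richness), 0)
})

test_that("temperature and water availability are weakly negatively correlated", {
  g <- generate_forest(forest_config(n_total = 5000), seed = 16)
  r <- cor(g$plots$mat_c, g$plots$wai, method = "spearman")
  expect_lt(abs(r - (-0.09)), 0.05)
})

test_that("config validation rejects impossible settings", {
  expect_error(forest_config(rho = 1.2), class = "domrare_config_error")
  expect_error(forest_config(richness_mean = c(boreal = 500)),
               class = "domrare_config_error")
  expect_error(forest_config(coupling = list(nope = list(b0 = 1))),
               class = "domrare_config_error")
  expect_error(forest_config(biome_overrides = list(alpine = list())),
               class = "domrare_config_error")
  expect_error(forest_config(n_plots = 10, n_total = 100),
               class = "domrare_config_error")
})

test_that("quadratic coupling constructor hits its stated roots and peak", {
  co <- quadratic_temperature_coupling(c(5, 25), 0.3)
  beta <- function(m) co$b0 + co$bt * m + co$btt * m^2
  expect_equal(beta(5), 0, tolerance = 1e-12)
  expect_equal(beta(25), 0, tolerance = 1e-12)
  expect_equal(beta(15), 0.3, tolerance = 1e-12)
})

mean_height_D <- function(b0, seed) {
  cfg <- forest_config(n_plots = c(temperate = 300),
                       coupling = if (b0 == 0) list() else
                         list(height = list(b0 = b0)))
  g <- generate_forest(cfg, seed = seed)
  filt <- apply_filters(g$plots, g$trees)
  trees_f <- g$trees[g$trees$plot_id %in% filt$plots$plot_id, ]
  dset <- classify_all(trees_f, plots = filt$plots)
  std <- standardize_traits(g$traits)
  ctr <- plot_contrasts(std, dset, filt$plots, trees_f, pca = FALSE)
  mean(ctr$D_height, na.rm = TRUE)
}

test_that("the trait-dominance coupling is monotone on a three-point grid", {
  d <- vapply(c(0, 0.5, 1.2), mean_height_D, numeric(1), seed = 17)
  expect_true(all(diff(d) > 0))
  expect_lt(abs(d[1]), 0.25)   # neutral grid point stays near zero
  expect_gt(d[3], 0.2)         # strong coupling forces a positive contrast
})

test_that("neutral communities have exchangeable dominant and rare traits", {
  # permutation check: the observed mean contrast sits inside the
  # label-permutation distribution
  cfg <- forest_config(n_plots = c(temperate = 150), neutral = TRUE)
  g <- generate_forest(cfg, seed = 18)
  filt <- apply_filters(g$plots, g$trees)
  trees_f <- g$trees[g$trees$plot_id %in% filt$plots$plot_id, ]
  dset <- classify_all(trees_f, plots = filt$plots)
  std <- standardize_traits(g$traits)
  ctr <- plot_contrasts(std, dset, filt$plots, trees_f, pca = FALSE)
  obs <- mean(ctr$D_height, na.rm = TRUE)
  set.seed(19)
  perm <- replicate(200, {
    flip <- sample(c(-1, 1), nrow(ctr), replace = TRUE)
    mean(flip * ctr$D_height, na.rm = TRUE)
  })
  expect_gt(mean(abs(perm) >= abs(obs)), 0.01)
})
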