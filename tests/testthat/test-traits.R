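mk_traits <- function(vals, species = paste0("s", seq_along(vals)),
                      plot_id = NULL) {
  df <- data.frame(species = species, stringsAsFactors = FALSE)
  if (!is.null(plot_id)) df$plot_id <- plot_id
  for (tn in trait_names()) df[[tn]] <- vals
  df$division <- "angiosperm"
  df
}

test_that("log/z-score standardization matches hand-computed constants", {
  std <- standardize_traits(mk_traits(c(exp(-1), 1, exp(1))))
  expect_equal(std$constants$mean, rep(0, 10))
  expect_equal(std$constants$sd, rep(1, 10))
  expect_equal(std$zscore$height, c(-1, 0, 1))
  expect_equal(std$log$height, c(-1, 0, 1))

  std2 <- standardize_traits(mk_traits(c(1, exp(2))))
  want <- as.vector(scale(c(0, 2)))
  expect_equal(std2$zscore$sla, want)

  # z-layer has mean 0, sd 1 over the population
  set.seed(41)
  std3 <- standardize_traits(mk_traits(exp(rnorm(40, 1, 0.7))))
  expect_equal(mean(std3$zscore$leaf_n), 0, tolerance = 1e-12)
  expect_equal(sd(std3$zscore$leaf_n), 1, tolerance = 1e-12)
})

test_that("degenerate trait inputs raise typed validation errors", {
  bad <- mk_traits(c(1, 2, 3))
  bad$sla[2] <- -1
  err <- tryCatch(standardize_traits(bad), error = identity)
  expect_s3_class(err, "domrare_validation_error")
  expect_match(conditionMessage(err), "sla")
  expect_match(conditionMessage(err), "s2")

  expect_error(standardize_traits(mk_traits(rep(2, 5))),
               class = "domrare_validation_error")
})

mk_assignment <- function(dom, rare, plot = "p1") {
  structure(list(plot_id = plot, dominant_set = dom, rare_set = rare,
                 k_dom = length(dom), k_rare = length(rare),
                 excluded = FALSE, exclusion_reason = "none"),
            class = "dominance_assignment")
}

test_that("group medians aggregate z-values robustly", {
  std <- std_from_z(c(0.1, 0.3, -0.7, -1, 0, 5),
                    species = paste0("s", 1:6), plot_id = "p1")
  a <- mk_assignment(c("s1", "s2"), c("s3"))
  expect_equal(group_median(std, a, "dominant", "height"), 0.2)
  expect_equal(group_median(std, a, "rare", "height"), -0.7)
  a2 <- mk_assignment(c("s4", "s5", "s6"), c("s3"))
  expect_equal(group_median(std, a2, "dominant", "sla"), 0)
  # duplicating every member leaves the median unchanged
  a3 <- mk_assignment(rep(c("s4", "s5", "s6"), 2), c("s3"))
  expect_equal(group_median(std, a3, "dominant", "sla"), 0)
  expect_error(group_median(std, mk_assignment(character(0), "s3"),
                            "dominant", "sla"),
               class = "domrare_parameter_error")
})

test_that("genus-level trees fall back to the congeneric mean", {
  df <- rbind(mk_traits(c(exp(1), exp(3), exp(0.5)),
                        species = c("Picea abies", "Picea glauca",
                                    "Abies alba"),
                        plot_id = NA_character_),
              mk_traits(c(exp(2), exp(0.2)),
                        species = c("Fagus sylvatica", "Quercus robur"),
                        plot_id = "p1"))
  std <- standardize_traits(df)
  a <- mk_assignment(c("Picea", "Fagus sylvatica"), c("Quercus robur"))
  zs <- std$zscore
  picea_mean <- mean(zs$height[zs$species %in% c("Picea abies",
                                                 "Picea glauca")])
  fagus <- zs$height[zs$species == "Fagus sylvatica"]
  expect_equal(group_median(std, a, "dominant", "height"),
               median(c(picea_mean, fagus)))
})

contrast_fixture <- function(seed = 3, n_plots = 60) {
  g <- generate_forest(forest_config(n_plots = ceiling(n_plots / 6)),
                       seed = seed)
  filt <- apply_filters(g$plots, g$trees)
  trees_f <- g$trees[g$trees$plot_id %in% filt$plots$plot_id, ]
  dset <- classify_all(trees_f, plots = filt$plots)
  std <- standardize_traits(g$traits)
  list(g = g, filt = filt, trees = trees_f, dset = dset, std = std)
}

test_that("contrasts equal dominant minus rare medians and obey antisymmetry", {
  fx <- contrast_fixture()
  ctr <- plot_contrasts(fx$std, fx$dset, fx$filt$plots, fx$trees,
                        pca = FALSE)
  expect_true(nrow(ctr) > 20)
  for (tn in c("height", "sla", "seed_mass")) {
    expect_equal(ctr[[paste0("D_", tn)]],
                 ctr[[paste0("dom_", tn)]] - ctr[[paste0("rare_", tn)]])
  }
  expect_true(all(ctr$gym_pct_dom >= 0 & ctr$gym_pct_dom <= 100,
                  na.rm = TRUE))
  # independent recomputation of one plot via group_median
  pid <- ctr$plot_id[5]
  a <- fx$dset$assignments[[pid]]
  expect_equal(ctr$dom_height[5],
               group_median(fx$std, a, "dominant", "height"))
  expect_equal(ctr$rare_wood_density[5],
               group_median(fx$std, a, "rare", "wood_density"))

  # swapping the group labels negates every D exactly
  swapped <- fx$dset
  swapped$assignments <- lapply(swapped$assignments, function(a) {
    if (a$excluded) return(a)
    tmp <- a$dominant_set
    a$dominant_set <- a$rare_set; a$rare_set <- tmp
    k <- a$k_dom; a$k_dom <- a$k_rare; a$k_rare <- k
    a
  })
  ctr2 <- plot_contrasts(fx$std, swapped, fx$filt$plots, fx$trees,
                         pca = FALSE)
  for (tn in trait_names())
    expect_equal(ctr2[[paste0("D_", tn)]], -ctr[[paste0("D_", tn)]])
})

test_that("contrasts are invariant to rescaling a raw trait", {
  fx <- contrast_fixture(seed = 4)
  ctr <- plot_contrasts(fx$std, fx$dset, fx$filt$plots, fx$trees,
                        pca = FALSE)
  traits2 <- fx$g$traits
  traits2$height <- traits2$height * 7.3
  std2 <- standardize_traits(traits2)
  ctr2 <- plot_contrasts(std2, fx$dset, fx$filt$plots, fx$trees,
                         pca = FALSE)
  expect_equal(ctr2$D_height, ctr$D_height, tolerance = 1e-10)
})

test_that("biome mean absolute difference pools |D| over traits and plots", {
  ctr <- data.frame(biome = c("boreal", "boreal", "temperate"))
  for (tn in trait_names()) ctr[[paste0("D_", tn)]] <- 0
  expect_equal(biome_mean_absolute_difference(ctr, "boreal"), 0)
  ctr$D_height <- c(0.2, -0.2, 1)
  expect_equal(biome_mean_absolute_difference(ctr, "boreal"),
               mean(c(abs(c(0.2, -0.2)), rep(0, 18))))
  expect_true(is.na(biome_mean_absolute_difference(ctr, "tropical_dry")))
})
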