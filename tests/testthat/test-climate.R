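test_that("correlations reproduce the t statistic formula and cor.test", {
  set.seed(81)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  got <- trait_climate_correlation(x, y)
  expect_equal(got$t, got$r * sqrt(48) / sqrt(1 - got$r^2))
  ref <- cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  lin <- trait_climate_correlation(1:20, 2 * (1:20) + 3)
  expect_equal(lin$r, 1)

  # rank correlation is invariant under monotone transforms
  sp <- trait_climate_correlation(x, exp(y), method = "spearman")
  expect_equal(sp$r, unname(cor(x, y, method = "spearman")))
  expect_error(trait_climate_correlation(rep(1, 10), rnorm(10)),
               class = "domrare_validation_error")
})

test_that("permuting one variable destroys the correlation", {
  set.seed(82)
  x <- rnorm(2000); y <- 0.8 * x + rnorm(2000)
  expect_gt(trait_climate_correlation(x, y)$r, 0.5)
  expect_lt(abs(trait_climate_correlation(x, sample(y))$r), 0.08)
})

test_that("LMG shares sum to R^2 and match closed forms", {
  set.seed(83)
  n <- 120
  # one group: share equals the full R^2
  x1 <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- x1 %*% c(1, -1) + rnorm(n)
  sh <- lmg_importance(x1, y, list(all = c("a", "b")))
  expect_equal(unname(sh["all"]), attr(sh, "r_squared"), tolerance = 1e-12)

  # two exactly orthogonal single-regressor groups: marginal R^2 each
  a <- rnorm(n); a <- a - mean(a)
  b <- rnorm(n); b <- residuals(lm(b ~ a)); b <- b / sd(b)
  x2 <- cbind(a = a, b = b)
  y2 <- 2 * a + b + rnorm(n)
  sh2 <- lmg_importance(x2, y2, list(A = "a", B = "b"))
  r2a <- summary(lm(y2 ~ a))$r.squared
  r2b <- summary(lm(y2 ~ b))$r.squared
  expect_equal(unname(sh2["A"]), r2a, tolerance = 1e-10)
  expect_equal(unname(sh2["B"]), r2b, tolerance = 1e-10)
})

test_that("LMG equals the factorial-ordering oracle and is order-invariant", {
  set.seed(84)
  for (i in 1:5) {
    n <- 80
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("v", 1:5)))
    y <- x %*% rnorm(5) + rnorm(n)
    groups <- list(g1 = c("v1", "v2"), g2 = "v3", g3 = c("v4", "v5"))
    sh <- lmg_importance(x, y, groups)
    want <- oracle_lmg(x, y, groups)
    expect_equal(as.vector(sh), as.vector(want), tolerance = 1e-10)
    expect_equal(sum(sh), attr(sh, "r_squared"), tolerance = 1e-12)
    expect_true(all(sh >= -1e-12))
    sh_perm <- lmg_importance(x, y, groups[c(3, 1, 2)])
    expect_equal(sh_perm[names(sh)], sh, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_error(lmg_importance(matrix(rnorm(40), 20, 2,
                                     dimnames = list(NULL, c("a", "b"))),
                              rnorm(20), list(A = "a")),
               class = "domrare_parameter_error")
})

mk_contrasts <- function(n, dfun, seed = 1, biome = "temperate") {
  set.seed(seed)
  mat <- runif(n, -10, 30); wai <- runif(n, 0.4, 2.5)
  ctr <- data.frame(
    plot_id = sprintf("p%05d", seq_len(n)), biome = biome,
    mat_c = mat, wai = wai, area_ha = runif(n, 0.02, 2),
    age = runif(n, 25, 120), elevation_m = runif(n, 0, 2000),
    stringsAsFactors = FALSE)
  ctr$D_height <- dfun(ctr)
  ctr
}

test_that("constructed quadratic responses recover their geometry", {
  ctr <- mk_contrasts(3000, function(d)
    -(d$mat_c - 5) * (d$mat_c - 25) / 100 + rnorm(nrow(d), sd = 0.01))
  f <- fit_climate_model(ctr, "D_height")
  expect_equal(f$geometry$temperature$roots, c(5, 25), tolerance = 0.05)
  expect_equal(unname(f$geometry$temperature$vertex), 15,
               tolerance = 0.05)
  expect_gt(f$r_squared, 0.95)

  # response exactly z_t: standardized coefficient 1, R^2 = 1
  ctr2 <- mk_contrasts(500, function(d)
    (d$mat_c - mean(d$mat_c)) / sd(d$mat_c))
  f2 <- fit_climate_model(ctr2, "D_height")
  expect_equal(unname(coef(f2)["t"]), 1, tolerance = 1e-8)
  expect_equal(f2$r_squared, 1, tolerance = 1e-8)
  # other groups can claim small chance shares in orderings where they
  # enter first, but temperature must carry essentially all of R^2
  expect_gt(unname(f2$lmg["temperature"]), 0.95)
  expect_equal(sum(f2$lmg), 1, tolerance = 1e-8)
})

test_that("pure-noise responses carry no importance", {
  ctr <- mk_contrasts(2000, function(d) rnorm(nrow(d)), seed = 7)
  f <- fit_climate_model(ctr, "D_height")
  expect_lt(f$r_squared, 0.02)
  expect_true(all(f$lmg < 0.02))
})

test_that("adding a constant to the response shifts only the intercept", {
  ctr <- mk_contrasts(800, function(d)
    0.3 * d$mat_c + rnorm(nrow(d)), seed = 9)
  f1 <- fit_climate_model(ctr, "D_height")
  ctr$D_height <- ctr$D_height + 5
  f2 <- fit_climate_model(ctr, "D_height")
  cf1 <- coef(f1); cf2 <- coef(f2)
  expect_equal(unname(cf2["(Intercept)"] - cf1["(Intercept)"]), 5,
               tolerance = 1e-10)
  expect_equal(cf1[names(cf1) != "(Intercept)"],
               cf2[names(cf2) != "(Intercept)"], tolerance = 1e-8)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)
})

test_that("model predictions follow the fitted climate surface", {
  ctr <- mk_contrasts(3000, function(d)
    -(d$mat_c - 5) * (d$mat_c - 25) / 100 + rnorm(nrow(d), sd = 0.01))
  f <- fit_climate_model(ctr, "D_height")
  nd <- data.frame(mat_c = c(5, 15, 25), wai = rep(1.4, 3))
  pred <- predict(f, nd)
  expect_equal(pred[2], 1, tolerance = 0.05)
  expect_equal(pred[c(1, 3)], c(0, 0), tolerance = 0.05)
})

test_that("importance comparison reports both t and F forms", {
  same <- compare_importance(1:13 / 13, 1:13 / 13)
  expect_equal(same$t, 0)
  expect_equal(same$F, 1)

  a <- (1:13) / 10; b <- a + 1
  got <- compare_importance(b, a)
  sp2 <- (12 * var(a) + 12 * var(b)) / 24
  t_hand <- (mean(b) - mean(a)) / sqrt(sp2 * 2 / 13)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  ref <- t.test(b, a, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_t, ref$p.value, tolerance = 1e-12)
  refF <- var.test(b, a)
  expect_equal(got$F, unname(refF$statistic), tolerance = 1e-12)
  expect_equal(got$p_F, refF$p.value, tolerance = 1e-12)

  deg <- compare_importance(rep(0.3, 13), (1:13) / 13)
  expect_true(deg$degenerate)
  expect_error(compare_importance(1:5, 1:6),
               class = "domrare_parameter_error")
})
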