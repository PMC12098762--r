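#' Correlation between a trait and a climate variable
#'
#' Pearson (product-moment) or Spearman (rank) correlation with the
#' companion t statistic `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and its
#' two-sided p-value.
#'
#' @param x,y Numeric vectors (pairs with NA dropped).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List: `r`, `t`, `n`, `p_value`, `method`.
#' @export
trait_climate_correlation <- function(x, y,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop_domrare("correlation needs at least 3 pairs",
                 "domrare_parameter_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_domrare("zero variance in correlation input",
                 "domrare_validation_error")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  t <- r * sqrt(n - 2) / sqrt(max(1 - r^2, .Machine$double.eps))
  list(r = r, t = t, n = n,
       p_value = 2 * stats::pt(-abs(t), n - 2), method = method)
}

#' Grouped LMG (Shapley) relative-importance decomposition
#'
#' Decomposes the R-squared of a least-squares fit of `y` on the columns
#' of `x` into non-negative shares per regressor group, by averaging each
#' group's incremental R-squared over all orders in which groups can
#' enter the model (the Shapley value of R-squared). Shares sum to the
#' full-model R-squared.
#'
#' @param x Numeric design matrix (no intercept column; one is added).
#' @param y Response vector.
#' @param groups Named list mapping group names to column names (or
#'   indices) of `x`; together they must cover every column exactly once.
#' @return Named numeric vector of shares with attribute `r_squared`
#'   (full model).
#' @export
lmg_importance <- function(x, y, groups) {
  x <- as.matrix(x)
  G <- length(groups)
  if (G < 1) stop_domrare("need at least one group",
                          "domrare_parameter_error")
  if (G > 20) stop_domrare("more than 20 groups: combinatorial guard",
                           "domrare_parameter_error")
  cols <- lapply(groups, function(g)
    if (is.character(g)) match(g, colnames(x)) else as.integer(g))
  if (anyNA(unlist(cols)))
    stop_domrare("group refers to an unknown column",
                 "domrare_parameter_error")
  all_cols <- sort(unname(unlist(cols)))
  if (!identical(all_cols, seq_len(ncol(x))))
    stop_domrare("groups must partition the design matrix columns",
                 "domrare_parameter_error")
  tss <- sum((y - mean(y))^2)
  r2_of <- function(ix) {
    if (!length(ix)) return(0)
    f <- stats::lm.fit(cbind(1, x[, ix, drop = FALSE]), y)
    1 - sum(f$residuals^2) / tss
  }
  nsub <- 2^G
  r2 <- numeric(nsub)              # R^2 by subset bitmask (1-based)
  sizes <- integer(nsub)
  for (mask in 0:(nsub - 1)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, 0:(G - 1))) > 0)
    sizes[mask + 1] <- length(members)
    r2[mask + 1] <- r2_of(unlist(cols[members]))
  }
  wt <- factorial(0:(G - 1)) * factorial(G - 1 - (0:(G - 1))) /
    factorial(G)
  shares <- stats::setNames(numeric(G), names(groups))
  for (g in seq_len(G)) {
    bit <- bitwShiftL(1L, g - 1L)
    for (mask in 0:(nsub - 1)) {
      if (bitwAnd(mask, bit) > 0) next
      s <- sizes[mask + 1]
      shares[g] <- shares[g] +
        wt[s + 1] * (r2[bitwOr(mask, bit) + 1] - r2[mask + 1])
    }
  }
  attr(shares, "r_squared") <- r2[nsub]
  shares
}

#' Second-order polynomial climate-response model for a trait contrast
#'
#' Fits, by least squares, the plot-level dominant-minus-rare contrast of
#' one response as a function of temperature and water availability --
#' both entered linearly and squared, plus their interaction -- while
#' correcting for plot size, forest age, elevation and biome. Continuous
#' predictors are z-scored before squaring (so the quadratic terms are
#' squares of the scaled variables), which makes the displayed
#' coefficients directly comparable. The grouped LMG decomposition
#' ([lmg_importance()]) attributes the model R-squared to temperature
#' (linear + squared), water availability (linear + squared), their
#' interaction, each covariate, and biome as one group.
#'
#' Curve geometry is reported in original climate units: the roots and
#' vertex of the fitted quadratic in each climate variable with the other
#' climate variable at its mean, covariates at their means and biome at
#' its observed mix. A model-selection flag (`delta_aic_water_linear`)
#' reports the AIC difference of the full fit minus a fit with water
#' entered linearly only; positive values mean the linear-water form fits
#' better by AIC.
#'
#' @param contrasts A [plot_contrasts()] table.
#' @param response Column to model, e.g. `"D_height"` or `"D_pc1"`.
#' @param min_ratio Minimum ratio of rows to regressors (default 10).
#' @return Object of class `climate_fit`: standardized `coefficients`,
#'   `r_squared`, `lmg` shares, `importance` (temperature, water,
#'   interaction, in R-squared units), `geometry` (per climate variable:
#'   roots, vertex, curvature), `scaling` constants, `n`,
#'   `delta_aic_water_linear`, and the underlying `lm` fit.
#' @export
fit_climate_model <- function(contrasts, response, min_ratio = 10) {
  need <- c(response, "mat_c", "wai", "area_ha", "age", "elevation_m",
            "biome")
  require_cols(contrasts, need, "contrasts")
  dat <- contrasts[stats::complete.cases(contrasts[, need]), need]
  y <- dat[[response]]
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  scaling <- list(mat = c(mean = mean(dat$mat_c), sd = stats::sd(dat$mat_c)),
                  wai = c(mean = mean(dat$wai), sd = stats::sd(dat$wai)))
  zt <- zs(dat$mat_c); zw <- zs(dat$wai)
  X <- cbind(t = zt, t2 = zt^2, w = zw, w2 = zw^2, t_x_w = zt * zw,
             plot_size = zs(dat$area_ha), forest_age = zs(dat$age),
             elevation = zs(dat$elevation_m))
  groups <- list(temperature = c("t", "t2"), water = c("w", "w2"),
                 interaction = "t_x_w", plot_size = "plot_size",
                 forest_age = "forest_age", elevation = "elevation")
  biomes <- unique(dat$biome)
  if (length(biomes) > 1) {
    ref <- names(sort(table(dat$biome), decreasing = TRUE))[1]
    f <- stats::relevel(factor(dat$biome), ref = ref)
    dm <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(dm) <- paste0("biome_", sub("^f", "", colnames(dm)))
    X <- cbind(X, dm)
    groups$biome <- colnames(dm)
  }
  if (nrow(X) < min_ratio * (ncol(X) + 1))
    stop_domrare(paste0("need at least ", min_ratio,
                        "x as many plots as regressors"),
                 "domrare_parameter_error")
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::lm(y ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    warning("collinear design; dropped term(s): ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / tss
  lmg <- lmg_importance(X, y, groups)
  importance <- c(temperature = unname(lmg["temperature"]),
                  water = unname(lmg["water"]),
                  interaction = unname(lmg["interaction"]))

  cfz <- function(nm) if (nm %in% names(cf) && !is.na(cf[nm]))
    unname(cf[nm]) else 0
  # base level: covariates and the other climate variable at their means
  # (z = 0), biome at its observed mix
  base0 <- cfz("(Intercept)")
  if (length(biomes) > 1)
    base0 <- base0 + sum(colMeans(X[, groups$biome, drop = FALSE]) *
                           vapply(groups$biome, cfz, numeric(1)))
  geom <- list(
    temperature = quad_geometry(cfz("t2"), cfz("t"), base0,
                                scaling$mat["mean"], scaling$mat["sd"]),
    water = quad_geometry(cfz("w2"), cfz("w"), base0,
                          scaling$wai["mean"], scaling$wai["sd"]))

  lin_cols <- setdiff(colnames(X), "w2")
  fit_lin <- stats::lm(y ~ ., data = data.frame(
    y = y, X[, lin_cols, drop = FALSE], check.names = FALSE))
  structure(list(response = response, coefficients = cf,
                 r_squared = r2, lmg = lmg, importance = importance,
                 geometry = geom, scaling = scaling, n = nrow(X),
                 delta_aic_water_linear =
                   stats::AIC(fit) - stats::AIC(fit_lin),
                 groups = groups, lm = fit),
            class = "climate_fit")
}

# roots and vertex of a2 z^2 + a1 z + a0, mapped back to original units
quad_geometry <- function(a2, a1, a0, mu, sd) {
  to_nat <- function(z) unname(mu + sd * z)
  roots <- c(NA_real_, NA_real_)
  if (a2 != 0) {
    disc <- a1^2 - 4 * a2 * a0
    if (disc >= 0) {
      z <- (-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2)
      roots <- sort(to_nat(z))
    }
    vertex <- to_nat(-a1 / (2 * a2))
  } else {
    vertex <- NA_real_
    if (a1 != 0) roots <- c(to_nat(-a0 / a1), NA_real_)
  }
  list(roots = roots, vertex = vertex, curvature = unname(a2))
}

#' @export
print.climate_fit <- function(x, ...) {
  cat("Climate-response model for", x$response,
      "(n =", x$n, ", R^2 =", round(x$r_squared, 3), ")\n")
  cat("LMG importance: temperature",
      round(x$importance["temperature"], 3), "| water",
      round(x$importance["water"], 3), "| interaction",
      round(x$importance["interaction"], 3), "\n")
  g <- x$geometry$temperature
  cat("Temperature curve: roots",
      paste(round(g$roots, 2), collapse = ", "),
      "degC; vertex", round(g$vertex, 2), "degC\n")
  invisible(x)
}

#' @export
coef.climate_fit <- function(object, ...) object$coefficients

#' @export
summary.climate_fit <- function(object, ...) {
  list(response = object$response, n = object$n,
       r_squared = object$r_squared,
       coefficients = summary(object$lm)$coefficients,
       lmg = object$lmg, importance = object$importance,
       geometry = object$geometry,
       delta_aic_water_linear = object$delta_aic_water_linear)
}

#' Predict trait contrasts along the climate surface
#'
#' Evaluates the fitted response surface at new temperature and
#' water-availability values, with the covariates held at their training
#' means (z = 0) and biome at its observed training mix -- the same
#' conditioning used for the reported curve geometry.
#'
#' @param object A [fit_climate_model()] result.
#' @param newdata Data frame with columns `mat_c` and `wai`.
#' @param ... Unused.
#' @return Numeric vector of predicted contrasts.
#' @export
predict.climate_fit <- function(object, newdata, ...) {
  cf <- object$coefficients
  cf[is.na(cf)] <- 0
  s <- object$scaling
  zt <- (newdata$mat_c - s$mat["mean"]) / s$mat["sd"]
  zw <- (newdata$wai - s$wai["mean"]) / s$wai["sd"]
  X <- cbind(`(Intercept)` = 1, t = zt, t2 = zt^2, w = zw, w2 = zw^2,
             t_x_w = zt * zw)
  pred <- as.vector(X %*% cf[colnames(X)])
  bio <- object$groups$biome
  if (!is.null(bio)) {
    mix <- colMeans(stats::model.matrix(object$lm)[, bio, drop = FALSE])
    pred <- pred + sum(mix * cf[bio])
  }
  pred
}

#' Compare temperature and water-availability importance
#'
#' Given the per-response importance shares of temperature and of water
#' availability (linear plus squared terms pooled), reports both a
#' pooled-variance two-sample t statistic and the variance-ratio F
#' statistic with their p-values, together with the sample means. Both
#' statistics are reported side by side because published summaries of
#' this comparison have labelled a mean comparison with an F value; the
#' discrepancy is surfaced rather than resolved.
#'
#' @param temp_shares,water_shares Numeric vectors of equal length
#'   (canonically 13: ten traits, gymnosperm percentage, two PC axes).
#' @return List of class `importance_comparison`: `n`, means, `t`,
#'   `p_t`, `F`, `p_F`, `degenerate` flag (TRUE when a sample is
#'   constant, making the F ratio undefined or infinite).
#' @export
compare_importance <- function(temp_shares, water_shares) {
  if (length(temp_shares) != length(water_shares))
    stop_domrare("samples must have equal length",
                 "domrare_parameter_error")
  n <- length(temp_shares)
  note <- if (n != 13)
    paste0("sample length ", n, " (canonical battery has 13 responses)")
  else NULL
  v1 <- stats::var(temp_shares); v2 <- stats::var(water_shares)
  degenerate <- !is.finite(v1) || !is.finite(v2) || v1 == 0 || v2 == 0
  sp2 <- ((n - 1) * v1 + (n - 1) * v2) / (2 * n - 2)
  t_stat <- if (sp2 > 0)
    (mean(temp_shares) - mean(water_shares)) / sqrt(sp2 * 2 / n)
  else NA_real_
  p_t <- if (is.finite(t_stat))
    2 * stats::pt(-abs(t_stat), 2 * n - 2) else NA_real_
  F_stat <- if (!degenerate) v1 / v2 else NA_real_
  p_F <- if (!degenerate) {
    p <- stats::pf(F_stat, n - 1, n - 1)
    min(1, 2 * min(p, 1 - p))
  } else NA_real_
  structure(list(n = n, mean_temperature = mean(temp_shares),
                 mean_water = mean(water_shares),
                 t = t_stat, p_t = p_t, F = F_stat, p_F = p_F,
                 degenerate = degenerate, note = note),
            class = "importance_comparison")
}

#' @export
print.importance_comparison <- function(x, ...) {
  cat("Importance comparison (n =", x$n, "per sample)\n")
  cat("  mean temperature share:", round(x$mean_temperature, 4), "\n")
  cat("  mean water share:      ", round(x$mean_water, 4), "\n")
  cat("  pooled t =", round(x$t, 3), ", p =", format.pval(x$p_t), "\n")
  if (x$degenerate) cat("  F ratio degenerate (constant sample)\n")
  else cat("  variance-ratio F =", round(x$F, 3), ", p =",
           format.pval(x$p_F), "\n")
  invisible(x)
}
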