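#' Principal component analysis over the ten traits
#'
#' Fits a PCA to rows of trait values (typically z-scored plot-by-group
#' median vectors, or species mean vectors for the species-level
#' variant). By default the decomposition is of the correlation matrix,
#' appropriate for traits on mixed scales; a covariance basis is also
#' available. Components are deterministically oriented so that each
#' component's largest-magnitude loading is positive, and the orientation
#' anchor (the trait that fixed each sign) is recorded.
#'
#' @param x Numeric matrix or data frame of trait columns; rows with any
#'   missing cell are dropped (their count is reported).
#' @param basis `"correlation"` (default) or `"covariance"`.
#' @return An object of class `trait_pca`: `loadings` (trait x
#'   component), `explained_fraction`, `scores` (rows in input order,
#'   dropped rows NA), `center`, `scale`, `orientation` (anchor trait per
#'   component), `n_dropped`.
#' @seealso [predict.trait_pca()]
#' @export
fit_pca <- function(x, basis = c("correlation", "covariance")) {
  basis <- match.arg(basis)
  x <- as.matrix(x)
  complete <- stats::complete.cases(x)
  xc <- x[complete, , drop = FALSE]
  if (nrow(xc) < 2)
    stop_domrare("PCA needs at least two complete rows",
                 "domrare_parameter_error")
  ctr <- colMeans(xc)
  scl <- if (basis == "correlation") {
    s <- apply(xc, 2, stats::sd)
    if (any(s == 0))
      stop_domrare("constant column under correlation-basis PCA",
                   "domrare_validation_error")
    s
  } else rep(1, ncol(xc))
  xs <- sweep(sweep(xc, 2, ctr), 2, scl, "/")
  cv <- crossprod(xs) / (nrow(xs) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  load <- eig$vectors
  # deterministic orientation: largest-|loading| entry positive
  anchor <- apply(abs(load), 2, which.max)
  flip <- vapply(seq_len(ncol(load)),
                 function(j) sign(load[anchor[j], j]), numeric(1))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, "*")
  dimnames(load) <- list(colnames(x),
                         paste0("PC", seq_len(ncol(load))))
  scores <- matrix(NA_real_, nrow(x), ncol(load),
                   dimnames = list(rownames(x), colnames(load)))
  scores[complete, ] <- xs %*% load
  structure(list(loadings = load,
                 explained_fraction = ev / sum(ev),
                 scores = scores,
                 center = ctr, scale = scl, basis = basis,
                 orientation = colnames(x)[anchor],
                 n_dropped = sum(!complete)),
            class = "trait_pca")
}

#' Project new trait rows onto a fitted PCA
#'
#' Centers and scales `newdata` with the fit's stored constants and
#' multiplies by the loadings, so projecting the training rows reproduces
#' their stored scores.
#'
#' @param object A [fit_pca()] result.
#' @param newdata Matrix or data frame with the fit's trait columns.
#' @param ... Unused.
#' @return Score matrix (rows x components).
#' @export
predict.trait_pca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(rownames(object$loadings), colnames(newdata))
  if (length(miss))
    stop_domrare(paste0("newdata lacks trait column(s): ",
                        paste(miss, collapse = ", ")),
                 "domrare_schema_error")
  nd <- newdata[, rownames(object$loadings), drop = FALSE]
  if (anyNA(nd))
    stop_domrare("missing trait value in newdata row",
                 "domrare_validation_error")
  xs <- sweep(sweep(nd, 2, object$center), 2, object$scale, "/")
  xs %*% object$loadings
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("Trait PCA (", x$basis, " basis), ",
      nrow(x$scores) - x$n_dropped, " rows (", x$n_dropped,
      " dropped)\n", sep = "")
  ef <- x$explained_fraction
  cat("Explained: ",
      paste0(colnames(x$loadings)[1:min(3, length(ef))], " ",
             round(100 * ef[1:min(3, length(ef))], 1), "%",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.trait_pca <- function(object, ...) {
  data.frame(component = colnames(object$loadings),
             explained_fraction = object$explained_fraction,
             cumulative = cumsum(object$explained_fraction),
             anchor_trait = object$orientation,
             stringsAsFactors = FALSE)
}
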