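#' Principal component analysis of trait columns
#'
#' Centres (and by default z-scales) the trait columns and decomposes them
#' by SVD. Loadings use a deterministic sign convention: the
#' largest-magnitude element of each loading column is positive. Variance
#' fractions are `sigma_k^2 / sum(sigma^2)`.
#'
#' @param table data.frame of observations.
#' @param traits numeric trait columns to decompose.
#' @param scale_unit_variance z-scale columns (default `TRUE`); constant
#'   columns are an error in this mode.
#' @return list of class `pca_result`: `scores` (n x k), `loadings`
#'   (traits x k), `variance_fraction`, `cumulative_fraction`, `center`,
#'   `scale`.
#' @examples
#' p <- pcaTraits(data.frame(x = 1:10, y = (1:10) * 2), c("x", "y"))
#' p$variance_fraction  # 1, 0
#' @export
pcaTraits <- function(table, traits, scale_unit_variance = TRUE) {
  x <- .traitMatrix(table, traits, scale_unit_variance, "PCA")
  if (!scale_unit_variance) x <- scale(x, scale = FALSE)
  s <- svd(x)
  k <- length(s$d)
  loadings <- s$v
  # sign convention: largest |element| of each loading column positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      s$u[, j] <- -s$u[, j]
    }
  }
  scores <- s$u %*% diag(s$d, k, k)
  vf <- s$d^2 / sum(s$d^2)
  dimnames(loadings) <- list(traits, paste0("PC", seq_len(k)))
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = vf,
                 cumulative_fraction = cumsum(vf),
                 center = attr(x, "scaled:center"),
                 scale = attr(x, "scaled:scale")),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", length(x$variance_fraction), "components\n")
  cat("  variance fraction:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  cat("  cumulative:      ",
      paste(sprintf("%.3f", x$cumulative_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Cohen's kappa for a confusion matrix
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with observed
#' agreement `po = trace / n` and expected agreement `pe` from the row and
#' column marginals. Returns 1 when `pe = 1` and agreement is perfect.
#'
#' @param confusion square numeric matrix of counts (rows: reference,
#'   columns: predicted).
#' @return kappa in \[-1, 1\].
#' @examples
#' cohenKappa(matrix(c(3, 1, 1, 3), 2))  # 0.5
#' @export
cohenKappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    .stopf("confusion matrix must be square")
  n <- sum(confusion)
  if (n == 0) .stopf("empty confusion matrix")
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

# Fisher LDA with equal priors; pooled within-group covariance with a
# small ridge when near-singular (tiny n relative to trait count).
.ldaFit <- function(x, g, ridge = 1e-8) {
  lv <- levels(g)
  p <- ncol(x)
  mus <- t(vapply(lv, function(l) colMeans(x[g == l, , drop = FALSE]),
                  numeric(p)))
  S <- matrix(0, p, p)
  for (l in lv) {
    xi <- x[g == l, , drop = FALSE]
    xc <- sweep(xi, 2, colMeans(xi))
    S <- S + crossprod(xc)
  }
  S <- S / (nrow(x) - length(lv))
  ok <- tryCatch({solve(S); TRUE}, error = function(e) FALSE)
  if (!ok || rcond(S) < 1e-10)
    S <- S + ridge * mean(diag(S)) * diag(p)
  Sinv <- solve(S)
  list(mus = mus, Sinv = Sinv, levels = lv)
}

.ldaPredict <- function(fit, xnew) {
  # equal-prior linear discriminant scores
  sc <- vapply(seq_len(nrow(fit$mus)), function(k) {
    mu <- fit$mus[k, ]
    as.numeric(xnew %*% fit$Sinv %*% mu - 0.5 * mu %*% fit$Sinv %*% mu)
  }, numeric(nrow(xnew)))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1)
  fit$levels[max.col(sc, ties.method = "first")]
}

#' Linear discriminant analysis with leave-one-out cross-validation
#'
#' Fisher LDA with equal priors: for each observation the classifier is
#' refitted on the remaining rows and the held-out row classified; the
#' resulting confusion matrix yields the cross-validated accuracy and
#' Cohen's kappa. The pooled within-group covariance receives a `1e-8`
#' ridge when near-singular, which stabilizes fits at small n.
#'
#' @param table data.frame of observations.
#' @param traits numeric trait columns used as predictors.
#' @param grouping factor column name; every group needs >= 2 rows.
#' @param standardize z-score traits first (default `TRUE`; affects
#'   neither the LDA decision rule in exact arithmetic nor the ridge-free
#'   fit, but keeps the ridge scale-free).
#' @return list of class `lda_cv_result`: `confusion_matrix`, `accuracy`,
#'   `kappa`, `predicted`, `scheme = "leave-one-out"`.
#' @export
ldaLoocv <- function(table, traits, grouping, standardize = TRUE) {
  g <- .checkFactorColumn(table, grouping)
  if (any(table(g) < 2))
    .stopf("every group needs at least 2 rows for leave-one-out CV")
  x <- .traitMatrix(table, traits, standardize, "LDA")
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    gi <- droplevels(g[-i])
    if (nlevels(gi) < 2L)
      .stopf("removing row %d leaves fewer than 2 groups", i)
    fit <- .ldaFit(x[-i, , drop = FALSE], gi)
    pred[i] <- .ldaPredict(fit, x[i, , drop = FALSE])
  }
  lv <- levels(g)
  conf <- table(factor(g, lv), factor(pred, lv))
  conf <- matrix(as.numeric(conf), nlevels(g), nlevels(g),
                 dimnames = list(reference = lv, predicted = lv))
  structure(list(confusion_matrix = conf,
                 accuracy = sum(diag(conf)) / sum(conf),
                 kappa = cohenKappa(conf),
                 predicted = pred, scheme = "leave-one-out"),
            class = "lda_cv_result")
}

#' @export
print.lda_cv_result <- function(x, ...) {
  cat(sprintf("LDA %s CV: accuracy %.1f%%, kappa %.3f\n",
              x$scheme, 100 * x$accuracy, x$kappa))
  print(x$confusion_matrix)
  invisible(x)
}
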