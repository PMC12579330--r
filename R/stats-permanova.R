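# Distance-based multivariate ANOVA by permutation.
#
# The observed statistic works on the Gower-centred inner-product matrix
# G = -(1/2) C D^2 C with C = I - 11'/n: the sum of squares attributable
# to a set of model columns X is tr(P G) for the projection P onto the
# span increment of X, and permuting object labels amounts to permuting
# rows/columns of G.

.gowerCenter <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  A <- -0.5 * dm^2
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

.projection <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  Q %*% t(Q)
}

# sequential projections for terms fitted in order after the intercept
.termProjections <- function(table, terms) {
  n <- nrow(table)
  Xcum <- matrix(1, n, 1)
  Hprev <- .projection(Xcum)
  out <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    vars <- strsplit(terms[i], ":", fixed = TRUE)[[1]]
    fs <- lapply(vars, function(v) .checkFactorColumn(table, v))
    f <- if (length(fs) == 1L) fs[[1]] else interaction(fs, drop = TRUE)
    if (nlevels(f) < 2L)
      .stopf("term '%s' has fewer than 2 levels", terms[i])
    X <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    Xcum <- cbind(Xcum, X)
    H <- .projection(Xcum)
    df <- qr(Xcum)$rank - qr(Hprev)$rank
    out[[i]] <- list(P = H - Hprev, df = df, name = terms[i])
    Hprev <- H
  }
  list(terms = out, Hfull = Hprev,
       df_resid = n - qr(Hprev)$rank)
}

.permanovaF <- function(G, proj) {
  ssT <- vapply(proj$terms, function(t) sum(t$P * G), numeric(1))
  Pres <- diag(nrow(G)) - proj$Hfull
  ssR <- sum(Pres * G)
  dfT <- vapply(proj$terms, `[[`, numeric(1), "df")
  Fv <- (ssT / dfT) / (ssR / proj$df_resid)
  list(ss = ssT, ss_resid = ssR, F = Fv)
}

# all permutations of 1..n (n! rows); used for exact enumeration
.allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)
    if (pos < n) blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                              sub[, pos:(n - 1), drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Distance-based ANOVA with sequential (Type-I) sums of squares: the
#' distance matrix is Gower-centred and each term's SS is the trace of the
#' centred inner-product matrix projected onto that term's span increment,
#' with terms fitted in the order listed. Significance is assessed by free
#' permutation of object labels (optionally restricted within `strata`),
#' with `p = (1 + #(F* >= F)) / (1 + n_perm)` so p is never 0. With
#' `exact = TRUE` all `n!` relabellings are enumerated instead and the
#' p-value is the exact proportion `#(F* >= F) / n!`.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param table data.frame with the factor columns named in `terms`.
#' @param terms character vector of terms in fitting order; interactions as
#'   `"a:b"`.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param strata optional factor column name; permutations are then
#'   performed within strata levels only.
#' @param exact enumerate all permutations (only sensible for n <= 8).
#' @return list of class `permanova` with components `aov_table`
#'   (data.frame: term, df, ss, pseudo_F, R2, p_perm), `ss_resid`,
#'   `df_resid`, `ss_total`, `n_perm`, `seed`.
#' @examples
#' tb <- data.frame(g = rep(c("a", "b"), each = 4),
#'                  x = c(rnorm(4), rnorm(4, 3)), y = rnorm(8))
#' d <- euclideanDistances(tb, c("x", "y"), standardize = FALSE)
#' permanova(d, tb, "g", n_perm = 199, seed = 1)
#' @export
permanova <- function(d, table, terms, n_perm = 10000, seed = 1,
                      strata = NULL, exact = FALSE) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n != nrow(table))
    .stopf("distance matrix size (%d) does not match table rows (%d)",
           n, nrow(table))
  if (!exact && n_perm < 1)
    .stopf("n_perm must be >= 1")
  G <- .gowerCenter(dm)
  proj <- .termProjections(table, terms)
  obs <- .permanovaF(G, proj)
  ssTot <- sum(diag(G))
  k <- length(proj$terms)
  if (exact) {
    if (n > 9)
      .stopf("exact enumeration is limited to n <= 9")
    perms <- .allPermutations(n)
    count <- numeric(k)
    # relative tie tolerance: equivalent relabellings must count as ties
    # despite summation-order float noise
    thr <- obs$F * (1 - 1e-8) - 1e-12
    for (r in seq_len(nrow(perms))) {
      Fp <- .permanovaF(G[perms[r, ], perms[r, ]], proj)$F
      count <- count + (Fp >= thr)
    }
    pvals <- count / nrow(perms)
    n_used <- nrow(perms)
  } else {
    strataF <- if (!is.null(strata)) .checkFactorColumn(table, strata)
    thr <- obs$F * (1 - 1e-8) - 1e-12
    count <- .withSeed(seed, {
      cnt <- numeric(k)
      for (b in seq_len(n_perm)) {
        p <- if (is.null(strata)) sample.int(n) else {
          p0 <- seq_len(n)
          for (lv in levels(strataF)) {
            i <- which(strataF == lv)
            p0[i] <- i[sample.int(length(i))]
          }
          p0
        }
        Fp <- .permanovaF(G[p, p], proj)$F
        cnt <- cnt + (Fp >= thr)
      }
      cnt
    })
    pvals <- (1 + count) / (1 + n_perm)
    n_used <- n_perm
  }
  aov_table <- data.frame(
    term = vapply(proj$terms, `[[`, character(1), "name"),
    df = vapply(proj$terms, `[[`, numeric(1), "df"),
    ss = obs$ss,
    pseudo_F = obs$F,
    R2 = obs$ss / ssTot,
    p_perm = pvals
  )
  structure(list(aov_table = aov_table, ss_resid = obs$ss_resid,
                 df_resid = proj$df_resid, ss_total = ssTot,
                 n_perm = n_used, seed = seed, exact = exact,
                 strata = strata),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s, %s):\n",
              if (x$exact) "exact enumeration"
              else sprintf("%d permutations, seed %s", x$n_perm, x$seed),
              if (is.null(x$strata)) "free permutation"
              else paste("strata:", x$strata)))
  tab <- x$aov_table
  tab$ss <- signif(tab$ss, 5); tab$pseudo_F <- signif(tab$pseudo_F, 4)
  tab$R2 <- signif(tab$R2, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Residual: df %d, SS %.5g (R2 %.3f); total SS %.5g\n",
              x$df_resid, x$ss_resid, x$ss_resid / x$ss_total, x$ss_total))
  invisible(x)
}

#' Pairwise permutation tests between group levels
#'
#' For every unordered pair of levels of `grouping`, tests the null of no
#' difference via label permutation within the pair's rows. The default
#' statistic is the Euclidean distance between multivariate group centroids
#' (on z-scored traits); with `statistic = "trait"` each single trait in
#' `traits` must be length 1 and the statistic is the absolute difference
#' of group means. P-values use the `(1 + b) / (1 + B)` estimator and are
#' Holm-adjusted across pairs.
#'
#' @param table data.frame of observations.
#' @param traits trait column(s) for the statistic.
#' @param grouping factor column name with >= 2 levels.
#' @param n_perm permutations per pair (default 10000).
#' @param seed integer seed.
#' @param statistic `"centroid"` (multivariate) or `"trait"` (univariate
#'   mean difference).
#' @param standardize z-score traits before computing centroid distances
#'   (default `TRUE`).
#' @return data.frame `group1, group2, statistic, p_raw, p_holm`; levels
#'   with fewer than 2 rows are skipped with a warning.
#' @export
pairwisePermutationTests <- function(table, traits, grouping,
                                     n_perm = 10000, seed = 1,
                                     statistic = c("centroid", "trait"),
                                     standardize = TRUE) {
  statistic <- match.arg(statistic)
  g <- .checkFactorColumn(table, grouping)
  if (statistic == "trait" && length(traits) != 1L)
    .stopf("'trait' mode uses exactly one trait column")
  x <- .traitMatrix(table, traits, standardize && statistic == "centroid",
                    "pairwise-test")
  lv <- levels(g)
  sizes <- table(g)
  usable <- lv[sizes[lv] >= 2]
  if (length(usable) < length(lv))
    warning("skipping level(s) with < 2 rows: ",
            paste(setdiff(lv, usable), collapse = ", "))
  if (length(usable) < 2L)
    .stopf("need at least 2 usable levels")
  pairs <- utils::combn(usable, 2)
  stat_fun <- function(xx, gg, a, b) {
    ma <- colMeans(xx[gg == a, , drop = FALSE])
    mb <- colMeans(xx[gg == b, , drop = FALSE])
    if (statistic == "centroid") sqrt(sum((ma - mb)^2)) else abs(ma - mb)
  }
  res <- .withSeed(seed, {
    out <- vector("list", ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      rows <- which(g %in% c(a, b))
      xx <- x[rows, , drop = FALSE]
      gg <- droplevels(g[rows])
      obs <- stat_fun(xx, gg, a, b)
      thr <- obs - 1e-8 * (abs(obs) + 1e-12)
      cnt <- 0L
      for (bb in seq_len(n_perm)) {
        gp <- gg[sample.int(length(gg))]
        if (stat_fun(xx, gp, a, b) >= thr) cnt <- cnt + 1L
      }
      out[[j]] <- data.frame(group1 = a, group2 = b, statistic = obs,
                             p_raw = (1 + cnt) / (1 + n_perm))
    }
    do.call(rbind, out)
  })
  res$p_holm <- holmAdjust(res$p_raw)
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  res
}
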