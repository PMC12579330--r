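# One-way ANOVA with Tukey HSD letter display.
#
# The compact letter display uses the insert-and-absorb algorithm: start
# from a single letter covering all groups; for every significantly
# different pair split any letter containing both; absorb redundant
# letters; order letters by descending group mean. This guarantees that
# significant pairs never share a letter and non-significant pairs always
# share at least one.

.letterDisplay <- function(groups, sigpairs, means) {
  sets <- list(groups)
  for (k in seq_len(nrow(sigpairs))) {
    a <- sigpairs[k, 1]; b <- sigpairs[k, 2]
    newsets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        newsets <- c(newsets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else newsets <- c(newsets, list(s))
    }
    # drop duplicates, then absorb sets strictly contained in another
    newsets <- unique(lapply(newsets, sort))
    keep <- vapply(seq_along(newsets), function(i) {
      !any(vapply(seq_along(newsets), function(j) {
        i != j && length(newsets[[i]]) < length(newsets[[j]]) &&
          all(newsets[[i]] %in% newsets[[j]])
      }, logical(1)))
    }, logical(1))
    sets <- newsets[keep]
  }
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  # order letter sets by the largest group mean they contain
  ord <- order(-vapply(sets, function(s) max(means[s]), numeric(1)))
  sets <- sets[ord]
  letters_out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets)) {
    l <- letters[(i - 1) %% 26 + 1]
    if (i > 26) l <- paste0(l, (i - 1) %/% 26)
    for (gname in sets[[i]])
      letters_out[gname] <- paste0(letters_out[gname], l)
  }
  letters_out
}

#' One-way ANOVA with Tukey HSD compact letter display
#'
#' Classical one-way ANOVA F test followed by Tukey's honestly significant
#' difference comparisons using the studentized-range distribution
#' (Tukey-Kramer standard errors for unequal group sizes), and a compact
#' letter display in which groups sharing a letter are not significantly
#' different at `alpha`. When all within-group variance is zero and the
#' means differ, pairwise p-values hit the numerical floor of 0 and all
#' unequal-mean pairs are declared different.
#'
#' @param values numeric response vector.
#' @param grouping factor (or coercible) of the same length; >= 2 groups
#'   with >= 2 values each.
#' @param alpha family-wise significance level (default 0.05).
#' @return list of class `anova_tukey`: `F`, `p`, `df`, `letters` (named
#'   by group, ordered by descending mean), `pairwise` (data.frame:
#'   group1, group2, diff, p_tukey), `group_means`.
#' @examples
#' set.seed(1)
#' r <- anovaTukey(c(rnorm(10), rnorm(10, 5)), rep(c("a", "b"), each = 10))
#' r$letters
#' @export
anovaTukey <- function(values, grouping, alpha = 0.05) {
  g <- factor(grouping)
  if (nlevels(g) < 2L)
    .stopf("need at least 2 groups")
  if (any(table(g) < 2))
    .stopf("every group needs at least 2 values")
  if (length(values) != length(g))
    .stopf("values and grouping lengths differ")
  lv <- levels(g)
  k <- nlevels(g)
  n <- length(values)
  means <- tapply(values, g, mean)
  sizes <- tapply(values, g, length)
  grand <- mean(values)
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum((values - means[g])^2)
  dfb <- k - 1; dfw <- n - k
  msw <- ssw / dfw
  if (msw == 0) {
    Fstat <- if (ssb == 0) 0 else Inf
    p <- if (ssb == 0) 1 else 0
  } else {
    Fstat <- (ssb / dfb) / msw
    p <- pf(Fstat, dfb, dfw, lower.tail = FALSE)
  }
  pairs <- utils::combn(lv, 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   diff = NA_real_, p_tukey = NA_real_)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    dd <- means[a] - means[b]
    se <- sqrt(msw / 2 * (1 / sizes[a] + 1 / sizes[b]))
    if (se == 0) {
      pw$p_tukey[j] <- if (abs(dd) < 1e-12) 1 else 0
    } else {
      q <- abs(dd) / se
      pw$p_tukey[j] <- ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
    }
    pw$diff[j] <- dd
  }
  sig <- pw[pw$p_tukey < alpha, c("group1", "group2"), drop = FALSE]
  lets <- .letterDisplay(lv, as.matrix(sig), means)
  lets <- lets[order(-means[names(lets)])]
  structure(list(F = Fstat, p = p, df = c(dfb, dfw), letters = lets,
                 pairwise = pw, group_means = means, alpha = alpha),
            class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat("Tukey HSD letters (alpha =", x$alpha, "):\n")
  for (gname in names(x$letters))
    cat(sprintf("  %-12s mean %8.4g  %s\n", gname,
                x$group_means[gname], x$letters[gname]))
  invisible(x)
}
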