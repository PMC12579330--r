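#' Euclidean distance matrix on trait columns
#'
#' Pairwise Euclidean distances between observations on the selected trait
#' columns. Because the traits mix micrometre and squared-micrometre
#' scales, columns are z-scored by default before distances are taken.
#'
#' @param table data.frame of observations.
#' @param traits character vector of numeric trait columns.
#' @param standardize z-score each trait first (default `TRUE`); a
#'   constant trait is an error in this mode.
#' @return A `dist` object.
#' @examples
#' d <- euclideanDistances(data.frame(a = c(0, 3), b = c(0, 4)),
#'                         c("a", "b"), standardize = FALSE)
#' as.numeric(d)  # 5
#' @export
euclideanDistances <- function(table, traits, standardize = TRUE) {
  if (nrow(table) < 2L)
    .stopf("need at least 2 rows")
  x <- .traitMatrix(table, traits, standardize, "distance")
  dist(x, method = "euclidean")
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the m p-values ascending, multiplies the k-th smallest by
#' `m - k + 1`, enforces a running maximum so adjusted values are monotone
#' in the step-down order, caps at 1, and returns values in the input
#' order.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @return Adjusted p-values, same order as input.
#' @examples
#' holmAdjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holmAdjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    .stopf("p-values must lie in [0, 1]")
  m <- length(pvals)
  o <- order(pvals)
  adj <- pvals[o] * (m - seq_len(m) + 1)
  adj <- cummax(adj)
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Colony radial growth rate
#'
#' Growth rate of an agar culture from its diameter series:
#' `GR = (diameter_final - diameter_initial) / days_elapsed`, in mm/day.
#'
#' @param series data.frame with columns `day` (strictly increasing) and
#'   `diameter_mm` (>= 0), or two numeric vectors via `day`/`diameter_mm`.
#' @param day,diameter_mm alternative vector interface.
#' @return list of class `growth_rate` with `gr_mm_per_day`, `days`,
#'   `n_points`.
#' @examples
#' growthRate(data.frame(day = c(0, 24), diameter_mm = c(5, 29)))
#' @export
growthRate <- function(series = NULL, day = NULL, diameter_mm = NULL) {
  if (is.null(series)) series <- data.frame(day = day,
                                            diameter_mm = diameter_mm)
  if (!all(c("day", "diameter_mm") %in% names(series)))
    .stopf("series needs 'day' and 'diameter_mm' columns")
  if (nrow(series) < 2L)
    .stopf("need at least 2 time points")
  o <- order(series$day)
  series <- series[o, ]
  if (any(diff(series$day) <= 0))
    .stopf("days must be strictly increasing")
  if (any(series$diameter_mm < 0))
    .stopf("diameters must be >= 0")
  gr <- (series$diameter_mm[nrow(series)] - series$diameter_mm[1]) /
    (series$day[nrow(series)] - series$day[1])
  structure(list(gr_mm_per_day = gr,
                 days = series$day[nrow(series)] - series$day[1],
                 n_points = nrow(series)),
            class = "growth_rate")
}

#' @export
print.growth_rate <- function(x, ...) {
  cat(sprintf("Growth rate: %.3g mm/day over %g days (%d points)\n",
              x$gr_mm_per_day, x$days, x$n_points))
  invisible(x)
}
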