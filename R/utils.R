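# internal helpers

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.checkScalar <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0)
    .stopf("'%s' must be > 0", name)
  invisible(x)
}

# run expr under a fixed RNG state, restoring the caller's stream
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

.checkFactorColumn <- function(table, name) {
  if (!name %in% names(table))
    .stopf("column '%s' not found in table", name)
  f <- factor(table[[name]])
  if (nlevels(f) < 2L)
    .stopf("factor '%s' has fewer than 2 levels", name)
  f
}

.traitMatrix <- function(table, traits, standardize, context = "analysis") {
  missing <- setdiff(traits, names(table))
  if (length(missing))
    .stopf("trait column(s) not found: %s", paste(missing, collapse = ", "))
  x <- as.matrix(table[, traits, drop = FALSE])
  if (!is.numeric(x))
    .stopf("trait columns must be numeric")
  if (anyNA(x))
    .stopf("missing trait values are not allowed in the %s subset", context)
  if (standardize) {
    sds <- apply(x, 2, sd)
    if (any(sds == 0))
      .stopf("constant trait cannot be standardized: %s",
             paste(traits[sds == 0], collapse = ", "))
    x <- scale(x)
    dimnames(x) <- list(NULL, traits)
  }
  x
}
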