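# Shared fixture builders and independent oracles. Everything here is
# deliberately naive (flood fills, double loops, closed forms) so the
# package implementation is checked against a different route.

SCALE <- 15.8097

# hard-edged rasterized ellipse on a light background
rasterEllipse <- function(nr, nc, cr, cc, a, b, theta = 0,
                          bg = 0.9, fg = 0.1) {
  img <- matrix(bg, nr, nc)
  rr <- row(img) - cr
  cd <- col(img) - cc
  u <- cd * cos(theta) + rr * sin(theta)
  v <- -cd * sin(theta) + rr * cos(theta)
  img[(u / a)^2 + (v / b)^2 <= 1] <- fg
  img
}

# naive 8-connected component count via stack-based flood fill
floodCount <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      k <- k + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 ||
            p[2] > ncol(mask)) next
        if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- k
        for (dr in -1:1) for (dc in -1:1)
          if (dr || dc) stack[[length(stack) + 1L]] <- c(p[1] + dr,
                                                         p[2] + dc)
      }
    }
  }
  list(n = k, labels = lab)
}

# brute-force double-loop Euclidean distances
bruteDist <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
  d
}

# sequential (Type-I) PERMANOVA oracle for Euclidean distances on raw
# data: sum per-trait univariate sequential ANOVA sums of squares
# (classical identity between Euclidean PERMANOVA and summed ANOVA)
aovSeqOracle <- function(table, traits, terms) {
  rhs <- paste(terms, collapse = " + ")
  ss <- NULL
  for (tr in traits) {
    fit <- stats::aov(stats::as.formula(paste(tr, "~", rhs)), data = table)
    an <- summary(fit)[[1]]
    ss <- if (is.null(ss)) an[, "Sum Sq"] else ss + an[, "Sum Sq"]
  }
  k <- length(terms)
  list(ss = ss[seq_len(k)], ss_resid = ss[k + 1])
}

# random DNA alignment with gaps/ambiguity for brute-force site scans
randomAlignment <- function(nseq, ncol_, gap_p = 0.08, amb_p = 0.03) {
  alphabet <- c("A", "C", "G", "T")
  m <- matrix(sample(alphabet, nseq * ncol_, replace = TRUE), nseq, ncol_)
  n <- length(m)
  m[sample(n, round(gap_p * n))] <- "-"
  m[sample(n, round(amb_p * n))] <- sample(c("N", "R", "Y"),
                                           round(amb_p * n), replace = TRUE)
  Biostrings::DNAStringSet(
    setNames(apply(m, 1, paste, collapse = ""),
             paste0("s", seq_len(nseq))))
}

# per-column brute-force site classification over unambiguous bases
siteOracle <- function(aln) {
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  nvar <- 0L; npi <- 0L
  snp_pos <- integer()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (!length(col)) next
    tabb <- table(col)
    if (length(tabb) >= 2) nvar <- nvar + 1L
    if (sum(tabb >= 2) >= 2) npi <- npi + 1L
  }
  list(n_variable = nvar, n_parsimony_informative = npi)
}

snpOracle <- function(aln, thr) {
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  pos <- integer()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) < 1) next
    tabb <- sort(table(col), decreasing = TRUE)
    if (length(tabb) < 2) next
    # majority with alphabetical tie-break
    top <- max(tabb)
    ref <- sort(names(tabb)[tabb == top])[1]
    rest <- tabb[names(tabb) != ref]
    if (max(rest) / length(col) >= thr) pos <- c(pos, j)
  }
  pos
}
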