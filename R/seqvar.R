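# Variability of DNA multiple alignments: variable / parsimony-informative
# site counts and minimum-variant-frequency SNP calls. Frequencies are
# computed over unambiguous bases (A, C, G, T) only; gaps and IUPAC
# ambiguity codes are excluded from denominators under the default gap
# policy.

.BASES <- c("A", "C", "G", "T")

#' Read and validate a FASTA multiple alignment
#'
#' Reads DNA records with [Biostrings::readDNAStringSet()], normalizes case
#' and checks the alignment contract: at least 2 records, unique ids,
#' equal lengths (ragged input is an error naming the offending records).
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] of equal-width records.
#' @export
readFastaAlignment <- function(path) {
  if (!file.exists(path))
    .stopf("alignment file not found: %s", path)
  aln <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    .stopf("cannot read FASTA '%s': %s", path,
                           conditionMessage(e)))
  if (length(aln) < 2L)
    .stopf("alignment needs at least 2 records")
  ids <- names(aln)
  if (anyDuplicated(ids))
    .stopf("duplicate sequence id(s): %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L) {
    common <- as.numeric(names(which.max(table(w))))
    .stopf("ragged alignment; offending id(s): %s",
           paste(ids[w != common], collapse = ", "))
  }
  aln
}

# per-column counts of unambiguous bases (4 x n_sites matrix)
.baseCounts <- function(aln) {
  cm <- Biostrings::consensusMatrix(aln)
  have <- intersect(.BASES, rownames(cm))
  out <- matrix(0, 4, ncol(cm), dimnames = list(.BASES, NULL))
  out[have, ] <- cm[have, , drop = FALSE]
  out
}

#' Count variable and parsimony-informative alignment sites
#'
#' A column is \emph{variable} when at least two distinct unambiguous
#' bases occur among the retained residues, and \emph{parsimony
#' informative} when at least two bases each occur in at least two
#' sequences. Under the default `gap_policy = "ignore"`, gaps and IUPAC
#' ambiguity codes are simply excluded per column, so a column whose only
#' variation is gap-vs-base is not variable.
#'
#' @param aln a [Biostrings::DNAStringSet] alignment (see
#'   [readFastaAlignment()]).
#' @param gap_policy only `"ignore"` is implemented: gaps/ambiguities are
#'   dropped from each column before counting.
#' @return list of class `site_summary`: `n_sites`, `n_variable`,
#'   `n_parsimony_informative`, `percent_variable` (1 decimal).
#' @examples
#' aln <- Biostrings::DNAStringSet(c(a = "ACGT", b = "ACGA",
#'                                   c = "ACGT", d = "ACGA"))
#' countVariableSites(aln)
#' @export
countVariableSites <- function(aln, gap_policy = "ignore") {
  gap_policy <- match.arg(gap_policy, "ignore")
  if (length(aln) < 2L)
    .stopf("alignment needs at least 2 sequences")
  bc <- .baseCounts(aln)
  retained <- colSums(bc) > 0
  if (!any(retained))
    .stopf("no alignment column retains an unambiguous base")
  n_states <- colSums(bc > 0)
  n_informative_states <- colSums(bc >= 2)
  n_var <- sum(n_states >= 2)
  n_pi <- sum(n_informative_states >= 2)
  n_sites <- ncol(bc)
  structure(list(n_sites = n_sites, n_variable = n_var,
                 n_parsimony_informative = n_pi,
                 percent_variable = round(100 * n_var / n_sites, 1)),
            class = "site_summary")
}

#' @export
print.site_summary <- function(x, ...) {
  cat(sprintf(
    "Sites: %d; variable %d (%.1f%%); parsimony-informative %d\n",
    x$n_sites, x$n_variable, x$percent_variable,
    x$n_parsimony_informative))
  invisible(x)
}

#' Call polymorphic positions at a minimum variant frequency
#'
#' Per alignment column, base frequencies are computed over the retained
#' unambiguous residues; the reference state is the majority base (ties
#' broken alphabetically) and a SNP is reported when the most frequent
#' non-majority base reaches `min_variant_freq` (inclusive boundary, so a
#' singleton among 4 sequences is called at the default 25% threshold).
#'
#' @param aln a [Biostrings::DNAStringSet] alignment.
#' @param min_variant_freq frequency threshold in (0, 1\]; values up to
#'   0.5 are the intended regime.
#' @return data.frame `position` (1-based column), `ref`, `alt`,
#'   `alt_freq`, `alt_all` (all variant states as `base:freq`,
#'   ';'-separated), `n_retained`.
#' @examples
#' aln <- Biostrings::DNAStringSet(c(a = "ACGT", b = "ACGT",
#'                                   c = "ACGT", d = "TCGT"))
#' callSnps(aln, 0.25)
#' @export
callSnps <- function(aln, min_variant_freq = 0.25) {
  if (min_variant_freq <= 0 || min_variant_freq > 1)
    .stopf("min_variant_freq must be in (0, 1]")
  bc <- .baseCounts(aln)
  calls <- list()
  for (j in seq_len(ncol(bc))) {
    cnts <- bc[, j]
    tot <- sum(cnts)
    if (tot == 0 || sum(cnts > 0) < 2) next
    ref <- .BASES[which.max(cnts)]       # ties: alphabetical (A<C<G<T)
    alt_cnts <- cnts
    alt_cnts[ref] <- 0
    alt <- .BASES[which.max(alt_cnts)]
    freqs <- cnts / tot
    if (freqs[alt] < min_variant_freq) next
    alts <- .BASES[cnts > 0 & .BASES != ref]
    calls[[length(calls) + 1L]] <- data.frame(
      position = j, ref = ref, alt = alt,
      alt_freq = unname(freqs[alt]),
      alt_all = paste(sprintf("%s:%.4g", alts, freqs[alts]),
                      collapse = ";"),
      n_retained = tot)
  }
  if (!length(calls))
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), alt_freq = numeric(),
                      alt_all = character(), n_retained = numeric()))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
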