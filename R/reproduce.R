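#' Recompute the published morphometric statistics from raw trait tables
#'
#' Given the raw conidial trait table (one row per measurement with the
#' nested factors `site`, `host_ploidy`, `individual`, `replicate` and the
#' five trait columns), recomputes the full statistics stack: trait
#' summaries, the PERMANOVA of individual identity on Euclidean distances,
#' the individual-level PCA cumulative variance, and the LDA leave-one-out
#' accuracy and kappa under host-ploidy grouping. Optionally recomputes
#' genome-size means from raw flow-cytometry measurement tables
#' (`group`, `pg` columns).
#'
#' This is the deterministic reproduction path for externally supplied raw
#' data; the package does not bundle any such table.
#'
#' @param trait_table data.frame of raw measurements.
#' @param conidium_traits traits entering the multivariate analyses.
#' @param n_perm,seed PERMANOVA permutation settings.
#' @param genome_tables optional named list of data.frames with columns
#'   `group` and `pg`; group means are reported per table.
#' @return list with `summaries`, `permanova_individual`
#'   (R2, pseudo_F, p), `pca_cumulative_2pc` (percent, individual-level
#'   means), `lda_ploidy` (accuracy percent, kappa, individual-level
#'   means), and `genome_means` (if given).
#' @export
reproduceSupplementStats <- function(trait_table,
                                     conidium_traits = c(
                                       "conidium_length_um",
                                       "conidium_width_um",
                                       "conidium_area_um2",
                                       "conidiophore_length_um"),
                                     n_perm = 10000, seed = 1,
                                     genome_tables = NULL) {
  needed <- c("site", "host_ploidy", "individual", conidium_traits)
  missing <- setdiff(needed, names(trait_table))
  if (length(missing))
    .stopf("trait table lacks column(s): %s",
           paste(missing, collapse = ", "))
  summaries <- do.call(rbind, lapply(
    intersect(c(conidium_traits, "conidiophore_width_um"),
              names(trait_table)),
    function(tr) summarizeTraits(trait_table, tr)))
  d <- euclideanDistances(trait_table, conidium_traits)
  pv <- permanova(d, trait_table, "individual", n_perm = n_perm,
                  seed = seed)
  # individual-level mean pooling for PCA / LDA (the n = 16 scheme)
  agg <- aggregate(trait_table[conidium_traits],
                   by = trait_table[c("site", "host_ploidy", "individual")],
                   FUN = mean)
  pca <- pcaTraits(agg, conidium_traits)
  lda_traits <- intersect(c(conidium_traits, "conidiophore_width_um"),
                          names(trait_table))
  agg_lda <- aggregate(trait_table[lda_traits],
                       by = trait_table[c("site", "host_ploidy",
                                          "individual")],
                       FUN = mean)
  lda <- ldaLoocv(agg_lda, lda_traits, "host_ploidy")
  out <- list(
    summaries = summaries,
    permanova_individual = list(
      R2 = pv$aov_table$R2[1], pseudo_F = pv$aov_table$pseudo_F[1],
      p = pv$aov_table$p_perm[1], df = pv$aov_table$df[1]),
    pca_cumulative_2pc = 100 * pca$cumulative_fraction[2],
    lda_ploidy = list(accuracy_percent = 100 * lda$accuracy,
                      kappa = lda$kappa))
  if (!is.null(genome_tables)) {
    out$genome_means <- lapply(genome_tables, function(tb) {
      stats::aggregate(pg ~ group, data = tb, FUN = mean)
    })
  }
  out
}
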