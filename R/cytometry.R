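#' Read flow-cytometry data from a delimited file
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{histogram}{two columns `channel,count`; passed through
#'     unchanged.}
#'   \item{events}{a single column of per-event fluorescence intensities;
#'     binned into `bins` equal-width bins over the observed range (bin
#'     centres are reported as channels).}
#' }
#' With `format = "auto"` (default) the dialect is chosen from the header.
#'
#' @param path path to a CSV file.
#' @param format `"auto"`, `"histogram"` or `"events"`.
#' @param bins number of bins for event-list input (default 1024).
#' @return An [EventHistogram-class].
#' @export
readCytometry <- function(path, format = c("auto", "histogram", "events"),
                          bins = 1024) {
  format <- match.arg(format)
  if (!file.exists(path))
    .stopf("cytometry file not found: %s", path)
  dat <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    .stopf("cannot parse '%s': %s", path,
                           conditionMessage(e)))
  if (nrow(dat) == 0L)
    .stopf("no data rows in '%s'", path)
  if (format == "auto") {
    format <- if (all(c("channel", "count") %in% names(dat)))
      "histogram" else "events"
  }
  if (format == "histogram") {
    if (!all(c("channel", "count") %in% names(dat)))
      .stopf("histogram input needs 'channel' and 'count' columns")
    bad <- which(!is.finite(dat$channel) | !is.finite(dat$count))
    if (length(bad))
      .stopf("malformed histogram row(s) at line %s of '%s'",
             paste(bad + 1L, collapse = ", "), path)
    o <- order(dat$channel)
    EventHistogram(dat$channel[o], dat$count[o])
  } else {
    v <- dat[[1]]
    bad <- which(!is.finite(v))
    if (length(bad))
      .stopf("malformed event row(s) at line %s of '%s'",
             paste(bad + 1L, collapse = ", "), path)
    if (any(v < 0))
      .stopf("negative fluorescence intensity in '%s'", path)
    binEvents(v, bins)
  }
}

#' Bin an event list into an EventHistogram
#'
#' @param events numeric vector of per-event intensities (>= 0).
#' @param bins number of equal-width bins over the observed range.
#' @return An [EventHistogram-class] whose counts sum to `length(events)`.
#' @export
binEvents <- function(events, bins = 1024) {
  if (!length(events))
    .stopf("no events to bin")
  if (any(events < 0))
    .stopf("negative fluorescence intensity")
  r <- range(events)
  if (diff(r) == 0) r <- r + c(-0.5, 0.5)
  edges <- seq(r[1], r[2], length.out = bins + 1)
  cnt <- tabulate(pmin(findInterval(events, edges, rightmost.closed = TRUE),
                       bins), nbins = bins)
  EventHistogram((edges[-1] + edges[-(bins + 1)]) / 2, cnt)
}

# peak prominence: height above the highest saddle separating the peak from
# higher terrain on either side
.prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- if (p > 1) y[seq_len(p - 1)] else numeric()
    right <- if (p < length(y)) y[(p + 1):length(y)] else numeric()
    saddle <- function(side) {
      higher <- which(side >= h)
      if (!length(higher)) return(min(c(side, h)))
      if (identical(side, left)) min(side[(max(higher)):length(side)])
      else min(side[seq_len(min(higher))])
    }
    sl <- if (length(left)) saddle(left) else min(y)
    sr <- if (length(right)) saddle(right) else min(y)
    h - max(sl, sr)
  }, numeric(1))
}

#' Detect fluorescence peaks in an event histogram
#'
#' Locates up to `n_expected` peaks: candidate local maxima are found on a
#' Savitzky-Golay-smoothed histogram and ranked by topographic prominence;
#' each retained candidate is refined by a Gaussian fit within +/- 2 x FWHM
#' of the candidate (moment-based fallback when the fit fails). For each
#' peak the coefficient of variation is `100 * sd / mean` of the fitted
#' Gaussian, and `events` integrates the raw counts within +/- 3 sd. Peaks
#' holding fewer than `min_frac` of total events are discarded; when
#' nothing remains an empty table is returned with a warning.
#'
#' @param hist an [EventHistogram-class].
#' @param n_expected maximum number of peaks to report (>= 1).
#' @param smooth_width odd Savitzky-Golay window length in bins
#'   (default 11).
#' @param min_frac minimum fraction of total events under a peak
#'   (default 0.01).
#' @return data.frame `mean_channel, cv_percent, events`, rows ordered by
#'   ascending `mean_channel`.
#' @examples
#' syn <- synthFcHistogram(peaks = data.frame(mean = 200, cv = 5,
#'                                            events = 10000), seed = 1)
#' detectPeaks(syn$histogram)
#' @export
detectPeaks <- function(hist, n_expected = 1, smooth_width = 11,
                        min_frac = 0.01) {
  stopifnot(is(hist, "EventHistogram"))
  if (totalEvents(hist) <= 0)
    .stopf("histogram holds no events")
  if (n_expected < 1)
    .stopf("n_expected must be >= 1")
  ch <- channels(hist); y <- counts(hist)
  total <- sum(y)
  nw <- min(smooth_width, length(y) - (1 - length(y) %% 2))
  if (nw %% 2 == 0) nw <- nw - 1
  ys <- if (nw >= 5) signal::sgolayfilt(y, p = 2, n = nw) else y
  ys[ys < 0] <- 0
  # interior local maxima (plateau-tolerant)
  n <- length(ys)
  cand <- which(ys[2:(n - 1)] > ys[1:(n - 2)] &
                ys[2:(n - 1)] >= ys[3:n]) + 1L
  if (!length(cand)) {
    warning("no peak found")
    return(.emptyPeaks())
  }
  prom <- .prominence(ys, cand)
  # a genuine peak rises well above its surroundings: require prominence
  # comparable to the candidate's own height (noise ripples fail)
  ok <- prom >= 0.5 * ys[cand] & ys[cand] > 0
  cand <- cand[ok]; prom <- prom[ok]
  if (!length(cand)) {
    warning("no peak found")
    return(.emptyPeaks())
  }
  cand <- cand[order(prom, decreasing = TRUE)]
  cand <- utils::head(cand, n_expected)
  calls <- lapply(cand, function(p) .refinePeak(ch, y, ys, p))
  calls <- do.call(rbind, calls)
  calls <- calls[calls$events >= min_frac * total, , drop = FALSE]
  if (!nrow(calls)) {
    warning("no peak holds at least ", format(100 * min_frac),
            "% of events")
    return(.emptyPeaks())
  }
  calls <- calls[order(calls$mean_channel), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

.emptyPeaks <- function() {
  data.frame(mean_channel = numeric(), cv_percent = numeric(),
             events = numeric())
}

.refinePeak <- function(ch, y, ys, p) {
  n <- length(ys)
  h <- ys[p]
  # FWHM from half-height crossings on the smoothed curve
  li <- p; while (li > 1 && ys[li] > h / 2) li <- li - 1
  ri <- p; while (ri < n && ys[ri] > h / 2) ri <- ri + 1
  fwhm <- ch[ri] - ch[li]
  if (fwhm <= 0) fwhm <- 2 * mean(diff(ch))
  sd0 <- fwhm / (2 * sqrt(2 * log(2)))
  win <- which(ch >= ch[p] - 2 * fwhm & ch <= ch[p] + 2 * fwhm)
  fit <- tryCatch({
    df <- data.frame(x = ch[win], y = y[win])
    m <- minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sg^2)), data = df,
      start = list(A = max(y[win]), mu = ch[p], sg = sd0),
      lower = c(A = 0, mu = min(ch), sg = 1e-8 * diff(range(ch))),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    co <- stats::coef(m)
    c(mu = unname(co["mu"]), sg = abs(unname(co["sg"])))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    wgt <- y[win]
    if (sum(wgt) == 0) wgt <- wgt + 1
    mu <- sum(ch[win] * wgt) / sum(wgt)
    sg <- sqrt(sum(wgt * (ch[win] - mu)^2) / sum(wgt))
    fit <- c(mu = mu, sg = max(sg, 1e-8))
  }
  inpk <- ch >= fit["mu"] - 3 * fit["sg"] & ch <= fit["mu"] + 3 * fit["sg"]
  data.frame(mean_channel = unname(fit["mu"]),
             cv_percent = unname(100 * fit["sg"] / fit["mu"]),
             events = sum(y[inpk]))
}

#' Registry of genome-size reference standards
#'
#' Internal standards co-processed with samples for ratio-based genome
#' sizing: three plant standards used against host leaf nuclei and one
#' fungal standard used against endophyte mycelium. Registry keys are
#' normalized genus names; display names are kept as published.
#'
#' @return data.frame `key, display, genome_pg, basis`.
#' @examples
#' referenceStandards()
#' @export
referenceStandards <- function() {
  data.frame(
    key = c("solanum", "pisum", "secale", "colletotrichum"),
    display = c("Solanum lycopersicum 'Stupicke polni rane'",
                "Pisum sativum 'Ctirad'",
                "Secale cereale 'Dankovske'",
                "Colletotrichum acutatum PT812"),
    genome_pg = c(1.96, 9.09, 16.19, 0.069),
    basis = c("2C", "2C", "2C", "1C"),
    stringsAsFactors = FALSE
  )
}

#' Look up a reference standard by key
#'
#' @param key normalized genus key (see [referenceStandards()]), matched
#'   case-insensitively.
#' @return One-row data.frame from the registry.
#' @export
getStandard <- function(key) {
  reg <- referenceStandards()
  i <- match(tolower(key), reg$key)
  if (is.na(i))
    .stopf("unknown standard '%s'; known: %s", key,
           paste(reg$key, collapse = ", "))
  reg[i, ]
}

#' Quality-control policy for genome-size measurements
#'
#' Measurements are accepted when both the sample and standard peaks hold
#' at least `min_events` nuclei and both CVs are at or below
#' `cv_max_percent`. The CV ceiling follows kingdom practice: 3% for plant
#' nuclei, 10% for fungal nuclei.
#'
#' @param kingdom `"plant"` or `"fungus"`; sets the default CV ceiling.
#' @param min_events minimum nuclei per peak (default 5000).
#' @param cv_max_percent CV ceiling in percent; default 3 (plant) or 10
#'   (fungus).
#' @return list of class `qc_policy`.
#' @export
qcPolicy <- function(kingdom = c("plant", "fungus"), min_events = 5000,
                     cv_max_percent = NULL) {
  kingdom <- match.arg(kingdom)
  if (is.null(cv_max_percent))
    cv_max_percent <- if (kingdom == "plant") 3 else 10
  if (min_events <= 0) .stopf("min_events must be > 0")
  .checkScalar(cv_max_percent, "cv_max_percent")
  structure(list(kingdom = kingdom, min_events = min_events,
                 cv_max_percent = cv_max_percent), class = "qc_policy")
}

#' Estimate genome size from a sample/standard peak pair
#'
#' Ratio-based sizing against an internal standard:
#' `pg = standard_pg * sample_mean / standard_mean`, reported on the same
#' C-value basis as the standard, with the megabase equivalent
#' `mbp = pg * mbp_per_pg`. QC passes when both peaks meet the
#' [qcPolicy()] event-count and CV gates.
#'
#' @param sample_peak,standard_peak one-row data.frames (or lists) with
#'   `mean_channel`, `cv_percent`, `events` — typically rows of
#'   [detectPeaks()] output.
#' @param standard a registry row from [getStandard()] or a standard key.
#' @param policy a [qcPolicy()].
#' @param mbp_per_pg pg -> Mbp conversion constant (default 978).
#' @return list of class `genome_size_estimate` with `pg`, `mbp`, `basis`,
#'   `qc_pass`, `cv_sample`, `cv_standard`, `events_sample`,
#'   `events_standard`, `standard`, `notes`.
#' @examples
#' pk <- function(m, cv, ev) data.frame(mean_channel = m, cv_percent = cv,
#'                                      events = ev)
#' estimateGenomeSize(pk(130, 4.2, 8000), pk(200, 3.8, 9000),
#'                    "colletotrichum", qcPolicy("fungus"))
#' @export
estimateGenomeSize <- function(sample_peak, standard_peak, standard,
                               policy = qcPolicy("plant"),
                               mbp_per_pg = 978) {
  if (is.character(standard)) standard <- getStandard(standard)
  stopifnot(inherits(policy, "qc_policy"))
  sm <- as.numeric(sample_peak$mean_channel)
  tm <- as.numeric(standard_peak$mean_channel)
  if (!is.finite(tm) || tm <= 0)
    .stopf("standard peak mean must be > 0")
  if (!is.finite(sm) || sm <= 0)
    .stopf("sample peak mean must be > 0")
  pg <- standard$genome_pg * sm / tm
  cvs <- as.numeric(sample_peak$cv_percent)
  cvt <- as.numeric(standard_peak$cv_percent)
  evs <- as.numeric(sample_peak$events)
  evt <- as.numeric(standard_peak$events)
  qc <- evs >= policy$min_events && evt >= policy$min_events &&
    cvs <= policy$cv_max_percent && cvt <= policy$cv_max_percent
  notes <- character()
  if (evs < policy$min_events || evt < policy$min_events)
    notes <- c(notes, sprintf("fewer than %d events under a peak",
                              policy$min_events))
  if (cvs > policy$cv_max_percent || cvt > policy$cv_max_percent)
    notes <- c(notes, sprintf("CV above %.1f%%", policy$cv_max_percent))
  structure(list(pg = pg, mbp = pg * mbp_per_pg, basis = standard$basis,
                 qc_pass = qc, cv_sample = cvs, cv_standard = cvt,
                 events_sample = evs, events_standard = evt,
                 standard = standard$key,
                 notes = if (length(notes)) paste(notes, collapse = "; ")
                         else ""),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("Genome size: %.4g pg/%s (~%.1f Mb), vs standard '%s'\n",
              x$pg, x$basis, x$mbp, x$standard))
  cat(sprintf("  CV sample %.2f%%, standard %.2f%%; events %d / %d; QC %s\n",
              x$cv_sample, x$cv_standard, round(x$events_sample),
              round(x$events_standard),
              if (x$qc_pass) "PASS" else paste("FAIL -", x$notes)))
  invisible(x)
}

#' Infer host ploidy from a 2C genome size
#'
#' Chooses the candidate ploidy `p` minimizing
#' `|pg_2C / p - monoploid_pg|`; ties break toward the smaller ploidy. The
#' default monoploid reference of 1.95 pg/1Cx is a convention for the
#' fescue cytotype series studied here, not a measured constant.
#'
#' @param pg_2C 2C DNA content in pg (> 0).
#' @param monoploid_pg monoploid (1Cx) genome size in pg.
#' @param candidates candidate ploidies (default `c(4, 6, 8)`).
#' @return list of class `ploidy_call` with `ploidy` and `residual`.
#' @examples
#' inferPloidy(7.54)   # tetraploid
#' inferPloidy(15.58)  # octoploid
#' @export
inferPloidy <- function(pg_2C, monoploid_pg = 1.95, candidates = c(4, 6, 8)) {
  .checkScalar(pg_2C, "pg_2C")
  .checkScalar(monoploid_pg, "monoploid_pg")
  if (!length(candidates))
    .stopf("candidates must be non-empty")
  res <- abs(pg_2C / candidates - monoploid_pg)
  o <- order(res, candidates)   # ties toward smaller ploidy
  structure(list(ploidy = candidates[o[1]], residual = res[o[1]]),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("Ploidy call: %dx (residual %.4g pg/1Cx)\n",
              x$ploidy, x$residual))
  invisible(x)
}

#' Convert between picograms and megabases of DNA
#'
#' Uses the standard 978 Mbp per pg of double-stranded DNA (configurable).
#'
#' @param value positive numeric value(s).
#' @param direction `"pg_to_mb"` or `"mb_to_pg"`.
#' @param mbp_per_pg conversion constant (default 978).
#' @return Converted numeric value(s).
#' @examples
#' pgMbConvert(1, "pg_to_mb")      # 978
#' pgMbConvert(68, "mb_to_pg")     # ~0.0695
#' @export
pgMbConvert <- function(value, direction = c("pg_to_mb", "mb_to_pg"),
                        mbp_per_pg = 978) {
  direction <- match.arg(direction)
  if (any(!is.finite(value)) || any(value <= 0))
    .stopf("value must be positive")
  if (direction == "pg_to_mb") value * mbp_per_pg else value / mbp_per_pg
}
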