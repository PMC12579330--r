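# Seeded synthetic inputs with ground truth, emulating the statistical
# structure of the real data: ellipsoidal spores with the published
# dimension distributions, Gaussian fluorescence peaks with stated CVs,
# and nested-factor morphometric tables. All generators are pure
# functions of their arguments and the seed.

# truncated-normal sampling by rejection: exact support control
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  guard <- 0L
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
    guard <- guard + 1L
    if (guard > 1000L)
      .stopf("truncated-normal rejection failed; check the bounds")
  }
  out[seq_len(n)]
}

# coverage-rendered filled ellipse added to a canvas (4x4 subpixel
# sampling gives anti-aliased edges)
.renderEllipse <- function(canvas, cr, cc, a, b, theta, value) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  pad <- ceiling(a) + 2
  rows <- max(1, floor(cr - pad)):min(nr, ceiling(cr + pad))
  cols <- max(1, floor(cc - pad)):min(nc, ceiling(cc + pad))
  sub <- seq(-0.375, 0.375, by = 0.25)
  cov <- matrix(0, length(rows), length(cols))
  for (dr in sub) for (dc in sub) {
    rr <- outer(rows + dr - cr, rep(1, length(cols)))
    cd <- outer(rep(1, length(rows)), cols + dc - cc)
    u <- cd * cos(theta) + rr * sin(theta)
    v <- -cd * sin(theta) + rr * cos(theta)
    cov <- cov + ((u / a)^2 + (v / b)^2 <= 1)
  }
  cov <- cov / length(sub)^2
  canvas[rows, cols] <- canvas[rows, cols] * (1 - cov) + value * cov
  canvas
}

#' Synthesize a spore-field micrograph with ground truth
#'
#' Renders dark, anti-aliased filled ellipses (sagittal-plane spores) and,
#' optionally, overlapping ellipse pairs (oblique/merged structures the
#' sagittal gate should reject) on a light background, then applies
#' Gaussian blur and additive Gaussian noise. Spore dimensions are drawn
#' from truncated normal distributions whose defaults are the published
#' conidium statistics: length 4.4 +/- 0.4 um on \[3.4, 5.5\], width
#' 2.0 +/- 0.2 um on \[1.5, 2.6\].
#'
#' @param n_sagittal,n_oblique number of clean spores and of merged
#'   two-ellipse clumps.
#' @param length_mean,length_sd,length_range conidium length distribution
#'   (um).
#' @param width_mean,width_sd,width_range conidium width distribution (um).
#' @param pixelsPerMicron calibration (default 15.8097 px/um).
#' @param noise_sd additive Gaussian noise SD on the \[0, 1\] intensity
#'   scale (default 0.02).
#' @param blur_sigma Gaussian blur SD in pixels (default 1).
#' @param min_sep_px minimum gap between object bounding circles
#'   (default 8).
#' @param canvas optional canvas side in pixels; sized automatically when
#'   `NULL`.
#' @param max_tries placement retries per object before giving up.
#' @param seed integer seed; identical arguments and seed give identical
#'   output.
#' @return list with `micrograph` (a [Micrograph-class]) and `truth`
#'   (data.frame: id, kind, centroid_row, centroid_col, orientation,
#'   length_um, width_um, area_um2 — area is the analytic ellipse area
#'   pi*a*b for sagittal spores).
#' @examples
#' syn <- synthMicrograph(n_sagittal = 5, seed = 1)
#' nrow(syn$truth)
#' @export
synthMicrograph <- function(n_sagittal = 10, n_oblique = 0,
                            length_mean = 4.4, length_sd = 0.4,
                            length_range = c(3.4, 5.5),
                            width_mean = 2.0, width_sd = 0.2,
                            width_range = c(1.5, 2.6),
                            pixelsPerMicron = 15.8097,
                            noise_sd = 0.02, blur_sigma = 1,
                            min_sep_px = 8, canvas = NULL,
                            max_tries = 200, seed = 1) {
  stopifnot(n_sagittal >= 0, n_oblique >= 0, n_sagittal + n_oblique > 0)
  s <- pixelsPerMicron
  .withSeed(seed, {
    ntot <- n_sagittal + n_oblique
    max_r <- (length_range[2] * s) / 2 + min_sep_px
    if (is.null(canvas))
      # ~8x the summed pairwise-exclusion disc area keeps sequential
      # random placement far from jamming
      canvas <- max(96L, ceiling(2 * max_r * sqrt(8 * ntot)) + 20L)
    bg <- 0.85; fg <- 0.15
    img <- matrix(bg, canvas, canvas)
    placed <- data.frame(r = numeric(), c = numeric(), rad = numeric())
    place <- function(rad) {
      for (t in seq_len(max_tries)) {
        cr <- runif(1, rad + min_sep_px, canvas - rad - min_sep_px)
        cc <- runif(1, rad + min_sep_px, canvas - rad - min_sep_px)
        if (!nrow(placed) ||
            all(sqrt((placed$r - cr)^2 + (placed$c - cc)^2) >
                placed$rad + rad + min_sep_px)) {
          placed[nrow(placed) + 1L, ] <<- c(cr, cc, rad)
          return(c(cr, cc))
        }
      }
      .stopf("could not place all objects; use a larger canvas")
    }
    truth <- list()
    for (i in seq_len(n_sagittal)) {
      L <- .rtruncnorm(1, length_mean, length_sd,
                       length_range[1], length_range[2])
      W <- .rtruncnorm(1, width_mean, width_sd,
                       width_range[1], width_range[2])
      a <- L * s / 2; b <- W * s / 2
      th <- runif(1, 0, pi)
      pos <- place(a + 1)
      img <- .renderEllipse(img, pos[1], pos[2], a, b, th, fg)
      truth[[length(truth) + 1L]] <- data.frame(
        id = i, kind = "sagittal", centroid_row = pos[1],
        centroid_col = pos[2], orientation = th,
        length_um = L, width_um = W, area_um2 = pi * (L / 2) * (W / 2))
    }
    for (i in seq_len(n_oblique)) {
      # merged clump: two ellipses overlapping at an angle (low solidity)
      L <- .rtruncnorm(1, length_mean, length_sd,
                       length_range[1], length_range[2])
      W <- .rtruncnorm(1, width_mean, width_sd,
                       width_range[1], width_range[2])
      a <- L * s / 2; b <- W * s / 2
      th <- runif(1, 0, pi)
      pos <- place(2 * a + 2)
      off <- 0.8 * a
      img <- .renderEllipse(img, pos[1], pos[2], a, b, th, fg)
      img <- .renderEllipse(img, pos[1] + off * sin(th + pi / 2),
                            pos[2] + off * cos(th + pi / 2),
                            a, b, th + pi / 2, fg)
      truth[[length(truth) + 1L]] <- data.frame(
        id = n_sagittal + i, kind = "oblique", centroid_row = pos[1],
        centroid_col = pos[2], orientation = th,
        length_um = L, width_um = W, area_um2 = NA_real_)
    }
    if (blur_sigma > 0)
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                               sigma = blur_sigma))
    if (noise_sd > 0)
      img <- img + rnorm(length(img), 0, noise_sd)
    img <- pmin(pmax(img, 0), 1)
    list(micrograph = Micrograph(img, s),
         truth = do.call(rbind, truth))
  })
}

#' Synthesize a flow-cytometry event histogram with ground truth
#'
#' Draws `events` fluorescence intensities per peak from
#' `Normal(mean, cv * mean / 100)`, optionally adds an exponential
#' low-channel debris background, and bins everything into an
#' [EventHistogram-class]. Total counts equal the number of drawn events.
#'
#' @param peaks data.frame with columns `mean`, `cv` (percent) and
#'   `events`.
#' @param debris_frac debris events as a fraction of the peak events
#'   (default 0).
#' @param debris_scale mean of the exponential debris distribution, in
#'   channel units (default: 1/4 of the lowest peak mean).
#' @param bins number of histogram bins (default 1024).
#' @param seed integer seed.
#' @return list with `histogram` (an [EventHistogram-class]) and `truth`
#'   (the peaks table plus `n_debris`).
#' @examples
#' syn <- synthFcHistogram(peaks = data.frame(mean = 200, cv = 5,
#'                                            events = 10000), seed = 1)
#' totalEvents(syn$histogram)
#' @export
synthFcHistogram <- function(peaks, debris_frac = 0, debris_scale = NULL,
                             bins = 1024, seed = 1) {
  stopifnot(is.data.frame(peaks),
            all(c("mean", "cv", "events") %in% names(peaks)))
  if (any(peaks$events <= 0) || any(peaks$cv <= 0) || any(peaks$mean <= 0))
    .stopf("peak means, CVs and event counts must be > 0")
  .withSeed(seed, {
    ev <- unlist(lapply(seq_len(nrow(peaks)), function(i) {
      x <- rnorm(peaks$events[i], peaks$mean[i],
                 peaks$cv[i] * peaks$mean[i] / 100)
      # fluorescence is non-negative; redraw the rare negative tails
      while (any(x <= 0))
        x[x <= 0] <- rnorm(sum(x <= 0), peaks$mean[i],
                           peaks$cv[i] * peaks$mean[i] / 100)
      x
    }))
    n_debris <- round(debris_frac * sum(peaks$events))
    if (n_debris > 0) {
      if (is.null(debris_scale)) debris_scale <- min(peaks$mean) / 4
      ev <- c(ev, rexp(n_debris, 1 / debris_scale))
    }
    if (!length(ev)) .stopf("zero total events")
    list(histogram = binEvents(ev, bins),
         truth = list(peaks = peaks, n_debris = n_debris))
  })
}

#' Synthesize a nested-design morphometric table with ground truth
#'
#' Emulates the sampling design of the morphometric survey: site-by-ploidy
#' cells, individuals nested in cells, replicate measurements nested in
#' individuals. Each trait value is
#' `grand mean + cell effect + individual random effect + replicate noise`.
#' Default cells mirror the study layout (Mon 4x, Can 4x, Cab 6x, Can 8x;
#' 4 individuals per cell, 10 replicates per individual) and default grand
#' means/SDs are the published trait statistics.
#'
#' @param cells data.frame with columns `site` and `host_ploidy`, one row
#'   per sampled site-by-ploidy combination.
#' @param n_individuals individuals per cell (default 4).
#' @param n_replicates replicate measurements per individual (default 10).
#' @param trait_means named numeric vector of grand means.
#' @param replicate_sd named numeric vector of within-individual
#'   (replicate) SDs.
#' @param individual_sd named numeric vector of between-individual SDs
#'   (default: half the replicate SD).
#' @param cell_effects optional data.frame of per-cell trait offsets:
#'   columns `site`, `host_ploidy`, plus trait columns (missing = 0).
#' @param seed integer seed.
#' @return list with `table` (data.frame: site, host_ploidy, individual,
#'   replicate, trait columns) and `truth` (all effects used).
#' @examples
#' syn <- synthMorphTable(seed = 1)
#' dim(syn$table)  # 160 rows
#' @export
synthMorphTable <- function(cells = data.frame(
                              site = c("Mon", "Can", "Cab", "Can"),
                              host_ploidy = c("4x", "4x", "6x", "8x")),
                            n_individuals = 4, n_replicates = 10,
                            trait_means = c(conidium_length_um = 4.4,
                                            conidium_width_um = 2.0,
                                            conidium_area_um2 = 7.1,
                                            conidiophore_length_um = 12.4,
                                            conidiophore_width_um = 1.8),
                            replicate_sd = c(conidium_length_um = 0.4,
                                             conidium_width_um = 0.2,
                                             conidium_area_um2 = 1.0,
                                             conidiophore_length_um = 2.3,
                                             conidiophore_width_um = 0.4),
                            individual_sd = NULL,
                            cell_effects = NULL, seed = 1) {
  stopifnot(all(c("site", "host_ploidy") %in% names(cells)),
            n_individuals >= 1, n_replicates >= 1)
  traits <- names(trait_means)
  if (!setequal(traits, names(replicate_sd)))
    .stopf("trait_means and replicate_sd must name the same traits")
  replicate_sd <- replicate_sd[traits]
  if (is.null(individual_sd)) individual_sd <- replicate_sd / 2
  individual_sd <- individual_sd[traits]
  .withSeed(seed, {
    rows <- list()
    ind_effects <- list()
    for (ci in seq_len(nrow(cells))) {
      site <- as.character(cells$site[ci])
      pl <- as.character(cells$host_ploidy[ci])
      ce <- setNames(rep(0, length(traits)), traits)
      if (!is.null(cell_effects)) {
        hit <- which(cell_effects$site == site &
                     cell_effects$host_ploidy == pl)
        if (length(hit)) {
          for (tr in intersect(traits, names(cell_effects)))
            ce[tr] <- cell_effects[[tr]][hit[1]]
        }
      }
      for (ii in seq_len(n_individuals)) {
        ind <- sprintf("%s%s_i%d", site, pl, ii)
        ie <- rnorm(length(traits), 0, individual_sd)
        names(ie) <- traits
        ind_effects[[ind]] <- ie
        for (ri in seq_len(n_replicates)) {
          noise <- rnorm(length(traits), 0, replicate_sd)
          vals <- trait_means + ce + ie + noise
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(site = site, host_ploidy = pl, individual = ind,
                       replicate = sprintf("r%d", ri)),
            as.data.frame(as.list(vals)))
        }
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(table = tab,
         truth = list(trait_means = trait_means,
                      replicate_sd = replicate_sd,
                      individual_sd = individual_sd,
                      cell_effects = cell_effects,
                      individual_effects = ind_effects))
  })
}
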