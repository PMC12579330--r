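#' Load a micrograph from a TIFF or PNG file
#'
#' Reads an 8- or 16-bit grayscale image (RGB images are accepted and
#' collapsed to grayscale by averaging the colour channels) and attaches the
#' spatial calibration. Intensities are returned on EBImage's \[0, 1\] scale,
#' which preserves the integer sample values of 8/16-bit sources up to the
#' constant rescaling factor.
#'
#' @param path path to a TIFF or PNG file.
#' @param pixelsPerMicron calibration in pixels per micrometre; the default
#'   15.8097 px/um is the fixed scale used for conidial photography.
#' @return A [Micrograph-class].
#' @examples
#' f <- tempfile(fileext = ".png")
#' EBImage::writeImage(EBImage::Image(matrix(runif(32 * 32), 32, 32)), f)
#' mg <- loadMicrograph(f, 15.8097)
#' dim(mg)
#' @export
loadMicrograph <- function(path, pixelsPerMicron = 15.8097) {
  if (!file.exists(path))
    .stopf("image file not found: %s", path)
  .checkScalar(pixelsPerMicron, "pixelsPerMicron")
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) .stopf("cannot read image '%s': %s",
                                             path, conditionMessage(e)))
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) {
    # RGB (or multi-frame): average across the trailing channel dimension
    dat <- apply(dat, c(1, 2), mean)
  }
  if (length(dim(dat)) != 2L)
    .stopf("unsupported image layout in '%s'", path)
  Micrograph(dat, pixelsPerMicron)
}

# --- low-level region machinery ------------------------------------------

# merge 4-connected labels across diagonal adjacencies -> 8-connectivity
.labels8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  storage.mode(lab) <- "integer"
  nmax <- max(lab)
  if (nmax <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal pairs
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nmax), find, integer(1))
  lab[lab > 0] <- root[lab[lab > 0]]
  lab
}

# moment-equivalent ellipse of a pixel set (rows, cols in pixel units).
# Axis lengths follow the standard regionprops convention: the ellipse with
# the same normalized second central moments as the region, including the
# 1/12 single-pixel variance correction.
.ellipseMoments <- function(rows, cols) {
  n <- length(rows)
  mr <- mean(rows); mc <- mean(cols)
  dr <- rows - mr; dc <- cols - mc
  u20 <- sum(dc * dc) / n + 1 / 12
  u02 <- sum(dr * dr) / n + 1 / 12
  u11 <- sum(dc * dr) / n
  common <- sqrt((u20 - u02)^2 + 4 * u11^2)
  l1 <- (u20 + u02 + common) / 2
  l2 <- (u20 + u02 - common) / 2
  l2 <- max(l2, 0)
  theta <- 0.5 * atan2(2 * u11, u20 - u02)
  list(centroid = c(row = mr, col = mc),
       major = 4 * sqrt(l1), minor = 4 * sqrt(l2), orientation = theta)
}

# convex hull area over pixel corners (so a filled region has solidity <= 1)
.hullArea <- function(rows, cols) {
  pts <- cbind(c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5),
               c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5))
  h <- grDevices::chull(pts)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

.regionFeatureRow <- function(rows, cols, nr, nc) {
  em <- .ellipseMoments(rows, cols)
  area <- length(rows)
  hull <- .hullArea(rows, cols)
  data.frame(
    area_px = area,
    centroid_row = em$centroid[["row"]],
    centroid_col = em$centroid[["col"]],
    major_axis_px = em$major,
    minor_axis_px = em$minor,
    orientation = em$orientation,
    solidity = min(1, area / hull),
    touches_border = any(rows == 1L | rows == nr | cols == 1L | cols == nc)
  )
}

#' Segment candidate structures in a micrograph
#'
#' Detects dark objects on a light background (or the reverse) with an
#' automatic Otsu global threshold, fills holes, labels 8-connected
#' components, and retains regions that do not touch the image border and
#' whose area falls inside the given gate after px^2 -> um^2 conversion.
#' A blank image (no foreground after thresholding) yields zero regions,
#' not an error.
#'
#' @param micrograph a [Micrograph-class].
#' @param min_area_um2,max_area_um2 area gate in um^2 (`0 < min < max`).
#' @param polarity `"dark"` (default) for dark objects on a light
#'   background, `"light"` for the opposite.
#' @return A [LabeledRegions-class]; labels are 1..k in raster order of each
#'   region's topmost-leftmost pixel.
#' @examples
#' syn <- synthMicrograph(n_sagittal = 3, seed = 1)
#' regs <- segmentObjects(syn$micrograph, 1, 50)
#' length(regs)
#' @export
segmentObjects <- function(micrograph, min_area_um2, max_area_um2,
                           polarity = c("dark", "light")) {
  stopifnot(is(micrograph, "Micrograph"))
  polarity <- match.arg(polarity)
  .checkScalar(min_area_um2, "min_area_um2")
  .checkScalar(max_area_um2, "max_area_um2")
  if (min_area_um2 >= max_area_um2)
    .stopf("min_area_um2 must be < max_area_um2")
  s <- pixelsPerMicron(micrograph)
  x <- intensities(micrograph)
  r <- range(x)
  if (diff(r) == 0) {
    # flat image: nothing to segment
    empty <- matrix(0L, nrow(x), ncol(x))
    return(new("LabeledRegions", labels = empty,
               features = .emptyFeatures(), pixelsPerMicron = s))
  }
  xn <- (x - r[1]) / diff(r)
  thr <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  mask <- if (polarity == "dark") xn < thr else xn > thr
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1)))
  lab <- .labels8(mask)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  nr <- nrow(lab); nc <- ncol(lab)
  keep <- list()
  for (id in ids) {
    idx <- which(lab == id)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    fr <- .regionFeatureRow(rows, cols, nr, nc)
    area_um2 <- fr$area_px / s^2
    if (fr$touches_border || area_um2 < min_area_um2 ||
        area_um2 > max_area_um2) {
      lab[idx] <- 0L
    } else {
      # raster position of the region's first pixel (row-major scan)
      fr$raster_key <- min((rows - 1) * nc + cols)
      fr$old_id <- id
      keep[[length(keep) + 1L]] <- fr
    }
  }
  if (!length(keep)) {
    return(new("LabeledRegions", labels = lab * 0L,
               features = .emptyFeatures(), pixelsPerMicron = s))
  }
  feats <- do.call(rbind, keep)
  feats <- feats[order(feats$raster_key), , drop = FALSE]
  relabel <- integer(max(feats$old_id))
  relabel[feats$old_id] <- seq_len(nrow(feats))
  newlab <- lab
  nz <- lab > 0L
  newlab[nz] <- relabel[lab[nz]]
  feats$label <- seq_len(nrow(feats))
  feats$raster_key <- feats$old_id <- NULL
  rownames(feats) <- NULL
  feats <- feats[, c("label", setdiff(names(feats), "label"))]
  new("LabeledRegions", labels = newlab, features = feats,
      pixelsPerMicron = s)
}

.emptyFeatures <- function() {
  data.frame(label = integer(), area_px = integer(),
             centroid_row = numeric(), centroid_col = numeric(),
             major_axis_px = numeric(), minor_axis_px = numeric(),
             orientation = numeric(), solidity = numeric(),
             touches_border = logical())
}

#' Criteria for the sagittal-plane gate
#'
#' Spores are measured only when imaged flat in the sagittal plane, so that
#' the full long-axis profile is visible. Operationally a region is accepted
#' when it is (i) solid (no concavities from overlapping or budding
#' structures), (ii) elongated like a conidium rather than circular or
#' thread-like, and (iii) well approximated by its moment-equivalent
#' ellipse.
#'
#' @param min_solidity minimum solidity (area / convex hull area).
#' @param aspect_range allowed `major/minor` axis ratio, `(min, max)` with
#'   `min >= 1`.
#' @param ellipse_residual_max maximum symmetric-difference area between the
#'   region and its fitted ellipse, as a fraction of region area.
#' @return A list of class `sagittal_criteria`.
#' @export
sagittalCriteria <- function(min_solidity = 0.90,
                             aspect_range = c(1.2, 4.0),
                             ellipse_residual_max = 0.10) {
  if (min_solidity <= 0 || min_solidity > 1)
    .stopf("min_solidity must be in (0, 1]")
  if (length(aspect_range) != 2L || aspect_range[1] < 1 ||
      aspect_range[2] <= aspect_range[1])
    .stopf("aspect_range must be (min, max) with min >= 1 and max > min")
  .checkScalar(ellipse_residual_max, "ellipse_residual_max")
  structure(list(min_solidity = min_solidity, aspect_range = aspect_range,
                 ellipse_residual_max = ellipse_residual_max),
            class = "sagittal_criteria")
}

# rasterize the fitted ellipse of region `id` and return the symmetric
# difference with the region mask, as a fraction of region area
.ellipseResidual <- function(regions, id) {
  lab <- regionLabels(regions)
  f <- regionFeatures(regions)
  fr <- f[f$label == id, ]
  a <- fr$major_axis_px / 2
  b <- fr$minor_axis_px / 2
  if (b <= 0) return(Inf)
  th <- fr$orientation
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- ceiling(a) + 2
  r0 <- max(1, floor(fr$centroid_row - pad))
  r1 <- min(nr, ceiling(fr$centroid_row + pad))
  c0 <- max(1, floor(fr$centroid_col - pad))
  c1 <- min(nc, ceiling(fr$centroid_col + pad))
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - fr$centroid_row, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - fr$centroid_col)
  # orientation measured from the column (x) axis, as in .ellipseMoments
  u <- dc * cos(th) + dr * sin(th)
  v <- -dc * sin(th) + dr * cos(th)
  inEllipse <- (u / a)^2 + (v / b)^2 <= 1
  inRegion <- lab[rows, cols] == id
  outside <- sum(lab == id) - sum(inRegion)  # region pixels outside window
  (sum(xor(inEllipse, inRegion)) + outside) / fr$area_px
}

#' Classify regions as sagittal-plane spores
#'
#' Applies the [sagittalCriteria()] gate to every region of a segmentation:
#' a region passes when `solidity >= min_solidity`, its `major/minor` aspect
#' ratio lies within `aspect_range`, and the symmetric-difference area
#' between the region and its fitted ellipse is at most
#' `ellipse_residual_max * area_px`. Degenerate regions (zero minor axis)
#' never pass.
#'
#' @param regions a [LabeledRegions-class].
#' @param criteria a [sagittalCriteria()] list.
#' @return Logical vector, one flag per region (in label order).
#' @export
classifySagittal <- function(regions, criteria = sagittalCriteria()) {
  stopifnot(is(regions, "LabeledRegions"),
            inherits(criteria, "sagittal_criteria"))
  f <- regionFeatures(regions)
  if (!nrow(f)) return(logical())
  ok <- logical(nrow(f))
  for (i in seq_len(nrow(f))) {
    if (f$minor_axis_px[i] <= 0) next
    aspect <- f$major_axis_px[i] / f$minor_axis_px[i]
    if (f$solidity[i] < criteria$min_solidity) next
    if (aspect < criteria$aspect_range[1] ||
        aspect > criteria$aspect_range[2]) next
    if (.ellipseResidual(regions, f$label[i]) >
        criteria$ellipse_residual_max) next
    ok[i] <- TRUE
  }
  ok
}

#' Measure conidia in calibrated micrometre units
#'
#' Converts the fitted-ellipse axes and the pixel count of each selected
#' region into micrometre measurements: `length_um = major_axis_px / s`,
#' `width_um = minor_axis_px / s` and `area_um2 = area_px / s^2`, with `s`
#' the calibration in px/um. Area is pixel-count based, so irregular spores
#' are measured as imaged rather than as modelled ellipses.
#'
#' @param regions a [LabeledRegions-class].
#' @param criteria sagittal gate used to flag (and by default select)
#'   measurable spores; see [classifySagittal()].
#' @param sagittal_only if `TRUE` (default) only sagittal-plane regions are
#'   returned.
#' @param isolate_id,replicate_id provenance labels copied into the output.
#' @return data.frame with columns `label`, `length_um`, `width_um`,
#'   `area_um2`, `sagittal`, `isolate`, `replicate`.
#' @examples
#' syn <- synthMicrograph(n_sagittal = 5, seed = 2)
#' regs <- segmentObjects(syn$micrograph, 1, 50)
#' measureConidia(regs, isolate_id = "Mon4x-1", replicate_id = "r1")
#' @export
measureConidia <- function(regions, criteria = sagittalCriteria(),
                           sagittal_only = TRUE,
                           isolate_id = NA_character_,
                           replicate_id = NA_character_) {
  stopifnot(is(regions, "LabeledRegions"))
  f <- regionFeatures(regions)
  s <- pixelsPerMicron(regions)
  sag <- classifySagittal(regions, criteria)
  out <- data.frame(
    label = f$label,
    length_um = f$major_axis_px / s,
    width_um = f$minor_axis_px / s,
    area_um2 = f$area_px / s^2,
    sagittal = sag,
    isolate = isolate_id,
    replicate = replicate_id
  )
  if (nrow(out) && any(out$width_um <= 0 & sag))
    .stopf("degenerate region with zero minor axis cannot be measured")
  if (sagittal_only) out <- out[out$sagittal, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Measure a conidiophore (stalk) region
#'
#' Conidiophores are elongated stalks, measured by total length along the
#' structure and by width at the basal end. The region is reduced to its
#' morphological skeleton (Zhang-Suen thinning); total length is the longest
#' geodesic path between skeleton endpoints, extended at both ends by the
#' local half-width (distance-map radius) so the measure spans the full
#' structure; the basal endpoint is the endpoint with the larger local
#' width, and `base_width_um` is the mean full width (twice the distance-map
#' radius) over the 3 skeleton pixels nearest that endpoint.
#'
#' @param regions a [LabeledRegions-class].
#' @param label region id to measure.
#' @param min_aspect minimum elongation (skeleton length over mean width)
#'   for a region to qualify as a stalk (default 2); compact blobs fail
#'   this precondition.
#' @param isolate_id,replicate_id provenance labels.
#' @return One-row data.frame with `label`, `total_length_um`,
#'   `base_width_um`, `isolate`, `replicate`.
#' @export
measureConidiophore <- function(regions, label, min_aspect = 2,
                                isolate_id = NA_character_,
                                replicate_id = NA_character_) {
  stopifnot(is(regions, "LabeledRegions"))
  f <- regionFeatures(regions)
  if (!label %in% f$label)
    .stopf("no region with label %s", label)
  s <- pixelsPerMicron(regions)
  mask <- regionLabels(regions) == label
  geo <- .skeletonGeodesic(mask)
  if (is.null(geo))
    .stopf("skeleton of region %d has no endpoints (ring-like structure)",
           label)
  # elongation measured along the skeleton, so bent stalks qualify too
  if (geo$total_length_px / geo$mean_width_px <= min_aspect)
    .stopf("region %d is not elongated (aspect <= %g); not a conidiophore",
           label, min_aspect)
  data.frame(label = as.integer(label),
             total_length_um = geo$total_length_px / s,
             base_width_um = geo$base_width_px / s,
             isolate = isolate_id, replicate = replicate_id)
}

#' Summarize a morphometric trait
#'
#' Reports the standard "mean +/- SD \[min-max\] (n)" summary used for
#' spore dimensions: sample mean, sample SD (n - 1 denominator), range and
#' count.
#'
#' @param measures data.frame of measurements (e.g. from
#'   [measureConidia()]) or a numeric vector.
#' @param trait column name when `measures` is a data.frame.
#' @return One-row data.frame `trait, mean, sd, min, max, n`.
#' @examples
#' summarizeTraits(data.frame(length_um = c(4.1, 4.4, 4.6)), "length_um")
#' @export
summarizeTraits <- function(measures, trait) {
  v <- if (is.data.frame(measures)) {
    if (!trait %in% names(measures))
      .stopf("trait '%s' not found", trait)
    measures[[trait]]
  } else as.numeric(measures)
  v <- v[!is.na(v)]
  if (!length(v))
    .stopf("cannot summarize an empty set of measurements")
  data.frame(trait = trait, mean = mean(v),
             sd = if (length(v) > 1) sd(v) else 0,
             min = min(v), max = max(v), n = length(v))
}
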