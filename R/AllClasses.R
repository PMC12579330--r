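#' @import methods
#' @importFrom stats sd var quantile median dist rnorm runif rexp pf ptukey
#'   setNames aggregate complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

#' Calibrated grayscale micrograph
#'
#' Container for a single grayscale micrograph together with its spatial
#' calibration. Intensities are stored as a numeric matrix (rows = image
#' rows, columns = image columns) on whatever scale the source file used;
#' 8- and 16-bit images read through [loadMicrograph()] arrive rescaled to
#' \[0, 1\] without loss of relative intensity. The calibration is a single
#' positive scalar in pixels per micrometre; the default used throughout the
#' package is 15.8097 px/um, the fixed magnification at which conidia are
#' photographed.
#'
#' @slot intensities numeric matrix of grayscale values.
#' @slot pixelsPerMicron positive scalar calibration (px/um).
#'
#' @seealso [loadMicrograph()], [segmentObjects()]
#' @export
setClass("Micrograph",
  representation(intensities = "matrix", pixelsPerMicron = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@intensities)
    if (any(d < 3L))
      msg <- c(msg, "micrograph must be at least 3x3 pixels")
    if (!all(is.finite(object@intensities)))
      msg <- c(msg, "intensities must be finite")
    if (length(object@pixelsPerMicron) != 1L ||
        !is.finite(object@pixelsPerMicron) || object@pixelsPerMicron <= 0)
      msg <- c(msg, "pixelsPerMicron must be a single positive number")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a Micrograph from a matrix
#'
#' @param intensities numeric matrix of grayscale values.
#' @param pixelsPerMicron calibration in pixels per micrometre (> 0).
#' @return A [Micrograph-class] object.
#' @examples
#' mg <- Micrograph(matrix(runif(64 * 64), 64, 64), 15.8097)
#' dim(mg)
#' @export
Micrograph <- function(intensities, pixelsPerMicron = 15.8097) {
  storage.mode(intensities) <- "double"
  new("Micrograph", intensities = intensities,
      pixelsPerMicron = as.numeric(pixelsPerMicron))
}

#' @describeIn Micrograph image dimensions (rows, columns)
#' @param x a `Micrograph`
#' @export
setMethod("dim", "Micrograph", function(x) dim(x@intensities))

#' Accessors for Micrograph and LabeledRegions
#'
#' `intensities()` returns the raw grayscale matrix; `pixelsPerMicron()` the
#' spatial calibration; `regionLabels()` the integer label matrix of a
#' segmentation (0 = background); `regionFeatures()` the per-region feature
#' table.
#'
#' @param x a [Micrograph-class] or [LabeledRegions-class] object.
#' @return See individual descriptions.
#' @name morphometry-accessors
NULL

#' @rdname morphometry-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname morphometry-accessors
#' @export
setMethod("intensities", "Micrograph", function(x) x@intensities)

#' @rdname morphometry-accessors
#' @export
setGeneric("pixelsPerMicron", function(x) standardGeneric("pixelsPerMicron"))
#' @rdname morphometry-accessors
#' @export
setMethod("pixelsPerMicron", "Micrograph", function(x) x@pixelsPerMicron)

setMethod("show", "Micrograph", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("Micrograph: %d x %d px, %.4f px/um (%.1f x %.1f um)\n",
              d[1], d[2], object@pixelsPerMicron,
              d[1] / object@pixelsPerMicron, d[2] / object@pixelsPerMicron))
  r <- range(object@intensities)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", r[1], r[2]))
})

#' Labelled segmentation of a micrograph
#'
#' Result of [segmentObjects()]: an integer label matrix (0 background,
#' 1..k objects in raster order) plus a per-region feature table with one
#' row per retained region. Columns of `features`:
#' \describe{
#'   \item{label}{integer region id, matching the label matrix}
#'   \item{area_px}{pixel count}
#'   \item{centroid_row, centroid_col}{intensity-free centroid, pixel units}
#'   \item{major_axis_px, minor_axis_px}{full axis lengths of the
#'     moment-equivalent ellipse}
#'   \item{orientation}{major-axis angle, radians}
#'   \item{solidity}{area / convex hull area, in (0, 1]}
#'   \item{touches_border}{whether the region touches the image border
#'     (such regions are never retained by `segmentObjects`)}
#' }
#'
#' @slot labels integer matrix of region labels.
#' @slot features data.frame of per-region properties.
#' @slot pixelsPerMicron calibration inherited from the source micrograph.
#' @export
setClass("LabeledRegions",
  representation(labels = "matrix", features = "data.frame",
                 pixelsPerMicron = "numeric"),
  validity = function(object) {
    msg <- character()
    k <- nrow(object@features)
    if (k > 0) {
      if (!identical(sort(unique(as.integer(object@features$label))),
                     seq_len(k)))
        msg <- c(msg, "feature labels must be 1..k")
      if (any(object@features$area_px < 1))
        msg <- c(msg, "regions must contain at least one pixel")
      if (any(object@features$solidity > 1 + 1e-9))
        msg <- c(msg, "solidity cannot exceed 1")
      if (any(object@features$minor_axis_px >
              object@features$major_axis_px + 1e-9))
        msg <- c(msg, "major axis must be >= minor axis")
    }
    if (object@pixelsPerMicron <= 0)
      msg <- c(msg, "pixelsPerMicron must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname morphometry-accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname morphometry-accessors
#' @export
setMethod("regionLabels", "LabeledRegions", function(x) x@labels)

#' @rdname morphometry-accessors
#' @export
setGeneric("regionFeatures", function(x) standardGeneric("regionFeatures"))
#' @rdname morphometry-accessors
#' @export
setMethod("regionFeatures", "LabeledRegions", function(x) x@features)

#' @rdname morphometry-accessors
#' @export
setMethod("pixelsPerMicron", "LabeledRegions", function(x) x@pixelsPerMicron)

#' @describeIn LabeledRegions number of retained regions
#' @param x a `LabeledRegions`
#' @export
setMethod("length", "LabeledRegions", function(x) nrow(x@features))

setMethod("show", "LabeledRegions", function(object) {
  cat(sprintf("LabeledRegions: %d region(s), %.4f px/um\n",
              nrow(object@features), object@pixelsPerMicron))
  if (nrow(object@features))
    print(head(object@features, 6))
})

#' Flow-cytometry event histogram
#'
#' Fluorescence-channel histogram of nuclei counts: strictly increasing
#' channel bin centres and a non-negative integer count per channel. The
#' usual source is [readCytometry()] (delimited histogram or event-list
#' files) or the simulator [synthFcHistogram()].
#'
#' @slot channels strictly increasing numeric bin centres.
#' @slot counts non-negative counts, same length as `channels`.
#' @export
setClass("EventHistogram",
  representation(channels = "numeric", counts = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@channels) != length(object@counts))
      msg <- c(msg, "channels and counts must have equal length")
    if (length(object@channels) < 2L)
      msg <- c(msg, "need at least 2 channels")
    if (any(diff(object@channels) <= 0))
      msg <- c(msg, "channels must be strictly increasing")
    if (any(object@counts < 0) || any(object@counts != round(object@counts)))
      msg <- c(msg, "counts must be non-negative integers")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an EventHistogram
#'
#' @param channels strictly increasing numeric bin centres.
#' @param counts non-negative integer counts per channel.
#' @return An [EventHistogram-class] object.
#' @examples
#' h <- EventHistogram(1:10, c(0, 1, 4, 9, 12, 9, 4, 1, 0, 0))
#' totalEvents(h)
#' @export
EventHistogram <- function(channels, counts) {
  new("EventHistogram", channels = as.numeric(channels),
      counts = as.numeric(counts))
}

#' Accessors for EventHistogram
#'
#' @param x an [EventHistogram-class] object.
#' @return `channels()`: bin centres; `counts()`: per-bin counts;
#'   `totalEvents()`: total number of events.
#' @name cytometry-accessors
NULL

#' @rdname cytometry-accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname cytometry-accessors
#' @export
setMethod("channels", "EventHistogram", function(x) x@channels)

#' @rdname cytometry-accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname cytometry-accessors
#' @export
setMethod("counts", "EventHistogram", function(x) x@counts)

#' @rdname cytometry-accessors
#' @export
setGeneric("totalEvents", function(x) standardGeneric("totalEvents"))
#' @rdname cytometry-accessors
#' @export
setMethod("totalEvents", "EventHistogram", function(x) sum(x@counts))

setMethod("show", "EventHistogram", function(object) {
  cat(sprintf(
    "EventHistogram: %d channels in [%.3g, %.3g], %d events\n",
    length(object@channels), min(object@channels), max(object@channels),
    sum(object@counts)))
})
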