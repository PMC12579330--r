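# Morphological skeleton utilities for stalk-like structures.
#
# Zhang-Suen thinning (vectorized over the whole mask per sub-iteration)
# followed by longest-geodesic-path extraction on the 8-connected skeleton
# graph. Lengths are in pixels; the caller applies the um calibration.

#' Thin a binary mask to its morphological skeleton
#'
#' Zhang-Suen iterative thinning. The result is an 8-connected,
#' 1-pixel-wide skeleton preserving the topology of the input mask.
#'
#' @param mask logical (or 0/1) matrix.
#' @return Logical matrix of the same dimension.
#' @export
thinMask <- function(mask) {
  m <- (mask != 0) * 1L
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(m == 1L)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  shift <- function(p, dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad
      p2 <- shift(p, -1, 0); p3 <- shift(p, -1, 1); p4 <- shift(p, 0, 1)
      p5 <- shift(p, 1, 1);  p6 <- shift(p, 1, 0);  p7 <- shift(p, 1, -1)
      p8 <- shift(p, 0, -1); p9 <- shift(p, -1, -1)
      ctr <- p[2:(nr + 1), 2:(nc + 1)]
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      # number of 0->1 transitions in the ordered neighbour ring
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- ctr == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- ctr == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        changed <- TRUE
        ctr[cond] <- 0L
        pad[2:(nr + 1), 2:(nc + 1)] <- ctr
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1), 2:(nc + 1)] == 1L
}

# Longest geodesic path along the skeleton of `mask`, plus base width.
# Returns NULL when the skeleton has no endpoints (a ring).
.skeletonGeodesic <- function(mask) {
  skel <- thinMask(mask)
  idx <- which(skel)
  if (length(idx) == 0L) return(NULL)
  nr <- nrow(skel)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  n <- length(idx)
  # half-width (radius) at every mask pixel via Euclidean distance map
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  radius <- dm[idx]
  if (n == 1L) {
    return(list(total_length_px = 2 * radius, base_width_px = 2 * radius,
                mean_width_px = 2 * radius))
  }
  key <- (cols - 1L) * nr + rows
  from <- integer(0); to <- integer(0); w <- numeric(0)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (k in seq_len(nrow(offs))) {
    r2 <- rows + offs[k, 1]; c2 <- cols + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(skel)
    j <- rep(NA_integer_, n)
    j[ok] <- match((c2[ok] - 1L) * nr + r2[ok], key)
    sel <- which(!is.na(j) & j > seq_len(n))
    if (length(sel)) {
      from <- c(from, sel); to <- c(to, j[sel])
      w <- c(w, rep(sqrt(sum(offs[k, ]^2)), length(sel)))
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  deg <- igraph::degree(g)
  endpoints <- which(deg <= 1)
  if (length(endpoints) == 0L) return(NULL)
  # longest geodesic between endpoints
  d <- igraph::distances(g, v = endpoints, to = endpoints)
  d[!is.finite(d)] <- -Inf
  best <- which(d == max(d), arr.ind = TRUE)[1, ]
  e1 <- endpoints[best[1]]; e2 <- endpoints[best[2]]
  path_len <- max(d)
  if (!is.finite(path_len)) path_len <- 0
  # extend by the local radius at both ends to span the full structure
  total <- path_len + radius[e1] + radius[e2]
  # basal endpoint: larger local width over its 3 nearest skeleton pixels
  widthNear <- function(e) {
    dd <- sqrt((rows - rows[e])^2 + (cols - cols[e])^2)
    mean(2 * radius[order(dd)[seq_len(min(3, n))]])
  }
  w1 <- widthNear(e1); w2 <- widthNear(e2)
  list(total_length_px = total, base_width_px = max(w1, w2),
       mean_width_px = mean(2 * radius))
}
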