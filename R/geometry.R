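# Shape-descriptor geometry shared by the vesicle and bead modules.
#
# All pixel coordinates are 1-based (row, col) matrix indices. Feret
# (caliper) diameters are computed on the convex hull of pixel centres,
# with one pixel width added to every caliper to account for the finite
# extent of the pixels themselves: a single pixel then has a Feret
# diameter of 1 px (not 0), a straight run of n pixels measures n px,
# and a rasterized disc of radius r measures 2r within quantization
# error.

#' Maximum and minimum Feret (caliper) diameters of a pixel region
#'
#' The maximum Feret diameter is the largest distance between two pixel
#' centres of the region's convex hull, plus 1 px of pixel extent; the
#' minimum Feret diameter (minimum width) is found by rotating calipers:
#' for each hull edge, the width of the hull perpendicular to that edge
#' is computed, the minimum over edges is taken, and 1 px is added.
#' Results are in pixel units; a single pixel yields `c(max = 1,
#' min = 1)`.
#'
#' @param pixels integer matrix with columns `row`, `col` (1-based pixel
#'   centres).
#' @return named numeric vector `c(max = , min = )` in pixel units.
#' @export
feret_diameters <- function(pixels) {
  stopifnot(is.matrix(pixels), ncol(pixels) == 2, nrow(pixels) >= 1)
  hull_idx <- grDevices::chull(pixels[, 1], pixels[, 2])
  h <- pixels[hull_idx, , drop = FALSE]
  n <- nrow(h)
  if (n == 1L) return(c(max = 1, min = 1))
  if (n == 2L) {
    d <- sqrt(sum((h[1, ] - h[2, ])^2))
    return(c(max = d + 1, min = 1))
  }
  # max caliper: largest pairwise distance among hull vertices
  dmax <- max(stats::dist(h))
  # min caliper: smallest hull width over directions normal to hull edges
  nxt <- c(2:n, 1L)
  ex <- h[nxt, 1] - h[, 1]
  ey <- h[nxt, 2] - h[, 2]
  len <- sqrt(ex^2 + ey^2)
  keep <- len > 0
  nx <- -ey[keep] / len[keep]
  ny <- ex[keep] / len[keep]
  # projections of all hull vertices onto each edge normal
  proj <- outer(nx, h[, 1]) + outer(ny, h[, 2])  # edges x vertices
  widths <- apply(proj, 1L, max) - apply(proj, 1L, min)
  c(max = dmax + 1, min = min(widths) + 1)
}

#' Brute-force Feret oracle by direction scanning
#'
#' Projects the region's pixel centres onto `n_angles` evenly spaced
#' directions in `[0, pi)` and takes the extreme projection widths (plus
#' the same 1 px pixel-extent term used by [feret_diameters()]). Used as
#' an independent check of the rotating-calipers implementation;
#' accuracy is limited by the angular step.
#'
#' @inheritParams feret_diameters
#' @param n_angles number of directions scanned.
#' @return named numeric vector `c(max = , min = )`.
#' @export
feret_diameters_scan <- function(pixels, n_angles = 3600L) {
  stopifnot(is.matrix(pixels), ncol(pixels) == 2, nrow(pixels) >= 1)
  hull_idx <- grDevices::chull(pixels[, 1], pixels[, 2])
  h <- pixels[hull_idx, , drop = FALSE]
  if (nrow(h) == 1L) return(c(max = 1, min = 1))
  theta <- seq(0, pi, length.out = n_angles + 1L)[seq_len(n_angles)]
  proj <- outer(cos(theta), h[, 1]) + outer(sin(theta), h[, 2])
  widths <- apply(proj, 1L, max) - apply(proj, 1L, min)
  c(max = max(widths) + 1, min = min(widths) + 1)
}

#' Roundness of a region
#'
#' `4 * area / (pi * feret_max^2)`: equals 1 for a circle and decreases
#' with elongation. `area` and `feret_max` must be in consistent units.
#'
#' @param area region area.
#' @param feret_max maximum Feret diameter.
#' @return dimensionless roundness.
#' @export
roundness_feret <- function(area, feret_max) {
  4 * area / (pi * feret_max^2)
}

# 8-connected component labelling. EBImage::bwlabel() is 4-connected;
# labels whose pixels touch diagonally are merged with a union-find pass,
# then relabelled 1..k in row-major order of each component's first pixel.
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(mask != 0)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nmax <- max(lab)
  if (nmax == 0L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour label pairs
  p1 <- cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1]))
  p2 <- cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))
  pairs <- rbind(p1, p2)
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(nmax)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- find_root(pairs[k, 1]); b <- find_root(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nmax), find_root, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  relabel_row_major(lab)
}

# Relabel positive labels to consecutive integers ordered by the
# row-major position (row, then column) of each component's first pixel.
relabel_row_major <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  nc <- ncol(lab)
  first_pos <- vapply(ids, function(id) {
    w <- which(lab == id)
    r <- (w - 1L) %% nrow(lab) + 1L
    c_ <- (w - 1L) %/% nrow(lab) + 1L
    min((r - 1L) * nc + (c_ - 1L))
  }, numeric(1))
  ord <- ids[order(first_pos)]
  out <- lab
  for (i in seq_along(ord)) out[lab == ord[i]] <- i
  out
}

# Pixel coordinates (row, col) of a label in a label image.
label_pixels <- function(lab, id) {
  w <- which(lab == id)
  cbind(row = (w - 1L) %% nrow(lab) + 1L,
        col = (w - 1L) %/% nrow(lab) + 1L)
}
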