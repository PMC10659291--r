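# Synthetic scene generators with exact ground truth.
#
# These emulate the statistical structure of the study inputs — EM
# micrographs of bright-rimmed vesicles (discs and spherocylinders),
# membrane fields with a known foreground fraction, two-channel resin
# bead images with known signal/reference ratios, and protein sequences
# with planted CRAC/CARC motifs — so every downstream stage can be
# verified against analytic truth rather than curated images.

#' Disc shape for a vesicle scene
#'
#' @param center numeric length-2, (row, col) centre in pixel units
#'   (pixel (i, j) has its centre at (i, j)).
#' @param radius disc radius in px, > 0.
#' @export
disc_shape <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = c("disc_shape", "ev_shape"))
}

#' Spherocylinder (stadium) shape for a vesicle scene
#'
#' A rectangle of length `axis_length - width` capped by two half-discs
#' of diameter `width`; `axis_length` is the cap-to-cap (tip-to-tip)
#' length, so `axis_length >= width` and the degenerate case equals a
#' disc. Continuous area is `w * (L - w) + pi * (w/2)^2`; the maximum and
#' minimum Feret diameters are `L` and `w`.
#'
#' @param center (row, col) centre in px.
#' @param axis_length cap-to-cap length L in px.
#' @param width tube width w in px.
#' @param orientation long-axis angle in radians (0 = along image rows).
#' @export
spherocylinder_shape <- function(center, axis_length, width, orientation = 0) {
  stopifnot(length(center) == 2, width > 0, axis_length >= width)
  structure(list(center = as.numeric(center),
                 axis_length = as.numeric(axis_length),
                 width = as.numeric(width),
                 orientation = as.numeric(orientation)),
            class = c("spherocylinder_shape", "ev_shape"))
}

# Signed distance (negative inside) from pixel centres to the shape
# boundary, over the full image grid. Returned as a matrix.
shape_signed_distance <- function(shape, nrow_img, ncol_img) {
  rr <- matrix(seq_len(nrow_img), nrow_img, ncol_img)
  cc <- matrix(rep(seq_len(ncol_img), each = nrow_img), nrow_img, ncol_img)
  if (inherits(shape, "disc_shape")) {
    d <- sqrt((rr - shape$center[1])^2 + (cc - shape$center[2])^2)
    return(d - shape$radius)
  }
  # spherocylinder: distance to core segment minus half-width
  half <- (shape$axis_length - shape$width) / 2
  dr <- cos(shape$orientation); dc <- sin(shape$orientation)
  a <- c(shape$center[1] - half * dr, shape$center[2] - half * dc)
  b <- c(shape$center[1] + half * dr, shape$center[2] + half * dc)
  vr <- b[1] - a[1]; vc <- b[2] - a[2]
  len2 <- vr^2 + vc^2
  if (len2 == 0) {
    d <- sqrt((rr - a[1])^2 + (cc - a[2])^2)
  } else {
    t <- ((rr - a[1]) * vr + (cc - a[2]) * vc) / len2
    t <- pmin(pmax(t, 0), 1)
    d <- sqrt((rr - (a[1] + t * vr))^2 + (cc - (a[2] + t * vc))^2)
  }
  d - shape$width / 2
}

# Continuous-geometry ground truth for one shape.
shape_truth <- function(shape) {
  if (inherits(shape, "disc_shape")) {
    data.frame(shape = "disc",
               area_px2 = pi * shape$radius^2,
               feret_max_px = 2 * shape$radius,
               feret_min_px = 2 * shape$radius)
  } else {
    w <- shape$width; L <- shape$axis_length
    data.frame(shape = "spherocylinder",
               area_px2 = w * (L - w) + pi * (w / 2)^2,
               feret_max_px = L,
               feret_min_px = w)
  }
}

# Axis-aligned bounding box of the continuous shape (row/col extents).
shape_bbox <- function(shape) {
  if (inherits(shape, "disc_shape")) {
    r <- shape$radius
    c(rmin = shape$center[1] - r, rmax = shape$center[1] + r,
      cmin = shape$center[2] - r, cmax = shape$center[2] + r)
  } else {
    half <- (shape$axis_length - shape$width) / 2
    dr <- cos(shape$orientation) * half; dc <- sin(shape$orientation) * half
    w2 <- shape$width / 2
    c(rmin = shape$center[1] - abs(dr) - w2, rmax = shape$center[1] + abs(dr) + w2,
      cmin = shape$center[2] - abs(dc) - w2, cmax = shape$center[2] + abs(dc) + w2)
  }
}

#' Specification of a synthetic vesicle micrograph
#'
#' @param image_shape integer length-2 `(rows, cols)` in px.
#' @param shapes list of [disc_shape()] / [spherocylinder_shape()] objects.
#' @param pixel_size_nm physical pixel size, nm/px.
#' @param rim_width_px membrane-rim thickness in px, >= 1.
#' @param background background intensity level.
#' @param contrast rim intensity minus background; signed, so both stain
#'   polarities (bright or dark membranes) can be emulated.
#' @param noise_sd standard deviation of additive Gaussian noise, >= 0.
#' @param seed integer RNG seed; identical spec + seed give bit-identical
#'   scenes.
#' @param allow_overlap if `FALSE` (default), overlapping shapes raise an
#'   error, keeping per-object ground truth exact.
#' @return object of class `vesicle_scene_spec`.
#' @export
vesicle_scene_spec <- function(image_shape, shapes, pixel_size_nm = 1,
                               rim_width_px = 3, background = 100,
                               contrast = 100, noise_sd = 0, seed = 1L,
                               allow_overlap = FALSE) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 16),
            pixel_size_nm > 0, rim_width_px >= 1, noise_sd >= 0,
            length(shapes) >= 0)
  for (s in shapes) stopifnot(inherits(s, "ev_shape"))
  structure(list(image_shape = as.integer(image_shape), shapes = shapes,
                 pixel_size_nm = pixel_size_nm, rim_width_px = rim_width_px,
                 background = background, contrast = contrast,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 allow_overlap = isTRUE(allow_overlap)),
            class = "vesicle_scene_spec")
}

#' Render a synthetic vesicle micrograph with exact ground truth
#'
#' Each shape is drawn filled, with an interior at half the rim contrast
#' and a rim of width `rim_width_px` at full contrast, so that in a
#' noise-free scene the set of pixels differing from background equals
#' the label mask exactly. A pixel belongs to a shape iff its centre lies
#' strictly inside the continuous outline. The ground-truth table carries
#' the continuous (analytic) area and Feret diameters; rasterized masks
#' agree with these within quantization error (about 1% for features
#' >= 20 px). Shapes whose continuous outline extends past the image
#' rectangle are rendered clipped and flagged `truncated`.
#'
#' @param spec a [vesicle_scene_spec()].
#' @return list with elements `micrograph` (a [micrograph()]), `labels`
#'   (integer label matrix, one positive label per shape in input order)
#'   and `truth` (data.frame: `label`, `shape`, `area_px2`,
#'   `feret_max_px`, `feret_min_px`, `truncated`).
#' @export
render_vesicle_scene <- function(spec) {
  stopifnot(inherits(spec, "vesicle_scene_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  img <- matrix(spec$background, nr, nc)
  labels <- matrix(0L, nr, nc)
  truth <- NULL
  for (i in seq_along(spec$shapes)) {
    s <- spec$shapes[[i]]
    sd_field <- shape_signed_distance(s, nr, nc)
    inside <- sd_field < 0
    if (!spec$allow_overlap && any(labels[inside] != 0L)) {
      stop("shapes ", unique(labels[inside][labels[inside] != 0L])[1], " and ",
           i, " overlap; set allow_overlap = TRUE to permit this")
    }
    rim <- inside & (sd_field >= -spec$rim_width_px)
    core <- inside & !rim
    img[rim] <- spec$background + spec$contrast
    img[core] <- spec$background + spec$contrast / 2
    labels[inside] <- i
    bb <- shape_bbox(s)
    truncated <- bb["rmin"] < 0.5 || bb["rmax"] > nr + 0.5 ||
      bb["cmin"] < 0.5 || bb["cmax"] > nc + 0.5
    tr <- shape_truth(s)
    tr$label <- i
    tr$truncated <- truncated
    truth <- rbind(truth, tr)
  }
  if (is.null(truth)) {
    truth <- data.frame(shape = character(), area_px2 = numeric(),
                        feret_max_px = numeric(), feret_min_px = numeric(),
                        label = integer(), truncated = logical())
  }
  truth <- truth[, c("label", "shape", "area_px2", "feret_max_px",
                     "feret_min_px", "truncated")]
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  }
  list(micrograph = micrograph(img, pixel_size_nm = spec$pixel_size_nm,
                               source_id = sprintf("synthetic_seed%d", spec$seed),
                               modality = "synthetic"),
       labels = labels, truth = truth)
}

#' Specification of a synthetic two-channel bead scene
#'
#' @param image_shape `(rows, cols)` in px.
#' @param beads data.frame with columns `row`, `col`, `radius`,
#'   `reference_intensity` (>= 0) and `ratio` (finite, >= 0).
#' @param artifacts optional data.frame with columns `row`, `col`,
#'   `radius`, `channel` (`"reference"`, `"signal"` or `"both"`) and
#'   `intensity`; rendered only in the designated channel(s).
#' @param background_reference,background_signal per-channel constant
#'   background levels, >= 0.
#' @param noise_sd Gaussian noise SD added independently per channel.
#' @param seed integer RNG seed.
#' @export
bead_scene_spec <- function(image_shape, beads, artifacts = NULL,
                            background_reference = 0, background_signal = 0,
                            noise_sd = 0, seed = 1L) {
  stopifnot(length(image_shape) == 2, is.data.frame(beads),
            all(c("row", "col", "radius", "reference_intensity", "ratio") %in%
                  names(beads)),
            all(beads$radius > 0), all(is.finite(beads$ratio)),
            all(beads$ratio >= 0), all(beads$reference_intensity >= 0),
            background_reference >= 0, background_signal >= 0, noise_sd >= 0)
  if (!is.null(artifacts)) {
    stopifnot(is.data.frame(artifacts),
              all(c("row", "col", "radius", "channel", "intensity") %in%
                    names(artifacts)),
              all(artifacts$channel %in% c("reference", "signal", "both")))
  }
  structure(list(image_shape = as.integer(image_shape), beads = beads,
                 artifacts = artifacts,
                 background_reference = background_reference,
                 background_signal = background_signal,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "bead_scene_spec")
}

#' Render a synthetic two-channel bead scene
#'
#' Each bead is a uniform disc: reference intensity `R` in the reference
#' channel and `ratio * R` in the signal channel, added on the
#' per-channel background. Artifacts appear only in their designated
#' channel(s). Per-channel Gaussian noise is then added. Beads fully
#' outside the image raise an error.
#'
#' @param spec a [bead_scene_spec()].
#' @return list with `reference` and `signal` intensity matrices and
#'   `truth` (the bead table with a `bead_id` column, plus the artifact
#'   table as attribute `"artifacts"`).
#' @export
render_bead_scene <- function(spec) {
  stopifnot(inherits(spec, "bead_scene_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  ref <- matrix(spec$background_reference, nr, nc)
  sig <- matrix(spec$background_signal, nr, nc)
  add_disc <- function(img, row, col, radius, value) {
    d <- shape_signed_distance(disc_shape(c(row, col), radius), nr, nc)
    img[d < 0] <- img[d < 0] + value
    img
  }
  for (i in seq_len(nrow(spec$beads))) {
    b <- spec$beads[i, ]
    if (b$row + b$radius < 0.5 || b$row - b$radius > nr + 0.5 ||
        b$col + b$radius < 0.5 || b$col - b$radius > nc + 0.5) {
      stop("bead ", i, " lies fully outside the image")
    }
    ref <- add_disc(ref, b$row, b$col, b$radius, b$reference_intensity)
    sig <- add_disc(sig, b$row, b$col, b$radius, b$ratio * b$reference_intensity)
  }
  if (!is.null(spec$artifacts)) {
    for (i in seq_len(nrow(spec$artifacts))) {
      a <- spec$artifacts[i, ]
      if (a$channel %in% c("reference", "both")) {
        ref <- add_disc(ref, a$row, a$col, a$radius, a$intensity)
      }
      if (a$channel %in% c("signal", "both")) {
        sig <- add_disc(sig, a$row, a$col, a$radius, a$intensity)
      }
    }
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    ref <- ref + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    sig <- sig + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  }
  truth <- cbind(bead_id = seq_len(nrow(spec$beads)), spec$beads)
  attr(truth, "artifacts") <- spec$artifacts
  list(reference = ref, signal = sig, truth = truth)
}

#' Render a synthetic membrane field with a known foreground fraction
#'
#' Foreground structure is generated by thresholding smoothed Gaussian
#' noise (blob size set by `texture_px`) at the order statistic that
#' yields exactly `round(target_fraction * n_pixels)` foreground pixels,
#' so the true mask fraction matches the target to within 1/n_pixels.
#' The image is drawn at `background` intensity with foreground raised by
#' `contrast`, then Gaussian observation noise is added.
#'
#' @param image_shape `(rows, cols)` in px.
#' @param target_fraction desired foreground pixel fraction in `[0, 1]`.
#' @param texture_px Gaussian smoothing sigma controlling blob size.
#' @param background,contrast intensity levels.
#' @param noise_sd observation noise SD.
#' @param seed integer RNG seed.
#' @return list with `image` (matrix) and `mask` (logical matrix, the
#'   true foreground).
#' @export
render_membrane_field <- function(image_shape, target_fraction,
                                  texture_px = 8, background = 100,
                                  contrast = 100, noise_sd = 0, seed = 1L) {
  stopifnot(length(image_shape) == 2, target_fraction >= 0,
            target_fraction <= 1, texture_px > 0, noise_sd >= 0)
  nr <- image_shape[1]; nc <- image_shape[2]
  n <- nr * nc
  set.seed(seed)
  field <- matrix(stats::rnorm(n), nr, nc)
  field <- EBImage::gblur(field, sigma = texture_px)
  field <- matrix(as.numeric(field), nr, nc)
  k <- round(target_fraction * n)
  mask <- matrix(FALSE, nr, nc)
  if (k >= n) {
    mask[] <- TRUE
  } else if (k > 0) {
    cutoff <- sort(field, decreasing = TRUE)[k]
    mask <- field >= cutoff
    # guard against ties at the cutoff
    if (sum(mask) > k) {
      idx <- order(field, decreasing = TRUE)[seq_len(k)]
      mask[] <- FALSE
      mask[idx] <- TRUE
    }
  }
  img <- background + contrast * mask
  if (noise_sd > 0) {
    img <- img + matrix(stats::rnorm(n, 0, noise_sd), nr, nc)
  }
  list(image = img, mask = mask)
}

# ---- motif sequence generation -------------------------------------------

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
MOTIF_ANCHOR_RESIDUES <- c("L", "V", "Y", "F", "K", "R")

# Anchor residue classes for CRAC ([L/V]-X1-5-[Y/F]-X1-5-[K/R]) and its
# mirror CARC ([K/R]-X1-5-[Y/F]-X1-5-[L/V]).
motif_anchor_classes <- function(motif_type) {
  motif_type <- match.arg(motif_type, c("CRAC", "CARC"))
  if (motif_type == "CRAC") {
    list(p1 = c("L", "V"), arom = c("Y", "F"), p3 = c("K", "R"))
  } else {
    list(p1 = c("K", "R"), arom = c("Y", "F"), p3 = c("L", "V"))
  }
}

# Exhaustive triple-loop motif enumeration; deliberately naive, used as
# the ground-truth oracle for the vectorized scanner.
motif_scan_bruteforce <- function(residues, motif_type) {
  cls <- motif_anchor_classes(motif_type)
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars)
  hits <- list()
  if (L >= 5) {
    for (i in seq_len(L)) {
      if (!(chars[i] %in% cls$p1)) next
      for (j in seq_len(L)) {
        if (!(chars[j] %in% cls$arom)) next
        if (j - i < 2 || j - i > 6) next
        for (k in seq_len(L)) {
          if (!(chars[k] %in% cls$p3)) next
          if (k - j < 2 || k - j > 6) next
          hits[[length(hits) + 1L]] <- c(i, j, k)
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(motif_type = character(), start = integer(),
                      end = integer(), p1 = integer(), p_aromatic = integer(),
                      p3 = integer(), match = character()))
  }
  m <- do.call(rbind, hits)
  out <- data.frame(motif_type = motif_type, start = m[, 1], end = m[, 3],
                    p1 = m[, 1], p_aromatic = m[, 2], p3 = m[, 3],
                    match = vapply(seq_len(nrow(m)), function(r)
                      substr(residues, m[r, 1], m[r, 3]), character(1)))
  out[order(out$start, out$end, out$p_aromatic), , drop = FALSE]
}

#' Generate protein sequences with planted CRAC/CARC motifs
#'
#' Background residues are sampled uniformly from `alphabet`; in strict
#' mode the background alphabet excludes all motif anchor residues
#' (L, V, Y, F, K, R), so the only pattern matches are the planted ones.
#' Each planted motif is a minimal-form instance (anchor, spacer,
#' aromatic, spacer, anchor) with the requested spacer lengths, anchors
#' sampled from the motif's residue classes and spacers from the
#' background alphabet. The ground truth lists *every* span matching the
#' pattern, found by exhaustive enumeration — so in non-strict mode
#' incidental background matches are listed too.
#'
#' @param n number of sequences.
#' @param length sequence length (all sequences equal length).
#' @param planted data.frame with columns `seq` (index 1..n), `type`
#'   (`"CRAC"`/`"CARC"`), `start` (1-based), and optional `spacer1`,
#'   `spacer2` (each 1..5, default 1). May be `NULL` for none.
#' @param strict if `TRUE`, background residues avoid motif anchor
#'   classes entirely.
#' @param alphabet residue alphabet for background sampling (default the
#'   20 standard amino acids).
#' @param seed integer RNG seed.
#' @return list with `sequences` (named character vector, names
#'   `"seq1"...`) and `truth` (data.frame of all pattern matches:
#'   `seq_id`, `motif_type`, `start`, `end`, `p1`, `p_aromatic`, `p3`,
#'   `match`).
#' @export
generate_motif_sequences <- function(n, length, planted = NULL,
                                     strict = TRUE, alphabet = AMINO_ACIDS,
                                     seed = 1L) {
  stopifnot(n >= 0, length >= 0)
  set.seed(seed)
  bg <- if (strict) setdiff(alphabet, MOTIF_ANCHOR_RESIDUES) else alphabet
  seqs <- character(n)
  for (s in seq_len(n)) {
    seqs[s] <- paste(sample(bg, length, replace = TRUE), collapse = "")
  }
  if (!is.null(planted) && nrow(planted) > 0) {
    stopifnot(all(c("seq", "type", "start") %in% names(planted)))
    if (is.null(planted$spacer1)) planted$spacer1 <- 1L
    if (is.null(planted$spacer2)) planted$spacer2 <- 1L
    stopifnot(all(planted$spacer1 >= 1), all(planted$spacer1 <= 5),
              all(planted$spacer2 >= 1), all(planted$spacer2 <= 5))
    for (i in seq_len(nrow(planted))) {
      p <- planted[i, ]
      cls <- motif_anchor_classes(p$type)
      motif <- c(sample(cls$p1, 1),
                 sample(bg, p$spacer1, replace = TRUE),
                 sample(cls$arom, 1),
                 sample(bg, p$spacer2, replace = TRUE),
                 sample(cls$p3, 1))
      end <- p$start + length(motif) - 1L
      if (p$start < 1 || end > length) {
        stop("planted motif ", i, " does not fit in sequence of length ", length)
      }
      chars <- strsplit(seqs[p$seq], "")[[1]]
      chars[p$start:end] <- motif
      seqs[p$seq] <- paste(chars, collapse = "")
    }
  }
  names(seqs) <- if (n > 0) paste0("seq", seq_len(n)) else character(0)
  truth <- NULL
  for (s in seq_len(n)) {
    for (ty in c("CRAC", "CARC")) {
      h <- motif_scan_bruteforce(seqs[[s]], ty)
      if (nrow(h) > 0) truth <- rbind(truth, cbind(seq_id = names(seqs)[s], h))
    }
  }
  if (is.null(truth)) {
    truth <- data.frame(seq_id = character(), motif_type = character(),
                        start = integer(), end = integer(), p1 = integer(),
                        p_aromatic = integer(), p3 = integer(),
                        match = character())
  }
  list(sequences = seqs, truth = truth)
}
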