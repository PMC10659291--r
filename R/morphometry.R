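# Vesicle segmentation and per-vesicle shape descriptors.
#
# The measurement chain mirrors how EV micrographs are quantified:
# segment vesicles into labelled regions, compute area / equivalent
# diameter / Feret calipers / roundness per region, classify morphology
# (tubular, non-round, spherical) for fully visible vesicles only, and
# summarize the population. Diameters are reported for all vesicles,
# including those clipped by the image border; roundness-based
# classification is restricted to vesicles completely visible in the
# field of view.

#' Construct a micrograph
#'
#' @param pixels numeric matrix of intensities (rows x cols), at least
#'   16 x 16.
#' @param pixel_size_nm physical pixel size in nm/px, > 0.
#' @param source_id identifier carried into per-vesicle tables.
#' @param modality one of `"NS-TEM"`, `"cryo-TEM"`, `"synthetic"`.
#' @return object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size_nm, source_id = "micrograph",
                       modality = c("synthetic", "NS-TEM", "cryo-TEM")) {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix")
  }
  if (nrow(pixels) < 16 || ncol(pixels) < 16) {
    stop("micrograph must be at least 16 x 16 px")
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("pixel_size_nm must be a single positive number")
  }
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 source_id = source_id, modality = modality),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph '%s'> %d x %d px, %.4g nm/px, %s\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_nm, x$modality))
  invisible(x)
}

# Difference-of-Gaussians bandpass; either sigma may be NULL to skip the
# corresponding side of the band.
bandpass_filter <- function(img, low_px = NULL, high_px = NULL) {
  if (!is.null(low_px) && !is.null(high_px) && low_px >= high_px) {
    stop("bandpass_low_px must be smaller than bandpass_high_px")
  }
  smooth <- function(m, s) {
    matrix(as.numeric(EBImage::gblur(m, sigma = s)), nrow(m), ncol(m))
  }
  out <- img
  if (!is.null(low_px) && low_px > 0) out <- smooth(out, low_px)
  if (!is.null(high_px) && is.finite(high_px)) out <- out - smooth(img, high_px)
  out
}

# Otsu threshold, or the absolute value passed through.
resolve_threshold <- function(img, threshold) {
  if (is.numeric(threshold)) return(threshold)
  if (!identical(threshold, "otsu")) stop("threshold must be 'otsu' or numeric")
  rng <- range(img)
  if (diff(rng) == 0) return(NA_real_)  # constant image: nothing to split
  EBImage::otsu(img, range = rng)
}

#' Segment vesicles in a micrograph
#'
#' Bandpass-filters (difference of Gaussians; both ends optional),
#' thresholds (Otsu or absolute), optionally fills holes (so vesicles
#' with a bright rim and darker lumen become solid regions), removes
#' regions smaller than `min_area_nm2` and labels 8-connected components
#' deterministically in row-major order of each component's first pixel.
#'
#' @param mg a [micrograph()] (or a label matrix via `labels=`, see
#'   below).
#' @param invert set `TRUE` for dark-feature (negative-stain) images.
#' @param bandpass_low_px,bandpass_high_px difference-of-Gaussians sigmas
#'   in px; `NULL` disables that side of the band.
#' @param threshold `"otsu"` or an absolute intensity value.
#' @param min_area_nm2 discard regions with area below this (nm^2).
#' @param fill_holes fill enclosed holes in each region.
#' @param labels optional externally supplied integer label matrix; when
#'   given, segmentation is skipped and regions are built directly from
#'   it, so measurements can be validated independently of detection.
#' @return list of `vesicle_region` objects, each with `label`, `pixels`
#'   (matrix of 1-based row/col centres), `touches_border`, `source_id`.
#'   Zero detections give an empty list.
#' @export
segment_vesicles <- function(mg, invert = FALSE, bandpass_low_px = NULL,
                             bandpass_high_px = NULL, threshold = "otsu",
                             min_area_nm2 = 0, fill_holes = TRUE,
                             labels = NULL) {
  stopifnot(inherits(mg, "micrograph"))
  if (is.null(labels)) {
    img <- mg$pixels
    if (invert) img <- -img
    img <- bandpass_filter(img, bandpass_low_px, bandpass_high_px)
    thr <- resolve_threshold(img, threshold)
    if (is.na(thr)) return(list())
    mask <- img > thr
    if (fill_holes) {
      mask <- matrix(as.logical(EBImage::fillHull(mask)), nrow(mask), ncol(mask))
    }
    labels <- label_components8(mask)
  } else {
    stopifnot(is.matrix(labels),
              all(dim(labels) == dim(mg$pixels)))
    labels <- relabel_row_major(matrix(as.integer(labels),
                                       nrow(labels), ncol(labels)))
  }
  nmax <- max(labels)
  if (nmax == 0L) return(list())
  min_px <- min_area_nm2 / mg$pixel_size_nm^2
  nr <- nrow(labels); nc <- ncol(labels)
  regions <- list()
  for (id in seq_len(nmax)) {
    px <- label_pixels(labels, id)
    if (nrow(px) < min_px) next
    regions[[length(regions) + 1L]] <- structure(
      list(label = length(regions) + 1L, pixels = px,
           touches_border = any(px[, 1] == 1L | px[, 1] == nr |
                                  px[, 2] == 1L | px[, 2] == nc),
           source_id = mg$source_id),
      class = "vesicle_region")
  }
  regions
}

#' Shape metrics for one labelled region
#'
#' Computes, in physical units: `area_nm2 = n_pixels * pixel_size^2`;
#' `eq_diameter_nm = 2 * sqrt(area / pi)` (equivalent-circle diameter);
#' maximum and minimum Feret caliper diameters by rotating calipers on
#' the convex hull of pixel centres plus one pixel of extent (see
#' [feret_diameters()]); and roundness. Two
#' roundness definitions are available: `"feret"` (default),
#' `4 * area / (pi * feret_max^2)`, and `"axis_ratio"`,
#' `feret_min / feret_max`. Roundness and Feret values are computed for
#' every region, including border-touching ones — the fully-visible rule
#' is applied downstream by [classify_morphology()], which callers must
#' honor when reporting roundness.
#'
#' A single-pixel region is degenerate: both Feret diameters are
#' reported as one pixel and the row is flagged.
#'
#' @param region a `vesicle_region` from [segment_vesicles()].
#' @param pixel_size_nm nm per pixel.
#' @param roundness_method `"feret"` or `"axis_ratio"`.
#' @return one-row data.frame with columns `source_id`, `label`,
#'   `n_pixels`, `area_nm2`, `eq_diameter_nm`, `feret_max_nm`,
#'   `feret_min_nm`, `roundness`, `morphology_class` (always
#'   `"unclassified"` here), `touches_border`, `degenerate`.
#' @export
measure_region <- function(region, pixel_size_nm,
                           roundness_method = c("feret", "axis_ratio")) {
  stopifnot(inherits(region, "vesicle_region"), pixel_size_nm > 0)
  roundness_method <- match.arg(roundness_method)
  n_px <- nrow(region$pixels)
  if (n_px == 0L) stop("empty region")
  area_px2 <- n_px
  if (n_px == 1L) {
    fmax <- 1; fmin <- 1; degenerate <- TRUE
  } else {
    f <- feret_diameters(region$pixels)
    fmax <- f[["max"]]; fmin <- f[["min"]]; degenerate <- FALSE
  }
  rnd <- if (roundness_method == "feret") {
    roundness_feret(area_px2, fmax)
  } else {
    fmin / fmax
  }
  data.frame(source_id = region$source_id, label = region$label,
             n_pixels = n_px,
             area_nm2 = area_px2 * pixel_size_nm^2,
             eq_diameter_nm = 2 * sqrt(area_px2 / pi) * pixel_size_nm,
             feret_max_nm = fmax * pixel_size_nm,
             feret_min_nm = fmin * pixel_size_nm,
             roundness = rnd,
             morphology_class = "unclassified",
             touches_border = region$touches_border,
             degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Measure a list of regions
#'
#' @param regions list from [segment_vesicles()].
#' @inheritParams measure_region
#' @return data.frame, one row per region (see [measure_region()]).
#' @export
measure_regions <- function(regions, pixel_size_nm,
                            roundness_method = c("feret", "axis_ratio")) {
  roundness_method <- match.arg(roundness_method)
  if (length(regions) == 0L) {
    return(measure_region(structure(list(label = 1L,
                                         pixels = matrix(1L, 1, 2),
                                         touches_border = FALSE,
                                         source_id = ""),
                                    class = "vesicle_region"), 1)[0, ])
  }
  do.call(rbind, lapply(regions, measure_region,
                        pixel_size_nm = pixel_size_nm,
                        roundness_method = roundness_method))
}

#' Classify vesicle morphology from roundness
#'
#' Border-touching (not fully visible) regions are left `unclassified`:
#' roundness is only meaningful for vesicles completely visible in one
#' micrograph. For the rest: roundness < `tubular` threshold gives
#' `tubular`; roundness <= `non_round` threshold (and >= tubular) gives
#' `non_round`; otherwise `spherical`. Tubular vesicles are a subset of
#' non-round vesicles for counting purposes (see
#' [summarize_population()]).
#'
#' @param metrics data.frame from [measure_regions()].
#' @param thresholds named numeric, `c(tubular = 0.6, non_round = 0.8)`;
#'   both must lie in (0, 1] with `tubular <= non_round`.
#' @return `metrics` with `morphology_class` filled in.
#' @export
classify_morphology <- function(metrics,
                                thresholds = c(tubular = 0.6, non_round = 0.8)) {
  stopifnot(is.data.frame(metrics),
            all(c("roundness", "touches_border") %in% names(metrics)))
  tb <- thresholds[["tubular"]]; nrd <- thresholds[["non_round"]]
  if (!is.finite(tb) || !is.finite(nrd) || tb <= 0 || nrd <= 0 ||
      tb > 1 || nrd > 1 || tb > nrd) {
    stop("thresholds must lie in (0, 1] with tubular <= non_round")
  }
  cls <- ifelse(metrics$touches_border, "unclassified",
                ifelse(metrics$roundness < tb, "tubular",
                       ifelse(metrics$roundness <= nrd, "non_round",
                              "spherical")))
  metrics$morphology_class <- cls
  metrics
}

#' Summarize a vesicle population
#'
#' Diameter statistics (mean, sample SD with n-1 denominator, histogram)
#' are computed over *all* vesicles, including border-truncated ones.
#' Morphology fractions use only classified (fully visible) vesicles as
#' denominator. `n_non_round` counts every classified vesicle with
#' roundness at or below the non-round threshold, so tubular vesicles
#' are included in it.
#'
#' @param metrics classified data.frame from [classify_morphology()].
#' @param diameter_source `"equivalent"` (equivalent-circle diameter) or
#'   `"feret_max"`.
#' @param bins histogram break points in nm, or a single bin count
#'   passed to [hist()].
#' @return object of class `population_summary` (a list): `n_total`,
#'   `n_measured`, `mean_diameter_nm`, `sd_diameter_nm`,
#'   `diameter_source`, `histogram` (`$breaks`, `$counts`), `n_tubular`,
#'   `fraction_tubular`, `n_non_round`, `fraction_non_round`.
#' @export
summarize_population <- function(metrics,
                                 diameter_source = c("equivalent", "feret_max"),
                                 bins = 30) {
  diameter_source <- match.arg(diameter_source)
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    stop("at least one measured vesicle is required")
  }
  d <- if (diameter_source == "equivalent") metrics$eq_diameter_nm else
    metrics$feret_max_nm
  h <- graphics::hist(d, breaks = bins, plot = FALSE)
  classified <- metrics$morphology_class != "unclassified"
  n_meas <- sum(classified)
  n_tub <- sum(metrics$morphology_class == "tubular")
  n_nonround <- sum(metrics$morphology_class %in% c("tubular", "non_round"))
  structure(list(
    n_total = nrow(metrics),
    n_measured = n_meas,
    mean_diameter_nm = mean(d),
    sd_diameter_nm = stats::sd(d),
    diameter_source = diameter_source,
    histogram = list(breaks = h$breaks, counts = h$counts),
    n_tubular = n_tub,
    fraction_tubular = if (n_meas > 0) n_tub / n_meas else NA_real_,
    n_non_round = n_nonround,
    fraction_non_round = if (n_meas > 0) n_nonround / n_meas else NA_real_
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Vesicle population: n = %d (%d fully visible)\n",
              x$n_total, x$n_measured))
  cat(sprintf("  diameter (%s): %.1f +/- %.1f nm\n", x$diameter_source,
              x$mean_diameter_nm, x$sd_diameter_nm))
  cat(sprintf("  tubular: %d (%.1f%%), non-round: %d (%.1f%%)\n",
              x$n_tubular, 100 * x$fraction_tubular,
              x$n_non_round, 100 * x$fraction_non_round))
  invisible(x)
}
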