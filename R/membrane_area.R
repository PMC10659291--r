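# Membrane abundance per micrograph, measured as the fraction of pixels
# occupied by membrane features.

#' Segment membrane features in a micrograph
#'
#' Optional smoothing/bandpass, thresholding (Otsu or absolute) and
#' removal of objects smaller than `min_object_px`. A constant image
#' under Otsu yields an empty mask with a warning (there is nothing to
#' split), not an error. Pixels outside `roi_mask` are forced to
#' background here; [membrane_fraction()] additionally excludes them
#' from the denominator.
#'
#' @inheritParams segment_vesicles
#' @param min_object_px remove connected foreground objects smaller than
#'   this many pixels.
#' @param roi_mask optional logical matrix, same shape; `TRUE` = analyse.
#' @return logical foreground mask.
#' @export
segment_membrane <- function(mg, invert = FALSE, bandpass_low_px = NULL,
                             bandpass_high_px = NULL, threshold = "otsu",
                             min_object_px = 0, roi_mask = NULL) {
  stopifnot(inherits(mg, "micrograph"))
  img <- mg$pixels
  if (!is.null(roi_mask)) {
    stopifnot(is.matrix(roi_mask), all(dim(roi_mask) == dim(img)))
  }
  if (invert) img <- -img
  img <- bandpass_filter(img, bandpass_low_px, bandpass_high_px)
  thr <- resolve_threshold(img, threshold)
  if (is.na(thr)) {
    warning("constant image: Otsu threshold undefined, returning empty mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  mask <- img > thr
  if (min_object_px > 0 && any(mask)) {
    lab <- label_components8(mask)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (!is.null(roi_mask)) mask <- mask & roi_mask
  mask
}

#' Membrane area fraction of a mask
#'
#' Exact integer bookkeeping: `foreground_fraction =
#' n_pixels_foreground / n_pixels_total`, where both counts are
#' restricted to the ROI when one is supplied.
#'
#' @param mask logical (or 0/1) foreground matrix.
#' @param roi_mask optional logical matrix restricting the imaging area.
#' @param source_id identifier for the output row.
#' @param threshold_used optional record of the threshold that produced
#'   the mask.
#' @return one-row data.frame: `source_id`, `foreground_fraction`,
#'   `n_pixels_total`, `n_pixels_foreground`, `threshold_used`,
#'   `roi_applied`.
#' @export
membrane_fraction <- function(mask, roi_mask = NULL, source_id = "micrograph",
                              threshold_used = NA_real_) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  if (!is.null(roi_mask)) {
    stopifnot(is.matrix(roi_mask), all(dim(roi_mask) == dim(mask)))
    roi <- roi_mask != 0
    if (!any(roi)) stop("empty ROI")
    n_total <- sum(roi)
    n_fg <- sum(mask & roi)
  } else {
    n_total <- length(mask)
    n_fg <- sum(mask)
  }
  data.frame(source_id = source_id,
             foreground_fraction = n_fg / n_total,
             n_pixels_total = n_total,
             n_pixels_foreground = n_fg,
             threshold_used = threshold_used,
             roi_applied = !is.null(roi_mask),
             stringsAsFactors = FALSE)
}

#' Compare membrane fractions between two conditions
#'
#' Fold change of means plus an unpaired two-tailed Mann-Whitney test
#' (see [mann_whitney_u()]). Optionally a mock-transfection baseline
#' mean can be subtracted from every micrograph fraction before
#' comparison; the result records whether that was done.
#'
#' @param fractions_a,fractions_b numeric vectors of per-micrograph
#'   foreground fractions (condition a vs b).
#' @param mock_baseline optional scalar mean fraction of a mock control,
#'   subtracted from both conditions before the fold change.
#' @return list with `fold_change` (mean(a)/mean(b); `NA` and
#'   `undefined_fold = TRUE` when mean(b) is 0), `test` (a `TestResult`
#'   from [mann_whitney_u()], computed on the uncorrected fractions) and
#'   `mock_subtracted`.
#' @export
compare_membrane_conditions <- function(fractions_a, fractions_b,
                                        mock_baseline = NULL) {
  stopifnot(length(fractions_a) >= 1, length(fractions_b) >= 1)
  a <- fractions_a; b <- fractions_b
  if (!is.null(mock_baseline)) {
    a <- a - mock_baseline
    b <- b - mock_baseline
  }
  mb <- mean(b)
  fold <- if (mb == 0) NA_real_ else mean(a) / mb
  list(fold_change = fold,
       undefined_fold = mb == 0,
       test = mann_whitney_u(fractions_a, fractions_b),
       mock_subtracted = !is.null(mock_baseline))
}
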