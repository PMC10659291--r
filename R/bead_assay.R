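# Bead-based fluorescent co-purification quantification.
#
# Resin beads are detected in the reference channel (the bead-bound
# normalizing fluorophore, e.g. mTagBFP2 imaged as DAPI/BFP), filtered
# on size, roundness and border contact, and the co-purified fluorescent
# species (e.g. BODIPY-cholesterol in FITC, AlexaFluor647-cholesterol in
# CY5) is quantified per bead as a background-corrected integrated
# signal/reference ratio.

#' Construct a two-channel bead image pair
#'
#' @param reference reference-channel intensity matrix (bead marker).
#' @param signal signal-channel intensity matrix, same shape.
#' @param condition_id experimental condition label.
#' @param saturation_value numeric length 1 or 2 (reference, signal):
#'   intensities at or above this are treated as saturated.
#' @return object of class `bead_image_pair`.
#' @export
bead_image_pair <- function(reference, signal, condition_id = "condition",
                            saturation_value = Inf) {
  stopifnot(is.matrix(reference), is.matrix(signal),
            all(dim(reference) == dim(signal)))
  if (length(saturation_value) == 1) {
    saturation_value <- rep(saturation_value, 2)
  }
  stopifnot(length(saturation_value) == 2)
  structure(list(reference = reference, signal = signal,
                 condition_id = condition_id,
                 saturation_value = saturation_value),
            class = "bead_image_pair")
}

#' Detect resin beads in the reference channel
#'
#' Thresholds the reference channel (artifacts present only in the
#' signal channel are therefore never detected), labels 8-connected
#' components, and attaches QC flags: `too_small` / `too_large` (area
#' window), `non_round` (roundness `4A/(pi Feret_max^2)` below
#' `min_roundness`; shared definition with the vesicle module) and
#' `border`. All detections are returned with their flags; summaries
#' downstream use only unflagged beads.
#'
#' @param reference reference-channel matrix or a [bead_image_pair()].
#' @param threshold `"otsu"` or absolute value.
#' @param min_area_px,max_area_px area acceptance window in px.
#' @param min_roundness minimum roundness for a valid bead.
#' @param exclude_border flag beads touching the image border.
#' @return list of `bead_region` objects: `bead_id`, `pixels`,
#'   `centroid` (row, col), `area_px`, `roundness`, `qc_flags`
#'   (character vector, empty when the bead passes).
#' @export
detect_beads <- function(reference, threshold = "otsu", min_area_px = 50,
                         max_area_px = Inf, min_roundness = 0.85,
                         exclude_border = TRUE) {
  if (inherits(reference, "bead_image_pair")) reference <- reference$reference
  stopifnot(is.matrix(reference))
  thr <- resolve_threshold(reference, threshold)
  if (is.na(thr)) return(list())
  mask <- reference > thr
  lab <- label_components8(mask)
  nmax <- max(lab)
  if (nmax == 0L) return(list())
  nr <- nrow(lab); nc <- ncol(lab)
  beads <- vector("list", nmax)
  for (id in seq_len(nmax)) {
    px <- label_pixels(lab, id)
    area <- nrow(px)
    rnd <- if (area == 1L) 1 else {
      roundness_feret(area, feret_diameters(px)[["max"]])
    }
    flags <- character(0)
    if (area < min_area_px) flags <- c(flags, "too_small")
    if (area > max_area_px) flags <- c(flags, "too_large")
    if (rnd < min_roundness) flags <- c(flags, "non_round")
    if (exclude_border && any(px[, 1] == 1L | px[, 1] == nr |
                                px[, 2] == 1L | px[, 2] == nc)) {
      flags <- c(flags, "border")
    }
    beads[[id]] <- structure(
      list(bead_id = id, pixels = px,
           centroid = c(row = mean(px[, 1]), col = mean(px[, 2])),
           area_px = area, roundness = rnd, qc_flags = flags),
      class = "bead_region")
  }
  beads
}

# Background level per channel: median of pixels not covered by any
# detected bead ("global_median_nonbead"), or the median of an annulus
# of given width around the bead ("annulus").
estimate_background <- function(img, bead, all_bead_mask,
                                mode = c("global_median_nonbead", "annulus"),
                                annulus_width_px = 5) {
  mode <- match.arg(mode)
  if (mode == "global_median_nonbead") {
    nonbead <- img[!all_bead_mask]
    if (length(nonbead) == 0L) return(0)
    return(stats::median(nonbead))
  }
  nr <- nrow(img); nc <- ncol(img)
  r0 <- bead$centroid[["row"]]; c0 <- bead$centroid[["col"]]
  rad <- sqrt(bead$area_px / pi)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  d <- sqrt((rr - r0)^2 + (cc - c0)^2)
  ring <- d >= rad & d < rad + annulus_width_px & !all_bead_mask
  if (!any(ring)) return(stats::median(img[!all_bead_mask]))
  stats::median(img[ring])
}

#' Quantify one bead
#'
#' Per-channel background (default: median over all non-bead pixels) is
#' subtracted per pixel before summation, and the bead's ratio is the
#' corrected integrated signal divided by the corrected integrated
#' reference. A bead with any in-bead pixel at or above the channel's
#' saturation value is flagged `saturated`; a corrected reference sum
#' <= 0 leaves the ratio undefined (`NA`) and flags the bead.
#'
#' @param bead a `bead_region` from [detect_beads()].
#' @param pair a [bead_image_pair()].
#' @param all_beads list of all detected beads (used to exclude every
#'   bead's pixels from the global background estimate); defaults to
#'   just `bead`.
#' @param background_mode `"global_median_nonbead"` or `"annulus"`.
#' @param annulus_width_px annulus width for `"annulus"` mode.
#' @return one-row data.frame (a BeadRecord): `bead_id`, `centroid_row`,
#'   `centroid_col`, `area_px`, `roundness`, `ref_integrated`,
#'   `signal_integrated`, `ratio`, `qc_flags` (comma-separated string,
#'   `""` = pass).
#' @export
quantify_bead <- function(bead, pair, all_beads = list(bead),
                          background_mode = c("global_median_nonbead", "annulus"),
                          annulus_width_px = 5) {
  stopifnot(inherits(bead, "bead_region"), inherits(pair, "bead_image_pair"))
  background_mode <- match.arg(background_mode)
  dims <- dim(pair$reference)
  all_mask <- matrix(FALSE, dims[1], dims[2])
  for (b in all_beads) all_mask[b$pixels] <- TRUE
  bg_ref <- estimate_background(pair$reference, bead, all_mask,
                                background_mode, annulus_width_px)
  bg_sig <- estimate_background(pair$signal, bead, all_mask,
                                background_mode, annulus_width_px)
  ref_vals <- pair$reference[bead$pixels]
  sig_vals <- pair$signal[bead$pixels]
  ref_sum <- sum(ref_vals - bg_ref)
  sig_sum <- sum(sig_vals - bg_sig)
  flags <- bead$qc_flags
  if (any(ref_vals >= pair$saturation_value[1]) ||
      any(sig_vals >= pair$saturation_value[2])) {
    flags <- c(flags, "saturated")
  }
  ratio <- if (ref_sum > 0) sig_sum / ref_sum else NA_real_
  if (ref_sum <= 0) flags <- c(flags, "ref_nonpositive")
  data.frame(bead_id = bead$bead_id,
             centroid_row = bead$centroid[["row"]],
             centroid_col = bead$centroid[["col"]],
             area_px = bead$area_px,
             roundness = bead$roundness,
             ref_integrated = ref_sum,
             signal_integrated = sig_sum,
             ratio = ratio,
             qc_flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Quantify all detected beads in an image pair
#'
#' @param beads list from [detect_beads()].
#' @inheritParams quantify_bead
#' @return data.frame of BeadRecords (possibly 0 rows).
#' @export
quantify_beads <- function(beads, pair,
                           background_mode = c("global_median_nonbead", "annulus"),
                           annulus_width_px = 5) {
  background_mode <- match.arg(background_mode)
  if (length(beads) == 0L) {
    return(data.frame(bead_id = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area_px = integer(),
                      roundness = numeric(), ref_integrated = numeric(),
                      signal_integrated = numeric(), ratio = numeric(),
                      qc_flags = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(beads, quantify_bead, pair = pair, all_beads = beads,
                        background_mode = background_mode,
                        annulus_width_px = annulus_width_px))
}

#' Apply condition-level QC to bead records
#'
#' Flags beads whose integrated reference intensity deviates from the
#' condition median by more than `ref_outlier_mads` median absolute
#' deviations (MAD with the usual 1.4826 consistency constant) as
#' `ref_outlier` — an automated surrogate for the manual exclusion of
#' air bubbles and other non-resin fluorescent artifacts. A review
#' manifest (centroid coordinates plus flags) is returned so a human can
#' mark additional beads; `manual_reject` takes those bead ids (or a
#' manifest data.frame with a `manual_reject` column) and honors them on
#' re-run.
#'
#' @param records BeadRecord data.frame from [quantify_beads()].
#' @param ref_outlier_mads MAD multiple for the reference-outlier rule.
#' @param manual_reject integer vector of bead ids to reject, or a
#'   review-manifest data.frame with columns `bead_id` and
#'   `manual_reject` (logical).
#' @return list with `passed` (records with no flags), `rejected`
#'   (flagged records) and `manifest` (data.frame: `bead_id`,
#'   `centroid_row`, `centroid_col`, `qc_flags`, `manual_reject`).
#' @export
apply_qc <- function(records, ref_outlier_mads = 5, manual_reject = NULL) {
  stopifnot(is.data.frame(records))
  if (is.data.frame(manual_reject)) {
    stopifnot(all(c("bead_id", "manual_reject") %in% names(manual_reject)))
    manual_reject <- manual_reject$bead_id[as.logical(manual_reject$manual_reject)]
  }
  flags <- strsplit(records$qc_flags, ",", fixed = TRUE)
  flags <- lapply(flags, function(f) f[nzchar(f)])
  if (nrow(records) > 0) {
    med <- stats::median(records$ref_integrated)
    madv <- stats::mad(records$ref_integrated)
    dev <- abs(records$ref_integrated - med)
    out <- dev > ref_outlier_mads * madv
    for (i in which(out)) flags[[i]] <- c(flags[[i]], "ref_outlier")
    for (i in which(records$bead_id %in% manual_reject)) {
      flags[[i]] <- c(flags[[i]], "manual_reject")
    }
  }
  records$qc_flags <- vapply(flags, paste, character(1), collapse = ",")
  pass <- records$qc_flags == ""
  manifest <- data.frame(bead_id = records$bead_id,
                         centroid_row = records$centroid_row,
                         centroid_col = records$centroid_col,
                         qc_flags = records$qc_flags,
                         manual_reject = records$bead_id %in% manual_reject,
                         stringsAsFactors = FALSE)
  list(passed = records[pass, , drop = FALSE],
       rejected = records[!pass, , drop = FALSE],
       manifest = manifest)
}

#' Summarize bead ratios for one condition
#'
#' Mean and sample SD (n-1) of the per-bead ratios. If the records carry
#' a `replicate_id` column, aggregation is replicate-level: the reported
#' mean is the mean of per-replicate means and the SD is across
#' replicates. With a control summary, the relative ratio
#' `mean / control mean` is reported (the usual normalization against a
#' reference construct).
#'
#' @param passed BeadRecord data.frame of QC-passing beads.
#' @param condition_id condition label.
#' @param control_summary optional `condition_summary` to normalize to.
#' @return object of class `condition_summary`: `condition_id`,
#'   `n_beads_pass`, `mean_ratio`, `sd_ratio`,
#'   `ratio_relative_to_control` (`NA` without a control).
#' @export
summarize_condition <- function(passed, condition_id = "condition",
                                control_summary = NULL) {
  stopifnot(is.data.frame(passed))
  if (nrow(passed) == 0L) stop("no passing beads to summarize")
  if ("replicate_id" %in% names(passed)) {
    per_rep <- tapply(passed$ratio, passed$replicate_id, mean)
    m <- mean(per_rep); s <- stats::sd(per_rep)
  } else {
    m <- mean(passed$ratio); s <- stats::sd(passed$ratio)
  }
  rel <- NA_real_
  if (!is.null(control_summary)) {
    stopifnot(inherits(control_summary, "condition_summary"))
    rel <- m / control_summary$mean_ratio
  }
  structure(list(condition_id = condition_id,
                 n_beads_pass = nrow(passed),
                 mean_ratio = m, sd_ratio = s,
                 ratio_relative_to_control = rel),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("Condition '%s': %d beads, ratio %.3f +/- %.3f",
              x$condition_id, x$n_beads_pass, x$mean_ratio, x$sd_ratio))
  if (!is.na(x$ratio_relative_to_control)) {
    cat(sprintf(" (%.2fx control)", x$ratio_relative_to_control))
  }
  cat("\n")
  invisible(x)
}
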