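# Bead detection, quantification, QC and condition summaries.

test_that("clean scenes detect every bead at its true centroid", {
  beads <- data.frame(row = c(30, 30, 90, 90, 60),
                      col = c(30, 90, 30, 90, 60),
                      radius = 10, reference_intensity = 1000,
                      ratio = c(0.5, 1, 2, 1.5, 0.8))
  sc <- render_bead_scene(bead_scene_spec(c(120, 120), beads))
  det <- detect_beads(sc$reference, min_area_px = 50)
  expect_length(det, 5L)
  got <- do.call(rbind, lapply(det, function(b) b$centroid))
  for (i in seq_len(nrow(beads))) {
    d <- sqrt((got[, 1] - beads$row[i])^2 + (got[, 2] - beads$col[i])^2)
    expect_lt(min(d), 1)
  }
})

test_that("uniform beads with zero background yield exact ratios", {
  beads <- data.frame(row = 40, col = 40, radius = 12,
                      reference_intensity = 1000, ratio = 2)
  sc <- render_bead_scene(bead_scene_spec(c(80, 80), beads))
  pair <- bead_image_pair(sc$reference, sc$signal)
  det <- detect_beads(pair$reference, min_area_px = 50)
  rec <- quantify_beads(det, pair)
  expect_equal(rec$ratio, 2, tolerance = 1e-12)
})

test_that("constant channel backgrounds are removed exactly (noise-free)", {
  beads <- data.frame(row = c(40, 40), col = c(40, 100), radius = 12,
                      reference_intensity = 1000, ratio = c(2, 0.5))
  sc <- render_bead_scene(bead_scene_spec(c(80, 140), beads,
                                          background_reference = 100,
                                          background_signal = 50))
  pair <- bead_image_pair(sc$reference, sc$signal)
  det <- detect_beads(pair$reference, min_area_px = 50)
  rec <- quantify_beads(det, pair)
  expect_equal(sort(rec$ratio), c(0.5, 2), tolerance = 0.01)
})

test_that("ratios are invariant to a common channel gain and constant offsets", {
  set.seed(14)
  beads <- data.frame(row = c(40, 40, 100), col = c(40, 100, 70), radius = 11,
                      reference_intensity = 800, ratio = c(0.7, 1.3, 2.1))
  sc <- render_bead_scene(bead_scene_spec(c(140, 140), beads,
                                          background_reference = 80,
                                          background_signal = 40))
  pair1 <- bead_image_pair(sc$reference, sc$signal)
  det <- detect_beads(pair1$reference, min_area_px = 50)
  r1 <- quantify_beads(det, pair1)
  # common gain on both channels
  pair2 <- bead_image_pair(3 * sc$reference, 3 * sc$signal)
  r2 <- quantify_beads(det, pair2)
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-12)
  # constant added to either channel
  pair3 <- bead_image_pair(sc$reference + 500, sc$signal + 120)
  r3 <- quantify_beads(det, pair3)
  expect_equal(r3$ratio, r1$ratio, tolerance = 1e-9)
})

test_that("saturated pixels flag the bead", {
  beads <- data.frame(row = 40, col = 40, radius = 10,
                      reference_intensity = 1000, ratio = 5)
  sc <- render_bead_scene(bead_scene_spec(c(80, 80), beads))
  pair <- bead_image_pair(sc$reference, sc$signal,
                          saturation_value = c(Inf, 4000))
  det <- detect_beads(pair$reference, min_area_px = 50)
  rec <- quantify_beads(det, pair)
  expect_match(rec$qc_flags, "saturated")
})

test_that("a nonpositive corrected reference leaves the ratio undefined and flagged", {
  pair <- bead_image_pair(matrix(10, 64, 64), matrix(30, 64, 64))
  bead <- structure(list(bead_id = 1L,
                         pixels = cbind(row = 30:34, col = rep(30L, 5)),
                         centroid = c(row = 32, col = 30),
                         area_px = 5L, roundness = 1, qc_flags = character(0)),
                    class = "bead_region")
  rec <- quantify_bead(bead, pair)   # bead no brighter than background
  expect_true(is.na(rec$ratio))
  expect_match(rec$qc_flags, "ref_nonpositive")
})

test_that("50-bead noisy scenes recover ratios within 5% per bead, 2% in the mean", {
  fx <- make_fifty_bead_scene(noise_sd = 50, seed = 21)
  sc <- render_bead_scene(fx$spec)
  pair <- bead_image_pair(sc$reference, sc$signal,
                          saturation_value = c(4000, 65535))
  det <- detect_beads(pair$reference, threshold = 500, min_area_px = 200,
                      max_area_px = 1000, min_roundness = 0.85)
  rec <- quantify_beads(det, pair)
  qc <- apply_qc(rec)
  # match passing beads back to planted truth by centroid
  truth <- sc$truth
  rel_err <- vapply(seq_len(nrow(qc$passed)), function(i) {
    d <- sqrt((truth$row - qc$passed$centroid_row[i])^2 +
                (truth$col - qc$passed$centroid_col[i])^2)
    j <- which.min(d)
    abs(qc$passed$ratio[i] - truth$ratio[j]) / truth$ratio[j]
  }, numeric(1))
  expect_gt(nrow(qc$passed), 40)
  expect_true(all(rel_err <= 0.05))
  expect_lte(mean(rel_err), 0.02)
})

test_that("every planted artifact class is excluded", {
  fx <- make_fifty_bead_scene(noise_sd = 50, seed = 22)
  sc <- render_bead_scene(fx$spec)
  pair <- bead_image_pair(sc$reference, sc$signal,
                          saturation_value = c(4000, 65535))
  det <- detect_beads(pair$reference, threshold = 500, min_area_px = 200,
                      max_area_px = 1000, min_roundness = 0.85)
  rec <- quantify_beads(det, pair)
  qc <- apply_qc(rec)
  truth <- sc$truth
  # signal-only artifact: nothing detected near its position
  cent <- cbind(rec$centroid_row, rec$centroid_col)
  d_art <- sqrt((cent[, 1] - 250)^2 + (cent[, 2] - 252)^2)
  expect_true(all(d_art > 20))
  # non-round reference artifact (bar at ~row 150, col 248) is rejected
  bar_idx <- which(sqrt((cent[, 1] - 150)^2 + (cent[, 2] - 248)^2) < 20)
  expect_true(length(bar_idx) >= 1)
  expect_true(all(grepl("non_round|too_large|too_small",
                        rec$qc_flags[bar_idx])))
  # border bead rejected
  brd <- which(sqrt((cent[, 1] - truth$row[fx$border_id])^2 +
                      (cent[, 2] - truth$col[fx$border_id])^2) < 15)
  expect_true(all(grepl("border", rec$qc_flags[brd])))
  # saturated bead rejected
  sat <- which(sqrt((cent[, 1] - truth$row[fx$saturated_id])^2 +
                      (cent[, 2] - truth$col[fx$saturated_id])^2) < 15)
  expect_true(length(sat) >= 1)
  expect_true(all(grepl("saturated|ref_outlier", rec$qc_flags[sat])))
  # nothing flagged survives into the passed set
  expect_false(any(grepl("[a-z]", qc$passed$qc_flags)))
})

test_that("reference outliers are flagged by the MAD rule and manifests round-trip", {
  rec <- data.frame(bead_id = 1:20, centroid_row = 1:20, centroid_col = 1,
                    area_px = 300, roundness = 1,
                    ref_integrated = c(rep(1000, 19), 100000),
                    signal_integrated = 1000, ratio = 1, qc_flags = "",
                    stringsAsFactors = FALSE)
  qc <- apply_qc(rec, ref_outlier_mads = 5)
  expect_equal(qc$rejected$bead_id, 20L)
  expect_match(qc$rejected$qc_flags, "ref_outlier")
  # identical beads: nothing rejected
  rec2 <- rec; rec2$ref_integrated <- 1000
  expect_equal(nrow(apply_qc(rec2)$rejected), 0L)
  # manifest round-trip with a manual rejection
  manifest <- qc$manifest
  manifest$manual_reject[manifest$bead_id == 3] <- TRUE
  qc2 <- apply_qc(rec, manual_reject = manifest)
  expect_true(3L %in% qc2$rejected$bead_id)
  expect_false(3L %in% qc2$passed$bead_id)
})

test_that("condition summaries normalize against a control", {
  rec <- data.frame(ratio = c(1, 1, 1))
  s <- summarize_condition(rec, "ctrl")
  expect_equal(s$mean_ratio, 1)
  expect_equal(s$sd_ratio, 0)
  expect_equal(summarize_condition(rec, "x", s)$ratio_relative_to_control, 1)
  set.seed(77)
  treated <- data.frame(ratio = rnorm(60, 2, 0.1))
  control <- data.frame(ratio = rnorm(60, 1, 0.1))
  ctrl_s <- summarize_condition(control, "control")
  rel <- summarize_condition(treated, "treated", ctrl_s)$ratio_relative_to_control
  expect_equal(rel, 2, tolerance = 0.1)
  expect_error(summarize_condition(rec[0, , drop = FALSE]), "no passing")
})

test_that("replicate-level aggregation averages per-replicate means", {
  rec <- data.frame(ratio = c(1, 3, 10, 20),
                    replicate_id = c("r1", "r1", "r2", "r2"))
  s <- summarize_condition(rec)
  expect_equal(s$mean_ratio, mean(c(2, 15)))
  expect_equal(s$sd_ratio, sd(c(2, 15)))
})
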