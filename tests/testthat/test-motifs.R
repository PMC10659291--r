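# CRAC/CARC motif scanning, TM restriction, prominin topology filter,
# conservation scoring.

test_that("minimal CRAC and CARC patterns are found with correct anchors", {
  h <- scan_motifs("VAYAK", "CRAC")
  expect_equal(nrow(h), 1L)
  expect_equal(unlist(h[1, c("start", "end", "p1", "p_aromatic", "p3")]),
               c(start = 1L, end = 5L, p1 = 1L, p_aromatic = 3L, p3 = 5L))
  expect_equal(h$match, "VAYAK")
  expect_equal(nrow(scan_motifs("KAYAV", "CARC")), 1L)
  expect_equal(nrow(scan_motifs("KAYAV", "CRAC")), 0L)
  expect_equal(nrow(scan_motifs("VAYA", "CRAC")), 0L)  # shorter than minimum
})

test_that("spacer lengths are bounded by 1..5 on each side", {
  # spacers of 5: V-AAAAA-Y-AAAAA-K matches; 6 does not
  expect_equal(nrow(scan_motifs("VAAAAAYAAAAAK", "CRAC")), 1L)
  expect_equal(nrow(scan_motifs("VAAAAAAYAAAAAAK", "CRAC")), 0L)
  # zero spacer does not match
  expect_equal(nrow(scan_motifs("VYK", "CRAC")), 0L)
})

test_that("X never satisfies an anchor class but may be a spacer", {
  expect_equal(nrow(scan_motifs("XAYAK", "CRAC")), 0L)
  expect_equal(nrow(scan_motifs("VXYXK", "CRAC")), 1L)
})

test_that("scanner equals the exhaustive triple-loop oracle on 500 random sequences", {
  set.seed(99)
  for (i in 1:500) {
    len <- sample(20:60, 1)
    s <- paste(sample(evquant:::AMINO_ACIDS, len, replace = TRUE),
               collapse = "")
    for (ty in c("CRAC", "CARC")) {
      got <- scan_motifs(s, ty)
      want <- evquant:::motif_scan_bruteforce(s, ty)
      rownames(got) <- rownames(want) <- NULL
      expect_identical(got[, c("start", "end", "p1", "p_aromatic", "p3")],
                       want[, c("start", "end", "p1", "p_aromatic", "p3")])
    }
  }
})

test_that("CARC hits are CRAC hits of the reversed sequence, reflected", {
  set.seed(123)
  for (i in 1:50) {
    s <- paste(sample(evquant:::AMINO_ACIDS, 50, replace = TRUE), collapse = "")
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    carc <- scan_motifs(s, "CARC")
    crac_rev <- scan_motifs(rev_s, "CRAC")
    L <- nchar(s)
    reflected <- data.frame(p1 = L + 1L - crac_rev$p3,
                            p_aromatic = L + 1L - crac_rev$p_aromatic,
                            p3 = L + 1L - crac_rev$p1)
    reflected <- reflected[order(reflected$p1, reflected$p3,
                                 reflected$p_aromatic), ]
    got <- carc[, c("p1", "p_aromatic", "p3")]
    got <- got[order(got$p1, got$p3, got$p_aromatic), ]
    rownames(got) <- rownames(reflected) <- NULL
    # CARC anchors: p1 in {K,R}, p3 in {L,V}; the reversed-CRAC p1/p3 swap
    expect_identical(got$p1, reflected$p1)
    expect_identical(got$p_aromatic, reflected$p_aromatic)
    expect_identical(got$p3, reflected$p3)
  }
})

test_that("appending residues never removes an existing hit", {
  set.seed(5)
  s <- paste(sample(evquant:::AMINO_ACIDS, 40, replace = TRUE), collapse = "")
  h0 <- scan_motifs(s, "CRAC")
  h1 <- scan_motifs(paste0(s, "WWAAA"), "CRAC")
  if (nrow(h0) > 0) {
    key0 <- paste(h0$p1, h0$p_aromatic, h0$p3)
    key1 <- paste(h1$p1, h1$p_aromatic, h1$p3)
    expect_true(all(key0 %in% key1))
  }
  expect_gte(nrow(h1), nrow(h0))
})

test_that("merged spans collapse overlapping hits", {
  # VAYAKAYAK: triples (1,3,5), (1,3,9)?, etc -> one merged span
  h <- scan_motifs("VAYAKAYAK", "CRAC")
  expect_gt(nrow(h), 1L)
  m <- merge_motif_spans(h)
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_hits, nrow(h))
  expect_equal(nrow(merge_motif_spans(h[0, ])), 0L)
})

test_that("TM restriction keeps hits by overlap fraction and annotates the TM", {
  topo <- topology_annotation(data.frame(
    kind = c("outside", "TM", "inside", "TM", "outside"),
    start = c(1, 21, 41, 61, 81), end = c(20, 40, 60, 80, 100)))
  hits <- data.frame(seq_id = "s", motif_type = "CRAC",
                     start = c(25, 15, 58), end = c(33, 22, 65),
                     p1 = c(25, 15, 58), p_aromatic = c(29, 18, 61),
                     p3 = c(33, 22, 65), match = "m")
  kept <- restrict_to_tm(hits, topo, min_overlap_fraction = 0.5)
  # hit 1 fully inside TM1; hit 2 overlaps TM1 by 2/8 < 0.5; hit 3
  # overlaps TM2 by 5/8 >= 0.5
  expect_equal(kept$start, c(25, 58))
  expect_equal(kept$tm_index, c(1L, 2L))
  expect_error(restrict_to_tm(hits, topo, sequence_length = 120), "120")
})

test_that("TM restriction agrees with direct interval arithmetic on random cases", {
  set.seed(8)
  topo <- topology_annotation(data.frame(
    kind = c("inside", "TM", "outside", "TM", "inside", "TM", "outside"),
    start = c(1, 31, 52, 91, 112, 151, 172),
    end = c(30, 51, 90, 111, 150, 171, 200)))
  tm <- topo$segments[topo$segments$kind == "TM", ]
  for (i in 1:100) {
    st <- sample(1:190, 1); en <- min(200, st + sample(4:12, 1))
    hits <- data.frame(seq_id = "s", motif_type = "CRAC", start = st,
                       end = en, p1 = st, p_aromatic = st + 2, p3 = en,
                       match = "m")
    kept <- restrict_to_tm(hits, topo)
    ov <- pmax(0, pmin(en, tm$end) - pmax(st, tm$start) + 1)
    keep_direct <- max(ov) / (en - st + 1) >= 0.5
    expect_equal(nrow(kept) == 1L, keep_direct)
  }
})

test_that("the prominin topology filter enforces its strict thresholds", {
  ok <- classify_prominin_topology(make_prominin_topology(10, 350, 15, 400))
  expect_true(ok$is_prominin_like)
  expect_length(ok$reasons, 0)
  # boundary values fail the strict inequalities
  ec_at_300 <- classify_prominin_topology(make_prominin_topology(10, 300, 15, 400))
  expect_false(ec_at_300$is_prominin_like)
  expect_match(ec_at_300$reasons, "ec_loop_size", all = FALSE)
  ic_at_25 <- classify_prominin_topology(make_prominin_topology(25, 350, 15, 400))
  expect_false(ic_at_25$is_prominin_like)
  expect_match(ic_at_25$reasons, "ic_loop_size", all = FALSE)
  # just inside the bounds passes
  expect_true(classify_prominin_topology(
    make_prominin_topology(24, 301, 24, 301))$is_prominin_like)
  # wrong TM count
  six <- classify_prominin_topology(make_prominin_topology(n_tm = 6))
  expect_false(six$is_prominin_like)
  expect_match(six$reasons, "n_tm", all = FALSE)
  four <- classify_prominin_topology(make_prominin_topology(n_tm = 4))
  expect_false(four$is_prominin_like)
})

test_that("grid of loop lengths around the thresholds classifies correctly", {
  for (ec in c(299, 300, 301, 500)) for (ic in c(1, 24, 25, 26)) {
    res <- classify_prominin_topology(make_prominin_topology(ic, ec, ic, ec))
    expect_equal(res$is_prominin_like, ec > 300 && ic < 25,
                 info = sprintf("ec=%d ic=%d", ec, ic))
  }
})

test_that("malformed topologies are rejected at construction", {
  expect_error(topology_annotation(data.frame(
    kind = c("TM", "TM"), start = c(1, 21), end = c(20, 40))), "alternate")
  expect_error(topology_annotation(data.frame(
    kind = c("inside", "TM"), start = c(1, 25), end = c(20, 40))),
    "contiguous")
})

test_that("conservation scoring follows the identity and property rules", {
  expect_equal(score_conservation(c("A", "A", "A", "A"))$score, 11L)
  # D vs E: identical in all properties except small (D yes, E no) -> 9
  expect_equal(score_conservation(c("D", "E"))$score, 9L)
  # gap handling
  expect_equal(score_conservation(c("G", "W", "-"))$score,
               score_conservation(c("G", "W"))$score)
  g <- score_conservation(c("G", "W", "-"), ignore_gaps = FALSE)
  expect_equal(g$score, 0L)
  allgap <- score_conservation(c("-", "-"))
  expect_true(allgap$all_gap)
  expect_true(is.na(allgap$score))
})

test_that("conservation equals a brute-force property-table count on random columns", {
  tab <- utils::read.csv(system.file("extdata", "residue_properties.csv",
                                     package = "evquant"),
                         row.names = 1, check.names = FALSE)
  tab <- as.matrix(tab) != 0
  set.seed(17)
  for (i in 1:100) {
    col <- sample(rownames(tab), sample(2:8, 1), replace = TRUE)
    want <- if (length(unique(col)) == 1L) 11L else {
      states <- tab[col, , drop = FALSE]
      sum(vapply(seq_len(ncol(states)), function(p)
        all(states[, p]) || all(!states[, p]), logical(1)))
    }
    expect_equal(score_conservation(col)$score, want)
  }
})

test_that("conservation is permutation-invariant and 11 only for identity", {
  set.seed(29)
  for (i in 1:30) {
    col <- sample(evquant:::AMINO_ACIDS, 6, replace = TRUE)
    s1 <- score_conservation(col)$score
    s2 <- score_conservation(sample(col))$score
    expect_identical(s1, s2)
    if (length(unique(col)) > 1) expect_lt(s1, 11L)
  }
})

test_that("the shipped property table is pinned by checksum", {
  path <- system.file("extdata", "residue_properties.csv", package = "evquant")
  expect_equal(unname(tools::md5sum(path)),
               "e414e46b7593a5f0a69e247eeab935ba")
})

test_that("alignment conservation scores every column", {
  aln <- c("AC-D", "ACED", "ACAD")
  sc <- score_alignment_conservation(aln)
  expect_equal(nrow(sc), 4L)
  expect_equal(sc$score[1], 11L)
  expect_equal(sc$score[4], 11L)
  expect_equal(sc$gap_fraction[3], 1 / 3)
  expect_error(score_alignment_conservation(c("AA", "AAA")), "share a length")
})
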