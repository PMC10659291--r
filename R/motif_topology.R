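# CRAC/CARC motif scanning, transmembrane restriction, prominin-family
# topology filtering and alignment-column conservation scoring.
#
# CRAC: [L/V]-X(1,5)-[Y/F]-X(1,5)-[K/R]; CARC is the mirrored pattern
# [K/R]-X(1,5)-[Y/F]-X(1,5)-[L/V]. Spacer residues are unrestricted;
# X and other nonstandard residues never satisfy an anchor class but may
# occupy spacer positions.

#' Scan a protein sequence for CRAC or CARC motifs
#'
#' Enumerates *every* anchor triple (p1, aromatic, p3) with both spacer
#' lengths in 1..5 — overlapping and nested matches are each reported
#' once; a triple is never duplicated. Sorted by (start, end, aromatic
#' position). Sequences shorter than the 5-residue minimal pattern give
#' an empty table.
#'
#' @param residues protein sequence as a single uppercase string.
#' @param motif_type `"CRAC"` or `"CARC"`.
#' @param seq_id identifier copied into the output.
#' @return data.frame with columns `seq_id`, `motif_type`, `start`,
#'   `end` (1-based inclusive), `p1`, `p_aromatic`, `p3`, `match`.
#' @export
scan_motifs <- function(residues, motif_type = c("CRAC", "CARC"),
                        seq_id = "seq") {
  motif_type <- match.arg(motif_type)
  stopifnot(is.character(residues), length(residues) == 1, nzchar(residues))
  cls <- motif_anchor_classes(motif_type)
  chars <- strsplit(residues, "")[[1]]
  p1_pos <- which(chars %in% cls$p1)
  ar_pos <- which(chars %in% cls$arom)
  p3_pos <- which(chars %in% cls$p3)
  empty <- data.frame(seq_id = character(), motif_type = character(),
                      start = integer(), end = integer(), p1 = integer(),
                      p_aromatic = integer(), p3 = integer(),
                      match = character(), stringsAsFactors = FALSE)
  if (length(p1_pos) == 0 || length(ar_pos) == 0 || length(p3_pos) == 0) {
    return(empty)
  }
  rows <- list()
  for (j in ar_pos) {
    left <- p1_pos[p1_pos >= j - 6L & p1_pos <= j - 2L]
    right <- p3_pos[p3_pos >= j + 2L & p3_pos <= j + 6L]
    if (length(left) == 0 || length(right) == 0) next
    grid <- expand.grid(p1 = left, p3 = right)
    grid$p_aromatic <- j
    rows[[length(rows) + 1L]] <- grid
  }
  if (length(rows) == 0L) return(empty)
  g <- do.call(rbind, rows)
  out <- data.frame(seq_id = seq_id, motif_type = motif_type,
                    start = g$p1, end = g$p3, p1 = g$p1,
                    p_aromatic = g$p_aromatic, p3 = g$p3,
                    match = substring(residues, g$p1, g$p3),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$start, out$end, out$p_aromatic), , drop = FALSE]
}

#' Collapse overlapping motif hits into maximal spans
#'
#' Counting conventions for motif totals differ; this merges hits whose
#' spans overlap into maximal disjoint intervals, giving the
#' merged-span motif count reported alongside the per-triple hit list.
#'
#' @param hits data.frame from [scan_motifs()].
#' @return data.frame with columns `start`, `end`, `n_hits`.
#' @export
merge_motif_spans <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(start = integer(), end = integer(), n_hits = integer()))
  }
  h <- hits[order(hits$start, hits$end), , drop = FALSE]
  starts <- ends <- counts <- integer(0)
  cur_s <- h$start[1]; cur_e <- h$end[1]; cur_n <- 1L
  for (i in seq_len(nrow(h))[-1]) {
    if (h$start[i] <= cur_e) {
      cur_e <- max(cur_e, h$end[i]); cur_n <- cur_n + 1L
    } else {
      starts <- c(starts, cur_s); ends <- c(ends, cur_e); counts <- c(counts, cur_n)
      cur_s <- h$start[i]; cur_e <- h$end[i]; cur_n <- 1L
    }
  }
  starts <- c(starts, cur_s); ends <- c(ends, cur_e); counts <- c(counts, cur_n)
  data.frame(start = starts, end = ends, n_hits = counts)
}

#' Construct a membrane topology annotation
#'
#' @param segments data.frame with columns `kind` (`"TM"`, `"inside"`,
#'   `"outside"`), `start`, `end` (1-based inclusive). Segments must be
#'   contiguous, non-overlapping, cover 1..L, and alternate between
#'   membrane (TM) and non-membrane kinds.
#' @param sequence_id identifier.
#' @return object of class `topology_annotation`; `n_term_side` is taken
#'   from the first non-TM segment (or, for a TM-first topology, the
#'   opposite side of the first loop).
#' @export
topology_annotation <- function(segments, sequence_id = "seq") {
  stopifnot(is.data.frame(segments),
            all(c("kind", "start", "end") %in% names(segments)),
            all(segments$kind %in% c("TM", "inside", "outside")))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (segments$start[1] != 1L) stop("topology must start at residue 1")
  if (nrow(segments) > 1 &&
      any(segments$start[-1] != segments$end[-nrow(segments)] + 1L)) {
    stop("topology segments must be contiguous and non-overlapping")
  }
  is_tm <- segments$kind == "TM"
  if (nrow(segments) > 1 && any(is_tm[-1] == is_tm[-length(is_tm)])) {
    stop("topology segments must alternate between TM and non-TM")
  }
  non_tm <- segments$kind[!is_tm]
  if (length(non_tm) > 1) {
    expected <- rep(c(non_tm[1], setdiff(c("inside", "outside"), non_tm[1])),
                    length.out = length(non_tm))
    if (any(non_tm != expected)) {
      stop("non-TM segments must alternate between inside and outside")
    }
  }
  n_term_side <- if (!is_tm[1]) segments$kind[1] else if (length(non_tm) > 0) {
    setdiff(c("inside", "outside"), non_tm[1])[1]
  } else "outside"
  structure(list(sequence_id = sequence_id, segments = segments,
                 n_term_side = n_term_side,
                 length = max(segments$end)),
            class = "topology_annotation")
}

#' Restrict motif hits to transmembrane segments
#'
#' Keeps hits whose span overlaps some TM segment by at least
#' `min_overlap_fraction` of the hit length, annotating each kept hit
#' with the index of the TM segment of maximal overlap.
#'
#' @param hits data.frame from [scan_motifs()].
#' @param topology a [topology_annotation()] covering the sequence.
#' @param min_overlap_fraction minimum overlap as a fraction of hit
#'   length (default 0.5).
#' @param sequence_length if given, checked against the topology extent.
#' @return the kept subset of `hits` with an added `tm_index` column.
#' @export
restrict_to_tm <- function(hits, topology, min_overlap_fraction = 0.5,
                           sequence_length = NULL) {
  stopifnot(inherits(topology, "topology_annotation"))
  if (!is.null(sequence_length) && topology$length != sequence_length) {
    stop("topology covers ", topology$length, " residues but sequence has ",
         sequence_length)
  }
  tm <- topology$segments[topology$segments$kind == "TM", , drop = FALSE]
  if (nrow(hits) == 0L || nrow(tm) == 0L) {
    out <- hits[0, , drop = FALSE]
    out$tm_index <- integer(0)
    return(out)
  }
  keep <- logical(nrow(hits))
  tm_idx <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- pmax(0L, pmin(hits$end[i], tm$end) - pmax(hits$start[i], tm$start) + 1L)
    len <- hits$end[i] - hits$start[i] + 1L
    j <- which.max(ov)
    if (ov[j] / len >= min_overlap_fraction) {
      keep[i] <- TRUE
      tm_idx[i] <- j
    }
  }
  out <- hits[keep, , drop = FALSE]
  out$tm_index <- tm_idx[keep]
  out
}

#' Test whether a topology is prominin-like
#'
#' A prominin-family candidate has exactly five transmembrane helices
#' whose four inter-TM loops are two large extracellular loops, each
#' strictly greater than `ec_min` residues, and two small intracellular
#' loops, each strictly smaller than `ic_max` residues (strict
#' inequalities, matching the curation rule "> 300" / "< 25").
#' Inter-TM loop sidedness follows from the N-terminal side and
#' alternation. N/C-terminal tails are not loops and are not checked.
#'
#' @param topology a [topology_annotation()].
#' @param ec_min extracellular loop length lower bound (exclusive), aa.
#' @param ic_max intracellular loop length upper bound (exclusive), aa.
#' @param n_tm required number of TM segments.
#' @return list with `is_prominin_like` (logical) and `reasons`
#'   (character vector of failed rules; empty when it passes).
#' @export
classify_prominin_topology <- function(topology, ec_min = 300, ic_max = 25,
                                       n_tm = 5) {
  stopifnot(inherits(topology, "topology_annotation"))
  seg <- topology$segments
  tm_rows <- which(seg$kind == "TM")
  reasons <- character(0)
  if (length(tm_rows) != n_tm) {
    reasons <- c(reasons, sprintf("n_tm: %d TM segments, expected %d",
                                  length(tm_rows), n_tm))
  }
  # inter-TM loops: non-TM segments strictly between the first and last TM
  if (length(tm_rows) >= 2) {
    loop_rows <- seq(min(tm_rows) + 1L, max(tm_rows) - 1L)
    loop_rows <- loop_rows[seg$kind[loop_rows] != "TM"]
    loops <- seg[loop_rows, , drop = FALSE]
    loops$len <- loops$end - loops$start + 1L
    ec <- loops[loops$kind == "outside", , drop = FALSE]
    ic <- loops[loops$kind == "inside", , drop = FALSE]
    if (nrow(ec) != 2) {
      reasons <- c(reasons, sprintf("n_ec_loops: %d extracellular loops, expected 2",
                                    nrow(ec)))
    }
    if (any(ec$len <= ec_min)) {
      reasons <- c(reasons, sprintf(
        "ec_loop_size: extracellular loop of %d aa not > %d aa",
        min(ec$len), ec_min))
    }
    if (nrow(ic) != 2) {
      reasons <- c(reasons, sprintf("n_ic_loops: %d intracellular loops, expected 2",
                                    nrow(ic)))
    }
    if (any(ic$len >= ic_max)) {
      reasons <- c(reasons, sprintf(
        "ic_loop_size: intracellular loop of %d aa not < %d aa",
        max(ic$len), ic_max))
    }
  } else if (length(tm_rows) < 2) {
    reasons <- c(reasons, "n_loops: fewer than 2 TM segments, no inter-TM loops")
  }
  list(is_prominin_like = length(reasons) == 0, reasons = reasons)
}

# ---- conservation scoring -------------------------------------------------

# Physicochemical property table (10 properties x 20 residues) for
# alignment-column conservation scoring, shipped as CSV so tests can pin
# its checksum.
conservation_property_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "residue_properties.csv",
                          package = "evquant")
      tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
      cache <<- as.matrix(tab) != 0
    }
    cache
  }
})

#' Score conservation of one alignment column
#'
#' Each residue is mapped to the presence/absence of ten physicochemical
#' properties (hydrophobic, polar, small, proline, tiny, aliphatic,
#' aromatic, positive, negative, charged). The column score is the
#' number of properties whose state (present in all, or absent from all)
#' is uniform across the counted residues; a column whose counted
#' residues are all the same amino acid scores 11 (identity). Gaps are
#' ignored by default; with `ignore_gaps = FALSE` any gap forces a score
#' of 0. An all-gap column yields `NA` with a flag.
#'
#' @param column character vector of single residues; `"-"` or `"."` is
#'   a gap. Residues absent from the property table (e.g. `X`) carry no
#'   properties.
#' @param ignore_gaps drop gaps before scoring (default `TRUE`).
#' @return one-row data.frame: `score` (0-11 or `NA`), `gap_fraction`,
#'   `all_gap` (logical).
#' @export
score_conservation <- function(column, ignore_gaps = TRUE) {
  stopifnot(is.character(column), length(column) >= 1)
  column <- toupper(column)
  is_gap <- column %in% c("-", ".", "")
  gap_fraction <- mean(is_gap)
  counted <- column[!is_gap]
  if (length(counted) == 0L) {
    return(data.frame(score = NA_integer_, gap_fraction = gap_fraction,
                      all_gap = TRUE))
  }
  if (!ignore_gaps && any(is_gap)) {
    return(data.frame(score = 0L, gap_fraction = gap_fraction,
                      all_gap = FALSE))
  }
  if (length(unique(counted)) == 1L) {
    return(data.frame(score = 11L, gap_fraction = gap_fraction,
                      all_gap = FALSE))
  }
  tab <- conservation_property_table()
  states <- matrix(FALSE, length(counted), ncol(tab))
  known <- counted %in% rownames(tab)
  states[known, ] <- tab[counted[known], , drop = FALSE]
  uniform <- vapply(seq_len(ncol(tab)), function(p) {
    length(unique(states[, p])) == 1L
  }, logical(1))
  data.frame(score = sum(uniform), gap_fraction = gap_fraction,
             all_gap = FALSE)
}

#' Score conservation for every column of an alignment
#'
#' @param alignment character vector of equal-length aligned sequences,
#'   or a [Biostrings::AAStringSet].
#' @inheritParams score_conservation
#' @return data.frame with one row per column: `column`, `score`,
#'   `gap_fraction`, `all_gap`.
#' @export
score_alignment_conservation <- function(alignment, ignore_gaps = TRUE) {
  if (inherits(alignment, "AAStringSet")) {
    alignment <- as.character(alignment)
  }
  stopifnot(is.character(alignment), length(alignment) >= 1)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) stop("aligned sequences must share a length")
  mat <- do.call(rbind, strsplit(alignment, ""))
  out <- do.call(rbind, lapply(seq_len(ncol(mat)), function(j) {
    score_conservation(mat[, j], ignore_gaps = ignore_gaps)
  }))
  cbind(column = seq_len(ncol(mat)), out)
}
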