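# Reporting arithmetic and hypothesis tests used across the pipeline:
# fraction records, fold changes, Student's pooled-variance t test,
# Mann-Whitney U, Bonferroni-adjusted significance thresholds, and the
# cross-module study report.

#' Fraction record with the 1-decimal percentage convention
#'
#' @param count non-negative integer numerator.
#' @param n positive integer denominator, `count <= n`.
#' @param condition_id label.
#' @return one-row data.frame: `condition_id`, `count`, `n`, `fraction`,
#'   `percent_1dp` (fraction x 100, rounded to 1 decimal).
#' @export
fraction_record <- function(count, n, condition_id = "condition") {
  stopifnot(count >= 0, n >= 1, count <= n, count == round(count),
            n == round(n))
  data.frame(condition_id = condition_id, count = as.integer(count),
             n = as.integer(n), fraction = count / n,
             percent_1dp = round(100 * count / n, 1),
             stringsAsFactors = FALSE)
}

#' Reconstruct an integer count from a printed 1-decimal percentage
#'
#' Inverts percentage reporting: returns `round(percent/100 * n)` and
#' verifies that this count, re-expressed as a 1-decimal percentage,
#' reproduces the input. If it does not (the printed percentage is
#' inconsistent or ambiguous for this n), an error lists every count
#' consistent with the printed value.
#'
#' @param percent_1dp printed percentage with one decimal (0..100).
#' @param n denominator.
#' @return integer count.
#' @export
reconstruct_count <- function(percent_1dp, n) {
  stopifnot(percent_1dp >= 0, percent_1dp <= 100, n >= 1)
  k <- round(percent_1dp / 100 * n)
  if (round(100 * k / n, 1) == percent_1dp) return(as.integer(k))
  consistent <- which(round(100 * (0:n) / n, 1) == percent_1dp) - 1L
  stop("count ", k, " re-rounds to ", round(100 * k / n, 1),
       "%, not ", percent_1dp, "%; consistent counts: ",
       if (length(consistent)) paste(consistent, collapse = ", ") else "none")
}

#' Fold change between two fraction records
#'
#' `value = (a$count/a$n) / (b$count/b$n)`, reported alongside its
#' 2-significant-figure rounding (the convention used for printed fold
#' changes).
#'
#' @param a,b one-row data.frames from [fraction_record()].
#' @return list: `value`, `value_2sf`, `undefined` (`TRUE` when b's
#'   count is 0, in which case `value` is `NA`).
#' @export
fraction_fold_change <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  if (b$count == 0) {
    return(list(value = NA_real_, value_2sf = NA_real_, undefined = TRUE))
  }
  v <- (a$count / a$n) / (b$count / b$n)
  list(value = v, value_2sf = signif(v, 2), undefined = FALSE)
}

#' Student's two-tailed unpaired t test (pooled variance)
#'
#' Classic equal-variance two-sample t test with df = n1 + n2 - 2 and a
#' two-tailed p value; Welch's unequal-variance form is available behind
#' `var_equal = FALSE`. Degenerate zero-variance inputs are handled by
#' convention: equal means give p = 1, unequal means give p = 0, both
#' flagged.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param var_equal pooled (Student's, default) vs Welch.
#' @return object of class `test_result` (a list): `test_name`,
#'   `statistic`, `p_value`, `df`, `n1`, `n2`, `degenerate`.
#' @export
student_t_test <- function(sample_a, sample_b, var_equal = TRUE) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2,
            all(is.finite(sample_a)), all(is.finite(sample_b)))
  n1 <- length(sample_a); n2 <- length(sample_b)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    equal <- mean(sample_a) == mean(sample_b)
    return(structure(list(test_name = "student_t",
                          statistic = if (equal) 0 else Inf,
                          p_value = if (equal) 1 else 0,
                          df = n1 + n2 - 2, n1 = n1, n2 = n2,
                          degenerate = TRUE),
                     class = "test_result"))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = var_equal,
                      alternative = "two.sided")
  structure(list(test_name = if (var_equal) "student_t" else "welch_t",
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 df = unname(ht$parameter), n1 = n1, n2 = n2,
                 degenerate = FALSE),
            class = "test_result")
}

#' Unpaired two-tailed Mann-Whitney U test
#'
#' U statistic computed from midranks. The two-tailed p value is exact
#' (full enumeration of rank assignments, as done by the base
#' distribution function) when `n1 + n2 <= exact_max` and the data are
#' tie-free; otherwise the normal approximation with tie correction and
#' continuity correction is used. `mode` forces one branch.
#'
#' @param sample_a,sample_b numeric vectors, length >= 1.
#' @param mode `"exact_if_small"` (default), `"exact"` or
#'   `"normal_approx"`.
#' @param exact_max largest combined sample size for the exact branch.
#' @return `test_result` list: `test_name`, `statistic` (U for sample
#'   a), `p_value`, `n1`, `n2`, `exact`.
#' @export
mann_whitney_u <- function(sample_a, sample_b,
                           mode = c("exact_if_small", "exact", "normal_approx"),
                           exact_max = 12) {
  mode <- match.arg(mode)
  stopifnot(length(sample_a) >= 1, length(sample_b) >= 1)
  n1 <- length(sample_a); n2 <- length(sample_b)
  ties <- any(duplicated(c(sample_a, sample_b)))
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal_approx = FALSE,
                      exact_if_small = (n1 + n2) <= exact_max && !ties)
  ht <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  structure(list(test_name = "mann_whitney",
                 statistic = unname(ht$statistic),
                 p_value = min(1, ht$p.value),
                 n1 = n1, n2 = n2, exact = use_exact),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise level, in (0, 1].
#' @param m number of comparisons, >= 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  alpha / m
}

#' Significance label under Bonferroni-adjusted thresholds
#'
#' Compares a p value to `alpha/m` for alpha in 0.05, 0.01, 0.001 and
#' returns the conventional star label (`"n.s."`, `"*"`, `"**"`,
#' `"***"`).
#'
#' @param p p value.
#' @param m number of comparisons.
#' @return character label.
#' @export
significance_label <- function(p, m = 1) {
  stopifnot(p >= 0, p <= 1)
  if (p < bonferroni_threshold(0.001, m)) return("***")
  if (p < bonferroni_threshold(0.01, m)) return("**")
  if (p < bonferroni_threshold(0.05, m)) return("*")
  "n.s."
}

#' Assemble the cross-module study report
#'
#' Merges population summaries, membrane fractions, bead condition
#' summaries, motif tables and test results into one versioned report
#' carrying the analysis parameters (roundness definition, class
#' thresholds, background mode, Bonferroni m) as metadata. Duplicate
#' condition ids across bead summaries raise an error.
#'
#' @param vesicles optional `population_summary` or named list of them.
#' @param membrane optional data.frame of membrane fractions.
#' @param beads optional list of `condition_summary` objects.
#' @param motifs optional motif hit data.frame.
#' @param tests optional named list of `test_result` objects.
#' @param parameters named list of analysis parameters to embed.
#' @return object of class `study_report` (a list, JSON-serializable via
#'   [write_report()]).
#' @export
build_report <- function(vesicles = NULL, membrane = NULL, beads = NULL,
                         motifs = NULL, tests = NULL,
                         parameters = list()) {
  if (is.null(vesicles) && is.null(membrane) && is.null(beads) &&
      is.null(motifs) && is.null(tests)) {
    stop("at least one module output is required")
  }
  if (!is.null(beads)) {
    if (inherits(beads, "condition_summary")) beads <- list(beads)
    ids <- vapply(beads, function(b) b$condition_id, character(1))
    if (anyDuplicated(ids)) {
      stop("conflicting condition ids in bead summaries: ",
           paste(ids[duplicated(ids)], collapse = ", "))
    }
  }
  defaults <- list(roundness_method = "feret",
                   tubular_threshold = 0.6,
                   non_round_threshold = 0.8,
                   bead_background_mode = "global_median_nonbead",
                   bonferroni_m = NA)
  parameters <- utils::modifyList(defaults, parameters)
  structure(list(report_version = "1.0",
                 parameters = parameters,
                 vesicles = vesicles, membrane = membrane, beads = beads,
                 motifs = motifs, tests = tests),
            class = "study_report")
}

#' Write a study report to disk
#'
#' Emits `report.json` plus one CSV per tabular section under
#' `out_dir/tables/`. Output is deterministic: no timestamps are
#' written, so identical inputs give byte-identical files.
#'
#' @param report a [build_report()] result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the path to `report.json`.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  strip <- function(x) {
    if (inherits(x, "population_summary") || inherits(x, "condition_summary") ||
        inherits(x, "test_result")) return(unclass(x))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  if (is.data.frame(report$membrane)) {
    utils::write.csv(report$membrane,
                     file.path(out_dir, "tables", "membrane_fractions.csv"),
                     row.names = FALSE)
  }
  if (is.data.frame(report$motifs)) {
    utils::write.csv(report$motifs,
                     file.path(out_dir, "tables", "motif_hits.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}
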