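# Co-occurrence summaries: per-marker positivity and conditional
# positivity percentages over ordered marker pairs, computed on
# pairwise-complete records only.

#' Summarize marker positivity and pairwise co-occurrence
#'
#' For every marker: number tested, number positive and positive percent.
#' For every ordered pair (A, B): the number of A-positive patients with a
#' B result, the number of those who are also B-positive, and the
#' conditional percent `100 * both / denominator`.  Pairs whose denominator
#' is zero are omitted from the report.
#'
#' Pair members may be any specification accepted by [marker_indicator()],
#' so TMB classes (`"TMB_HIGH"`, `"TMB_INTERMEDIATE"`, `"TMB_LOW"`) and the
#' composite `"ANY"` can be crossed with ordinary markers.
#'
#' @param cohort A [marker_cohort()]; must be nonempty.
#' @param pairs List of length-2 character vectors `(A, B)`.  Default: each
#'   immunotherapy marker crossed with every other marker, in both roles.
#' @param percent_digits Rounding for the reported percents: `1` for
#'   one-decimal (tabular) style, `0` for whole-percent (figure) style.
#' @return A `cooccurrence_report`: list with data frames `markers`
#'   (marker, tested, positive, percent) and `pairs`
#'   (a, b, n_a_pos_b_tested, n_both_pos, percent).
#' @export
cooccurrence_summary <- function(cohort, pairs = NULL, percent_digits = 1) {
  if (nrow(cohort) == 0L) stop("cohort is empty")
  if (is.null(pairs)) {
    pairs <- list()
    for (a in IMMUNO_MARKERS)
      for (b in setdiff(ALL_MARKERS, a))
        pairs <- c(pairs, list(c(a, b)), list(c(b, a)))
    pairs <- unique(pairs)
  }

  mk <- data.frame(marker = ALL_MARKERS,
                   tested = NA_integer_, positive = NA_integer_,
                   percent = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mk))) {
    ind <- marker_indicator(cohort, mk$marker[i])
    mk$tested[i] <- sum(ind$tested)
    mk$positive[i] <- sum(ind$positive)
    mk$percent[i] <- if (mk$tested[i] > 0)
      round(100 * mk$positive[i] / mk$tested[i], percent_digits) else NA_real_
  }

  pr <- data.frame(a = character(0), b = character(0),
                   n_a_pos_b_tested = integer(0), n_both_pos = integer(0),
                   percent = numeric(0), stringsAsFactors = FALSE)
  for (p in pairs) {
    ia <- marker_indicator(cohort, p[1])
    ib <- marker_indicator(cohort, p[2])
    denom <- sum(ia$positive & ib$tested)
    if (denom == 0L) next  # undefined conditional percent: pair omitted
    both <- sum(ia$positive & ib$positive)
    pr <- rbind(pr, data.frame(
      a = p[1], b = p[2], n_a_pos_b_tested = denom, n_both_pos = both,
      percent = round(100 * both / denom, percent_digits),
      stringsAsFactors = FALSE))
  }

  structure(list(markers = mk, pairs = pr,
                 percent_digits = percent_digits,
                 n_patients = nrow(cohort)),
            class = "cooccurrence_report")
}

#' @export
print.cooccurrence_report <- function(x, ...) {
  cat(sprintf("Co-occurrence report over %d patients\n", x$n_patients))
  cat("Per-marker positivity:\n")
  print(x$markers, row.names = FALSE)
  if (nrow(x$pairs)) {
    cat("Conditional positivity for ordered pairs (A positive, B tested):\n")
    print(x$pairs, row.names = FALSE)
  }
  invisible(x)
}

#' Write a co-occurrence report
#'
#' @param report A `cooccurrence_report`.
#' @param path Output path; one file for TSV (`<path>` gets the pair table,
#'   `<path>` with suffix `.markers.tsv` the marker table), a single JSON
#'   document for JSON.
#' @param format `"tsv"` or `"json"`.
#' @export
write_cooccurrence <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(n_patients = report$n_patients,
           percent_digits = report$percent_digits,
           markers = report$markers, pairs = report$pairs),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.table(report$pairs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(report$markers,
                       sub("(\\.tsv)?$", ".markers.tsv", path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
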