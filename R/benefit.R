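# Translation of association results into chemotherapy + immunotherapy
# combination-benefit verdicts.
#
# The decision rule for a pooled result: a significant odds ratio below 1
# means the protein marker's negative/low status is enriched in
# immunomarker-positive patients; above 1, its positive status is.  If the
# enriched status is the one that predicts drug sensitivity, the
# combination is likely to benefit; if it is the opposite status, the
# combination is unlikely to benefit; a non-significant result gives no
# association.  Heterogeneous pairs get per-tumor-type verdicts by the
# same rule applied to each significant stratum's sample odds ratio.

.verdict_from_or <- function(or, sensitive_when) {
  if (or == 1)
    stop("odds ratio exactly 1 with a significant p-value: inconsistent input")
  enriched <- if (or < 1) "negative" else "positive"
  if (enriched == sensitive_when) "likely_benefit" else "unlikely_benefit"
}

#' Map an association result to a combination-benefit verdict
#'
#' @param assoc An `association_result` (from [gated_association()] or
#'   [pooled_association()]).
#' @param direction A single-row marker-direction entry (see
#'   [default_marker_directions()]) whose `marker` matches the
#'   association's protein marker.
#' @return A `benefit_call`: list with `immunomarker`, `protein_marker`,
#'   `drugs`, `verdict` (one of `"likely_benefit"`, `"unlikely_benefit"`,
#'   `"no_association"`, `"heterogeneous"`) and `supporting` detail (the
#'   pooled statistics, or a per-stratum verdict data frame).
#' @export
map_benefit <- function(assoc, direction) {
  stopifnot(inherits(assoc, "association_result"))
  if (is.data.frame(direction)) {
    if (nrow(direction) != 1L) {
      direction <- direction[direction$marker == assoc$protein_marker, ]
      if (nrow(direction) != 1L)
        stop("no unique direction entry for marker ", assoc$protein_marker)
    }
    direction <- as.list(direction)
  }
  if (!identical(direction$marker, assoc$protein_marker))
    stop(sprintf("direction is for %s but association is for %s",
                 direction$marker, assoc$protein_marker))

  if (assoc$method == "pooled_mh") {
    p <- assoc$pooled$p_value
    or <- assoc$pooled$or
    verdict <- if (p > assoc$alpha) "no_association"
               else .verdict_from_or(or, direction$sensitive_when)
    supporting <- list(or = or, p_value = p,
                       ci_low = assoc$pooled$ci_low,
                       ci_high = assoc$pooled$ci_high)
  } else {
    per <- assoc$per_stratum
    per$verdict <- "no_association"
    sig <- which(per$significant)
    for (i in sig)
      per$verdict[i] <- .verdict_from_or(per$sample_or[i],
                                         direction$sensitive_when)
    verdict <- "heterogeneous"
    supporting <- per[c("stratum", "p_value", "sample_or", "verdict")]
  }
  structure(list(immunomarker = assoc$immunomarker,
                 protein_marker = assoc$protein_marker,
                 drugs = direction$drugs,
                 verdict = verdict,
                 breslow_day_p = assoc$breslow_day_p,
                 supporting = supporting),
            class = "benefit_call")
}

#' @export
print.benefit_call <- function(x, ...) {
  cat(sprintf("%s x %s (%s): %s\n", x$immunomarker, x$protein_marker,
              x$drugs, x$verdict))
  if (x$verdict == "heterogeneous") {
    sig <- x$supporting[x$supporting$verdict != "no_association", ]
    cat(sprintf("  %d of %d tumor types with a directional call\n",
                nrow(sig), nrow(x$supporting)))
  }
  invisible(x)
}

#' Benefit verdict grid over all marker pairs
#'
#' Runs [build_stratified_table()], [gated_association()] and
#' [map_benefit()] for each immunotherapy marker (MSI, TMB, PD-L1, plus
#' the composite ANY row) against each protein marker in the registry,
#' honoring per-protein stratum exclusions (by default ERCC1 pairs drop
#' nonsmall cell lung cancer, where ERCC1 is not considered predictive of
#' platinum response).
#'
#' @param cohort A [marker_cohort()].
#' @param registry Marker-direction registry
#'   (default [default_marker_directions()]).
#' @param alpha Significance level.
#' @param stratum_exclusions Named list: protein marker -> character
#'   vector of tumor types excluded for its pairs.
#' @param immunomarkers Immunotherapy-side rows of the grid.
#' @param correct,tarone Passed to [gated_association()].
#' Pairs whose stratified table is degenerate (no informative stratum, or
#' a zero/infinite pooled odds ratio) are reported with verdict
#' `"not_evaluable"` rather than aborting the grid.
#'
#' @return A `benefit_matrix`: data frame with one row per pair
#'   (`immunomarker`, `protein_marker`, `drugs`, `verdict`, `method`,
#'   `breslow_day_p`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   `n_significant_strata`, `n_used`), with the full `benefit_call`
#'   objects in the `"calls"` attribute.
#' @export
benefit_matrix <- function(cohort,
                           registry = default_marker_directions(),
                           alpha = 0.05,
                           stratum_exclusions =
                             list(ERCC1 = "nonsmall cell lung cancer"),
                           immunomarkers = c("MSI", "TMB", "PDL1", "ANY"),
                           correct = TRUE, tarone = FALSE) {
  if (nrow(cohort) == 0L) stop("cohort is empty")
  registry <- validate_marker_directions(registry)
  rows <- list()
  calls <- list()
  for (im in immunomarkers) {
    for (j in seq_len(nrow(registry))) {
      pm <- registry$marker[j]
      tab <- build_stratified_table(cohort, im, pm,
                                    excluded_strata =
                                      stratum_exclusions[[pm]])
      key <- paste(im, pm, sep = ":")
      assoc <- tryCatch(
        gated_association(tab, alpha = alpha, correct = correct,
                          tarone = tarone),
        error = function(e) e)
      if (inherits(assoc, "error")) {
        # degenerate pair (e.g. no informative stratum, or a zero/infinite
        # pooled odds ratio): report the cell as not evaluable
        rows[[key]] <- data.frame(
          immunomarker = im, protein_marker = pm,
          drugs = registry$drugs[j], verdict = "not_evaluable",
          method = NA_character_, breslow_day_p = NA_real_,
          or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          p_value = NA_real_, n_significant_strata = NA_integer_,
          n_used = attr(tab, "n_used"), stringsAsFactors = FALSE)
        next
      }
      call <- map_benefit(assoc, registry[j, ])
      calls[[key]] <- call
      pooled <- assoc$method == "pooled_mh"
      rows[[key]] <- data.frame(
        immunomarker = im,
        protein_marker = pm,
        drugs = registry$drugs[j],
        verdict = call$verdict,
        method = assoc$method,
        breslow_day_p = assoc$breslow_day_p,
        or = if (pooled) assoc$pooled$or else NA_real_,
        ci_low = if (pooled) assoc$pooled$ci_low else NA_real_,
        ci_high = if (pooled) assoc$pooled$ci_high else NA_real_,
        p_value = if (pooled) assoc$pooled$p_value else NA_real_,
        n_significant_strata =
          if (pooled) NA_integer_ else sum(assoc$per_stratum$significant),
        n_used = assoc$n_used,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, calls = calls, alpha = alpha,
            class = c("benefit_matrix", "data.frame"))
}

#' @export
print.benefit_matrix <- function(x, ...) {
  cat("Combination-benefit verdicts (rows: immunomarker, columns: protein marker)\n")
  grid <- stats::reshape(
    as.data.frame(x)[c("immunomarker", "protein_marker", "verdict")],
    idvar = "immunomarker", timevar = "protein_marker",
    direction = "wide")
  names(grid) <- sub("^verdict\\.", "", names(grid))
  print(grid, row.names = FALSE)
  invisible(x)
}

#' Write a benefit matrix
#'
#' @param matrix A `benefit_matrix`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_benefit_matrix <- function(matrix, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(matrix)
  if (format == "json") {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
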