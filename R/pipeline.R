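# End-to-end pipeline entry points: call markers from panel-level input
# files, then run the full association + benefit analysis, writing
# auditable delimited reports.  A thin command-line wrapper around these
# lives in inst/cli/immunochemo.

#' Pipeline run configuration
#'
#' @param output_dir Directory for report files (created if needed).
#' @param alpha Significance level in (0, 1).
#' @param percent_digits Rounding for co-occurrence percents.
#' @param stratum_exclusions Named list: protein marker -> tumor types to
#'   exclude from its pairs.  Default drops nonsmall cell lung cancer for
#'   ERCC1.
#' @param registry Marker-direction registry.
#' @param tumor_types Stratum list used when reading cohorts.
#' @param seed Optional integer seed set before any stochastic step.
#' @param verbose Emit per-stage record counts via [message()].
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir = ".",
                       alpha = 0.05,
                       percent_digits = 1,
                       stratum_exclusions =
                         list(ERCC1 = "nonsmall cell lung cancer"),
                       registry = default_marker_directions(),
                       tumor_types = default_tumor_types(),
                       seed = NULL,
                       verbose = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  registry <- validate_marker_directions(registry)
  structure(list(output_dir = output_dir, alpha = alpha,
                 percent_digits = percent_digits,
                 stratum_exclusions = stratum_exclusions,
                 registry = registry, tumor_types = tumor_types,
                 seed = seed, verbose = verbose),
            class = "run_config")
}

.say <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

#' Call markers for a cohort from panel-level input files
#'
#' Reads the skeleton (patient id + tumor type), locus observations,
#' mutation and IHC tables, derives every available marker status with
#' [call_markers()], and writes the augmented cohort as TSV.
#'
#' @param config A [run_config()].
#' @param skeleton_path Cohort skeleton TSV (`patient_id`, `tumor_type`).
#' @param catalog_path Microsatellite locus catalog TSV (unfiltered; the
#'   target filter is applied here).
#' @param locus_obs_path,mutations_path,ihc_path Optional input TSVs.
#' @param panel A [panel_definition()] with MSI threshold set if locus
#'   observations are given.
#' @param ihc_thresholds See [classify_ihc()].
#' @param out_file Output file name inside `config$output_dir`.
#' @return The called [marker_cohort()], invisibly; the TSV path is in
#'   attribute `"path"`.
#' @export
run_call_markers <- function(config, skeleton_path,
                             catalog_path = NULL,
                             locus_obs_path = NULL,
                             mutations_path = NULL,
                             ihc_path = NULL,
                             panel = panel_definition(),
                             ihc_thresholds = default_ihc_thresholds(),
                             out_file = "cohort_called.tsv") {
  for (p in c(skeleton_path, catalog_path, locus_obs_path,
              mutations_path, ihc_path)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  if (is.null(locus_obs_path) && is.null(mutations_path) &&
      is.null(ihc_path))
    stop("no marker-level inputs given: nothing to call")
  skeleton <- .read_delim_guess(skeleton_path)
  if (nrow(skeleton) == 0L) stop("cohort skeleton is empty")
  target_loci <- NULL
  if (!is.null(catalog_path)) {
    catalog <- read_locus_catalog(catalog_path)
    target_loci <- filter_locus_catalog(catalog)
    .say(config, "locus catalog: %d loci, %d targets after filtering",
         nrow(catalog), nrow(target_loci))
  }
  read_opt <- function(p) if (is.null(p)) NULL else .read_delim_guess(p)
  cohort <- call_markers(skeleton,
                         locus_observations = read_opt(locus_obs_path),
                         mutations = read_opt(mutations_path),
                         ihc_observations = read_opt(ihc_path),
                         target_loci = target_loci,
                         panel = panel,
                         ihc_thresholds = ihc_thresholds,
                         tumor_types = config$tumor_types)
  for (m in ALL_MARKERS) {
    .say(config, "%s: %d tested, %d positive", m,
         sum(!is.na(cohort[[m]])),
         sum(cohort[[m]] == "positive", na.rm = TRUE))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$output_dir, out_file)
  write_cohort(cohort, path)
  attr(cohort, "path") <- path
  invisible(cohort)
}

#' Run the full association and benefit analysis
#'
#' Builds every immunomarker x protein-marker stratified table (including
#' the composite ANY row), applies the Breslow-Day-gated Mantel-Haenszel /
#' Fisher procedure, maps verdicts, and writes the association summary,
#' the benefit grid (TSV + JSON) and the co-occurrence report.
#'
#' @param config A [run_config()].
#' @param cohort A [marker_cohort()] or a path to a cohort TSV.
#' @return The `benefit_matrix`, invisibly.
#' @export
run_associations <- function(config, cohort) {
  if (is.character(cohort))
    cohort <- read_cohort(cohort, tumor_types = config$tumor_types)
  if (!is.null(config$seed)) set.seed(config$seed)
  .say(config, "cohort: %d patients", nrow(cohort))

  bm <- benefit_matrix(cohort,
                       registry = config$registry,
                       alpha = config$alpha,
                       stratum_exclusions = config$stratum_exclusions)
  .say(config, "associations: %d pair rows (%d pooled, %d heterogeneous)",
       nrow(bm), sum(bm$method == "pooled_mh"),
       sum(bm$method == "per_stratum_fisher"))

  cooc <- cooccurrence_summary(cohort,
                               percent_digits = config$percent_digits)

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(bm),
                     file.path(config$output_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_benefit_matrix(bm, file.path(config$output_dir,
                                     "benefit_matrix.json"),
                       format = "json")
  write_cooccurrence(cooc, file.path(config$output_dir,
                                     "cooccurrence.tsv"))

  per_stratum <- attr(bm, "calls")
  het <- Filter(function(x) x$verdict == "heterogeneous", per_stratum)
  if (length(het)) {
    det <- do.call(rbind, lapply(het, function(x) {
      cbind(immunomarker = x$immunomarker,
            protein_marker = x$protein_marker,
            x$supporting)
    }))
    utils::write.table(det,
                       file.path(config$output_dir,
                                 "per_stratum_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bm)
}
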