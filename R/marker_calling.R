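# Derivation of marker statuses from panel-level inputs:
#   MSI  - count of microsatellite loci altered by repeat-changing somatic
#          indels, thresholded against a calibrated cut-off
#   TMB  - somatic nonsilent protein-coding mutations per megabase of panel
#          territory, classified high / intermediate / low
#   IHC  - percent of tumor cells stained plus staining intensity (0-3+),
#          thresholded per marker

#' Panel definition
#'
#' Bundles the sequencing-panel constants the callers need.  The TMB class
#' cut-points default to >= 17 mutations/Mb for high and < 6 for low, with
#' intermediate covering [6, 17).  The panel footprint and the MSI
#' altered-locus threshold are configuration: the threshold is either set
#' explicitly or obtained from [calibrate_msi_threshold()]; no default
#' constant is shipped.
#'
#' @param panel_size_mb Megabases of coding territory covered by the panel.
#' @param tmb_high_cutoff TMB high threshold in mutations/Mb (inclusive).
#' @param tmb_intermediate_lower Lower bound of the intermediate band
#'   (inclusive); values below are low.
#' @param msi_altered_loci_threshold Integer count of altered loci at or
#'   above which a sample is called MSI-high, or `NULL` if not yet set.
#' @return A `panel_definition` list.
#' @export
panel_definition <- function(panel_size_mb = 1.4,
                             tmb_high_cutoff = 17,
                             tmb_intermediate_lower = 6,
                             msi_altered_loci_threshold = NULL) {
  stopifnot(panel_size_mb > 0,
            tmb_intermediate_lower > 0,
            tmb_intermediate_lower < tmb_high_cutoff)
  if (!is.null(msi_altered_loci_threshold))
    stopifnot(msi_altered_loci_threshold >= 1)
  structure(list(panel_size_mb = panel_size_mb,
                 tmb_high_cutoff = tmb_high_cutoff,
                 tmb_intermediate_lower = tmb_intermediate_lower,
                 msi_altered_loci_threshold = msi_altered_loci_threshold),
            class = "panel_definition")
}

#' Read a microsatellite locus catalog
#'
#' Expected columns: `locus_id`, `chrom`, `pos`, `unit_length`,
#' `ref_repeat_count`, `low_coverage` (logical or 0/1).
#'
#' @param path TSV/CSV path.
#' @param sep Separator; guessed from extension when `NULL`.
#' @return Data frame of loci.
#' @export
read_locus_catalog <- function(path, sep = NULL) {
  cat_ <- .read_delim_guess(path, sep)
  required <- c("locus_id", "chrom", "pos", "unit_length",
                "ref_repeat_count", "low_coverage")
  missing <- setdiff(required, names(cat_))
  if (length(missing))
    stop("locus catalog is missing column(s): ",
         paste(missing, collapse = ", "))
  cat_$low_coverage <- as.logical(cat_$low_coverage)
  if (any(cat_$unit_length < 1) || any(cat_$ref_repeat_count < 1))
    stop("locus catalog has unit_length or ref_repeat_count < 1")
  cat_
}

#' Filter a microsatellite locus catalog to analysis targets
#'
#' Drops sex-chromosome loci, loci in regions flagged as typically
#' low-coverage, and loci whose repeat unit is longer than five
#' nucleotides.  Order is preserved and the result is always a subset, so
#' the filter is idempotent.
#'
#' @param catalog Data frame of loci (see [read_locus_catalog()]).
#' @param sex_chromosomes Chromosome labels counted as sex chromosomes.
#' @param max_unit_length Longest retained repeat unit (default 5 nt).
#' @return The filtered catalog.
#' @export
filter_locus_catalog <- function(catalog,
                                 sex_chromosomes = c("chrX", "chrY", "X", "Y"),
                                 max_unit_length = 5L) {
  if (nrow(catalog) == 0L) stop("locus catalog is empty")
  keep <- !(catalog$chrom %in% sex_chromosomes) &
    !catalog$low_coverage &
    catalog$unit_length <= max_unit_length
  catalog[keep, , drop = FALSE]
}

#' Count microsatellite loci altered by repeat-changing indels
#'
#' A locus counts as altered when at least one of its somatic indel events
#' changes the number of repeats, i.e. has a length change that is a
#' nonzero multiple of the locus repeat-unit length.  A locus is never
#' counted more than once, whatever the number or lengths of its events.
#' Events at catalog loci that were filtered out of the target set are
#' ignored; events at locus ids absent from `known_loci` are an error.
#'
#' @param observations Data frame with columns `patient_id`, `locus_id`,
#'   `length_delta` (signed, nonzero); all rows must belong to one patient.
#' @param target_loci Filtered catalog (see [filter_locus_catalog()]).
#' @param known_loci Character vector of all valid locus ids; defaults to
#'   the target catalog's ids, so that any off-target id errors.  Pass the
#'   unfiltered catalog's ids to silently ignore off-target events.
#' @return Integer count of distinct altered target loci.
#' @export
count_altered_loci <- function(observations, target_loci,
                               known_loci = target_loci$locus_id) {
  if (nrow(observations) == 0L) return(0L)
  if (length(unique(observations$patient_id)) > 1L)
    stop("observations must belong to a single patient")
  if (any(observations$length_delta == 0))
    stop("length_delta must be nonzero for every event")
  unknown <- setdiff(observations$locus_id, known_loci)
  if (length(unknown))
    stop("observation references unknown locus id(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  idx <- match(observations$locus_id, target_loci$locus_id)
  on_target <- !is.na(idx)
  unit <- target_loci$unit_length[idx[on_target]]
  delta <- observations$length_delta[on_target]
  changes_repeats <- delta %% unit == 0
  length(unique(observations$locus_id[on_target][changes_repeats]))
}

#' Classify MSI status from an altered-locus count
#'
#' @param altered_count Nonnegative integer count(s) of altered loci.
#' @param panel A [panel_definition()] with `msi_altered_loci_threshold`
#'   set.
#' @return `"positive"` (MSI-high) when the count is at or above the
#'   threshold, else `"negative"` (microsatellite stable).  Vectorized.
#' @export
classify_msi <- function(altered_count, panel) {
  if (is.null(panel$msi_altered_loci_threshold))
    stop("panel has no msi_altered_loci_threshold; set one or calibrate")
  stopifnot(all(altered_count >= 0))
  ifelse(altered_count >= panel$msi_altered_loci_threshold,
         "positive", "negative")
}

#' Calibrate the MSI altered-locus threshold against reference labels
#'
#' Scans every candidate integer cut-off and returns the one maximizing
#' concordance (accuracy) of the rule `count >= threshold => MSI-high`
#' with the reference labels (e.g. from fragment-analysis testing).  Ties
#' are broken toward the smallest threshold.
#'
#' @param altered_counts Integer vector of per-sample altered-locus counts.
#' @param reference_labels Corresponding labels, `"positive"`/`"negative"`
#'   (MSI-high / stable); both classes must be present.
#' @return List with `threshold` (positive integer) and `concordance`
#'   (achieved accuracy in `[0, 1]`).
#' @export
calibrate_msi_threshold <- function(altered_counts, reference_labels) {
  stopifnot(length(altered_counts) == length(reference_labels))
  lab <- reference_labels
  if (!all(lab %in% STATUS_LEVELS))
    stop("reference labels must be 'positive' or 'negative'")
  if (length(unique(lab)) < 2L)
    stop("threshold undefined: reference labels contain a single class")
  # Accuracy changes only at observed counts; candidate cut-offs are every
  # observed count and every observed count + 1 (and 1, the minimum legal).
  cand <- sort(unique(c(1L, altered_counts, altered_counts + 1L)))
  cand <- cand[cand >= 1L]
  acc <- vapply(cand, function(t)
    mean((altered_counts >= t) == (lab == "positive")), numeric(1))
  best <- which.max(acc)  # which.max takes the first (smallest) maximizer
  list(threshold = as.integer(cand[best]), concordance = acc[best])
}

#' Compute tumor mutational burden in mutations per megabase
#'
#' Counts somatic nonsilent protein-coding mutations, excluding copy-number
#' alterations and structural rearrangements (and silent or noncoding
#' records), divided by the panel footprint.
#'
#' @param mutations Data frame for one patient with columns `variant_class`
#'   (one of `"nonsilent_coding"`, `"silent"`, `"copy_number"`,
#'   `"structural"`, `"noncoding"`) and logical `somatic`.
#' @param panel A [panel_definition()].
#' @return Nonnegative mutations/Mb.
#' @export
compute_tmb <- function(mutations, panel) {
  if (nrow(mutations) == 0L) return(0)
  bad <- setdiff(unique(mutations$variant_class),
                 c("nonsilent_coding", "silent", "copy_number",
                   "structural", "noncoding"))
  if (length(bad))
    stop("unknown variant class(es): ", paste(bad, collapse = ", "))
  n <- sum(mutations$variant_class == "nonsilent_coding" & mutations$somatic)
  n / panel$panel_size_mb
}

#' Classify a TMB value into high / intermediate / low
#'
#' High means at or above the high cut-off (default 17 mutations/Mb), low
#' means below the intermediate lower bound (default 6), and intermediate
#' covers the half-open band between them, so every nonnegative value gets
#' exactly one class.
#'
#' @param tmb Nonnegative mutations/Mb (vectorized).
#' @param panel A [panel_definition()].
#' @return `"high"`, `"intermediate"` or `"low"`.
#' @export
classify_tmb <- function(tmb, panel) {
  stopifnot(all(tmb >= 0))
  ifelse(tmb >= panel$tmb_high_cutoff, "high",
         ifelse(tmb < panel$tmb_intermediate_lower, "low", "intermediate"))
}

#' Example immunohistochemistry positivity thresholds
#'
#' Per-marker minimum percent of stained tumor cells and minimum staining
#' intensity for a positive call.  These are package example defaults for
#' testing and simulation, not clinically validated cut-offs: real analyses
#' should supply laboratory-specific thresholds.
#'
#' @return Data frame with columns `marker`, `min_percent`, `min_intensity`.
#' @export
default_ihc_thresholds <- function() {
  data.frame(
    marker = c("PDL1", PROTEIN_MARKERS),
    min_percent = c(5, 10, 35, 50, 10, 30, 10, 30),
    min_intensity = c(2L, rep(1L, 7)),
    stringsAsFactors = FALSE
  )
}

#' Classify immunohistochemistry observations into positive / negative-low
#'
#' Positive iff the percent of stained tumor cells and the staining
#' intensity both reach the marker's thresholds (boundary values count as
#' positive).
#'
#' @param marker Marker name(s).
#' @param percent_positive Percent of tumor cells stained, 0-100.
#' @param intensity Staining intensity, integer 0-3.
#' @param thresholds Data frame as returned by [default_ihc_thresholds()].
#' @return `"positive"` or `"negative"` (vectorized).
#' @export
classify_ihc <- function(marker, percent_positive, intensity,
                         thresholds = default_ihc_thresholds()) {
  stopifnot(all(percent_positive >= 0 & percent_positive <= 100),
            all(intensity %in% 0:3))
  idx <- match(marker, thresholds$marker)
  if (anyNA(idx))
    stop("no IHC threshold configured for marker: ",
         paste(unique(marker[is.na(idx)]), collapse = ", "))
  ifelse(percent_positive >= thresholds$min_percent[idx] &
           intensity >= thresholds$min_intensity[idx],
         "positive", "negative")
}

#' Call all markers for a cohort from panel-level inputs
#'
#' Applies [count_altered_loci()] + [classify_msi()],
#' [compute_tmb()] + [classify_tmb()] and [classify_ihc()] patient by
#' patient, producing a [marker_cohort()] with derived statuses.  Patients
#' absent from an input table are untested for the corresponding marker(s).
#'
#' @param skeleton Data frame with `patient_id` and `tumor_type`.
#' @param locus_observations Data frame (`patient_id`, `locus_id`,
#'   `length_delta`) or `NULL`.
#' @param mutations Data frame (`patient_id`, `variant_class`, `somatic`)
#'   or `NULL`.
#' @param ihc_observations Data frame (`patient_id`, `marker`,
#'   `percent_positive`, `intensity`) or `NULL`.
#' @param target_loci Filtered locus catalog (required with
#'   `locus_observations`).
#' @param panel A [panel_definition()]; needs a calibrated MSI threshold
#'   when locus observations are supplied.
#' @param ihc_thresholds See [classify_ihc()].
#' @param tumor_types Stratum list for the resulting cohort.
#' @return A [marker_cohort()] with statuses filled in.
#' @export
call_markers <- function(skeleton,
                         locus_observations = NULL,
                         mutations = NULL,
                         ihc_observations = NULL,
                         target_loci = NULL,
                         panel = panel_definition(),
                         ihc_thresholds = default_ihc_thresholds(),
                         tumor_types = default_tumor_types()) {
  ids <- as.character(skeleton$patient_id)
  out <- data.frame(patient_id = ids,
                    tumor_type = as.character(skeleton$tumor_type),
                    stringsAsFactors = FALSE)
  for (m in ALL_MARKERS) out[[m]] <- NA_character_
  out$tmb_class <- NA_character_

  if (!is.null(locus_observations) && nrow(locus_observations)) {
    if (is.null(target_loci))
      stop("target_loci catalog required with locus observations")
    counts <- vapply(split(locus_observations,
                           locus_observations$patient_id),
                     count_altered_loci, integer(1),
                     target_loci = target_loci)
    hit <- match(names(counts), ids)
    out$MSI[hit[!is.na(hit)]] <-
      classify_msi(counts[!is.na(hit)], panel)
  }

  if (!is.null(mutations) && nrow(mutations)) {
    tmb <- vapply(split(mutations, mutations$patient_id),
                  compute_tmb, numeric(1), panel = panel)
    hit <- match(names(tmb), ids)
    cls <- classify_tmb(tmb[!is.na(hit)], panel)
    rows <- hit[!is.na(hit)]
    out$tmb_class[rows] <- cls
    out$TMB[rows] <- ifelse(cls == "high", "positive", "negative")
  }

  if (!is.null(ihc_observations) && nrow(ihc_observations)) {
    status <- classify_ihc(ihc_observations$marker,
                           ihc_observations$percent_positive,
                           ihc_observations$intensity,
                           thresholds = ihc_thresholds)
    for (i in seq_len(nrow(ihc_observations))) {
      row <- match(as.character(ihc_observations$patient_id[i]), ids)
      if (!is.na(row)) out[[ihc_observations$marker[i]]][row] <- status[i]
    }
  }

  marker_cohort(out, tumor_types = tumor_types)
}
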