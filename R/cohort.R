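# Cohort data model and delimited-text input/output.
#
# A cohort is a data frame with one row per patient:
#   patient_id  - opaque string, unique
#   tumor_type  - member of a configured stratum list
#   MSI, TMB, PDL1, ERCC1, MGMT, RRM1, TOP2A, TOPO1, TS, TUBB3
#               - "positive" / "negative" / NA (untested)
#   tmb_class   - "high" / "intermediate" / "low" / NA, consistent with TMB
# Missingness is explicit: NA means the marker was never tested for that
# patient, and every pairwise analysis uses pairwise-complete deletion.

#' Construct a marker cohort
#'
#' Validates a data frame of patient-level marker statuses and returns a
#' `marker_cohort` object.  Marker columns not present are added as all-`NA`
#' (never tested).  If `tmb_class` is absent it is derived from the `TMB`
#' status: `"high"` when positive, `NA` otherwise (the split of negatives
#' into intermediate and low is then unknown).
#'
#' @param data Data frame with at least `patient_id` and `tumor_type`
#'   columns, plus any of the marker columns listed above.
#' @param tumor_types Character vector of allowed stratum names.
#' @return A `marker_cohort`: the validated data frame with a
#'   `tumor_types` attribute.
#' @export
marker_cohort <- function(data, tumor_types = default_tumor_types()) {
  stopifnot(is.data.frame(data))
  if (!all(c("patient_id", "tumor_type") %in% names(data)))
    stop("cohort needs 'patient_id' and 'tumor_type' columns")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$patient_id <- as.character(data$patient_id)
  data$tumor_type <- as.character(data$tumor_type)

  unknown <- !(data$tumor_type %in% tumor_types)
  if (any(unknown)) {
    i <- which(unknown)[1L]
    stop(sprintf("row %d: unknown tumor type '%s'", i, data$tumor_type[i]))
  }

  for (m in ALL_MARKERS) {
    if (!m %in% names(data)) {
      data[[m]] <- NA_character_
    } else {
      data[[m]] <- as.character(data[[m]])
      bad <- !is.na(data[[m]]) & !(data[[m]] %in% STATUS_LEVELS)
      if (any(bad)) {
        i <- which(bad)[1L]
        stop(sprintf("row %d: malformed status token '%s' for marker %s",
                     i, data[[m]][i], m))
      }
    }
  }

  if (!"tmb_class" %in% names(data)) {
    data$tmb_class <- ifelse(!is.na(data$TMB) & data$TMB == "positive",
                             "high", NA_character_)
  } else {
    data$tmb_class <- as.character(data$tmb_class)
    bad <- !is.na(data$tmb_class) & !(data$tmb_class %in% TMB_CLASSES)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("row %d: malformed TMB class '%s'", i, data$tmb_class[i]))
    }
    # TMB high <=> status positive; intermediate/low <=> negative;
    # untested <=> untested.  Either field may be filled in from the
    # other; the representable gaps are a tested-negative patient whose
    # intermediate/low split was not recorded (class NA), and a positive
    # status without a class (implies high).
    derived <- ifelse(is.na(data$tmb_class), NA_character_,
                      ifelse(data$tmb_class == "high", "positive", "negative"))
    both <- !is.na(data$TMB) & !is.na(derived)
    mism <- which(both & data$TMB != derived)
    if (length(mism))
      stop(sprintf("row %d: TMB status '%s' inconsistent with tmb_class '%s'",
                   mism[1L], data$TMB[mism[1L]], data$tmb_class[mism[1L]]))
    fill <- is.na(data$TMB) & !is.na(derived)
    data$TMB[fill] <- derived[fill]
    fill_cls <- is.na(data$tmb_class) & !is.na(data$TMB) &
      data$TMB == "positive"
    data$tmb_class[fill_cls] <- "high"
  }

  keep <- c("patient_id", "tumor_type", ALL_MARKERS, "tmb_class")
  extra <- setdiff(names(data), keep)
  data <- data[c(keep, extra)]
  structure(data,
            tumor_types = tumor_types,
            class = c("marker_cohort", "data.frame"))
}

#' @export
print.marker_cohort <- function(x, ...) {
  cat(sprintf("Marker cohort: %d patients, %d tumor types in stratum list\n",
              nrow(x), length(attr(x, "tumor_types"))))
  tested <- vapply(ALL_MARKERS, function(m) sum(!is.na(x[[m]])), integer(1))
  pos <- vapply(ALL_MARKERS, function(m)
    sum(x[[m]] == "positive", na.rm = TRUE), integer(1))
  print(data.frame(marker = ALL_MARKERS, tested = tested, positive = pos,
                   row.names = NULL))
  invisible(x)
}

#' Read a patient cohort from a delimited text file
#'
#' The file must have a header row and one patient per row.  Column names
#' and status tokens are configurable; by default the canonical column names
#' are used and statuses are coded `"positive"` / `"negative"` with the
#' empty string meaning untested.
#'
#' @param path Path to a UTF-8 TSV or CSV file.
#' @param tumor_types Allowed stratum names; rows with other labels are
#'   rejected with the offending row number.
#' @param sep Field separator; guessed from the file extension when `NULL`.
#' @param status_tokens Named list with elements `positive`, `negative` and
#'   `untested` giving the tokens used in the file.
#' @param col_map Optional named character vector mapping canonical column
#'   names (`patient_id`, `tumor_type`, marker names, `tmb_class`) to the
#'   names used in the file.
#' @return A [marker_cohort()].
#' @export
read_cohort <- function(path, tumor_types = default_tumor_types(),
                        sep = NULL,
                        status_tokens = list(positive = "positive",
                                             negative = "negative",
                                             untested = ""),
                        col_map = NULL) {
  raw <- .read_delim_guess(path, sep)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw))
        names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  if (!all(c("patient_id", "tumor_type") %in% names(raw)))
    stop("cohort file must have 'patient_id' and 'tumor_type' columns ",
         "(after applying col_map)")

  decode <- function(x, col) {
    x <- as.character(x)
    x[is.na(x)] <- status_tokens$untested
    out <- rep(NA_character_, length(x))
    out[x == status_tokens$positive] <- "positive"
    out[x == status_tokens$negative] <- "negative"
    bad <- x != status_tokens$untested & is.na(out)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("row %d: malformed status token '%s' in column %s",
                   i, x[i], col))
    }
    out
  }
  for (m in intersect(ALL_MARKERS, names(raw))) raw[[m]] <- decode(raw[[m]], m)
  if ("tmb_class" %in% names(raw)) {
    tc <- as.character(raw$tmb_class)
    tc[is.na(tc) | tc == status_tokens$untested] <- NA_character_
    raw$tmb_class <- tolower(tc)
  }
  marker_cohort(raw, tumor_types = tumor_types)
}

#' Write a cohort back to delimited text
#'
#' Inverse of [read_cohort()] under the default tokens: writing then reading
#' reproduces the cohort field for field.
#'
#' @param cohort A [marker_cohort()].
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_cohort <- function(cohort, path, sep = "\t") {
  out <- as.data.frame(cohort)
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Composite immunotherapy-marker status
#'
#' Tri-state disjunction of the three immunotherapy-response markers:
#' positive if any of MSI, TMB or PD-L1 is positive; negative if none is
#' positive and at least one was tested; untested (`NA`) only when all
#' three are untested.
#'
#' @param cohort A [marker_cohort()] (or data frame with `MSI`, `TMB`,
#'   `PDL1` columns).
#' @return Character vector over the cohort: `"positive"`, `"negative"`
#'   or `NA`.
#' @export
any_immunomarker_positive <- function(cohort) {
  m <- cbind(cohort$MSI, cohort$TMB, cohort$PDL1)
  any_pos <- rowSums(m == "positive", na.rm = TRUE) > 0
  any_tested <- rowSums(!is.na(m)) > 0
  ifelse(any_pos, "positive", ifelse(any_tested, "negative", NA_character_))
}

#' Marker indicator with class-level and composite extensions
#'
#' Resolves a marker specification to a pair of logical vectors over the
#' cohort: whether each patient was tested for it and whether they are
#' positive for it.  Beyond the ten marker names, the specifications
#' `"TMB_HIGH"`, `"TMB_INTERMEDIATE"` and `"TMB_LOW"` select a single TMB
#' class (tested means TMB tested), and `"ANY"` is the composite of
#' [any_immunomarker_positive()].
#'
#' @param cohort A [marker_cohort()].
#' @param spec Marker specification string.
#' @return List with logical elements `tested` and `positive`.
#' @export
marker_indicator <- function(cohort, spec) {
  if (spec %in% ALL_MARKERS) {
    s <- cohort[[spec]]
    return(list(tested = !is.na(s), positive = !is.na(s) & s == "positive"))
  }
  if (spec %in% c("TMB_HIGH", "TMB_INTERMEDIATE", "TMB_LOW")) {
    cls <- tolower(sub("TMB_", "", spec))
    tested <- !is.na(cohort$TMB)
    positive <- !is.na(cohort$tmb_class) & cohort$tmb_class == cls
    return(list(tested = tested, positive = positive))
  }
  if (spec == "ANY") {
    s <- any_immunomarker_positive(cohort)
    return(list(tested = !is.na(s), positive = !is.na(s) & s == "positive"))
  }
  stop("unknown marker specification: ", spec)
}
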