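# Marker vocabulary shared by every module.

#' Marker names
#'
#' The pipeline works with three immunotherapy-response markers (MSI status,
#' TMB class collapsed to high vs intermediate/low, PD-L1 expression) and
#' seven chemotherapy-response protein markers scored by
#' immunohistochemistry.
#'
#' @format Character vectors of canonical marker names.
#' @name marker_names
NULL

#' @rdname marker_names
#' @export
IMMUNO_MARKERS <- c("MSI", "TMB", "PDL1")

#' @rdname marker_names
#' @export
PROTEIN_MARKERS <- c("ERCC1", "MGMT", "RRM1", "TOP2A", "TOPO1", "TS", "TUBB3")

#' @rdname marker_names
#' @export
ALL_MARKERS <- c(IMMUNO_MARKERS, PROTEIN_MARKERS)

# Tri-state status tokens used throughout: "positive", "negative", NA
# (untested).  For MSI, "positive" means MSI-high and "negative" means
# microsatellite stable; for TMB, "positive" means TMB-high.
STATUS_LEVELS <- c("positive", "negative")

TMB_CLASSES <- c("high", "intermediate", "low")

#' Default tumor-type stratum list
#'
#' A packaged list of 40 solid-tumor histologies used as the default
#' stratification for the Mantel-Haenszel analysis.  Any character vector of
#' stratum names can be supplied instead wherever a cohort is read or
#' simulated.
#'
#' @return Character vector of 40 tumor-type names.
#' @export
default_tumor_types <- function() {
  c("bladder cancer",
    "breast cancer",
    "cholangiocarcinoma",
    "colorectal cancer",
    "cancer of unknown primary",
    "epithelial ovarian cancer",
    "esophageal cancer",
    "female genital tract malignancy",
    "gastric cancer",
    "gastrointestinal stromal tumor",
    "glioblastoma",
    "head and neck cancer",
    "kidney cancer",
    "melanoma",
    "merkel cell carcinoma",
    "mesothelioma",
    "neuroendocrine tumor",
    "nonepithelial ovarian cancer",
    "nonmelanoma skin cancer",
    "nonsmall cell lung cancer",
    "pancreatic cancer",
    "small intestinal cancer",
    "soft tissue sarcoma",
    "adrenocortical carcinoma",
    "ampullary carcinoma",
    "anal cancer",
    "appendiceal cancer",
    "bone sarcoma",
    "gallbladder cancer",
    "germ cell tumor",
    "hepatocellular carcinoma",
    "low-grade glioma",
    "meningioma",
    "neuroblastoma",
    "prostate cancer",
    "salivary gland cancer",
    "small cell lung cancer",
    "thymic carcinoma",
    "thyroid cancer",
    "uveal melanoma")
}

#' Default marker-direction registry
#'
#' For each chemotherapy-response protein marker, records which status level
#' predicts drug sensitivity and which drugs that prediction covers.  ERCC1,
#' MGMT, RRM1, TS and TUBB3 predict sensitivity when negative/low; TOP2A and
#' TOPO1 predict sensitivity when positive.
#'
#' @return A data frame with columns `marker`, `sensitive_when` (one of
#'   `"negative"`, `"positive"`) and `drugs` (slash-separated drug names).
#' @export
default_marker_directions <- function() {
  data.frame(
    marker = c("ERCC1", "MGMT", "RRM1", "TS", "TUBB3", "TOP2A", "TOPO1"),
    sensitive_when = c("negative", "negative", "negative", "negative",
                       "negative", "positive", "positive"),
    drugs = c("platinum",
              "dacarbazine/temozolomide",
              "gemcitabine",
              "fluorouracil/pemetrexed/capecitabine",
              "taxanes",
              "doxorubicin/epirubicin/etoposide",
              "irinotecan/topotecan"),
    stringsAsFactors = FALSE
  )
}

#' Read a marker-direction registry from a delimited file
#'
#' The file must have columns `marker`, `sensitive_when` and `drugs`.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return A validated registry data frame (see [default_marker_directions()]).
#' @export
read_marker_directions <- function(path, sep = NULL) {
  reg <- .read_delim_guess(path, sep)
  required <- c("marker", "sensitive_when", "drugs")
  missing <- setdiff(required, names(reg))
  if (length(missing))
    stop("marker-direction file is missing column(s): ",
         paste(missing, collapse = ", "))
  validate_marker_directions(reg[required])
}

validate_marker_directions <- function(registry) {
  if (anyDuplicated(registry$marker))
    stop("marker-direction registry lists a marker more than once")
  bad <- setdiff(registry$sensitive_when, STATUS_LEVELS)
  if (length(bad))
    stop("invalid sensitive_when value(s): ", paste(bad, collapse = ", "))
  unknown <- setdiff(registry$marker, PROTEIN_MARKERS)
  if (length(unknown))
    stop("unknown protein marker(s) in registry: ",
         paste(unknown, collapse = ", "))
  registry
}

# Shared delimited-file reader: tab for .tsv/.txt, comma for .csv.
.read_delim_guess <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = NULL)
}
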