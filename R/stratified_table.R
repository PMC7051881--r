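# Stratified 2x2 tables: one 2x2 per tumor type for an
# immunomarker x protein-marker pair.
#
# Cell layout per stratum:
#   a = immunomarker positive & protein positive
#   b = immunomarker positive & protein negative
#   c = immunomarker negative & protein positive
#   d = immunomarker negative & protein negative

#' Construct a stratified 2x2 table
#'
#' @param counts Data frame with columns `stratum`, `a`, `b`, `c`, `d`
#'   (nonnegative integers; stratum names unique).
#' @param immunomarker,protein_marker Pair labels.
#' @return A `stratified_table`: the counts data frame with pair labels
#'   and `n_used` (total count) attributes, plus an `informative` logical
#'   column flagging strata where both margins vary.
#' @export
stratified_table <- function(counts, immunomarker = NA_character_,
                             protein_marker = NA_character_) {
  stopifnot(is.data.frame(counts),
            all(c("stratum", "a", "b", "c", "d") %in% names(counts)))
  cells <- as.matrix(counts[c("a", "b", "c", "d")])
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  if (anyDuplicated(counts$stratum))
    stop("stratum names must be unique")
  counts <- counts[c("stratum", "a", "b", "c", "d")]
  counts$a <- as.integer(counts$a); counts$b <- as.integer(counts$b)
  counts$c <- as.integer(counts$c); counts$d <- as.integer(counts$d)
  # A stratum is informative when no row or column margin is zero: only
  # then does it contribute to the stratified statistics.
  counts$informative <- with(counts,
    (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0)
  structure(counts,
            immunomarker = immunomarker,
            protein_marker = protein_marker,
            n_used = sum(cells),
            class = c("stratified_table", "data.frame"))
}

#' @export
print.stratified_table <- function(x, ...) {
  cat(sprintf("Stratified 2x2 table: %s x %s, %d strata, n = %d\n",
              attr(x, "immunomarker"), attr(x, "protein_marker"),
              nrow(x), attr(x, "n_used")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Build a stratified table from a cohort
#'
#' Cross-tabulates an immunotherapy marker (or `"ANY"`, the composite)
#' against a protein marker within each tumor type, using only patients
#' tested for both (pairwise-complete deletion).  Strata named in
#' `excluded_strata` are omitted entirely, as are strata with no
#' pairwise-complete patient.
#'
#' @param cohort A [marker_cohort()].
#' @param immunomarker One of `"MSI"`, `"TMB"`, `"PDL1"`, `"ANY"`.
#' @param protein_marker One of the seven protein marker names.
#' @param excluded_strata Character vector of tumor types to drop for this
#'   pair (e.g. nonsmall cell lung cancer for ERCC1).
#' @return A [stratified_table()].
#' @export
build_stratified_table <- function(cohort, immunomarker, protein_marker,
                                   excluded_strata = NULL) {
  if (identical(immunomarker, protein_marker))
    stop("immunomarker and protein marker must differ")
  im <- marker_indicator(cohort, immunomarker)
  pm <- marker_indicator(cohort, protein_marker)
  use <- im$tested & pm$tested &
    !(cohort$tumor_type %in% excluded_strata)
  tt <- cohort$tumor_type[use]
  ip <- im$positive[use]
  pp <- pm$positive[use]
  strata <- unique(tt)
  counts <- data.frame(
    stratum = strata,
    a = vapply(strata, function(s) sum(tt == s & ip & pp), numeric(1)),
    b = vapply(strata, function(s) sum(tt == s & ip & !pp), numeric(1)),
    c = vapply(strata, function(s) sum(tt == s & !ip & pp), numeric(1)),
    d = vapply(strata, function(s) sum(tt == s & !ip & !pp), numeric(1)),
    stringsAsFactors = FALSE)
  stratified_table(counts, immunomarker, protein_marker)
}

#' Read / write stratified tables as TSV
#'
#' Plain four-count-per-stratum files (`stratum`, `a`, `b`, `c`, `d`) so
#' tables can be analyzed standalone.
#'
#' @param path File path.
#' @param sep Separator; guessed from extension when `NULL`.
#' @param immunomarker,protein_marker Pair labels for the imported table.
#' @return [read_stratified_table()] returns a [stratified_table()];
#'   `write_stratified_table` returns the path invisibly.
#' @export
read_stratified_table <- function(path, sep = NULL,
                                  immunomarker = NA_character_,
                                  protein_marker = NA_character_) {
  stratified_table(.read_delim_guess(path, sep), immunomarker,
                   protein_marker)
}

#' @rdname read_stratified_table
#' @param table A [stratified_table()].
#' @export
write_stratified_table <- function(table, path, sep = "\t") {
  utils::write.table(as.data.frame(table)[c("stratum", "a", "b", "c", "d")],
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
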