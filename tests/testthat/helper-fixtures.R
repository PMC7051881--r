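# Fixture builders shared across test files.  Everything is generated in
# code; no data files.

# A tiny hand-written cohort covering the tri-state conventions.
tiny_cohort <- function() {
  marker_cohort(data.frame(
    patient_id = sprintf("P%02d", 1:6),
    tumor_type = c("colorectal cancer", "colorectal cancer",
                   "breast cancer", "breast cancer",
                   "melanoma", "melanoma"),
    MSI   = c("positive", "negative", "negative", NA, "negative", "positive"),
    TMB   = c("positive", "negative", NA, "negative", "negative", "negative"),
    PDL1  = c(NA, "negative", "positive", NA, "negative", "negative"),
    ERCC1 = c("negative", "positive", "negative", "negative", NA, "negative"),
    tmb_class = c("high", "intermediate", NA, "low", "low", "intermediate"),
    stringsAsFactors = FALSE))
}

# Random 2x2 with given total n (uniform over margins, then cell).
random_2x2 <- function(n_max = 200) {
  n <- sample(1:n_max, 1)
  m1 <- sample(0:n, 1)
  t1 <- sample(0:n, 1)
  lo <- max(0, t1 - (n - m1)); hi <- min(m1, t1)
  a <- (lo:hi)[sample.int(hi - lo + 1, 1)]
  c(a = a, b = m1 - a, c = t1 - a, d = n - m1 - t1 + a)
}

# Stratified table literal.
st <- function(a, b, c, d, strata = NULL,
               immunomarker = "MSI", protein_marker = "ERCC1") {
  if (is.null(strata)) strata <- sprintf("S%02d", seq_along(a))
  stratified_table(data.frame(stratum = strata, a = a, b = b, c = c, d = d,
                              stringsAsFactors = FALSE),
                   immunomarker, protein_marker)
}

# Cohort whose TMB-class x MSI cross-tabulation is fixed exactly:
# counts named high_pos, high_neg, int_pos, int_neg, low_pos, low_neg,
# untested_msi_neg (MSI tested, TMB untested).
exact_msi_tmb_cohort <- function(high_pos, high_neg, int_pos, int_neg,
                                 low_pos, low_neg, untested_msi_neg = 0) {
  blocks <- list(
    c("positive", "high"),  c("negative", "high"),
    c("positive", "intermediate"), c("negative", "intermediate"),
    c("positive", "low"), c("negative", "low"))
  counts <- c(high_pos, high_neg, int_pos, int_neg, low_pos, low_neg)
  msi <- character(0); cls <- character(0)
  for (i in seq_along(blocks)) {
    msi <- c(msi, rep(blocks[[i]][1], counts[i]))
    cls <- c(cls, rep(blocks[[i]][2], counts[i]))
  }
  msi <- c(msi, rep("negative", untested_msi_neg))
  cls <- c(cls, rep(NA_character_, untested_msi_neg))
  tmb <- ifelse(is.na(cls), NA_character_,
                ifelse(cls == "high", "positive", "negative"))
  marker_cohort(data.frame(
    patient_id = sprintf("P%07d", seq_along(msi)),
    tumor_type = "colorectal cancer",
    MSI = msi, TMB = tmb, tmb_class = cls,
    stringsAsFactors = FALSE))
}
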