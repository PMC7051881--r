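# MSI locus filtering and counting, threshold calibration, TMB, IHC.

make_catalog <- function() {
  data.frame(
    locus_id = c("L1", "L2", "L3", "L4", "L5"),
    chrom = c("chrX", "chr2", "chr3", "chr4", "chr5"),
    pos = 1:5 * 1000L,
    unit_length = c(2L, 2L, 6L, 1L, 3L),
    ref_repeat_count = c(10L, 12L, 8L, 20L, 9L),
    low_coverage = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

test_that("locus catalog filtering removes each offender exactly once", {
  cat5 <- make_catalog()
  filt <- filter_locus_catalog(cat5)
  expect_equal(filt$locus_id, c("L4", "L5"))  # sexchrom, lowcov, unit>5 out
  # idempotent and identity on clean catalogs
  expect_identical(filter_locus_catalog(filt), filt)
  # overlapping offenses remove a locus once, keep the rest
  cat5$chrom[2] <- "chrY"  # L2 now sex-chromosome AND low-coverage
  filt2 <- filter_locus_catalog(cat5)
  expect_equal(filt2$locus_id, c("L4", "L5"))
  # brute-force set-filter oracle
  oracle <- cat5[!(cat5$chrom %in% c("chrX", "chrY", "X", "Y")) &
                   !cat5$low_coverage & cat5$unit_length <= 5, ]
  expect_equal(filt2$locus_id, oracle$locus_id)
})

test_that("altered-locus counting: once per locus, multiples of the unit only", {
  targets <- filter_locus_catalog(make_catalog())  # L4 (unit 1), L5 (unit 3)
  obs <- data.frame(patient_id = "P1",
                    locus_id = c("L5", "L5", "L5"),
                    length_delta = c(3L, -6L, 1L),
                    stringsAsFactors = FALSE)
  # two repeat-changing events at one locus count once; +1 at unit-3 ignored
  expect_equal(count_altered_loci(obs, targets), 1L)
  # a lone non-multiple delta does not change the repeat count
  obs2 <- data.frame(patient_id = "P1", locus_id = "L5",
                     length_delta = 2L, stringsAsFactors = FALSE)
  expect_equal(count_altered_loci(obs2, targets), 0L)
  # duplicating an already-counted event leaves the count unchanged
  expect_equal(count_altered_loci(rbind(obs, obs[1, ]), targets), 1L)
  # unknown locus errors; off-target but known is ignored
  bad <- data.frame(patient_id = "P1", locus_id = "L99",
                    length_delta = 2L, stringsAsFactors = FALSE)
  expect_error(count_altered_loci(bad, targets), "unknown locus")
  offt <- data.frame(patient_id = "P1", locus_id = "L1",
                     length_delta = 2L, stringsAsFactors = FALSE)
  expect_equal(count_altered_loci(offt, targets,
                                  known_loci = make_catalog()$locus_id), 0L)
})

test_that("set-cardinality oracle: distinct altered targets are counted", {
  set.seed(42)
  targets <- data.frame(locus_id = sprintf("T%02d", 1:8),
                        chrom = "chr1", pos = 1:8,
                        unit_length = rep(2L, 8),
                        ref_repeat_count = 10L, low_coverage = FALSE,
                        stringsAsFactors = FALSE)
  loci <- sample(targets$locus_id[1:4], 10, replace = TRUE)
  obs <- data.frame(patient_id = "P1", locus_id = loci,
                    length_delta = sample(c(-4L, -2L, 2L, 4L), 10,
                                          replace = TRUE),
                    stringsAsFactors = FALSE)
  expect_equal(count_altered_loci(obs, targets),
               length(unique(loci)))
})

test_that("MSI threshold calibration maximizes concordance, smallest tie", {
  cal <- calibrate_msi_threshold(c(1L, 2L, 3L, 40L, 41L),
                                 c("negative", "negative", "negative",
                                   "positive", "positive"))
  expect_equal(cal$threshold, 4L)
  expect_equal(cal$concordance, 1)
  # interleaved labels: exhaustive-scan oracle
  counts <- c(1L, 2L, 3L, 4L, 5L, 6L)
  labels <- c("negative", "positive", "negative", "positive",
              "positive", "positive")
  cal2 <- calibrate_msi_threshold(counts, labels)
  acc <- vapply(1:7, function(t)
    mean((counts >= t) == (labels == "positive")), numeric(1))
  expect_equal(cal2$concordance, max(acc))
  expect_equal(cal2$threshold, which.max(acc))
  expect_error(calibrate_msi_threshold(c(1L, 2L), c("negative", "negative")),
               "single class")
})

test_that("MSI classification thresholds at >= and recovers separated truth", {
  panel <- panel_definition(msi_altered_loci_threshold = 10L)
  expect_equal(classify_msi(0, panel), "negative")
  expect_equal(classify_msi(10, panel), "positive")  # boundary inclusive
  expect_equal(classify_msi(9, panel), "negative")
  set.seed(7)
  truth <- rep(c("negative", "positive"), each = 300)
  counts <- c(rpois(300, 3), rpois(300, 45))
  cal <- calibrate_msi_threshold(counts, truth)
  panel2 <- panel_definition(msi_altered_loci_threshold = cal$threshold)
  expect_gte(mean(classify_msi(counts, panel2) == truth), 0.99)
})

test_that("TMB computation counts somatic nonsilent coding only", {
  panel <- panel_definition(panel_size_mb = 1.0)
  muts <- data.frame(
    variant_class = c(rep("nonsilent_coding", 17), rep("copy_number", 3),
                      rep("structural", 2)),
    somatic = TRUE, stringsAsFactors = FALSE)
  expect_equal(compute_tmb(muts, panel), 17.0)
  expect_equal(compute_tmb(muts[0, ], panel), 0.0)
  panel14 <- panel_definition(panel_size_mb = 1.4)
  muts21 <- data.frame(variant_class = rep("nonsilent_coding", 21),
                       somatic = TRUE, stringsAsFactors = FALSE)
  expect_equal(compute_tmb(muts21, panel14), 15.0)
  # germline records are excluded too
  muts$somatic[1:5] <- FALSE
  expect_equal(compute_tmb(muts, panel), 12.0)
})

test_that("TMB classification partitions [0, Inf) with stated cut-points", {
  panel <- panel_definition()
  expect_equal(classify_tmb(17.0, panel), "high")
  expect_equal(classify_tmb(5.99, panel), "low")
  expect_equal(classify_tmb(16.5, panel), "intermediate")
  expect_equal(classify_tmb(6.0, panel), "intermediate")
  grid <- c(0, runif(500, 0, 40), 6, 16, 16.999, 17, 100)
  cls <- classify_tmb(grid, panel)
  expect_true(all(cls %in% c("high", "intermediate", "low")))
  expect_equal(cls, ifelse(grid >= 17, "high",
                           ifelse(grid < 6, "low", "intermediate")))
})

test_that("IHC classification is the two-condition conjunction at boundaries", {
  thr <- data.frame(marker = "ERCC1", min_percent = 10, min_intensity = 1L,
                    stringsAsFactors = FALSE)
  expect_equal(classify_ihc("ERCC1", 0, 0L, thr), "negative")
  expect_equal(classify_ihc("ERCC1", 10, 1L, thr), "positive")  # boundary
  expect_error(classify_ihc("MGMT", 50, 2L, thr), "MGMT")
  set.seed(11)
  pct <- sample(0:100, 300, replace = TRUE)
  int <- sample(0:3, 300, replace = TRUE)
  got <- classify_ihc(rep("ERCC1", 300), pct, int, thr)
  oracle <- ifelse(pct >= 10 & int >= 1, "positive", "negative")
  expect_equal(got, oracle)
})

test_that("end-to-end caller recovers simulated truth", {
  set.seed(123)
  cfg <- cohort_sim_config(n_patients = 300,
                           tumor_types = c("melanoma", "breast cancer"),
                           seed = 5)
  cohort <- generate_cohort(cfg)
  catalog <- simulate_locus_catalog(150)
  targets <- filter_locus_catalog(catalog)
  panel <- panel_definition(panel_size_mb = 1.4,
                            msi_altered_loci_threshold = 15L)
  prof <- generate_ngs_profile(cohort, targets, panel)
  called <- call_markers(as.data.frame(cohort)[c("patient_id", "tumor_type")],
                         locus_observations = prof$locus_observations,
                         mutations = prof$mutations,
                         ihc_observations = prof$ihc_observations,
                         target_loci = targets, panel = panel,
                         tumor_types = c("melanoma", "breast cancer"))
  for (m in c("MSI", "PDL1", "ERCC1", "TOPO1")) {
    both <- !is.na(cohort[[m]]) & !is.na(called[[m]])
    expect_gte(mean(cohort[[m]][both] == called[[m]][both]), 0.99)
  }
  both <- !is.na(cohort$tmb_class) & !is.na(called$tmb_class)
  expect_equal(cohort$tmb_class[both], called$tmb_class[both])
})
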