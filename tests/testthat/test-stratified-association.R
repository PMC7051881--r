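# The stratified association engine against independent oracles:
# stats::fisher.test and stats::mantelhaen.test live, Breslow-Day values
# frozen from an independent reference implementation.

test_that("stratified tables use pairwise-complete records and exclusions", {
  cohort <- tiny_cohort()
  tab <- build_stratified_table(cohort, "TMB", "ERCC1")
  # P3 (TMB untested) and P5 (ERCC1 untested) drop out
  expect_equal(attr(tab, "n_used"), 4L)
  expect_error(build_stratified_table(cohort, "MSI", "MSI"), "differ")
  # shuffling records leaves the table unchanged
  perm <- marker_cohort(as.data.frame(cohort)[c(4, 2, 6, 1, 3, 5), ])
  tab2 <- build_stratified_table(perm, "TMB", "ERCC1")
  o1 <- tab[order(tab$stratum), c("a", "b", "c", "d")]
  o2 <- tab2[order(tab2$stratum), c("a", "b", "c", "d")]
  expect_equal(as.matrix(o1), as.matrix(o2), ignore_attr = TRUE)
  # stratum exclusion removes the stratum entirely
  tab3 <- build_stratified_table(cohort, "TMB", "ERCC1",
                                 excluded_strata = "colorectal cancer")
  expect_false("colorectal cancer" %in% tab3$stratum)
})

test_that("stratified table round-trips through TSV", {
  tab <- st(a = c(3, 5), b = c(7, 2), c = c(4, 9), d = c(11, 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stratified_table(tab, path)
  back <- read_stratified_table(path, immunomarker = "MSI",
                                protein_marker = "ERCC1")
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("fisher_exact matches stats::fisher.test across random tables", {
  set.seed(2024)
  for (i in 1:300) {
    x <- random_2x2(200)
    if (sum(x) == 0) next
    mine <- fisher_exact(x["a"], x["b"], x["c"], x["d"])
    ref <- stats::fisher.test(matrix(c(x["a"], x["c"], x["b"], x["d"]), 2))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("fisher_exact handles symmetric, enumerated and zero-cell tables", {
  expect_equal(fisher_exact(5, 5, 5, 5)$p_value, 1.0)
  # margins (4,4;4,4): 5 tables; p for a=3 by direct enumeration
  probs <- dhyper(0:4, 4, 4, 4)
  expected <- sum(probs[probs <= probs[4] * (1 + 1e-7)])
  expect_equal(fisher_exact(3, 1, 1, 3)$p_value, expected)
  f <- fisher_exact(2, 0, 0, 2)
  probs2 <- dhyper(0:2, 2, 2, 2)
  expect_equal(f$p_value, sum(probs2[probs2 <= probs2[3] * (1 + 1e-7)]))
  expect_true(f$or_corrected)
  expect_equal(f$sample_or, (2.5 * 2.5) / (0.5 * 0.5))
  expect_error(fisher_exact(0, 0, 0, 0), "zero")
})

test_that("MH chi-square and common OR match mantelhaen.test exactly", {
  set.seed(99)
  for (rep_i in 1:5) {
    tab <- simulate_stratified_table(K = sample(2:8, 1),
                                     n_per_stratum = sample(50:300, 1),
                                     p_immuno = runif(1, 0.05, 0.4),
                                     p_protein = runif(1, 0.2, 0.7),
                                     or = exp(runif(1, -1, 1)))
    arr <- array(rbind(tab$a, tab$c, tab$b, tab$d), dim = c(2, 2, nrow(tab)))
    for (correct in c(TRUE, FALSE)) {
      ref <- stats::mantelhaen.test(arr, correct = correct)
      chi <- mh_chi_square(tab, correct = correct)
      expect_equal(chi$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(chi$p_value, ref$p.value, tolerance = 1e-12)
    }
    ref <- stats::mantelhaen.test(arr, correct = FALSE)
    orci <- mh_common_or_ci(tab)
    expect_equal(orci$or, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(c(orci$ci_low, orci$ci_high),
                 as.numeric(ref$conf.int), tolerance = 1e-12)
  }
})

test_that("MH degenerate and single-stratum behavior", {
  null_tab <- st(a = 10, b = 10, c = 10, d = 10)
  chi <- mh_chi_square(null_tab, correct = FALSE)
  expect_equal(chi$statistic, 0)
  expect_equal(chi$p_value, 1)
  expect_equal(mh_common_or_ci(null_tab)$or, 1.0)
  single <- st(a = 12, b = 5, c = 7, d = 20)
  expect_equal(mh_common_or_ci(single)$or, (12 * 20) / (5 * 7))
  # replicating a stratum K times leaves the common OR at the single value
  rep5 <- st(a = rep(12, 5), b = rep(5, 5), c = rep(7, 5), d = rep(20, 5))
  expect_equal(mh_common_or_ci(rep5)$or, (12 * 20) / (5 * 7))
  # OR infinite / zero across all strata errors rather than clipping
  expect_error(mh_common_or_ci(st(a = 5, b = 0, c = 0, d = 5)), "infinite")
  expect_error(mh_chi_square(st(a = c(5, 3), b = c(5, 3), c = 0, d = 0)),
               "no informative stratum")
})

test_that("Breslow-Day matches frozen independent reference values", {
  # 5-stratum table: reference statistic 5.58041901450831, p 0.2327505009,
  # Tarone-adjusted 5.580118345065507, p 0.2327762608 (statsmodels
  # StratifiedTable.test_equal_odds, computed once and frozen).
  t1 <- st(a = c(36, 32, 28, 35, 29), b = c(26, 26, 31, 23, 36),
           c = c(84, 97, 96, 94, 96), d = c(154, 145, 145, 148, 139))
  bd <- breslow_day(t1)
  expect_equal(bd$statistic, 5.58041901450831, tolerance = 1e-10)
  expect_equal(bd$p_value, 0.2327505009009283, tolerance = 1e-10)
  expect_equal(bd$df, 4L)
  bdt <- breslow_day(t1, tarone = TRUE)
  expect_equal(bdt$statistic, 5.580118345065507, tolerance = 1e-10)
  # 3-stratum table: reference 0.6751350803286109, p 0.7135037829163493
  t3 <- st(a = c(12, 5, 8), b = c(18, 25, 22), c = c(30, 20, 25),
           d = c(40, 50, 45))
  bd3 <- breslow_day(t3)
  expect_equal(bd3$statistic, 0.6751350803286109, tolerance = 1e-10)
  expect_equal(bd3$p_value, 0.7135037829163493, tolerance = 1e-10)
})

test_that("Breslow-Day behavior on homogeneous and heterogeneous strata", {
  # exact copies: statistic ~ 0, p ~ 1
  hom <- st(a = c(20, 20), b = c(30, 30), c = c(15, 15), d = c(35, 35))
  bd <- breslow_day(hom)
  expect_lt(bd$statistic, 1e-6)
  expect_gt(bd$p_value, 0.999)
  # sample ORs 5 and 0.2 at n = 200 per stratum: strongly heterogeneous
  het <- st(a = c(40, 10), b = c(10, 40), c = c(40, 110), d = c(110, 40))
  expect_lt(breslow_day(het)$p_value, 0.05)
  expect_error(breslow_day(st(a = 5, b = 5, c = 5, d = 5)),
               "not testable")
})

test_that("Breslow-Day fitted cells are nonnegative over random tables", {
  set.seed(314)
  for (i in 1:50) {
    tab <- simulate_stratified_table(K = sample(2:6, 1),
                                     n_per_stratum = sample(20:100, 1),
                                     p_immuno = runif(1, 0.1, 0.5),
                                     p_protein = runif(1, 0.2, 0.8),
                                     or = exp(runif(1, -2, 2)))
    m <- as.data.frame(tab)
    inf <- m$informative
    if (sum(inf) < 2) next
    ok <- tryCatch(breslow_day(tab), error = function(e) NULL)
    if (is.null(ok)) next  # pooled OR degenerate for this draw
    fit <- ok$fitted
    r1 <- (m$a + m$b)[inf]; r2 <- (m$c + m$d)[inf]; c1 <- (m$a + m$c)[inf]
    expect_true(all(fit >= -1e-9))
    expect_true(all(r1 - fit >= -1e-9))
    expect_true(all(c1 - fit >= -1e-9))
    expect_true(all(r2 - c1 + fit >= -1e-9))
  }
})

test_that("the homogeneity gate selects pooled vs per-stratum reporting", {
  set.seed(77)
  hom_tab <- simulate_stratified_table(K = 10, n_per_stratum = 200,
                                       p_immuno = 0.15, p_protein = 0.4,
                                       or = 0.7)
  res <- gated_association(hom_tab)
  expect_equal(res$method, "pooled_mh")
  expect_gte(res$breslow_day_p, 0.05)
  expect_true(res$pooled$ci_low <= res$pooled$or &&
                res$pooled$or <= res$pooled$ci_high)

  het_tab <- st(a = c(40, 10), b = c(10, 40), c = c(40, 110),
                d = c(110, 40))
  res2 <- gated_association(het_tab)
  expect_equal(res2$method, "per_stratum_fisher")
  expect_equal(nrow(res2$per_stratum), 2L)
  expect_true(all(res2$per_stratum$significant))
  # per-stratum p equals the standalone Fisher test
  expect_equal(res2$per_stratum$p_value[1],
               fisher_exact(40, 10, 40, 110)$p_value)

  single <- st(a = 12, b = 5, c = 7, d = 20)
  res3 <- gated_association(single)
  expect_equal(res3$method, "pooled_mh")
  expect_true(is.na(res3$breslow_day_p))
})

test_that("significance flags follow p <= alpha at the configured alpha", {
  tab <- simulate_stratified_table(K = 4, n_per_stratum = 500,
                                   p_immuno = 0.2, p_protein = 0.4,
                                   or = 1.45)
  res05 <- gated_association(tab, alpha = 0.05)
  res001 <- gated_association(tab, alpha = 0.001)
  expect_equal(res05$pooled$significant, res05$pooled$p_value <= 0.05)
  expect_equal(res001$pooled$significant, res001$pooled$p_value <= 0.001)
})
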