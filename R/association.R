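# The stratified association engine: Fisher exact test, Mantel-Haenszel
# chi-square, Mantel-Haenszel common odds ratio with
# Robins-Breslow-Greenland confidence interval, Breslow-Day homogeneity
# test, and the homogeneity-gated reporting procedure that decides between
# the pooled summary and per-stratum exact tests.

# Relative tolerance used when collecting hypergeometric probabilities at
# or below the observed table's probability (two-sided Fisher p).
.FISHER_REL_TOL <- 1e-7

#' Two-sided Fisher exact test for a single 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, under
#' fixed margins, of every table at most as probable as the observed one
#' (probability-mass ordering, with a 1e-7 relative tolerance for ties).
#' The sample odds ratio is `ad/bc`; when any cell is zero it is computed
#' on cells with 0.5 added throughout (Haldane-Anscombe) and flagged.
#'
#' @param a,b,c,d Nonnegative integer cell counts (`a` = both positive,
#'   `b`, `c` the off-diagonal, `d` both negative).
#' @return List with `p_value`, `sample_or` and logical `or_corrected`.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  if (sum(cells) == 0)
    stop("all four cell counts are zero")
  m1 <- a + b   # immunomarker-positive margin (white balls)
  m2 <- c + d
  t1 <- a + c   # protein-positive margin (balls drawn)
  support <- max(0, t1 - m2):min(m1, t1)
  probs <- stats::dhyper(support, m1, m2, t1)
  p_obs <- stats::dhyper(a, m1, m2, t1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + .FISHER_REL_TOL)]))
  corrected <- any(cells == 0)
  or <- if (corrected) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(p_value = p, sample_or = or, or_corrected = corrected)
}

# Margins and informativeness helper shared by the stratified statistics.
.table_margins <- function(tab) {
  df <- as.data.frame(tab)
  # compute in double precision: margin products overflow integer range
  with(lapply(df[c("a", "b", "c", "d")], as.numeric), {
    n <- a + b + c + d
    list(a = a, b = b, c = c, d = d, n = n,
         r1 = a + b, r2 = c + d, c1 = a + c, c2 = b + d,
         informative = (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0)
  })
}

#' Mantel-Haenszel chi-square test across strata
#'
#' Conditional test of association summed over the informative strata,
#' using the hypergeometric mean and variance of the `a` cell per stratum:
#' `(|sum(a) - sum(E)| - 1/2)^2 / sum(V)` with one degree of freedom.  The
#' classic 1/2 continuity correction is applied by default.  Strata with a
#' zero row or column margin contribute nothing.
#'
#' @param table A [stratified_table()].
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return List with `statistic`, `p_value`, `df`.
#' @export
mh_chi_square <- function(table, correct = TRUE) {
  m <- .table_margins(table)
  inf <- m$informative
  if (!any(inf))
    stop("no informative stratum: Mantel-Haenszel test undefined")
  E <- (m$r1 * m$c1 / m$n)[inf]
  V <- (m$r1 * m$r2 * m$c1 * m$c2 / (m$n^2 * (m$n - 1)))[inf]
  delta <- abs(sum(m$a[inf]) - sum(E))
  if (correct) delta <- max(0, delta - 0.5)
  stat <- delta^2 / sum(V)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Mantel-Haenszel common odds ratio with 95% confidence interval
#'
#' The pooled odds ratio `sum(a_k d_k / n_k) / sum(b_k c_k / n_k)` with a
#' confidence interval from the Robins-Breslow-Greenland variance of its
#' logarithm.  Degenerate tables whose pooled numerator or denominator is
#' zero (odds ratio zero or infinite) raise an error rather than returning
#' a clipped value.
#'
#' @param table A [stratified_table()].
#' @param conf_level Confidence level (default 0.95).
#' @return List with `or`, `ci_low`, `ci_high`, `se_log_or`.
#' @export
mh_common_or_ci <- function(table, conf_level = 0.95) {
  m <- .table_margins(table)
  use <- m$n > 0
  a <- m$a[use]; b <- m$b[use]; c <- m$c[use]; d <- m$d[use]; n <- m$n[use]
  R_k <- a * d / n
  S_k <- b * c / n
  R <- sum(R_k); S <- sum(S_k)
  if (S == 0) stop("pooled odds ratio is infinite (no discordant b*c mass)")
  if (R == 0) stop("pooled odds ratio is zero (no concordant a*d mass)")
  or <- R / S
  P <- (a + d) / n
  Q <- (b + c) / n
  var_log <- sum(P * R_k) / (2 * R^2) +
    sum(P * S_k + Q * R_k) / (2 * R * S) +
    sum(Q * S_k) / (2 * S^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(var_log)
  list(or = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       se_log_or = se)
}

#' Breslow-Day test of odds-ratio homogeneity
#'
#' Tests whether the stratum-specific odds ratios share a common value.
#' For each informative stratum the fitted `a` cell under the
#' Mantel-Haenszel common odds ratio solves the quadratic fitted-count
#' equation, taking the root for which all four fitted cells are
#' nonnegative; the statistic sums `(a - fitted)^2 / Var(fitted)` and is
#' referred to chi-square with (number of informative strata - 1) degrees
#' of freedom.  Tarone's adjustment (subtracting
#' `(sum(a - fitted))^2 / sum(Var)`) is available via a flag.
#'
#' @param table A [stratified_table()] with at least two informative
#'   strata.
#' @param tarone Apply Tarone's correction (default `FALSE`).
#' @return List with `statistic`, `p_value`, `df` and the per-stratum
#'   `fitted` counts.
#' @export
breslow_day <- function(table, tarone = FALSE) {
  m <- .table_margins(table)
  inf <- m$informative
  if (sum(inf) < 2L)
    stop("homogeneity not testable: fewer than two informative strata")
  psi <- mh_common_or_ci(table)$or
  a <- m$a[inf]; r1 <- m$r1[inf]; r2 <- m$r2[inf]; c1 <- m$c1[inf]

  fitted <- numeric(length(a))
  for (k in seq_along(a)) {
    fitted[k] <- .bd_fitted_a(psi, r1[k], r2[k], c1[k])
  }
  var_fit <- 1 / (1 / fitted + 1 / (r1 - fitted) + 1 / (c1 - fitted) +
                    1 / (r2 - c1 + fitted))
  stat <- sum((a - fitted)^2 / var_fit)
  if (tarone) stat <- stat - sum(a - fitted)^2 / sum(var_fit)
  df <- sum(inf) - 1L
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       df = df,
       fitted = fitted)
}

# Fitted a-cell under a common odds ratio psi for a stratum with
# immunomarker margins (r1, r2) and protein-positive margin c1:
# psi = x * (r2 - c1 + x) / ((r1 - x) * (c1 - x)) rearranges to
# (psi - 1) x^2 - [psi (r1 + c1) + (r2 - c1)] x + psi r1 c1 = 0.
.bd_fitted_a <- function(psi, r1, r2, c1) {
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  if (abs(psi - 1) < 1e-12) return(r1 * c1 / (r1 + r2))
  A <- psi - 1
  B <- -(psi * (r1 + c1) + (r2 - c1))
  C <- psi * r1 * c1
  disc <- B^2 - 4 * A * C
  disc <- max(disc, 0)
  roots <- c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A))
  ok <- roots >= lo - 1e-9 & roots <= hi + 1e-9
  if (!any(ok))
    stop("no admissible root for the fitted-count equation")
  x <- roots[ok][1L]
  min(max(x, lo), hi)
}

#' Homogeneity-gated stratified association
#'
#' The reporting procedure: run the Breslow-Day test; when its p-value is
#' at or above `alpha` (or homogeneity is untestable because only one
#' stratum is informative) the tumor types are pooled and described by the
#' Mantel-Haenszel chi-square and common odds ratio with its confidence
#' interval; when below `alpha` the strata cannot be pooled, and each
#' tumor type is tested separately with the two-sided Fisher exact test.
#'
#' @param table A [stratified_table()].
#' @param alpha Significance level for both the gate and the reported
#'   significance flags (default 0.05; significance means p <= alpha).
#' @param correct Continuity correction for the pooled chi-square.
#' @param tarone Tarone adjustment for the Breslow-Day statistic.
#' @return An `association_result`: list with `immunomarker`,
#'   `protein_marker`, `method` (`"pooled_mh"` or `"per_stratum_fisher"`),
#'   `breslow_day_p` (`NA` when untestable), `alpha`, `n_used`, and either
#'   `pooled` (statistic, p_value, or, ci_low, ci_high, significant) or
#'   `per_stratum` (data frame: stratum, p_value, sample_or, or_corrected,
#'   significant).
#' @export
gated_association <- function(table, alpha = 0.05, correct = TRUE,
                              tarone = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  m <- .table_margins(table)
  n_informative <- sum(m$informative)
  bd_p <- NA_real_
  if (n_informative >= 2L)
    bd_p <- breslow_day(table, tarone = tarone)$p_value

  res <- list(immunomarker = attr(table, "immunomarker"),
              protein_marker = attr(table, "protein_marker"),
              breslow_day_p = bd_p,
              alpha = alpha,
              n_used = attr(table, "n_used"))

  if (is.na(bd_p) || bd_p >= alpha) {
    chi <- mh_chi_square(table, correct = correct)
    orci <- mh_common_or_ci(table)
    res$method <- "pooled_mh"
    res$pooled <- list(statistic = chi$statistic,
                       p_value = chi$p_value,
                       or = orci$or,
                       ci_low = orci$ci_low,
                       ci_high = orci$ci_high,
                       significant = chi$p_value <= alpha)
  } else {
    tab <- as.data.frame(table)
    nonzero <- with(tab, a + b + c + d > 0)
    tab <- tab[nonzero, , drop = FALSE]
    per <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      f <- fisher_exact(tab$a[i], tab$b[i], tab$c[i], tab$d[i])
      data.frame(stratum = tab$stratum[i],
                 p_value = f$p_value,
                 sample_or = f$sample_or,
                 or_corrected = f$or_corrected,
                 significant = f$p_value <= alpha,
                 stringsAsFactors = FALSE)
    }))
    res$method <- "per_stratum_fisher"
    res$per_stratum <- per
  }
  structure(res, class = "association_result")
}

#' Construct a pooled association result from summary statistics
#'
#' For re-analyzing published pooled summaries (odds ratio, confidence
#' interval, p-value) without patient-level data, e.g. to feed
#' [map_benefit()].
#'
#' @param immunomarker,protein_marker Pair labels.
#' @param or Pooled odds ratio.
#' @param p_value Pooled test p-value.
#' @param ci_low,ci_high Optional confidence bounds.
#' @param alpha Significance level.
#' @param n_used Optional number of patients behind the summary.
#' @return An `association_result` with method `"pooled_mh"`.
#' @export
pooled_association <- function(immunomarker, protein_marker, or, p_value,
                               ci_low = NA_real_, ci_high = NA_real_,
                               alpha = 0.05, n_used = NA_integer_) {
  stopifnot(or > 0, p_value >= 0, p_value <= 1)
  structure(list(immunomarker = immunomarker,
                 protein_marker = protein_marker,
                 breslow_day_p = NA_real_,
                 alpha = alpha,
                 n_used = n_used,
                 method = "pooled_mh",
                 pooled = list(statistic = NA_real_,
                               p_value = p_value,
                               or = or,
                               ci_low = ci_low,
                               ci_high = ci_high,
                               significant = p_value <= alpha)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("Association %s x %s (n = %s, alpha = %g)\n",
              x$immunomarker, x$protein_marker,
              format(x$n_used), x$alpha))
  cat(sprintf("  Breslow-Day p: %s\n",
              ifelse(is.na(x$breslow_day_p), "not testable",
                     format(x$breslow_day_p, digits = 3))))
  if (x$method == "pooled_mh") {
    with(x$pooled, cat(sprintf(
      "  Pooled M-H: OR %.3f (%.3f-%.3f), chi2 %s, p %s%s\n",
      or, ci_low, ci_high, format(statistic, digits = 4),
      format(p_value, digits = 3),
      ifelse(isTRUE(significant), " *", ""))))
  } else {
    cat(sprintf("  Heterogeneous: per-stratum Fisher, %d strata, %d significant\n",
                nrow(x$per_stratum), sum(x$per_stratum$significant)))
  }
  invisible(x)
}
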