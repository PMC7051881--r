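# Synthetic cohorts and panel-level profiles with the statistical
# structure the analysis assumes: configurable marginal prevalences,
# pairwise immunomarker x protein-marker odds ratios (common or varying
# across tumor-type strata), per-marker tested fractions, and an optional
# conditional coupling of TMB-high prevalence on MSI status.

#' Joint cell probability of a 2x2 distribution with given margins and OR
#'
#' Returns `P(A+ and B+)` for the unique bivariate Bernoulli distribution
#' with marginal positive probabilities `p1`, `p2` and odds ratio `psi`
#' (Plackett's solution of the quadratic in the joint cell).
#'
#' @param p1,p2 Marginal positive probabilities in (0, 1).
#' @param psi Target odds ratio (> 0).
#' @return The joint probability `p11`.
#' @export
p11_from_margins_or <- function(p1, p2, psi) {
  stopifnot(psi > 0)
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
    stop("margins must be strictly inside (0, 1) to target an odds ratio")
  if (abs(psi - 1) < 1e-12) return(p1 * p2)
  s <- 1 + (p1 + p2) * (psi - 1)
  disc <- s^2 - 4 * psi * (psi - 1) * p1 * p2
  (s - sqrt(disc)) / (2 * (psi - 1))
}

#' Simulation configuration for a synthetic cohort
#'
#' Defaults mirror a large pan-cancer clinical testing population: 28,034
#' patients over 40 tumor types with marginal positivity MSI-H 3.3%,
#' TMB-H 8.4%, PD-L1 11.0%, ERCC1 20.9%, MGMT 55.4%, RRM1 19.9%, TOP2A
#' 75.8%, TOPO1 58.7%, TS 34.0% and TUBB3 56.8%, and per-marker tested
#' fractions reproducing the varying per-pair sample sizes of such a
#' database (each marker is assayed in only a subset of patients).
#'
#' @param n_patients Cohort size.
#' @param tumor_types Stratum names.
#' @param stratum_weights Relative stratum sizes (default uniform).
#' @param prevalence Named vector of marginal positive prevalences.
#' @param tested_fraction Named vector of per-marker tested fractions.
#' @param pair_or Named list of target odds ratios, keys
#'   `"<immunomarker>:<protein>"` (e.g. `"MSI:ERCC1"`); each value a
#'   scalar (common OR) or a vector with one OR per stratum.  Pairs not
#'   listed default to 1 (independence).
#' @param p_tmb_high_given_msi Optional conditional prevalence
#'   `P(TMB-high | MSI-high)` (e.g. 0.73) while preserving the marginal
#'   TMB prevalence; `NULL` leaves TMB independent of MSI.
#' @param tmb_intermediate_frac Fraction of TMB-negative (non-high)
#'   patients classed intermediate rather than low (default 0.313).
#' @param seed Integer seed used by [generate_cohort()]; `NULL` leaves
#'   the RNG state alone.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_patients = 28034,
                              tumor_types = default_tumor_types(),
                              stratum_weights = NULL,
                              prevalence = c(MSI = 0.033, TMB = 0.084,
                                             PDL1 = 0.110, ERCC1 = 0.209,
                                             MGMT = 0.554, RRM1 = 0.199,
                                             TOP2A = 0.758, TOPO1 = 0.587,
                                             TS = 0.340, TUBB3 = 0.568),
                              tested_fraction = c(MSI = 1.000, TMB = 0.993,
                                                  PDL1 = 0.789,
                                                  ERCC1 = 0.778,
                                                  MGMT = 0.185,
                                                  RRM1 = 0.614,
                                                  TOP2A = 0.460,
                                                  TOPO1 = 0.792,
                                                  TS = 0.731,
                                                  TUBB3 = 0.709),
                              pair_or = list(),
                              p_tmb_high_given_msi = NULL,
                              tmb_intermediate_frac = 0.313,
                              seed = NULL) {
  stopifnot(n_patients >= 1,
            all(prevalence >= 0 & prevalence <= 1),
            all(tested_fraction >= 0 & tested_fraction <= 1),
            tmb_intermediate_frac >= 0, tmb_intermediate_frac <= 1)
  missing_prev <- setdiff(ALL_MARKERS, names(prevalence))
  if (length(missing_prev))
    stop("prevalence missing for marker(s): ",
         paste(missing_prev, collapse = ", "))
  missing_tf <- setdiff(ALL_MARKERS, names(tested_fraction))
  if (length(missing_tf))
    stop("tested_fraction missing for marker(s): ",
         paste(missing_tf, collapse = ", "))
  if (is.null(stratum_weights))
    stratum_weights <- rep(1, length(tumor_types))
  stopifnot(length(stratum_weights) == length(tumor_types),
            all(stratum_weights > 0))
  for (key in names(pair_or)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !(parts[1] %in% IMMUNO_MARKERS) ||
        !(parts[2] %in% PROTEIN_MARKERS))
      stop("pair_or key must be '<immunomarker>:<protein>', got: ", key)
    psi <- pair_or[[key]]
    if (any(psi <= 0)) stop("odds ratios must be positive (pair ", key, ")")
    if (!length(psi) %in% c(1L, length(tumor_types)))
      stop("pair_or['", key, "'] must be a scalar or one value per stratum")
    if (any(psi != 1) &&
        (prevalence[[parts[1]]] %in% c(0, 1) ||
         prevalence[[parts[2]]] %in% c(0, 1)))
      stop("infeasible margin/odds-ratio combination for pair ", key)
  }
  if (!is.null(p_tmb_high_given_msi)) {
    pM <- prevalence[["MSI"]]; pT <- prevalence[["TMB"]]
    p_not <- (pT - pM * p_tmb_high_given_msi) / (1 - pM)
    if (p_not < 0 || p_not > 1)
      stop("p_tmb_high_given_msi incompatible with the MSI/TMB marginals")
  }
  structure(list(n_patients = n_patients, tumor_types = tumor_types,
                 stratum_weights = stratum_weights,
                 prevalence = prevalence,
                 tested_fraction = tested_fraction,
                 pair_or = pair_or,
                 p_tmb_high_given_msi = p_tmb_high_given_msi,
                 tmb_intermediate_frac = tmb_intermediate_frac,
                 seed = seed),
            class = "cohort_sim_config")
}

# Deterministic largest-remainder apportionment of n into weighted parts.
.apportion <- function(n, weights) {
  exact <- n * weights / sum(weights)
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
  }
  as.integer(base)
}

# Intercept of the additive log-odds model for a protein marker so that
# its marginal prevalence is hit given the immunomarker state
# distribution.  states: 8 x 3 matrix of indicator rows; w: their
# probabilities; lpsi: log odds ratios vs (MSI, TMB, PDL1).
.solve_intercept <- function(p_target, states, w, lpsi) {
  f <- function(alpha)
    sum(w * stats::plogis(alpha + as.vector(states %*% lpsi))) - p_target
  stats::uniroot(f, c(-40, 40), tol = 1e-12)$root
}

#' Generate a synthetic patient cohort
#'
#' Draws immunomarker states (optionally with TMB coupled to MSI), then
#' each protein marker from a logistic model whose coefficients are the
#' logs of the configured pairwise odds ratios and whose intercept is
#' solved per stratum so the marginal prevalence is exact in expectation.
#' When a protein marker is coupled to a single immunomarker this
#' reproduces exactly the 2x2 joint distribution with the configured
#' margins and odds ratio; with several simultaneous couplings the
#' pairwise odds ratios are conditional ones and marginal pair odds
#' ratios can be attenuated by immunomarker co-occurrence (higher-order
#' dependence is not controlled).  Tested-status masks are applied
#' independently per marker.  The same seed yields an identical cohort.
#'
#' @param config A [cohort_sim_config()].
#' @return A [marker_cohort()] with attribute `truth`: a data frame of
#'   the underlying (pre-masking) states for every marker plus
#'   `tmb_class`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- length(config$tumor_types)
  n_k <- .apportion(config$n_patients, config$stratum_weights)
  tumor_type <- rep(config$tumor_types, n_k)
  n <- length(tumor_type)
  stratum_idx <- rep(seq_len(K), n_k)

  pM <- config$prevalence[["MSI"]]
  pT <- config$prevalence[["TMB"]]
  pP <- config$prevalence[["PDL1"]]

  msi <- stats::rbinom(n, 1, pM)
  if (is.null(config$p_tmb_high_given_msi)) {
    pT_m <- pT; pT_s <- pT
  } else {
    pT_m <- config$p_tmb_high_given_msi
    pT_s <- (pT - pM * pT_m) / (1 - pM)
  }
  tmb <- stats::rbinom(n, 1, ifelse(msi == 1, pT_m, pT_s))
  pdl1 <- stats::rbinom(n, 1, pP)

  # Theoretical distribution of the 8 immunomarker states, used to solve
  # each protein marker's intercept.
  states <- as.matrix(expand.grid(MSI = 0:1, TMB = 0:1, PDL1 = 0:1))
  w <- apply(states, 1, function(s) {
    p_m <- if (s[1] == 1) pM else 1 - pM
    p_t_given <- if (s[1] == 1) pT_m else pT_s
    p_t <- if (s[2] == 1) p_t_given else 1 - p_t_given
    p_p <- if (s[3] == 1) pP else 1 - pP
    p_m * p_t * p_p
  })

  truth <- data.frame(MSI = msi, TMB = tmb, PDL1 = pdl1)
  imat <- cbind(msi, tmb, pdl1)

  for (pm in PROTEIN_MARKERS) {
    p_pm <- config$prevalence[[pm]]
    lpsi_by_stratum <- matrix(0, nrow = K, ncol = 3)
    for (j in seq_along(IMMUNO_MARKERS)) {
      key <- paste(IMMUNO_MARKERS[j], pm, sep = ":")
      if (!is.null(config$pair_or[[key]])) {
        psi <- config$pair_or[[key]]
        lpsi_by_stratum[, j] <- log(if (length(psi) == 1) rep(psi, K)
                                    else psi)
      }
    }
    prob <- numeric(n)
    for (k in seq_len(K)) {
      rows <- stratum_idx == k
      if (!any(rows)) next
      lpsi <- lpsi_by_stratum[k, ]
      if (all(lpsi == 0)) {
        prob[rows] <- p_pm
      } else {
        if (p_pm <= 0 || p_pm >= 1)
          stop("infeasible margin/odds-ratio combination for marker ", pm)
        alpha <- .solve_intercept(p_pm, states, w, lpsi)
        prob[rows] <- stats::plogis(alpha +
                                      as.vector(imat[rows, , drop = FALSE]
                                                %*% lpsi))
      }
    }
    truth[[pm]] <- stats::rbinom(n, 1, prob)
  }

  # TMB class: high when TMB-positive; negatives split intermediate/low.
  interm <- stats::rbinom(n, 1, config$tmb_intermediate_frac)
  truth$tmb_class <- ifelse(truth$TMB == 1, "high",
                            ifelse(interm == 1, "intermediate", "low"))

  out <- data.frame(patient_id = sprintf("P%06d", seq_len(n)),
                    tumor_type = tumor_type, stringsAsFactors = FALSE)
  for (m in ALL_MARKERS) {
    tested <- stats::rbinom(n, 1, config$tested_fraction[[m]]) == 1
    out[[m]] <- ifelse(tested,
                       ifelse(truth[[m]] == 1, "positive", "negative"),
                       NA_character_)
  }
  out$tmb_class <- ifelse(is.na(out$TMB), NA_character_, truth$tmb_class)

  cohort <- marker_cohort(out, tumor_types = config$tumor_types)
  attr(cohort, "truth") <- truth
  cohort
}

#' Simulate a stratified 2x2 table directly
#'
#' Table-level counterpart of [generate_cohort()] for statistical
#' calibration studies: each stratum draws its immunomarker-positive count
#' binomially and fills the 2x2 from the exact conditional probabilities
#' of the joint distribution with the given margins and odds ratio.
#'
#' @param n_per_stratum Patients per stratum (scalar or length-`K`).
#' @param p_immuno,p_protein Marginal positive probabilities (scalar or
#'   length-`K`).
#' @param or Odds ratio (scalar for a common OR, or length-`K`).
#' @param K Number of strata.
#' @param immunomarker,protein_marker Labels for the resulting table.
#' @return A [stratified_table()].
#' @export
simulate_stratified_table <- function(K = 10, n_per_stratum = 200,
                                      p_immuno = 0.1, p_protein = 0.3,
                                      or = 1,
                                      immunomarker = "IMM",
                                      protein_marker = "PROT") {
  n_k <- rep_len(n_per_stratum, K)
  p1 <- rep_len(p_immuno, K)
  p2 <- rep_len(p_protein, K)
  psi <- rep_len(or, K)
  a <- b <- c <- d <- integer(K)
  for (k in seq_len(K)) {
    p11 <- p11_from_margins_or(p1[k], p2[k], psi[k])
    x1 <- stats::rbinom(1, n_k[k], p1[k])
    a[k] <- stats::rbinom(1, x1, p11 / p1[k])
    c[k] <- stats::rbinom(1, n_k[k] - x1, (p2[k] - p11) / (1 - p1[k]))
    b[k] <- x1 - a[k]
    d[k] <- n_k[k] - x1 - c[k]
  }
  stratified_table(data.frame(stratum = sprintf("S%02d", seq_len(K)),
                              a = a, b = b, c = c, d = d,
                              stringsAsFactors = FALSE),
                   immunomarker, protein_marker)
}

#' Simulate a microsatellite locus catalog
#'
#' A synthetic stand-in for a panel's microsatellite locus catalog, with a
#' mix of autosomal and sex-chromosome loci, occasional low-coverage
#' flags, and repeat-unit lengths 1-6 so the target filter has work to do.
#' Uses the current RNG state (seed outside if reproducibility matters).
#'
#' @param n_loci Number of catalog entries.
#' @return Data frame in the locus-catalog layout
#'   (see [read_locus_catalog()]).
#' @export
simulate_locus_catalog <- function(n_loci = 200) {
  chroms <- c(paste0("chr", 1:22), "chrX", "chrY")
  probs <- c(rep(0.95 / 22, 22), 0.04, 0.01)
  data.frame(
    locus_id = sprintf("MS%05d", seq_len(n_loci)),
    chrom = sample(chroms, n_loci, replace = TRUE, prob = probs),
    pos = sample.int(2.4e8, n_loci, replace = TRUE),
    unit_length = sample(1:6, n_loci, replace = TRUE,
                         prob = c(0.45, 0.2, 0.15, 0.1, 0.05, 0.05)),
    ref_repeat_count = sample(5:30, n_loci, replace = TRUE),
    low_coverage = stats::runif(n_loci) < 0.05,
    stringsAsFactors = FALSE
  )
}

#' Configuration for synthetic panel-level profiles
#'
#' @param msi_mean_stable,msi_mean_high Mean altered-locus counts (Poisson)
#'   for microsatellite-stable and MSI-high patients; well separated by
#'   default so the calibrated caller can recover truth.
#' @param tmb_max_mutspermb Upper bound of the TMB-high band sampler.
#' @param silent_rate,cnv_rate,structural_rate Poisson means for
#'   non-countable mutation records added as distractors.
#' @param distractor_indel_rate Poisson mean for non-repeat-changing
#'   indel events added at loci with repeat units of 2+ nucleotides.
#' @return A `ngs_profile_config` list.
#' @export
ngs_profile_config <- function(msi_mean_stable = 3, msi_mean_high = 45,
                               tmb_max_mutspermb = 60,
                               silent_rate = 2, cnv_rate = 1,
                               structural_rate = 0.5,
                               distractor_indel_rate = 1) {
  stopifnot(msi_mean_stable < msi_mean_high)
  structure(list(msi_mean_stable = msi_mean_stable,
                 msi_mean_high = msi_mean_high,
                 tmb_max_mutspermb = tmb_max_mutspermb,
                 silent_rate = silent_rate, cnv_rate = cnv_rate,
                 structural_rate = structural_rate,
                 distractor_indel_rate = distractor_indel_rate),
            class = "ngs_profile_config")
}

#' Generate panel-level profiles consistent with a cohort's truth states
#'
#' For every patient with an assigned status, draws: microsatellite locus
#' observations whose distinct repeat-changing-altered-locus count comes
#' from a low-mean (stable) or high-mean (MSI-high) Poisson; somatic
#' mutation records whose nonsilent-coding count falls inside the
#' patient's TMB class band for the panel footprint (so the computed
#' mutations/Mb classifies back to the same class by construction), plus
#' silent / copy-number / structural distractors; and IHC observations
#' whose percent and intensity respect the configured positivity
#' thresholds for the truth status.
#'
#' @param cohort A [marker_cohort()] (typically from [generate_cohort()]);
#'   statuses are taken as the truth to emulate.
#' @param target_loci Filtered locus catalog used for MSI draws.
#' @param panel A [panel_definition()].
#' @param config A [ngs_profile_config()].
#' @param ihc_thresholds See [classify_ihc()].
#' @return List with data frames `locus_observations`, `mutations`,
#'   `ihc_observations`.
#' @export
generate_ngs_profile <- function(cohort, target_loci,
                                 panel = panel_definition(),
                                 config = ngs_profile_config(),
                                 ihc_thresholds = default_ihc_thresholds()) {
  n_loci <- nrow(target_loci)
  if (n_loci < 1L) stop("target locus catalog is empty")
  any_truth <- FALSE
  for (m in ALL_MARKERS) any_truth <- any_truth || any(!is.na(cohort[[m]]))
  if (!any_truth)
    stop("cohort has no assigned truth statuses to emulate")
  mb <- panel$panel_size_mb
  bands <- list(
    low = c(0L, as.integer(ceiling(panel$tmb_intermediate_lower * mb)) - 1L),
    intermediate = c(as.integer(ceiling(panel$tmb_intermediate_lower * mb)),
                     as.integer(ceiling(panel$tmb_high_cutoff * mb)) - 1L),
    high = c(as.integer(ceiling(panel$tmb_high_cutoff * mb)),
             as.integer(floor(config$tmb_max_mutspermb * mb))))

  pick1 <- function(x) x[sample.int(length(x), 1L)]  # safe for length 1
  lobs <- list(); muts <- list(); ihc <- list()
  ihc_markers <- intersect(c("PDL1", PROTEIN_MARKERS),
                           ihc_thresholds$marker)

  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]

    if (!is.na(cohort$MSI[i])) {
      mean_alt <- if (cohort$MSI[i] == "positive")
        config$msi_mean_high else config$msi_mean_stable
      n_alt <- min(stats::rpois(1, mean_alt), n_loci)
      rows <- NULL
      if (n_alt > 0) {
        hit <- sample.int(n_loci, n_alt)
        unit <- target_loci$unit_length[hit]
        delta <- sample(c(-1L, 1L), n_alt, replace = TRUE) *
          unit * sample(1:2, n_alt, replace = TRUE)
        rows <- data.frame(patient_id = pid,
                           locus_id = target_loci$locus_id[hit],
                           length_delta = delta,
                           stringsAsFactors = FALSE)
      }
      n_noise <- stats::rpois(1, config$distractor_indel_rate)
      wide <- which(target_loci$unit_length >= 2L)
      if (n_noise > 0 && length(wide)) {
        hit <- wide[sample.int(length(wide), min(n_noise, length(wide)))]
        rows <- rbind(rows, data.frame(
          patient_id = pid,
          locus_id = target_loci$locus_id[hit],
          length_delta = sample(c(-1L, 1L), length(hit), replace = TRUE),
          stringsAsFactors = FALSE))
      }
      if (!is.null(rows)) lobs[[pid]] <- rows
    }

    if (!is.na(cohort$tmb_class[i])) {
      band <- bands[[cohort$tmb_class[i]]]
      n_mut <- if (band[2] >= band[1])
        band[1] + sample.int(band[2] - band[1] + 1L, 1L) - 1L else band[1]
      extras <- c(silent = stats::rpois(1, config$silent_rate),
                  copy_number = stats::rpois(1, config$cnv_rate),
                  structural = stats::rpois(1, config$structural_rate))
      classes <- c(rep("nonsilent_coding", n_mut),
                   rep(names(extras), extras))
      if (length(classes)) {
        muts[[pid]] <- data.frame(
          patient_id = pid,
          gene = sprintf("GENE%03d", sample.int(592, length(classes),
                                                replace = TRUE)),
          variant_class = classes,
          somatic = TRUE,
          stringsAsFactors = FALSE)
      }
    }

    for (mk in ihc_markers) {
      status <- cohort[[mk]][i]
      if (is.na(status)) next
      thr <- ihc_thresholds[ihc_thresholds$marker == mk, ]
      if (status == "positive") {
        pct <- pick1(seq(thr$min_percent, 100))
        int <- pick1(seq(thr$min_intensity, 3L))
      } else if (stats::runif(1) < 0.5 && thr$min_percent >= 1) {
        # fail on percent; intensity unconstrained
        pct <- pick1(seq(0, thr$min_percent - 1))
        int <- pick1(0:3)
      } else if (thr$min_intensity >= 1) {
        # fail on intensity
        pct <- pick1(0:100)
        int <- pick1(seq(0L, thr$min_intensity - 1L))
      } else {
        pct <- pick1(seq(0, max(thr$min_percent - 1, 0)))
        int <- 0L
      }
      ihc[[paste(pid, mk)]] <- data.frame(
        patient_id = pid, marker = mk,
        percent_positive = pct, intensity = int,
        stringsAsFactors = FALSE)
    }
  }

  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                  cols))
  }
  list(
    locus_observations = if (length(lobs)) do.call(rbind, c(lobs, list(
      make.row.names = FALSE))) else
        empty(c("patient_id", "locus_id", "length_delta")),
    mutations = if (length(muts)) do.call(rbind, c(muts, list(
      make.row.names = FALSE))) else
        empty(c("patient_id", "gene", "variant_class", "somatic")),
    ihc_observations = if (length(ihc)) do.call(rbind, c(ihc, list(
      make.row.names = FALSE))) else
        empty(c("patient_id", "marker", "percent_positive", "intensity")))
}
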