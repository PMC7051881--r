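---
title: "Methods: biomarker co-occurrence and combination-benefit analysis"
author: "immunochemo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biomarker co-occurrence and combination-benefit analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunochemo)
```

## The scientific question

Checkpoint-inhibitor immunotherapy is increasingly given together with
cytotoxic chemotherapy. Tumors that are microsatellite-instability-high
(MSI-H), have a high tumor mutational burden (TMB-H, measured in somatic
nonsilent coding mutations per megabase), or express PD-L1 are more likely
to respond to anti-PD-1/PD-L1 agents. Separately, a set of protein markers
scored by immunohistochemistry (IHC) predicts response or resistance to
specific chemotherapies: ERCC1, MGMT, RRM1, TS and TUBB3 predict
sensitivity when *negative/low*, while TOP2A and TOPO1 predict sensitivity
when *positive*. If, within a tumor type, an immunotherapy marker and the
sensitivity-predicting state of a chemotherapy marker tend to co-occur,
then combining the corresponding drugs is more likely to benefit that
population; if the resistance-predicting state co-occurs, less likely.

`immunochemo` implements that analysis chain end to end: calling marker
statuses from panel-level inputs, testing each immunomarker ×
protein-marker pair with a tumor-type-stratified procedure, and mapping
significant associations through a marker-direction registry to
combination-benefit verdicts.

## Data model and missingness

Each patient carries a tri-state status per marker: positive,
negative/low, or untested (`NA`). Missingness is structural — in a
clinical testing database each assay is ordered for only a subset of
patients — so every pairwise analysis uses *pairwise-complete deletion*:
the ERCC1 × MSI table is built from exactly the patients tested for both,
which is why each pair has its own N. Co-occurrence percentages are
conditional: among A-positive patients *with a B result*, the percent also
B-positive. Percents are rounded to one decimal for tabular output and to
whole percents for figure-style output, chosen by a single rounding
argument.

The TMB class (`high`/`intermediate`/`low`) and the binary TMB status are
kept consistent by construction: high ⟺ positive, intermediate or low ⟺
negative, untested ⟺ untested. A tested-negative patient whose
intermediate/low split was not recorded is representable (class `NA`).

## Marker calling

**MSI.** The caller takes a microsatellite locus catalog (an input file;
the package never pretends to know a proprietary panel's loci), filters it
to analysis targets by dropping sex-chromosome loci, loci flagged as
typically low-coverage, and loci with repeat units longer than five
nucleotides, then counts — once per locus at most — the target loci
altered by a somatic indel whose length change is a nonzero multiple of
the repeat-unit length (the strict reading of "changes the number of
repeats"; partial-unit indels are ignored). The count is thresholded:
MSI-H iff `count >= threshold`. No default threshold constant is shipped,
because the operating point depends on the panel; it is either configured
or calibrated with `calibrate_msi_threshold()`, which scans every integer
cut-off, maximizes concordance with reference labels (e.g.
fragment-analysis results), and breaks ties toward the smaller threshold.

**TMB.** Somatic nonsilent protein-coding mutations are counted, excluding
copy-number alterations, structural rearrangements, silent and noncoding
records, and divided by the panel footprint in Mb (configuration; the
package default of 1.4 Mb is a typical large-panel coding footprint, not a
published constant). Classes: high at ≥ 17 mutations/Mb, low below 6,
intermediate on `[6, 17)` — the half-open convention closes the gap between
"6–16" and "≥ 17" for non-integer values.

**IHC.** An observation is a percent of stained tumor cells (0–100) and a
staining intensity (0, 1+, 2+, 3+). A marker is positive iff both reach
the marker's configured minimums (boundary inclusive).
`default_ihc_thresholds()` ships *example* cut-offs (≥1+ intensity with
marker-specific percents; ≥2+ at ≥5% for PD-L1) so the classifier is
testable; they are documented as examples precisely because validated
laboratory cut-offs are assay-specific and belong in configuration.

## The stratified association engine

For each pair, a K-stratum set of 2×2 tables is built (strata = tumor
types). Cell `a` counts patients positive for both markers. A stratum is
*informative* when no row or column margin is zero; uninformative strata
carry no information under fixed-margin models and contribute nothing to
the statistics, though their patients still count toward the pair's N.

**Mantel–Haenszel chi-square.** With hypergeometric mean `E_k` and
variance `V_k` of `a_k` per stratum, the statistic is
`(|Σa_k − ΣE_k| − ½)² / ΣV_k` on 1 df. The classic ½ continuity
correction is the default (a flag disables it); the procedure that this
package models names the test but not the variant, so the classic form
was chosen and exposed.

**Common odds ratio.** `OR_MH = Σ(a_k d_k/n_k) / Σ(b_k c_k/n_k)`, with a
95% CI from the Robins–Breslow–Greenland variance of `log(OR_MH)` — the
standard dually-consistent estimator, exact-matching
`stats::mantelhaen.test`. A pooled OR of zero or infinity (no concordant
or no discordant mass) raises an error rather than returning a clipped
number.

**Breslow–Day.** For each informative stratum the fitted `a` under the
common OR solves the quadratic `(ψ−1)x² − [ψ(r1+c1) + (r2−c1)]x + ψ·r1·c1
= 0`, taking the root with all four fitted cells nonnegative (a property
verified over randomized tables in the test suite); the statistic
`Σ(a_k − ã_k)²/Var(ã_k)` is referred to chi-square on (#informative − 1)
df. The uncorrected statistic is the default, with Tarone's adjustment
behind a flag. When the common OR is exactly 1 the quadratic degenerates
and the linear solution `r1·c1/n` is used directly.

**Fisher exact.** Two-sided p by probability-mass ordering: the sum of
hypergeometric probabilities of all tables with fixed margins at most as
probable as the observed one, with a `1e-7` relative tolerance for ties —
the dominant convention, and checkable against enumeration. Sample ORs
for tables with a zero cell get the Haldane–Anscombe +0.5 on every cell
and are flagged; the exact p is unaffected.

**The gate.** `gated_association()` runs Breslow–Day first. If its p ≥ α
(or homogeneity is untestable because only one stratum is informative),
tumor types are pooled and described by the M–H chi-square and common OR;
if p < α the odds ratios differ by histology, pooling is invalid, and each
tumor type is tested with Fisher's exact test, reporting per-stratum ORs
and significance at the same α. Significance everywhere means p ≤ α, with
α = 0.05 by default. No multiplicity adjustment is applied across the
marker-pair grid, by design fidelity to the modeled procedure; the α
argument is the hook for users who want one.

## Benefit mapping

The marker-direction registry records, per protein marker, which status
predicts drug sensitivity and for which drugs. For a pooled result:
non-significant → `no_association`; significant with OR < 1 → protein
*negativity* is enriched among immunomarker-positives, so the verdict is
`likely_benefit` when the marker is sensitive-when-negative and
`unlikely_benefit` otherwise; OR > 1 mirrors. An OR of exactly 1 with a
significant p is rejected as inconsistent input. Heterogeneous pairs get
verdict `heterogeneous` with the same rule applied per significant
stratum ("X of K tumor types"); non-significant strata are
`no_association`. `benefit_matrix()` runs the whole grid — MSI, TMB,
PD-L1 and the composite ANY row (positive if any immunomarker is
positive) against the seven protein markers — honoring per-protein stratum
exclusions; by default ERCC1 pairs drop nonsmall cell lung cancer, where
ERCC1 is not considered predictive of platinum benefit. Degenerate cells
(sparse cohorts with no informative stratum or a zero/infinite pooled OR)
are reported `not_evaluable` rather than aborting the grid.

## The synthetic-cohort generator

There is no public cohort to ship, so the generator *is* the study
condition. Defaults: 28,034 patients over 40 tumor types; marginal
positivity MSI-H 3.3%, TMB-H 8.4%, PD-L1 11.0%, ERCC1 20.9%, MGMT 55.4%,
RRM1 19.9%, TOP2A 75.8%, TOPO1 58.7%, TS 34.0%, TUBB3 56.8%; per-marker
tested fractions matching the per-assay Ns of a commercial testing
database (e.g. MGMT ~18.5%, TOP2A ~46%); and an optional conditional
coupling `P(TMB-H | MSI-H)` (0.73 reproduces the observed nesting of
MSI-H inside TMB-H). Stratum sizes are uniform unless configured —
real per-histology prevalences are not public.

Pair structure is targeted *pairwise*: each protein marker is drawn from
a logistic model whose coefficients are the logs of the configured ORs
against the three immunomarkers and whose intercept is solved numerically
per stratum so the marginal prevalence is exact in expectation. When a
protein is coupled to a single immunomarker this is algebraically
identical to the unique 2×2 joint with the given margins and OR
(Plackett's quadratic, exposed as `p11_from_margins_or()`); with several
simultaneous couplings the targeted ORs are conditional and the marginal
pair ORs can be attenuated by immunomarker co-occurrence. Higher-order
dependence among the ten markers is not controlled — the analysis itself
is purely pairwise. Heterogeneity is simulated by giving a pair a
per-stratum OR vector. `simulate_stratified_table()` is the table-level
shortcut used for statistical calibration: it draws the 2×2 directly from
the exact conditional probabilities, which is how the package verifies
Breslow–Day size (3–7% rejections at α = 0.05 under a common OR over
2,000 replicates of 10 strata × 200 patients) and RBG interval coverage
(93–97% at a true common OR of 0.68 over 1,000 replicates at the
40-stratum, ~21,800-patient scale of the largest published pair).

Profile generation (`generate_ngs_profile()`) emulates the panel-level
inputs: altered-locus counts from well-separated Poisson means (3 vs 45
by default) plus non-repeat-changing distractor indels, mutation counts
drawn inside the truth class's band so the computed mutations/Mb
re-classifies identically, and IHC scores drawn to respect the configured
thresholds. What passing recovery tests show is therefore internal
consistency of the callers at a configured separation — not performance
on real sequencing data, where count distributions overlap, tumor purity
varies, and threshold calibration against an orthogonal assay is the
hard part.

## Numerical choices and degenerate inputs

* All margin products are computed in double precision (integer overflow
  territory at clinical-database scale).
* Fisher tie tolerance `1e-7` relative; oracle agreement with full
  enumeration is asserted to `1e-9` relative over 1,000 random tables with
  n ≤ 200.
* Breslow–Day root selection is bounds-checked (`max(0, c1−r2) ≤ x ≤
  min(r1, c1)`) with a `1e-9` slack, and the common-OR-equal-1 case takes
  the closed-form linear branch.
* `calibrate_msi_threshold()` errors on single-class input (threshold
  undefined); `fisher_exact()` errors on the all-zero table;
  `mh_common_or_ci()` errors on zero/infinite pooled ORs;
  `breslow_day()` errors with fewer than two informative strata
  ("homogeneity not testable"), which the gate treats as pool-by-default.
* Cohort generation is a pure function of its config including the seed:
  the same seed yields a byte-identical cohort.

## Problem sizes used in the packaged checks

The test suite and the acceptance script size their simulations as: 2,000
replicates for Breslow–Day null calibration (10 strata × 200), 500–200
replicates for heterogeneity power, 1,000 replicates for CI coverage
(40 × 544), 1,000 random tables for the exact-test oracle, and 800-patient
cohorts for end-to-end caller recovery. These sizes give Monte-Carlo
standard errors comfortably inside the asserted bands while keeping a
full run in well under a minute.

## Known limitations

* Verdicts are co-occurrence statements, not outcome predictions; no
  survival or response data enter the model.
* The locus catalog, panel footprint, MSI threshold and IHC cut-offs are
  configuration, because the corresponding proprietary constants are not
  public; results depend on them.
* The generator controls pairwise structure only, assumes
  missing-completely-at-random testing masks, and uniform stratum sizes
  by default — all simplifications relative to a real clinical database,
  where testing is indication-driven and histology mix is far from
  uniform.
* With many simultaneous non-unit ORs on one protein marker, configured
  and realized marginal ORs diverge slightly (conditional vs marginal);
  calibration studies in this package always couple one pair at a time.
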