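---
title: "Scoring CEBPA promoter methylation from bisulfite-Sanger data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring CEBPA promoter methylation from bisulfite-Sanger data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cebpameth)
```

## The problem

CEBPA encodes a myeloid transcription factor whose loss of function — by
mutation or by epigenetic silencing — contributes to leukemic
transformation in acute myeloid leukemia. In cytogenetically normal AML
(CN-AML), aberrant CpG methylation of the CEBPA *distal* promoter region is
common, while core-promoter methylation is rare and proximal methylation
essentially absent. This package implements the full quantitative chain for
such a study: per-CpG methylation calling from bisulfite-Sanger
electropherogram peak heights, a per-case methylation ratio with
mean-threshold dichotomization, in-silico methylation-specific PCR (MSP)
for the core promoter, and the downstream cohort statistics and survival
analyses.

## Coordinates and regions

All positions are signed offsets relative to the transcription start site
(TSS), with no position 0 (−1 is the base immediately upstream of +1), and
all regions are half-open `[start, end)`:

* distal promoter: −1423 to −1121, carrying 24 analyzable CpG dinucleotides;
* proximal promoter: −1121 to −896, carrying 20;
* core promoter: −141 to +103 (TATA box and basal machinery).

The literature is inconsistent about the distal start (−1422 vs −1423); we
adopt −1423 and keep all bounds configurable through the `regions` argument
of `promoter_reference()`. Analysis is confined to the bisulfite-converted
sense strand: the assay design this models is single-stranded, and
reverse-strand support is deliberately out of scope. A CpG site is
identified by the position of its C; `N` bases never form sites.

No genomic CEBPA sequence ships with the package (users supply their own
FASTA plus TSS offset). For testing and simulation we bundle
`synthetic_promoter_reference()`: a deterministic synthetic sequence with a
CpG-free background carrying exactly 24/20/8 planted CpGs in the
distal/proximal/core regions. It reproduces the region *geometry* of the
real promoter, not its sequence; results on it validate the machinery, not
genomic coordinates.

## From peak heights to the methylation ratio

At each CpG read on bisulfite-converted template, the cytosine peak height
`C` reports the methylated fraction and the thymine peak `T` the converted,
unmethylated fraction. We quantify

\[ \mathrm{percent}_i = 100 \cdot \frac{C_i}{C_i + T_i}, \]

so a pure cytosine is 100% methylation and a pure thymine 0%. (A bare
quotient `C/T` is unbounded and incompatible with a 0–100 scale, which is
why the bounded form is used.) A site is *called* methylated when its
percent is **at or above 15** — the threshold is inclusive. Sites where
both peaks are zero are missing: excluded from counts with a warning, and a
case with under half its sites observed is reported unevaluable.

The per-case **methylation ratio** combines intensity and extent:

\[ \mathrm{ratio} = \sum_{i \,\in\, \text{called}} \mathrm{percent}_i
   \;=\; \text{methylated count} \times \overline{\mathrm{percent}}_{\text{called}}, \]

ranging from 0 (no called site) to 2400 (24 sites at 100%). A case is
dPM-positive when at least one site is called (`positivity_min_sites`,
configurable). Among positives, the dichotomization threshold is the
*cohort mean ratio of the positive cases* (a fixed threshold — e.g. the
published 541 — can be configured instead): ratio below the threshold is
`low`, above is `high`, and exact equality goes to `low` because the
published rule ("less than … lowly, higher than … highly") leaves equality
undefined.

```{r scoring-example}
pm <- rbind(case_a = c(rep(60, 10), rep(5, 14)),
            case_b = c(rep(20, 4), rep(0, 20)),
            case_c = rep(2, 24))
colnames(pm) <- paste0("cpg_", 1:24)
scores <- run_score(pm)
as.data.frame(scores)
```

## In-silico MSP

MSP is qualitative, so the latent per-site methylation fraction is
binarized at 0.5 (configurable) before conversion: protected sites stay
`CG`, unprotected convert to `TG`. A reaction amplifies only when both its
primers match the converted template with **zero mismatches** (forward on
the template, reverse on its reverse complement) in amplifiable
orientation. The U pair is designed against the fully converted sequence
and the M pair against the methylation-protected one; because each primer
covers at least two CpGs, the two reactions are mutually exclusive on ideal
templates. Core-promoter status is `methylated` iff the M reaction
amplifies, and `invalid` when neither amplifies. `design_msp_primers()`
derives assay primers from any reference; published primer tables are read
with `read_primer_tsv()`.

## Cohort statistics

* 2×2 associations (mutation × dPM status, or × low/high class among
  positives) use the continuity-corrected χ² by default; plain Pearson and
  Fisher's exact test are selectable. The corrected test reproduces the
  published NPM1 (p = 0.003) and TET2 (p = 0.02) values from their printed
  counts; a small number of published values (e.g. the low-vs-high NPM1
  p = 0.04) match Fisher's exact test instead, so the variant is always
  reported alongside the p-value.
* Denominators are pairwise-complete: each marker's n counts only the cases
  in which that marker was measured, never the cohort size.
* Ratio comparisons between marker groups include dPM-negative cases at
  ratio 0 and default to the equal-variance t test (Welch and
  Mann–Whitney are available because the ratio is zero-inflated and
  right-skewed).
* FLT3-ITD allelic ratio is grouped strictly: only ratio > 0.5 is the
  adverse group; 0.5 itself is grouped low, since the published "<0.5" /
  ">0.5" wording leaves equality open.
* Expression is normalized as %CEBPA/ABL1 (`100 * target / control`) and
  correlated with the ratio by Spearman's rank correlation (exact
  permutation p for n ≤ 10 without ties, t-approximation otherwise).
* No multiple-testing correction is applied by default, matching the
  reference analysis conventions; reports print p-values to 3 decimals with a `<0.001`
  floor.

## Survival analysis

Kaplan–Meier estimation, the two-sided log-rank test and Cox proportional
hazards all delegate to the `survival` package (Efron tie handling). Two
conventions are pinned down explicitly:

* the reported median is the **smallest time with S(t) ≤ 0.5** (`"NR"`
  when never reached) — not the interval-midpoint convention `survfit`
  prints when the curve sits exactly at 0.5;
* deaths precede censorings at tied times.

`cox_fit()` runs each covariate univariably and then refits jointly the
covariates with univariable p ≤ 0.05 (the stated stepwise rule; a manual
override exists). Continuous covariates are entered pre-scaled — age per
10 years, WBC per 10×10⁹/L, and the dPM ratio per 100 units (its scaling
has no canonical convention; per-100 keeps relative risks in a
readable range and is configurable). Subgroup analyses (`subgroup_survival()`)
apply the FLT3 grouping or mutation filters before testing and warn when
any arm has fewer than 10 cases.

## The synthetic cohort generator

`simulation_config()` fixes the study conditions; every draw is
reproducible from one integer seed, and all latent quantities are returned
in a truth ledger for recovery tests. What it emulates:

* **Methylation states.** A case is dPM-positive with probability 0.429.
  Positive cases draw per-site methylation indicators from a 5′-biased
  propensity vector (0.62 for sites 1–11, 0.26 for sites 12–24,
  conditioned on at least one methylated site), scaled per case by a
  lognormal dispersion factor (σ = 0.7, mean 1, capped at 0.95
  propensity). Called-site intensities are Beta(1.6, 1.5) rescaled to
  [0.15, 1]; background sites draw Beta(1.2, 12)·0.15, keeping their mass
  well below the call threshold so that realistic peak noise does not
  manufacture false calls. At large n this yields a positive-case mean
  ratio of ≈ 542 with a right-skewed distribution (≈ 57% of positives
  below the mean threshold).
* **Peak heights.** `C = scale·m`, `T = scale·(1−m)` with Gaussian noise
  (default σ = 5% of scale) truncated at zero; as σ → 0 the
  percent-methylation round trip recovers `100·m` exactly.
* **Mutations.** Drawn conditionally on dPM status at the reference cohort
  frequencies (NPM1 38.0%/51.0%, TET2 17.2%/38.2%, IDH2 R140 26.8%/14.7%,
  FLT3-ITD high-ratio 13.4%/21.0%, …), with per-marker missingness matching
  the measured subsets (e.g. TET2 known in ~20% of cases).
* **Clinical variables.** Log-normal WBC with medians 34.6 vs 50.9×10⁹/L
  by dPM status, and age/Hb/platelet/blast distributions around the
  modeled medians. One caveat: with the printed blast medians (58 vs 68.5)
  at n = 555 the blast comparison is reliably significant even though the
  reference cohort reports it as not significant; we keep the printed medians
  and accept the discrepancy.
* **Expression.** A Gaussian copula links expression (log-normal, median
  134.7) to the methylation ratio, targeting Spearman ρ = −0.2. Because
  the ratio is zero-inflated (every negative case ties at 0), a naive
  copula under-delivers the rank correlation; the generator numerically
  inverts the exact large-n Spearman coefficient of a bottom-tied Gaussian
  copula (`spearman_given_copula_r()`) so the realized ρ hits the target
  in expectation. The latent score is built on a continuous ordering
  (ratio, tie-broken by total methylation burden).
* **Survival.** Exponential event times whose hazards multiply covariate
  effects (age, WBC, FLT3-ITD high ratio, NPM1, RUNX1) with exponential
  censoring (median 60 months, administrative cap 84) and follow-up
  available in ~78% of cases. The dPM effect is deliberately null overall
  and restricted to subgroups (OS HR 1.35 within FLT3-low, 2.2 within
  TET2-mutated). These HRs are kept modest: FLT3-low is the cohort
  majority, so a large "subgroup" effect would contradict the near-null
  overall contrast of the reference cohort.

What it does **not** emulate: chromatogram waveforms, cloning-based
single-molecule patterns, immunophenotype markers, microarray expression,
competing risks, or the correlation structure among mutations beyond their
dPM-conditioning. Passing tests on synthetic cohorts therefore validate
the pipeline's arithmetic and statistical behaviour, not biological
conclusions about real patients.

## Numerical and degenerate-input choices

* Percent methylation is clamped to [0, 100] against floating-point
  overshoot when one peak is zero.
* Contingency tables with a zero margin return p = 1 with a warning rather
  than erroring.
* Two-sample comparisons where both groups have zero variance return p = 0
  (distinct means) or 1 (equal means) instead of failing inside `t.test`.
* `cox_fit()` refuses fewer than 10 events or constant covariates and
  flags likely separation (huge standard errors).
* Generators restore the caller's RNG stream, so library use never
  perturbs user-level reproducibility.

## Problem sizes used in the checks

The package's own verification suite runs the scoring round-trip and ratio
identity on 10⁴ random profiles, calibrates the log-rank test's type-I
error over 2,000 null simulations of 80 subjects, measures Cox log-HR
recovery bias over 200 replicates at n = 2,000 with ~70% events, and
generates cohorts of 555 (the reference cohort size) and 1,000 cases for
distributional checks. These sizes give Monte-Carlo standard errors
comfortably below the asserted tolerances while keeping the full suite
fast.

## Known limitations

* The exact arithmetic of the published ratio is not given in closed form
  anywhere; the sum-over-called-sites form is adopted on
  numerical-consistency grounds (a quotient of an intensity ≤ 100 by a
  count cannot average 541) and is configurable.
* Published p-values mix χ² variants; where a printed value is only
  reproducible by Fisher's exact test we say so rather than silently
  switching defaults.
* Real-cohort survival medians, immunophenotype comparisons and expression
  profiling results are outside what synthetic data can reproduce; the
  property-based suite stands in for them.
* The synthetic promoter reference validates CpG enumeration and MSP
  mechanics; genomic coordinates of the real promoter must come from a
  user-supplied sequence.
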