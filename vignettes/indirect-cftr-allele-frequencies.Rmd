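---
title: "Indirect estimation of CFTR variant allele frequencies from a patient registry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect estimation of CFTR variant allele frequencies from a patient registry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cftrmonitor)
```

## The problem

Carrier screening and infertility work-ups need region-specific allele
frequencies (AFs) of pathogenic *CFTR* variants, but population
sequencing databases cover most regions thinly or not at all. What usually
does exist is a national registry of diagnosed cystic fibrosis (CF)
patients with genotypes. This package implements, tests and validates the
classical indirect route from such a registry to population AFs, and the
contingency statistics used to compare variant spectra between regions
and cohorts.

## Model and assumptions

CF is autosomal recessive. Under random mating (Hardy–Weinberg
equilibrium, HWE) the birth prevalence of affected children equals $q^2$,
where $q$ is the combined frequency of all pathogenic alleles at the
locus. The chain has three steps:

1. **Prevalence.** $F_d = n / (N \cdot h)$ — registered affected children
   under the ascertainment age ($n$) over all births in the region across
   the horizon ($N$ births/year for $h$ years). `horizon_years` is a
   parameter with default 18 because the registry convention is "under the
   age of 18"; other registries may differ.
2. **Disease-allele frequency.** $q = \sqrt{F_d}$
   (`allele_freq_from_prevalence()`).
3. **Per-variant indirect AF.** $\mathrm{AF}_v = q \cdot f_a(v)$, where
   $f_a(v)$ is variant $v$'s share among the alleles of genotyped CF
   patients (`spectrum_proportions()`), so that the indirect AFs over a
   partition of patient alleles sum back to $q$.

The assumptions this encodes: random mating (no inbreeding or population
structure), complete ascertainment (every affected child is registered),
full penetrance of biallelic genotypes, and a patient cohort whose allele
spectrum is representative of the region's disease alleles. Registry
incompleteness biases $F_d$ — and hence every indirect AF — downward;
no correction is applied because no ascertainment model is available, and
indirect estimates should be read as mild underestimates.

A subtlety worth making explicit: step 2 yields the *disease-allele
frequency*, not the heterozygote carrier rate $2pq \approx 2q$. Only
$q \cdot f_a$ is consistent with the published calculated AF column this
package reproduces (the national calculated F508del AF of 0.0054 divided
by the registry share 0.5155 gives $q = 0.010476$, whose square is a
plausible CF birth prevalence of about $1.1 \times 10^{-4}$).

## Data contracts

* **Cohort tables** (`read_cohort_table()`): wide TSV, one column per
  diploid cohort with its size in the header; the allele number is always
  $2n$. The token `n.a.` is *missing*, never zero; every aggregate
  (`total_burden()`) reports how many entries it excluded. Frequencies are
  printed at 4 decimals; internal precision is full.
* **Spectrum tables** (`read_spectrum_table()`): one row per region with
  AF/AC (allele frequency / allele count) pairs per category. The AC
  columns are authoritative; AF columns are cross-checked against
  `AC / sum(AC)` at $5 \times 10^{-4}$ and mismatches warn. The packaged
  reference rows are internally off by up to 12 alleles (their counts were
  back-computed from rounded frequencies before publication), so the sum
  constraint $\sum AC = 2n$ is enforced exactly only for synthetic data
  and warns otherwise.
* Published frequencies without counts are re-integerised as
  `round(af * allele_number)` (`allele_count_from_af()`); every
  reconstruction is logged, because statistics recomputed from
  reconstructed counts differ from published ones at the rounding level
  (see "Numerical behaviour").

## Statistical choices

* **Confidence intervals** are Clopper–Pearson exact by default
  (`binomial_ci()`), because they reproduce the published interval
  (0.0053, 0.0117) for 27/3342 where a Wald interval does not; Wilson is
  available via `method = "wilson"`. The exact interval is tested against
  an independent inversion of the binomial tail sums.
* **Spectrum comparisons** use the Pearson chi-squared statistic with
  expected counts from the margins (`chi_square_test()`). The Yates
  continuity correction follows the mainstream-software convention:
  applied iff the table is 2×2 under `yates = "auto"`, forceable on or
  off. The published 2×2 statistic for St. Petersburg vs Yugra (15.238)
  matches the Yates value computed here (15.259, 0.14% apart on
  reconstructed counts), not the uncorrected one (16.04), which is what
  fixes the default. The smallest expected count is always reported and
  values below 5 warn rather than switch tests: no exact test is
  substituted, and no multiple-testing correction is applied, matching
  the reference analysis; reports say so.
* For across-district tests the national total row is excluded (it is the
  sum of the district rows, and the published df of 14 implies 8 regions
  × 3 categories), and rare variants are pooled into the reserved
  `"other"` category with the top-2 registry variants kept apart — the
  keep set is a parameter.

## The synthetic generator

`simulation_params()` defines a ground-truth world the estimator assumes:
each chromosome independently carries a disease allele with probability
`q_true`, disease alleles are assigned variants by the multinomial
`fa_true`, affected births are binomial over the birth cohort with rate
`q_true^2`, and patient spectra are multinomial over
`2 * n_patients_genotyped` chromosomes. Defaults mirror the national study
conditions: `q_true = 0.0105`, the national F508del /
CFTRdele2,3(21kb) / other split (0.5155 / 0.0611 / 0.4234 as exact count
fractions), 1.67 million births/year (chosen so that 18 years at
prevalence $q^2$ yield about the 3.3 thousand registered cases the
national registry holds), 1671 healthy individuals and 3292 patients.

What it deliberately does **not** model: population structure and
inbreeding, incomplete ascertainment (emulatable by thinning `n_cases`),
genotyping error, drift or selection. Passing recovery tests therefore
show the estimation chain is correct *under its own assumptions* — they
say nothing about violations of HWE or registry completeness in real
data.

Seeds: each experiment takes one master seed; replicate $i$ of
`recovery_experiment()` runs on `seed + i - 1`, so results are portable
and bit-reproducible. The recovery experiment at the packaged analysis
scale (500 replicates, 140 thousand births/year, 500 patients — a
regional rather than national birth cohort, so Monte-Carlo error is
visible but small) recovers every per-variant indirect AF with mean bias
below 1% relative.

## Numerical behaviour and degenerate inputs

* The published tables are internally rounded; recomputing their
  statistics from the printed allele counts gives 198.68 for the 8×3
  district test where 197.55 was published (counts re-derived from the
  rounded frequencies give 197.49, bracketing the published value). The
  package computes from the counts it is given and logs reconstructions
  rather than guessing which rounding the original analysis used.
* `q_true = 0` propagates exactly: zero cases, zero indirect AFs, and
  comparisons are skipped with a logged reason (a zero column margin is a
  degenerate-table error, not a zero statistic).
* Missing (`n.a.`) frequencies are refused by pairwise comparisons with
  an explicit error; they are never imputed as zero.
* Proportions from a spectrum sum to 1 within $10^{-12}$; collapse
  conserves total allele counts exactly (integer arithmetic).
* Report rendering: frequencies at 4 decimals, $F_d$ and $q$ at 6
  significant digits, p-values below $2.2 \times 10^{-16}$ rendered as
  `< 2.2e-16`.

## Problem sizes

The packaged tests and scripts run at desk scale: all published-table
computations are instantaneous; the stochastic validation uses 500
recovery replicates and 1000 prevalence replicates of a one-million-birth
cohort, which completes in seconds while leaving the Monte-Carlo error an
order of magnitude below the tolerances tested.

## Known limitations

* No ascertainment-bias correction; indirect AFs are lower bounds in the
  presence of registry incompleteness.
* The chain targets autosomal recessive diseases only.
* HGVS strings in the catalog are carried as labels, not validated
  against a transcript.
* Some published pairwise statistics cannot be reproduced from the
  printed tables at all (their input counts were rounded away); the
  package recomputes them generically from reconstructed counts and
  documents the difference instead of special-casing them.
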