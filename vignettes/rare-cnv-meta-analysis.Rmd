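---
title: "Stratified rare-CNV burden and association meta-analysis with rarecnv"
author: "rarecnv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified rare-CNV burden and association meta-analysis with rarecnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarecnv)
```

## The problem

Rare copy-number variants (CNVs) — deletions and duplications typically
larger than 100 kb — carry substantial risk for neurodevelopmental and
psychiatric phenotypes, but individual variants are too rare for any
single cohort to test. Meta-analysing CNV calls across many SNP-array
cohorts raises two hazards that this package is built around:

1. **Technical heterogeneity.** Cohorts are genotyped on arrays with
   very different probe densities, so raw calls differ systematically in
   resolution and noise. Per-sample intensity metrics (LRR SD, BAF
   drift, GC waviness) and per-array-group call-count limits are needed
   before any comparison is meaningful.
2. **Population structure.** Case/control ratios differ across
   ancestries, arrays and sexes. Any pooled test conflates these
   differences with disease association.

The package addresses both with a fixed recipe: harmonized QC filters;
strata defined by the unique combination of *array group x ancestry
cluster x sex*; and association tests that condition on those strata.

## The statistical model

### Carrier tests via Cochran–Mantel–Haenszel

Every association test in the package reduces to a stratified 2x2
carrier table: per stratum \(i\), the number of cases \(a_i\) (of
\(n_{1i}\)) and controls \(c_i\) (of \(n_{2i}\)) carrying at least one
qualifying CNV at the locus. The CMH score statistic

\[
X^2 = \frac{\left(\sum_i (a_i - E[a_i])\right)^2}{\sum_i \mathrm{Var}(a_i)},
\qquad
E[a_i] = \frac{n_{1i} m_{1i}}{N_i}, \quad
\mathrm{Var}(a_i) = \frac{n_{1i} n_{2i} m_{1i} (N_i - m_{1i})}{N_i^2 (N_i - 1)}
\]

uses the conditional (hypergeometric) moments per stratum and is
referred to \(\chi^2_1\). The common odds ratio is the Mantel–Haenszel
estimator \(\sum_i a_i d_i / N_i \,/\, \sum_i b_i c_i / N_i\) with a
Robins–Breslow–Greenland confidence interval. Design choices worth
stating explicitly because ties and edge cases are otherwise ambiguous:

* **No continuity correction by default** (`continuity = FALSE`): the
  plain two-sided score form matches the permutation null exactly; a
  corrected statistic would not be the quantity being permuted.
* **Degenerate strata** (no carriers, or everyone a carrier) have zero
  conditional variance; they contribute nothing to the statistic or the
  MH estimator and are skipped. A locus where *every* stratum is
  degenerate is flagged and reported with \(p = 1\) and an undefined
  odds ratio — flagged, never dropped, so locus lists remain complete.
* The kernel is implemented as vectorized arithmetic over loci because
  the permutation engine re-evaluates every locus for every label
  permutation; `stats::mantelhaen.test` is used as an independent
  cross-check in the test suite (agreement to 1e-8 on randomized
  tables), never as the production path.

### Burden regression

Global burden is additionally tested with the covariate-adjusted
logistic model

```
status ~ burden_metric + GROUP + LRR_SD + n_cnv_raw
```

where `GROUP` is the categorical stratum label. LRR SD and the raw call
count enter because residual intensity noise and call-rate differences
between cohorts correlate with both phenotype availability and call
quality. Perfect separation and constant burden metrics raise explicit
non-identifiability errors instead of returning enormous Wald estimates.

### Genome-wide significance by min(P) permutation

Sliding-window and gene-based scans run thousands of heavily correlated
tests; Bonferroni on the window count would be far too conservative.
The package instead permutes case/control labels *within each stratum*
(preserving stratum case counts), recomputes all locus p-values per
iteration and records the minimum. The empirical significance threshold
is the \(\alpha\)-quantile of these minima, taken conservatively as the
\(k\)-th smallest with \(k = \max(1, \lfloor \alpha\, n_{perm} \rfloor)\).
Per-locus FWER-adjusted p-values use the \((r+1)/(n_{perm}+1)\)
convention, which guarantees validity (an adjusted p can never be
exactly zero). Because deletion and duplication scans are run
separately, adjusted p-values are finally doubled (capped at 1); the
doubling is applied after FWER adjustment. Each of the four test
families (gene/window x DEL/DUP) gets its own permutation null.

External cohorts that contribute only stratified count tables (no
individual-level data) enter every observed test, but their labels
cannot be permuted; they are held fixed across iterations. This is
conservative: a real signal present in the external counts shifts the
observed statistic but not the null.

Raw p-values feed the genomic inflation factor
\(\lambda = \mathrm{median}(\chi^2_{obs}) / 0.4549\), the standard
calibration diagnostic.

## The filter cascade

Two call grades are distinguished, with deliberately explicit boundary
semantics (the thresholds come in "at least"/"between"/"greater than"
flavours and ties must land somewhere):

* **Qualifying** calls: \(\ge 10\) probes, length in \([30\,kb, 20\,Mb]\)
  (inclusive), autosomes 1–22 only. These define carrier status for
  burden tables.
* **Analysis-grade** calls: qualifying and additionally length strictly
  \(> 100\,kb\) with \(\ge 15\) probes. These enter burden and
  association. The stricter grade exists because cross-array
  heterogeneity makes small calls unreliable in exactly the cohorts
  with sparse probes.

Sample-level QC removes intensity outliers (any of LRR SD, BAF drift,
GCWF more than 3 SD from the per-dataset *median* — the median centring
is intentional, making the cut robust to the outliers being flagged)
and samples exceeding their array group's raw-call budget (15 calls for
dense OmniExpress-style arrays, 30 for 610K/GSA-style arrays, both
capped at 20 Mb total footprint).

A separate biobank-style profile mirrors external callsets: strict
intensity bounds (LRR SD < 0.3, BAF drift < 0.01, absWF < 0.05), at
most 50 calls, no call over 20 Mb, gap-based call merging (merge when
the gap is under 20% of the merged span, scanned left-to-right to a
fixed point — the rule is self-referential, so the candidate merge's
own span is what the 20% is measured against), blacklist-region
exclusion (any 1 bp overlap removes, under half-open coordinates), and
a carrier-frequency cap (< 1% of samples). Locus identity for the
frequency cap and for singleton marking is *50% reciprocal overlap of
same-type calls* — a choice, documented here, since "the same CNV" has
no canonical definition at array resolution.

All coordinates are 0-based half-open internally; 1-based inclusive
dialects (e.g. PennCNV text output) are converted on ingest, so length
arithmetic is uniformly `end - start`.

## Stratification

Ancestry clusters come from Louvain community detection on a
k-nearest-neighbour graph (k = 15, unweighted, Euclidean distance) over
the first 6 principal components of an upstream genotype PCA. The PCA
itself is consumed, not computed: LD-pruning and PC computation are
standard genotype operations outside this package's scope. The cluster
count is data-dependent and deliberately not a contract. Strata are the
occupied array-group x cluster x sex combinations with at least 5 cases
and 5 controls and a case fraction inside \([0.10, 0.90]\) (bounds
inclusive); samples in failing combinations are reported as dropped,
never silently discarded.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` generates exactly the structure the analysis
conditions on: strata with their own sizes, baseline Poisson call
rates, probe densities and LRR SD distributions; log-normal call
lengths (median 150 kb, sdlog 0.7 by default, so both the qualifying
and analysis-grade filters bite); probe counts proportional to length;
cluster-separated PC coordinates; and planted risk loci parameterized
by control carrier frequency \(f\) and carrier odds ratio, with case
carrier frequency \(f\,OR/(1 - f + f\,OR)\).

The default toy genome (3 autosomes of 5/4/3 Mb) compresses a genome's
CNV density into a few megabases: the default 1 background call per
sample is ~200x denser per megabase than real data, so that filters,
carrier tables and permutation nulls are all exercised with a few
hundred samples. Consequences to keep in mind when interpreting green
tests:

* Per-window background carrier frequencies (several percent) are far
  above real rare-CNV data (where the < 1% frequency filter caps them);
  power scenarios therefore use a sparser rate (0.2) so planted signals
  sit on a realistic background.
* Adjacent 200 kb/10 kb windows on a 3.19 Mb chromosome form only ~16
  independent blocks. A single simulated cohort's genomic inflation
  factor is therefore extremely noisy, and calibration checks pool raw
  p-values across replicate cohorts before computing \(\lambda\); with
  hundreds of cohorts the estimate is tight.
* No probe-level intensity signal (LRR/BAF tracks) is simulated, so
  nothing about CNV *calling* is validated here — only everything
  downstream of calls.

Planted calls span their locus exactly; background calls are placed
independently of genes, so genic burden signal arises only through
planted loci. Everything is deterministic given the master seed, with
per-stage substreams, and fixtures are written with fixed number
formatting so two writes are byte-identical.

## Validation scales

The shipped checks run at sizes chosen to make their statistical
assertions sharp while staying desk-sized: CMH equivalence on 50
randomized stratified tables; exhaustive-vs-Monte-Carlo permutation
agreement on a 20-sample toy (all 63,504 within-stratum label
assignments enumerated, 10,000 Monte-Carlo permutations compared within
3 binomial SEs of the estimator's exact expectation); family-wise error
measured over 200 null cohorts of 500 samples x 300 windows at 500
permutations; planted-effect recovery over 100 cohorts of 4,000 samples
at 1,000 permutations (top locus + adjusted p <= 0.05, and
MH-estimator CI coverage of the simulated carrier OR 10 — coverage is
assessed on the planted variant's own carrier table, because any >= 1 bp
overlap window necessarily mixes planted and background carriers and so
estimates a smaller, attenuated quantity); and confounding control over
200 cohorts where one stratum has both a higher case fraction and a
higher call rate.

## Known limitations

* No exact (conditional-likelihood) stratified odds ratios: with very
  sparse strata the MH estimator and RBG interval are the documented
  choice, and degenerate tables are flagged rather than estimated.
* The two-round doubling assumes exactly two scans (deletions and
  duplications); a third class would need a different correction.
* External count tables cannot participate in permutation; with most
  of the data external, the min(P) threshold becomes conservative.
* Gene-based tests use merged coding intervals only; regulatory-region
  overlap is out of scope.
* The kNN/Louvain clustering assumes the leading PCs separate ancestry;
  with fewer than ~20 samples per cluster the stratum filters will drop
  most combinations, which is reported but not repaired.
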