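---
title: "Models and methods behind promoMethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind promoMethyl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoMethyl)
```

# Overview

promoMethyl analyses targeted (amplicon) bisulfite sequencing of
alternative promoter regions — the motivating system is the *ESR1*
(oestrogen receptor alpha) locus in breast cancer cell lines and
tumours, where several alternative first exons (promA–promF) drive the
same coding sequence and their usage is coupled to local CpG
methylation. The package covers five connected analyses:

1. **Methylation quantification.** Per-read CpG calls (`M`/`U`/`N`) are
   parsed from a native TSV or from bismark-style CpG-context output
   (`Z` → `M`, `z` → `U`, absent site → `N`) and summarized into a
   site-by-sample matrix of methylated-read fractions with coverage.
2. **Epiallele analysis.** Because each sequencing read reports one
   original DNA strand, the joint methylation state of all CpGs in a
   region on one read (the epiallele) reveals cellular subpopulations;
   pattern frequencies and their sharing between related samples are
   quantified.
3. **Differential and correlation analysis.** Per-site methylation
   differences between derived sublines and their parental line,
   site-by-site Spearman correlation, and methylation-versus-expression
   Spearman correlation with Benjamini–Hochberg correction.
4. **Functional annotation.** Overlap of CpG sites with transcription
   factor binding sites, construction of an expression-matched
   background region set, and comparison of phyloP conservation at
   C-of-CpG positions versus their surroundings, absolute and relative
   to the regional mean (ΔphyloP).
5. **Cohort analysis.** Relative first-exon usage fractions in a tumour
   cohort, clustering of usage profiles, and survival stratification
   (Kaplan–Meier, log-rank, Cox regression).

A synthetic-data generator emulates the statistical structure of every
input so the whole pipeline is testable without sequence data.

# The data model

Read-level data live in a `ReadCallSet`: one record per read with a
call string over `{M, U, N}`, one character per CpG of the region in
coordinate order, plus the site table as a `GRanges` (1-based position
of the C on the forward strand; calls from the bottom strand are
attributed to the same symmetric CpG). Non-CpG-context tallies
(converted/unconverted cytosines) ride along for conversion QC.

Site-level summaries are a `MethylationExperiment`, a
`RangedSummarizedExperiment` with assays `fraction` and `coverage`.
The methylated fraction at a site is

$$m = \frac{\#M}{\#M + \#U},$$

with `N` calls excluded from numerator and denominator. A validity
method enforces $m \in [0,1]$ and that $m \cdot c$ is within 0.5 of an
integer (it is a read count). Sites below `min_coverage` are missing
(`NA`), never zero; the default `min_coverage = 1` reflects that
amplicon sequencing yields high depth at every designed site, and the
threshold is exposed for sparser data.

# Epiallele patterns

Reads containing any `N` are excluded from pattern analysis (and
counted), because an amplicon read should span its whole region: keeping
partial reads would inflate the pattern alphabet with artefacts of
incomplete observation. They are retained for per-site fractions, where
each site stands alone. Both behaviours are selectable at the parser
level; exclusion is the default. Reporting keeps the union of the
`top_k = 10` most frequent patterns and all patterns with frequency at
least `min_frequency = 0.01`, with count ties broken lexicographically —
this truncation is purely presentational and every computation uses the
full counts (a test verifies that per-site fractions recomputed from
full pattern counts equal those computed from reads).

`patternSharing()` classifies a derived sample's pattern as
*pre-existing* when its parental frequency reaches `presence_threshold`
(default 0.01, i.e. detectable at typical coverage), and reports the
fraction of derived reads carried by pre-existing patterns. Values near
1 are consistent with selection acting on standing subpopulations;
low values indicate de novo methylation change.

# Correlation statistics

All correlation is Spearman's rank correlation with mid-ranks for ties.
p-values are exact permutation probabilities (full enumeration of the
$n!$ orderings) for $n \le 9$ and the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df otherwise; with 19
samples the design sits comfortably in the asymptotic regime, and the
exact branch guarantees correctness for small cell-line panels. Missing
values are handled by pairwise-complete deletion, so each pair reports
its own $n$. Constant vectors make rank correlation undefined; such
pairs are skipped and counted, never reported as 0.

The methylation–expression family is corrected jointly over **all**
site-by-target pairs with Benjamini–Hochberg (`bhFDR()` validates
inputs and applies the standard step-up rule), because the scientific
conclusion — how many sites relate to any first exon — is a single
family-level question. `alpha = 0.05` is used wherever a significance
count is reported, and is configurable.

Expression input is normalized to *ACTB* and scaled by 10 000
(first exons) or 100 (3′ UTR); the scale only aids plotting and cannot
affect rank-based statistics (tested).

# Conservation analysis

phyloP scores are $-\log_{10} p$ under a neutral-evolution null:
positive means conserved, negative accelerated. `conservationCompare()`
pools all region positions, splits them into C-of-CpG versus other
positions and applies a two-sided Wilcoxon rank-sum test — exact when
the combined sample is at most 10 with no ties, otherwise the normal
approximation with tie and continuity correction. Pooling across
regions is the default (a stratified per-region mode is provided);
ΔphyloP — each position's score minus its region's mean — removes
between-region baseline differences before the same comparison, and by
construction the per-region mean of Δ is 0 (enforced to 1e-9 in
tests).

The background set for conservation comparisons is built by:
selecting genes whose mean expression lies within the interquartile
range of the target gene's per-sample expression (quartiles by linear
interpolation, R type 7 — the published range comes without a quantile
rule, so the common default is used); padding their first exons by
±750 bp, merging overlapping padded exons of the same gene (prevents
double-counting positions); subtracting all protein-coding intervals;
and keeping fragments strictly longer than 400 bp with at least four
CpGs. "Longer than" is strict and "at least" inclusive, taken
literally from the construction rule.

# Cohort analysis

Relative first-exon usage is the fraction of a tumour's first-exon
reads on each exon; tumours with fewer than 10 total first-exon reads
are excluded (inclusive at exactly 10). Clustering defaults to
hierarchical Ward (ward.D2) linkage on Euclidean distances, cut at
$k = 5$ — usage profiles form a handful of archetypes and Ward on
compositional vectors is a robust default — but method and $k$ are fully
configurable since no single choice is canonical; a mean silhouette
width is returned as a cohesion diagnostic. Stratification labels a
tumour *high* when its fraction strictly exceeds the cutoff. Published
stratification cutoffs are typically only graphical, so the cutoff is a
required analysis input; `quantileCutoff()` offers a tertile-style
helper without claiming to reproduce any published strata.

Survival uses the product-limit estimator, the log-rank test with the
standard hypergeometric variance, and Cox proportional-hazards
regression with Efron tie handling (the common modern default). Tumour
size is dichotomized at 20 mm when requested as a covariate. Degenerate
inputs (no events, empty groups, fewer events than parameters,
separation) raise explicit errors rather than returning numbers.

# The synthetic-data generator

The generator defines the conditions under which the package is
validated:

* **Reads** come from an epiallele mixture: each read draws a pattern
  by its mixture weight, then unmethylated sites flip to `M` with
  probability `conversion_failure` (bisulfite chemistry only fails in
  that direction; failure of methylation protection is folded into the
  symmetric `call_error`), then every call flips with probability
  `call_error`. The packaged dataset uses 12 regions × 9 CpGs
  (108 sites) × 19 samples — six cell lines as parental / resistant /
  withdrawn sublines plus one late-withdrawal sample — with
  `conversion_failure = 0.015` and `call_error = 0.005`, typical of
  well-converted libraries.
* **Expression** per target is
  $\log e = \beta_0 + s\,\sigma\,\bar m + \varepsilon$, with sign
  $s = -1$ for negative coupling, $\bar m$ the mean methylation of the
  linked sites and Gaussian noise on the log scale.
* **Conservation** scores are i.i.d. Normal(mean, 1) per base with
  C-of-CpG positions shifted down by `cpg_depression`.
* **Cohorts** draw a cluster per tumour, a read depth (negative
  binomial by default), multinomial exon counts on the cluster profile,
  and exponential event and censoring times — the simplest model
  satisfying proportional hazards, so Cox recovery is well-posed.

Each operation runs its own RNG stream seeded from the spec, restored
afterwards, so stages are individually reproducible and reruns are
byte-identical.

What the generator does **not** emulate: PCR duplicates and
amplification bias, alignment and trimming artefacts, strand-resolved
hemimethylation, spatially autocorrelated conservation scores,
covariate-dependent censoring, and the event hierarchy relating
OS/RFI/DRFI endpoints (endpoints are independent draws). Passing tests
therefore demonstrate correctness of the estimators under the stated
statistical model, not robustness to those real-data artefacts.

# Numerical choices and problem sizes

Exact enumeration limits (permutation Spearman at $n \le 9$, exact
rank-sum at combined $n \le 10$) follow the conventional cross-over
to asymptotics. Validation problem sizes were chosen so each check is
well-powered: mixture recovery at $10^5$ reads (binomial error
≈ 0.0015), coupling-sign recovery over 50 seeds at 19 samples, cluster
recovery over 20 seeds of 120 tumours, Cox hazard-ratio recovery at
$n = 2000$ (HR truth 2.0), null calibration of the conservation test
over 1000 seeds, and the full pipeline at the 108-site/19-sample design
scale with 60 reads per region and sample.

# Known limitations

* The Spearman t approximation is slightly anticonservative for
  $10 \le n \le 15$ with heavy ties; the exact branch can be widened
  via `exact_n` at factorial cost.
* Background-region construction assumes first-exon and CDS annotation
  on a shared assembly; no liftover is provided.
* The Cox interface refuses separated fits rather than penalizing them.
* Pattern analysis assumes reads span whole amplicons; data from
  shotgun bisulfite protocols should be summarized per-site instead.
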