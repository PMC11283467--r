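---
title: "Methods: consensus fusion calling, burden stratification and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus fusion calling, burden stratification and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices behind
`fusionburden`, in the order the pipeline runs them. It is a methods
document, not a tutorial; the README holds a worked example and the
`analysis/` drivers run the full study on a synthetic cohort.

# Canonical fusion calls

A fusion is an ordered 5'→3' gene pair ("gene1–gene2"). The order is part of
the event's identity and is never sorted away: the 5' and 3' partners play
different biological roles, the per-chromosome accounting distinguishes the
two partners' chromosomes, and a pair and its reversal are counted as two
distinct events (an assumption the burden definition inherits).

Importer conventions, fixed once for all three caller dialects:

* Coordinates are 1-based and fully closed, as emitted by the modeled
  callers; nothing converts to 0-based half-open.
* Chromosomes are normalized to `chr`-prefixed names; the 24 canonical human
  chromosomes are kept and calls on any other contig (mitochondrial, alt,
  decoy) are dropped with a logged count.
* Multi-symbol gene fields such as `"ESR1,AKAP12"` resolve to the first
  listed symbol. This is a decision, not caller intent: it is deterministic
  and respects the caller's own ranking of candidate annotations. `SYMBOL^ENSG...`
  identifiers reduce to the symbol.
* Rows with an unparseable gene pair, malformed numeric fields, or
  non-canonical contigs are skipped, counted, and reported; a bad row never
  aborts an import.

# The filter cascade

Four rules, applied in a fixed order (support → read-through → blacklist →
consensus), with the first three being pure per-call predicates that
commute — the order is fixed only for reproducible intermediate counts.
Consensus must come last because it aggregates across callers.

* **Support** (`min_total_support = 3`, `min_split_reads = 1`): calls with
  fewer than three supporting reads (split + discordant) or without any
  split read are removed. A junction-spanning read is the only direct
  evidence of the fused transcript; discordant pairs alone are compatible
  with many artifacts.
* **Read-through** (`read_through_max_gap = 50000` bp): transcription that
  runs into the downstream neighbor produces chimeras that are not genomic
  rearrangements. Calls flagged by their caller are dropped; as a fallback
  for callers that do not flag them, unflagged same-chromosome, same-strand
  calls whose 3' breakpoint lies within 50 kb downstream of the 5'
  breakpoint are also dropped. The 50 kb default spans typical adjacent-gene
  distances; the heuristic requires known equal strands ("." never
  matches), and setting the gap to 0 disables it.
* **Blacklist**: ordered pairs found in healthy-tissue/homology "red
  herring" lists are removed, as is any call touching a banned single gene.
  Matching is exact on canonicalized symbols — alias resolution is
  cohort-specific curation and out of scope.
* **Consensus** (`min_callers = 2`): within a sample, calls are grouped by
  ordered gene pair, deliberately ignoring breakpoint coordinates, because
  callers frequently disagree on the exact junction of the same event.
  Groups predicted by at least two of the three callers survive. Read
  support is aggregated as the per-field **maximum** across callers, not the
  sum: all callers see the same library, so summing would double-count the
  same reads.

Per-sample **fusion burden** is the number of distinct ordered pairs after
consensus; isoform-level breakpoint variety collapses into one event.
Samples with no surviving event count 0, not missing.

# Cohort catalog and tabulations

The catalog deduplicates consensus events into unique ordered pairs with the
number of distinct carrying samples. *Recurrent* means carried by at least 2
cohort samples (configurable); *known* means the ordered pair occurs in at
least one supplied curated database list. The 2×2 classification table
reports counts and percentages of the grand total.

The per-chromosome table uses the counted-twice convention: each fusion
contributes one count for each partner gene's chromosome, so an
intrachromosomal fusion adds 2 to its chromosome's intra column and an
interchromosomal fusion adds 1 to each partner's inter column. Column
percentages are per chromosome (intra / (intra + inter)). Because the
convention is ambiguous about multiplicity, both modes are implemented:
`unique` (default; each catalog entry once) and `per_sample` (each entry
weighted by its carrying samples).

Percentages everywhere round **half-up to one decimal** (base R's `round`
is half-even, which disagrees with how such tables are conventionally
printed); an all-zero table reports 0 rather than NaN.

# Burden dichotomization and the cutoff scan

The high/low split at quantile $q$ uses the empirical type-1 quantile: the
threshold is the smallest observed value with at least $qn$ values at or
below it, and **high means strictly above** the threshold. With tied,
discrete burdens this pushes ties into the low group, so the high group is
always the minority arm — which matches how a "patients exceeding the 60%
cutoff" rule behaves on real burden distributions. An all-tied input yields
an all-low grouping with a warning.

The scan evaluates quantiles 0.1–0.9 (step 0.1). At each quantile the
**full analyzed cohort** is dichotomized once — one global threshold shared
by all subgroup panels, as in stratified KM figures — and a log-rank test is
run within each panel. The default panel set is: all patients, each IHC
subtype present, and each intrinsic subtype with at least 10 samples (a
handful of normal-like samples cannot support a two-arm survival test). A
panel whose high or low arm is empty at some quantile is untestable there
and excluded from that quantile's coverage.

Coverage is the number of panels significant at $\alpha = 0.05$. Following
the convention that significance is judged on FDR-adjusted p-values, the
default adjusts each quantile's panel p-values by Benjamini–Hochberg before
thresholding (`p_adjust = "BH"`; `"none"` gives raw-p coverage). The
selected quantile maximizes coverage; ties break by the smaller raw
all-patients p, then by the smaller quantile. A caveat worth stating: the
panels overlap (all patients contain every subtype; intrinsic subtypes
overlap IHC subtypes), so chance associations tend to reach significance in
two or three panels at once rather than one — multi-panel coverage under
the null is more common than independent tests would suggest, and a
coverage of 2 on its own is weak evidence of a real cutpoint.

# Survival estimation

The Kaplan–Meier estimator is implemented directly (the `survival` package
serves as an independent cross-check in the test suite, never as the
implementation): product-limit over distinct event times, with subjects
censored at an event time remaining at risk for that time's factor.
Greenwood's variance accumulates $d_i/(n_i(n_i-d_i))$; once the curve
reaches 0 the variance is defined as 0 (the estimator is degenerate there).
Five-year rates read the step function at the last event time at or before
60 months — time is in months throughout, and 5 years is exactly 60 months.
Confidence intervals use the complementary log-log transform
$\theta = \log(-\log S)$ with $\mathrm{se}(\theta) = \sqrt{\mathrm{Var}}/|S
\log S|$, clipped to $[0,1]$; it respects the unit interval without ad hoc
truncation of a linear interval. Degenerate inputs (no events before $t$,
zero variance) return a point-mass interval.

The two-group log-rank statistic sums observed-minus-expected events with
hypergeometric variance over distinct event times; p-values are two-sided
from $\chi^2_1$ with no continuity correction. With no events, or zero
variance, the statistic is 0 and p = 1. Single-event-time terms with
$n_i = 1$ contribute zero variance.

Rank comparisons (Wilcoxon, Kruskal–Wallis) and BH adjustment delegate to
base R's `wilcox.test`, `kruskal.test` and `p.adjust` — standard
implementations are called, not re-derived; the test suite still pins their
behavior to definitional oracles (exact enumeration for a small two-group
comparison, the min-over-k formula for BH).

# Immune enrichment score

The per-sample score is an ssGSEA-style running sum: genes are ranked by
expression within the sample (average ranks for ties) and walked in
decreasing order; the score sums the difference between the weighted in-set
ECDF (weights $r^\alpha$, $\alpha = 0.25$, the conventional exponent) and
the unweighted out-of-set ECDF. Properties that the tests assert: the score
is invariant to any strictly increasing per-sample transform of expression
(it is rank-based), raising only in-set genes strictly increases the score,
and with $\alpha = 0$ it reduces to an unweighted two-sample rank
comparison. Ties in expression are ordered by gene symbol, so the score
cannot depend on the row order of the input matrix. Scoring requires at
least 2 set genes in the matrix and refuses a set that covers the whole
matrix (no background).

The absolute scale of such scores depends on normalization details and is
comparable only within a cohort; the 60th-percentile grouping
(`immune_groups`) uses ranks only, which is all the downstream analyses
need. No stromal score or tumor-purity transform is computed — only the
immune component feeds the analyses here.

# The synthetic cohort generator

The generator emulates the structure of an early-breast-cancer RNA-seq
cohort so the whole pipeline can be exercised and validated offline. Its
defaults are the study conditions; they were fixed once and are not tuned:

* 300 samples; IHC subtype mix 22.6 / 14.1 / 12.1 / 51.2 %
  (HR+HER2− / HR+HER2+ / HR−HER2+ / TNBC), with intrinsic subtypes drawn
  conditionally on IHC subtype (e.g. TNBC is mostly basal-like).
* True burden per sample is negative binomial with per-subtype means
  7 / 10 / 10 / 9 and dispersion 2.5, echoing reported per-subtype medians;
  a shared recurrent pool of pairs (drawn with probability 0.3) creates
  recurrent and known fusions, the rest are private.
* The gene universe (400 symbols with chromosome, strand and position)
  over-weights chromosomes 17, 1, 11 and 8, mimicking the skewed placement
  of real fusion landscapes. Its last 40 genes are reserved for artifacts
  and blacklists and never host true fusions.
* Caller sensitivities A 0.90, B 0.85, C 0.75 (the Arriba-like dialect
  detects most, the STAR-SEQR-like least). Three artifact classes per
  sample: read-throughs (Poisson mean 2; 70% carry the caller's flag, the
  rest rely on the coordinate heuristic), blacklist hits (mean 1.5) and
  low-support calls (mean 2). A 5% fraction of true fusions is planted
  below the support filter so that filter tests are non-degenerate.
* EFS is exponential with baseline hazard $-\log(0.8)/60$ per month (an
  80% five-year rate in the low-burden arm) and hazard ratio 3 for samples
  above the 0.6 burden quantile; censoring is uniform with its range solved
  numerically so the expected censored fraction is 20%.
* Expression is log-normal TPM-like (per-gene log-mean drawn once, log-sd
  0.6) over 1000 genes; the 50-gene immune set is shifted down by 1 log
  unit in high-burden samples.

Design guarantees, relied on by the tests: blacklist genes never collide
with true fusions, non-low-support true calls always satisfy the default
support thresholds, and true pairs are rejected if they would look like
read-throughs (same chromosome, same strand, within 1.2× the heuristic
gap). Consequently, with sensitivity 1 and artifact rates 0 the pipeline
recovers the planted per-sample burden exactly — a lossless regime that
pins the whole cascade. All randomness flows through seeds derived from the
single configured seed, the caller's RNG state is saved and restored, and
identical configurations produce byte-identical file bundles.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level evidence (no FASTQ/BAM), caller
breakpoint disagreement beyond positional jitter, caller-specific artifact
spectra, gene-length and expression-dependent detection bias, correlated
subtype/burden/immune structure beyond the planted monotone effects, and
non-proportional hazards or informative censoring.

# Problem sizes and test design

The suite favors exhaustive small problems over large simulations: oracle
equivalence for the cascade runs 500 random instances of up to 40 calls;
the survival core is checked against closed forms, the `survival` package,
and a 20,000-draw permutation null on 60 subjects; scan recovery and
calibration use 50 and 100 seeded replicates of 300-sample cohorts; immune
recovery uses 50 replicates of 120-sample expression matrices. These sizes
were chosen to make Monte-Carlo error small relative to the properties
asserted while keeping the suite fast to iterate on.

# Known limitations

* Known-fusion annotation is exact symbol matching; no alias tables, no
  breakpoint-level matching.
* The scan's coverage criterion inherits the overlapping-panel caveat above;
  treat the selected quantile as descriptive, not inferential.
* No Cox modelling or multivariable adjustment: the package tests marginal
  burden–EFS association only, by design.
* The ssGSEA score is cohort-relative; scores from different cohorts or
  normalizations are not comparable.
* Breakpoint coordinates are carried through but never used for matching;
  analyses needing junction-level resolution are out of scope.
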