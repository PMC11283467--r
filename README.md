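# fusionburden

Tools for studying the prognostic value of gene fusions (chimeric
transcripts) called from bulk RNA-seq in breast cancer cohorts. The package
is aimed at translational genomics analysts who have per-sample output
tables from several fusion callers plus a clinical table with event-free
survival (EFS), and who want to go from raw multi-caller calls to a
cohort-level answer: *does a patient's fusion burden stratify survival, and
how does it relate to the immune microenvironment?*

The real cohorts this kind of analysis targets are controlled-access, so the
package also ships a fully seeded synthetic-cohort generator that emulates
the whole data bundle (caller files, clinical table, expression matrix,
truth file). Every stage of the pipeline is testable offline against planted
ground truth.

## What the pipeline does

1. **Harmonize caller output** (`read_caller_table`): three TSV dialects
   modeled on Arriba-, STAR-Fusion- and STAR-SEQR-style layouts are parsed
   into one canonical call table (ordered 5'→3' gene pair, `chr`-prefixed
   1-based breakpoints, split/discordant read counts, read-through flag).
2. **Filter cascade + consensus** (`filter_cascade`): calls with fewer than
   3 supporting reads or no split reads are removed, read-through
   transcripts are dropped (caller flag, or same-chromosome same-strand
   pairs within 50 kb as a fallback), blacklisted gene pairs/genes from
   healthy-tissue and homology lists are removed, and only gene pairs
   predicted by ≥ 2 of the 3 callers within a sample are kept. Consensus
   matches at the gene-pair level (callers disagree on exact breakpoints);
   read support is the per-field maximum across callers.
3. **Cohort catalog** (`build_catalog`, `classification_table`,
   `chromosome_table`): unique fusions are classified private (1 carrying
   sample) vs recurrent (≥ 2), and unknown vs known (exact ordered-pair
   match against curated databases such as Mitelman/COSMIC-style lists).
   The per-chromosome table counts every fusion twice — once for each
   partner gene's chromosome — so an intrachromosomal fusion adds 2 to its
   chromosome's intra count and an interchromosomal one adds 1 to each
   partner.
4. **Burden and survival** (`per_sample_burden`, `scan_cutoffs`,
   `km_estimate`, `logrank_test`): fusion burden is the number of distinct
   gene-pair events per sample. The burden cutoff is chosen by scanning
   quantiles 0.1–0.9: at each quantile the full cohort is dichotomized
   (strictly-greater-than rule, so ties go to the low group) and a log-rank
   test is run within every subgroup panel (all patients, IHC subtypes,
   intrinsic subtypes); the quantile significant in the most panels wins.
   Five-year EFS rates come with complementary log-log confidence
   intervals.
5. **Immune enrichment** (`ssgsea_score`, `immune_groups`): a rank-based
   single-sample enrichment score of a user-supplied immune gene set
   (ssGSEA-style running sum, exponent α = 0.25), dichotomized at the 60th
   percentile.

### The statistics, briefly

Kaplan–Meier: $\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$ with Greenwood
variance $\widehat{\mathrm{Var}}[\hat S(t)] = \hat S(t)^2 \sum_{t_i \le t}
d_i / (n_i(n_i - d_i))$; confidence intervals on the
$\log(-\log \hat S)$ scale. Two-group log-rank: $\chi^2 = (O_1 - E_1)^2/V$
with $E_1 = \sum_i d_i n_{1i}/n_i$ and hypergeometric variance $V = \sum_i
d_i (n_{1i}/n_i)(1 - n_{1i}/n_i)(n_i - d_i)/(n_i - 1)$, p from
$\chi^2_1$. Rank comparisons use Wilcoxon/Kruskal–Wallis; multiple panels
are adjusted by Benjamini–Hochberg FDR. The ssGSEA score walks the genes of
a sample in decreasing expression order and accumulates the difference
between the weighted in-set ECDF (weights $r^\alpha$ of the expression
ranks) and the unweighted out-of-set ECDF.

## Worked example

```r
library(fusionburden)

cfg    <- cohort_config(n_samples = 60, seed = 42)
bundle <- generate_cohort(cfg)
cons   <- filter_cascade(bundle$calls, filter_config(), bundle$blacklists)
burden <- per_sample_burden(cons, bundle$clinical$sample_id)
median(burden)
#> [1] 8

print(classification_table(build_catalog(cons, list(bundle$known_db))))
#> Unique fusions by occurrence and annotation
#>            Unknown          Known            Sum
#> private    440 (93.4%)      1 (0.2%)         441 (93.6%)
#> recurrent  11 (2.3%)        19 (4.0%)        30 (6.4%)
#> Sum        451 (95.8%)      20 (4.2%)        471 (100.0%)

dq <- dichotomize_quantile(burden, 0.6)   # high = strictly above threshold
#> high-burden group: > 10 fusions, 23 of 60 samples

times  <- setNames(bundle$clinical$efs_months, bundle$clinical$sample_id)
events <- setNames(bundle$clinical$efs_event, bundle$clinical$sample_id)
logrank_test(times, events, dq$groups[names(times)])
#> log-rank high vs low: chi-square 15.58, p = 0.0001

survival_at(km_estimate(times[dq$groups == "high"],
                        events[dq$groups == "high"]), 60)
#> 5Y-EFS: high 47.8% (26.8-66.1); low arm: 70.7% (52.4-83.0)
```

The high-burden arm's worse five-year EFS is the planted effect of the
generator (hazard ratio 3 on an 80% five-year baseline) recovered by the
pipeline.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on a synthetic cohort
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # cohort bundle -> results/cohort/
Rscript analysis/02_filter_consensus.R  # cascade + consensus + burden
Rscript analysis/03_annotate_catalog.R  # catalog, 2x2 table, chromosomes
Rscript analysis/04_burden_survival.R   # cutoff scan, KM, log-rank
Rscript analysis/05_immune.R            # immune scores vs burden and EFS
```

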