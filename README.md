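# irsplit

Exon–intron split quantification of intron retention (IR) in two-group
bulk RNA-seq cohorts, with a six-set differential IR/expression
classification under FDR control.

## What it is for

Retained introns leave reads on intronic positions of annotated
transcripts.  `irsplit` is for analysts who want to measure that signal
cohort-wide — typically a disease group against a small control group
(the defaults emulate a 97 chronic-lymphocytic-leukemia vs 9
normal-B-cell design) — without committing to a full isoform
reconstruction pipeline.  It decomposes each multi-exon transcript into
exonic and intronic regions, quantifies both as TPM, and summarises
retention per transcript and sample as the pseudocounted intron/exon
ratio

    R = (TPM_intron + eps) / (TPM_exon + eps),      eps = 0.01 TPM

compared between groups as `log2( median R_group1 / median R_group2 )`.

Differential structure is found with two one-sided Wilcoxon rank-sum
screens on intronic TPM (group1 > group2 and the reverse), each
Benjamini–Hochberg adjusted at 5%: rejections form **set-I** (more
intron usage in the disease group) and **set-II** (more in controls).
Within each set, transcript-level expression screens split members into
**A** (over-expressed in the set's group), **B** (under-expressed) and
**C** (non-differential, two-sided raw p > 0.05).  The IR–expression
association is then tested on the 2×3 contingency table (Pearson
chi-square) and the 2×2 {A, B} subtable (sample odds ratio `ad/bc`,
Fisher exact p).  Downstream products: top-N ranked transcript lists,
per-row Z-score heatmap matrices with control → low-risk → high-risk
column blocks, volcano and quadrant tables, and a local hypergeometric
over-representation test against GMT gene-set collections with
Bonferroni correction.

A synthetic-cohort generator with planted ground truth
(`generate_cohort()`) makes every stage testable end-to-end without any
external or controlled-access data.

## Worked example

```r
library(irsplit)

co  <- generate_cohort(cohort_config(n_transcripts = 2000), seed = 7)
co
#> <ir_cohort> 2000 transcripts x 106 samples (97 CLL), mode = tpm, seed = 7
#> planted: none 1500, set-I 300, set-II 200

run <- run_ir_pipeline(co$exonic, co$intronic, co$transcript, co$metadata,
                       group1 = "CLL")
glance(run)
#> # A tibble: 1 x 5
#>   n_screened n_set1 n_set2 odds_ratio   chi2_p
#>        <int>  <int>  <int>      <dbl>    <dbl>
#> 1       2000    300    349      0.988 8.98e-12

run$contingency
#> <ir_contingency>
#> 2 x 3 table (IR set x expression subset):
#>         expr_subset
#> ir_set     A  B   C
#>   set-I  150 61  86
#>   set-II 102 41 191
#> chi-square = 50.87 (df = 2), p = 8.98e-12
#> 2 x 2 {A,B}: odds ratio = 0.9884, Fisher p = 1

head(run$top, 3)
#> # A tibble: 3 x 4
#>   transcript_id           p log2_ratio  rank
#> 1 TX00190       0.000000387       2.77     1
#> 2 TX00285       0.000000387       2.16     2
#> 3 TX00169       0.000000387       1.98     3
```

Reading this: all 300 planted set-I transcripts are recovered
(`n_set1 = 300`); `n_set2` exceeds the 200 planted set-II because strong
one-sided signal plus TPM's compositional normalisation depresses other
transcripts' intronic TPM in the boosted group — see the methods
vignette.  The chi-square p shows the planted IR–expression association;
the odds ratio near 1 reflects the symmetric A/B planting of this
simulation.  The top-ranked list is tie-broken by `|log2_ratio|`, hence
equal p's in a deterministic order.  `run$heatmap_intron`,
`run$volcano`, `plot_volcano()`, `plot_ir_heatmap()` and
`autoplot(run$ir)` provide the display tables and figures.

Real annotations enter through `read_transcript_models("anno.gtf")` →
`filter_intronless()` → `count_reads(features, bams)` →
`compute_tpm()`; precomputed matrices through `ingest_matrix()`.

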