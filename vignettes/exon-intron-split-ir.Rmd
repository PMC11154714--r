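---
title: "Exon-intron split analysis of intron retention: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-intron split analysis of intron retention: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irsplit)
library(dplyr)
```

## The problem and the statistic

Intron retention (IR) is a splicing outcome in which an intron survives
into the mature transcript.  In bulk RNA-seq it leaves a simple footprint:
reads covering intronic positions of an annotated transcript.  irsplit
quantifies that footprint with an exon–intron split: every multi-exon
transcript is decomposed into its exonic regions, its intronic regions
(the gaps between consecutive merged exons), and the whole-locus span.
After length-normalised abundance estimation (TPM), the per-transcript,
per-sample IR statistic is the pseudocounted ratio

$$R = \frac{\mathrm{TPM}_{\text{intron}} + \varepsilon}
           {\mathrm{TPM}_{\text{exon}} + \varepsilon},$$

a surrogate for alternative splicing activity that is insensitive to
overall transcript abundance: doubling expression doubles both the
intronic and exonic signal and leaves $R$ unchanged.  Between two groups
(here labelled CLL-like and NBC-like after the leukemia-versus-normal-B-cell
design the defaults emulate), each group's $R$ values are summarised by
the median — TPM is heavily right-tailed, and a mean would let a few
extreme samples dominate — and compared as
$\log_2(\tilde R_{g1} / \tilde R_{g2})$, which is antisymmetric under
swapping the groups.

## Coordinates and annotation

All internal coordinates are 1-based and inclusive at both ends, the
convention of genome-browser text; an interval's length is
$end - start + 1$.  BED export converts to 0-based half-open and the
conversion round-trips exactly.  Overlapping or book-ended exon records
within one transcript are unioned before introns are derived, which
guarantees no negative-length introns; single-exon transcripts carry no
IR information and are removed before quantification.

Whether intronic regions should exclude positions covered by exons of
*other, overlapping* transcripts is a genuinely open design point: some
IR tools mask, some do not.  irsplit derives introns per transcript
without masking by default — the quantity of interest is that
transcript's own unspliced signal — and offers `mask_exons = TRUE` in
`transcript_models()` for the stricter variant.

## Counting and TPM

`count_reads()` counts union-style: a read increments every feature it
overlaps by at least `min_overlap` bases (default 1 bp), so a read
straddling an exon–intron junction counts toward both — junction-spanning
reads are precisely the evidence IR detection relies on.  Reads with
mapping quality below 1 are skipped, which discards typical multi-mapped
reads; no multi-mapping rescue is attempted.  Counting is unstranded by
default because library strandedness cannot be assumed, with `fr`/`rf`
modes available.

TPM for feature $f$ is
$\mathrm{TPM}_f = 10^6 (r_f/L_f) / \sum_g (r_g/L_g)$.  The normalisation
universe is the feature class: exonic TPMs sum to $10^6$ over exonic
features, intronic over intronic, transcript over transcripts.  Each
class answers a different question ("what fraction of the intronic signal
is here?"), and mixing them would let the far larger exonic mass drown
the intronic scale.  A shared-universe mode exists for sensitivity
analysis.  A consequence worth knowing: TPM is compositional, so a strong
planted (or real) IR shift concentrated in one group slightly depresses
every *other* transcript's intronic TPM in that group, and with very
unbalanced, low-noise designs the screens can pick that artifact up.  The
synthetic-cohort tests therefore evaluate recovery on the transcripts
with planted effects.

The pseudocount default $\varepsilon = 0.01$ TPM keeps $R$ finite and
positive when the exonic TPM of a filtered-in transcript is still zero in
some sample; transcripts with zero exonic TPM in more than 40% of samples
are additionally flagged, since their ratios are pseudocount-dominated.

## Screens, sets, and FDR

Transcripts enter the analysis only if their transcript-level TPM is
positive in at least 60% of samples of *each* group (inclusive bound) —
an expressed-in-the-majority filter applied before any testing.

The differential machinery is two one-sided Wilcoxon rank-sum screens on
the intronic TPM (group1 > group2, and the reverse), each adjusted by
Benjamini–Hochberg across all filtered transcripts at the 5% level.
The rank-sum (Mann–Whitney) form is the only applicable reading of a
"one-sided Wilcoxon" here: the groups are unpaired and of unequal size
(97 vs 9 by default).  The cohort screens use the normal approximation
with mid-rank tie correction and continuity correction — the same
formulas `stats::wilcox.test(exact = FALSE, correct = TRUE)` applies, and
the vectorized implementation is tested for exact agreement with it.  The
scalar `rank_test_one_sided()` switches to the exact distribution for
$n_1+n_2 \le 12$ without ties, and is property-tested against full
permutation enumeration for every design with $n_1+n_2 \le 10$.

Rejection of a directional intronic screen places a transcript in set-I
(more intron usage in group 1) or set-II (more in group 2); the two
screens cannot both reject at any usable level, so the sets are disjoint
(double rejections, impossible in practice, would be left unclassified).
Within a set, transcript-level expression screens assign subsets relative
to the set's own group: A (over-expressed, directional screen rejects
under BH), B (under-expressed), C (non-differential, two-sided raw
$p > 0.05$).  The C rule is deliberately asymmetric — raw-p, not
FDR-adjusted — mirroring how non-differential backgrounds are typically
declared; transcripts fitting no rule are reported as `unassigned`
rather than silently forced into C.  Whether the A/B expression screens
should be BH-adjusted or raw-thresholded is ambiguous in common
shorthand ("p < 0.05; FDR = 5%"); BH is the default and
`expr_adjust = "raw"` the alternative.

The association between IR direction and expression direction is tested
on the 2×3 contingency table {set-I, set-II} × {A, B, C} with Pearson's
chi-square (no continuity correction), and on the 2×2 {A, B} subtable
with the sample odds ratio $ad/bc$ (Haldane–Anscombe +0.5 on a zero
cell, flagged) plus Fisher's exact p.  Reported percentages are rounded
half-up: from counts 10,436 / 188 / 1,345 of a set of 11,969 this yields
87% / 2% / 11%.

## Ranking, heatmaps, volcano

`select_top_n()` ranks a set's members by the p-value of that set's own
directional intronic screen, breaking ties by larger
$|\log_2\text{-ratio}|$ and then transcript id, so rankings are fully
deterministic.  The default source is set-I with `n = 200`; subset
sources such as `"set-IA"` are accepted, since both conventions exist for
"top transcripts".  Heatmap matrices are per-row Z scores (sample
standard deviation, $n-1$; constant rows become zero) with columns in
fixed blocks: controls first, then the low-risk, then the high-risk
disease subgroup — ordering by prognosis block rather than clustering.

The volcano table carries both y-axis readings that appear in practice:
$-\log_{10} p$ of the two-sided intronic comparison (the plotted axis)
and the $\log_{10}$ expression fold change (used for quadrant
interpretation, e.g. upper-right = more IR and more expression in
group 1).  The "regression line" of the group-versus-group IR scatter is
the identity line $y = x$ — the locus of equal retention — and
`quadrant_counts()` counts transcripts strictly above, on, and below it.

## Over-representation analysis

`ora_test()` is a local, network-free over-representation test: the
one-sided hypergeometric tail $P(X \ge k)$ per gene set, Bonferroni
corrected over the sets actually tested.  The background universe
defaults, in the pipeline, to the genes of all transcripts surviving the
expression filter — the population the query was actually drawn from —
not the whole annotation; any universe can be supplied.  Gene sets come
from GMT files; the query is the top fraction (default 25%) of the
ranked set-I list, mapped to unique gene symbols.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture: it is
the only way to exercise the full pipeline without controlled-access
patient data.  Its defaults *are* the emulated study conditions: 97
disease samples (41 high-risk, 56 low-risk) vs 9 controls.  Baseline
transcript abundance is log-normal (meanlog 3, sdlog 1.5), reproducing
TPM's heavy right tail; the baseline intron/exon abundance ratio is
log-normal with median 0.1 (sdlog 0.5), a realistic pre-mRNA fraction;
per-cell noise is multiplicative log-normal with $\sigma = 0.5$.  Planted
fractions default to 15% set-I and 10% set-II with A/B/C proportions
0.5/0.2/0.3 — chosen once so that every one of the six labels has enough
members to measure recovery on.  Effects are multiplicative, matching the
ratio statistic: `delta_ir` (default 4) scales intronic abundance in the
set's group, `delta_expr` (default 3) scales transcript-level abundance
in the set's group.  The expression effect deliberately does **not**
touch the intronic matrix: the directional IR screens test intronic
abundance itself, and coupling the two would make an under-expressed
(B) transcript's intron boost partially self-cancelling —
the planted labels would no longer mean what they claim.

In `mode = "counts"` the same abundances become negative-binomial read
counts (dispersion 0.3) with log-normal feature lengths, for exercising
the TPM conversion path.  Everything is drawn in a fixed order from a
single seed, so output is bitwise reproducible.

What the generator does *not* model: genuine read-level sampling,
isoform ambiguity and multi-mapping, GC/length bias, batch structure,
and correlated transcripts.  Passing tests on this cohort therefore
demonstrate the statistical machinery under the declared model, not
end-to-end fidelity to any real cohort.

## Calibration and recovery

Two simulation-based properties anchor the test suite, at sizes chosen
to characterise the exact study geometry:

* **Null calibration** — on 200 complete-null cohorts (97 vs 9, 2,000
  transcripts, $\sigma = 0.5$, nothing planted) the mean false-discovery
  proportion of combined set-I/set-II calls under BH at 5% stays below
  the nominal level plus Monte-Carlo tolerance.  Under a complete null
  every call is false, so the mean FDP is the fraction of cohorts with
  any call; it comes out well *below* 5% (typically 0.5–3%) because the
  continuity-corrected normal approximation is conservative in the far
  tail where BH's smallest thresholds live.
* **Parameter recovery** — with `delta_ir = 4`, `delta_expr = 3`,
  $\sigma = 0.5$ on a 2,000-transcript cohort, the classifier recovers
  over 90% of planted six-set labels (observed ≈ 98–99%); recovery of
  planted set-I is non-decreasing in `delta_ir` across a 1.5/2.5/4 grid
  with paired seeds.

## Numerical and degenerate-input rules

* Constant rows: Z score 0; rank screens return $p = 1$ in every
  direction, flagged degenerate.
* All-zero samples: TPM columns stay zero rather than dividing by zero.
* Empty feature sets, empty query lists, empty source sets: explicit
  warnings and typed empty results, never silent NA propagation.
* Percentages intended for reporting are rounded half away from zero
  (`round_half_up()`), not banker's-rounded.
* One-sided p-value pairs satisfy $p_{>} + p_{<} \ge 1$ (they overlap at
  the observed statistic), and BH rejections are always a subset of
  $\{p \le \alpha\}$.

## Known limitations

The upstream alignment and any multi-mapping correction are out of
scope: counting starts from given BAMs (or matrices) and discards
low-MAPQ reads instead of rescuing them.  No isoform deconvolution is
attempted — ambiguous reads count toward every overlapped feature.  No
covariate adjustment, batch correction or mixed models are offered, and
heatmaps are block-ordered, never clustered.  The compositional caveat
of TPM under strong asymmetric signal, noted above, applies to any
TPM-based screen and is the main reason simulator-based claims are
phrased in terms of planted-label recovery.
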