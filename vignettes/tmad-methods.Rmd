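---
title: "Methods: t-MAD ctDNA scoring, trial statistics and the synthetic cohort"
author: "tmadtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: t-MAD ctDNA scoring, trial statistics and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmadtools)
```

## The problem

Shallow whole-genome sequencing (sWGS, < 1x coverage) of plasma cell-free
DNA reveals somatic copy-number aberrations (SCNAs) when enough of the
circulating DNA derives from a tumour. The **t-MAD** score summarises a
genome-wide copy-number profile into a single number that tracks the ctDNA
tumour fraction: reads are counted in fixed 30 kb bins, corrected for GC
and mappability bias, normalised against a healthy control, log2
transformed, segmented, and the **median absolute deviation from
log2R = 0** is taken over bins surviving two blacklists. Alongside the
copy-number pipeline, the package recomputes a phase-II trial's clinical
statistics from its published count tables and implements a PCA-based
procedure for assessing an overexpressed-gene signature.

Everything is exercisable on a bundled synthetic-data generator, so the
whole pipeline is testable on a desk with no external downloads.

## The dilution model

A tumour fraction $f \in [0,1]$ dilutes integer tumour copy numbers
$\mathrm{CN}_i$ (base ploidy 2) into the expected relative depth of bin $i$:

$$d_i = \frac{2(1-f) + f\,\mathrm{CN}_i}{2},$$

multiplied by a bin-specific technical bias $b_i$ (a unimodal quadratic
GC response on the log scale and a monotone power of mappability). After
perfect correction and control normalisation, the log2 ratio of an
aberrant segment is $\log_2 d_i$ — e.g. $\log_2 1.5 \approx 0.585$ for
CN 4 at $f = 0.5$. The generator simulates negative-binomial counts around
these expectations (dispersion 0.05 by default; sWGS bin counts are
overdispersed relative to Poisson, which is also available).

## Pipeline stages and the parameters that matter

1. **Downsampling** (`downsample_counts`) — exact multivariate
   hypergeometric thinning to a target total (sequential `rhyper`), so
   totals are hit exactly and no bin ever gains reads. Mirrors the
   practice of downsampling all samples to a common depth (10M reads in
   production settings) for comparability.
2. **Bias correction** (`correct_gc_mappability`) — a robust 2D LOESS
   (span 0.3, degree 2, symmetric family) of counts over
   (GC, mappability); corrected = raw / fitted, rescaled to preserve the
   mean. A stratified-median surface (GC deciles x binary mappability) is
   the fallback and an explicit option. The span/degree are conventional
   smoother settings; nothing in the procedure is sensitive to them at the
   simulated smoothness.
3. **Static blacklist** (`apply_static_blacklist`) — bins flagged in the
   grid (the public exclusion-list analogue) are masked. Masks only grow
   along the chain; no stage unmasks a bin.
4. **Control normalisation and log2 ratio** (`median_normalise_control`,
   `log2_ratio`) — the control is scaled to unit median; ratios are
   re-centred so the median log2 ratio is 0. Re-centring is needed because
   the genome-wide depth scale is unidentifiable; it assumes copy-neutral
   bins dominate (or at least straddle) the genome, which holds for the
   profiles simulated here. Zero-count and zero-control bins are masked
   rather than pseudocounted — a pseudocount would manufacture extreme
   ratios in empty bins and inflate the score; `pseudocount` is available
   for comparability studies. Two reference modes exist: a single healthy
   control (default, `prepare_control`) and a median-of-panel reference
   (`prepare_panel_reference`), which shrinks reference sampling noise by
   roughly $\sqrt{n_\text{controls}}$ and is what the cohort-level
   analyses below use.
5. **Segmentation** (`cbs_segment`, `hmm_segment`) — two independent
   segmenters, per chromosome:
   * *Circular binary segmentation*: recursive splitting on the maximal
     circular two-sample t statistic, accepted when the within-segment
     permutation p-value is below `alpha` (default 0.01, 1000
     permutations with early stopping once significance is impossible);
     segments narrower than `min_width = 3` are merged into the
     mean-nearer neighbour.
   * *Gaussian HMM*: shared-variance Gaussian emissions, 5 states
     (covering loss / neutral / gain levels), EM with quantile
     initialisation and 3 jittered restarts, Viterbi decoding. The M step
     adds a Dirichlet pseudo-count (20) to self-transitions: without this
     sticky prior a flat profile decodes into hundreds of micro-segments
     of pure noise and the healthy-sample score floor triples. Segment
     means are always the empirical means of member bins, not state
     means.
6. **Averaging** (`average_segmentations`) — the per-bin arithmetic mean
   of the two segmental values; a bin masked in either input stays
   masked. Geometric or weighted averages have no support in the
   procedure being mirrored and were rejected.
7. **Empirical blacklist** (`build_empirical_blacklist`) — per healthy
   control, a 2D LOESS of median-normalised counts over
   (GC, mappability); per bin, the median residual across controls; bins
   with |median residual| beyond `n_sd` (default 4) standard deviations
   are flagged, two-sided (systematically depleted bins are as
   untrustworthy as inflated ones). The SD is estimated robustly
   (1.4826 x MAD) by default: the aberrant bins being hunted would
   otherwise inflate their own threshold — with a plain SD and 5% of bins
   at a 3x distortion, recall drops from ~100% to ~60%. `sd_method =
   "sd"` restores the plain estimator; a pooled-median fit mode is also
   provided.
8. **t-MAD** (`tmad`) — the median of |averaged segmental log2R| over
   non-masked, non-blacklisted bins. The deviation is from 0, not from
   the sample median; with a copy-neutral genome the score is exactly 0.

Because t-MAD is a median, it responds to tumour fraction only when
aberrant bins form a substantial share of the genome; with the simulated
high-burden profiles (~50–70% aberrant, see below) the score is an
approximately monotone function of $f$ down to $f \approx 0.05$, with a
healthy-replicate floor set by segment-mean sampling noise
($\sigma_{\text{bin}}/\sqrt{L}$ per segment of $L$ bins).

## The synthetic cohort: what it emulates, and what it does not

`make_bin_grid` draws an autocorrelated GC track (AR(1) squashed into
[0.3, 0.6]), mappability near 1 with a low tail, and a static-blacklist
flag per bin. Desk-scale grids are 600–2000 bins over 2–8 chromosomes;
the production-scale 30 kb genome-wide grid is the same code at larger
`n_bins`.

`random_cna_profile` tiles each genome with `n_segments` aberrant
segments (CN drawn from {0, 1, 3, 4}) totalling a uniformly drawn 50–70%
of bins — the extensive SCNA burden typical of heavily pre-treated
metastatic ER+ breast cancer, and the regime in which a median-based
score is informative. `simulate_cohort` gives every subject one profile
shared across timepoints and a group-specific tumour-fraction trajectory,
by default PD = (0.10, 0.15, 0.20), SD = (0.08, 0.08, 0.08),
PR = (0.10, 0.04, 0.02) at (baseline, wk4, wk6) — rising disease,
stasis, and response, reproducing the qualitative on-treatment ordering
PR < SD < PD. Default group sizes (5 PR / 6 SD / 6 PD subjects) are a
desk-scale reduction of a ~44-sample trial timepoint.

`simulate_expression` emulates a targeted expression panel: log-normal
baseline means, negative-binomial counts (dispersion 0.1), six designated
signature genes shifted up by log2FC = 2 in the benefit (non-PD) group,
and 20 secondary differential genes at |log2FC| = 0.6 split between
directions. The dispersion and secondary effect size were fixed once so
that the planted primary effects are recoverable at the panel's group
sizes (12 vs 6) under the rank-based test below; they represent a tight
panel, not patient-to-patient biological variability at large.

What the generator does **not** emulate: read-level artefacts (it works
on binned counts), fragment-length structure, subclonal or allele-specific
copy number, replication-timing waves, batch effects between cohorts, and
the count-model mean-variance structure a dedicated RNA-seq DE model
would exploit. Passing tests therefore demonstrate the pipeline's
internal correctness and sensitivity under the stated noise model — not
clinical performance on real plasma.

## Clinical statistics

The packaged tables mirror a 52-patient phase-II trial's published
counts: response categories at weeks 6/12/20/28 (columns sum to 52),
per-eye retinal pigment epithelial detachment (RPED) records for the 11
affected subjects, and the RPED x clinical-benefit margins (13 benefit /
32 no-benefit / 3 unassessable). From these the package recomputes:

* **Exact (Clopper–Pearson) binomial intervals** via beta quantiles, the
  method identified by matching all five printed intervals to the
  printed decimals (Wilson gives 15.9% where 14.6% is printed for
  13/50).
* **Response rates**: ORR = CR + PR over enrolled; week-12
  CBR = CR + PR + SD over enrolled (21/52 = 40.4%); week-28 CBR = PR at
  any time + SD at week 28 over assessable (13/50 = 26%), plus the
  intention-to-treat version (13/52). The week-12/week-28 denominators
  (enrolled vs assessable) are inferred from the printed rates.
* **RPED association**: Pearson chi-square on the 2x2 margins without
  continuity correction (p = 0.55; Fisher's exact, available behind a
  flag, gives 0.70 and is not what was printed).
* **RPED event summaries**: per-subject reduction first — the
  earliest-onset eye supplies that subject's onset and duration — then
  medians and ranges. Per-eye pooling fails to reproduce the printed
  duration median (0.8 instead of 0.7), which pins down the rule.

## Response-group comparisons

`wilcoxon_rank_sum` is self-contained: exact mode enumerates all
$\binom{n_x+n_y}{n_x}$ assignments on midranks (so ties are handled);
normal mode applies tie and continuity corrections. `auto` uses exact
enumeration up to 12 total observations without ties. Tests are two-sided
throughout, per-sample at each timepoint, with no multiplicity
adjustment — matching how such trial analyses report raw pairwise
p-values. Boxplot summaries fix the percentile definition (linear
interpolation, R type 7) so figures are exactly reproducible.

## The expression-signature procedure

The differential statistic is a deliberate stand-in: the original
analysis combined two count-model DE algorithms, which are not part of
this package's scope; here each gene gets a two-sided rank-sum test on
median-normalised values with Benjamini–Hochberg adjustment, and a gene
is differential at p < 0.05 and FDR < 0.1. Two numerical consequences
drove design choices:

* At 12 vs 6 samples the *normal-approximation* p-value floors at
  ~9e-4, which cannot pass FDR < 0.1 among hundreds of genes; candidate
  genes (approximate p < 0.1) are therefore re-tested **exactly** — via
  the closed-form rank-sum null when untied, or full midrank enumeration
  otherwise — bringing the floor to $2/\binom{18}{6} \approx 1.1 \times
  10^{-4}$.
* The discrete exact p-values tie heavily at that floor, so ranking the
  significant genes "by q" is nearly uninformative. **Top-k
  overexpressed** therefore ranks significant up-regulated genes by log2
  fold change (q breaking ties); which ranking key "top overexpressed"
  refers to was genuinely open, and fold change is both the natural
  reading and the stable one.

`pca_separation` centres and unit-scales genes, projects samples onto the
top two principal axes (sign fixed by forcing each component's
largest-absolute loading positive), and scores PD vs benefit separation
as the mean silhouette width in that plane — a bounded, label-aware
quantity standing in for the visual "tight clustering" judgement.
`signature_comparison` reports the score for all genes, all DEGs, and the
top-k over-/under-expressed subsets.

## Numerical choices and degenerate inputs

* Fitted bias surfaces are floored at a small positive value; degenerate
  GC distributions fall back to mappability-only correction, and LOESS
  failure to the stratified-median surface (both with warnings).
* EM variance is floored at 1e-4; non-convergence returns the best
  iterate with a warning.
* CBS permutation p-values use the (1 + exceedances)/(1 + permutations)
  estimator; permutation loops stop early only when the split can no
  longer be significant, which never changes the accept/reject decision.
* All-masked chromosomes segment to nothing (with a message); fewer than
  50 usable bins abort the ratio stage; fewer than 30 retained bins abort
  t-MAD — each error names the offending count.
* Every generator is a pure function of (configuration, seed).

## Problem sizes used by the test suite and acceptance script

Chosen as the package's own desk-scale study conditions: fraction
tracking uses a 2000-bin / 5-chromosome grid, a 20-control panel at 3e5
reads, one fixed disease profile, and 5 fraction levels x 10 replicates;
the response-pattern analysis uses a 1200-bin / 4-chromosome grid and 100
seeded 17-subject cohorts scored at wk6 with CBS n_perm = 150 and one HMM
restart (the lighter segmentation settings change scores negligibly
relative to group separation); blacklist recovery uses five 600-bin
panels with 5% planted artifacts at 3x; breakpoint localisation uses 50
planted 400-bin step profiles; the expression checks use 100 seeds of the
500-gene fixture.

## Known limitations

* t-MAD is reported as a score, not converted to an absolute tumour
  fraction (that calibration requires external spike-in/dilution data).
* The median-based score is insensitive to focal aberrations in
  low-burden genomes; this is a property of the statistic, faithfully
  reproduced.
* The DE stand-in has less power than count-model DE methods; the planted
  fixtures are calibrated to the stand-in, and the specific published
  gene lists are out of scope (they require the original expression
  data).
* Kaplan–Meier survival, pharmacokinetics, serum markers and network
  enrichment analyses are out of scope.
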