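---
title: "Profiling nucleosome depletion at TSSs from plasma cfDNA"
author: "cfTSS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling nucleosome depletion at TSSs from plasma cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

Plasma cell-free DNA is mostly nucleosome-protected chromatin debris:
apoptotic nucleases spare DNA wrapped around nucleosomes and digest the
exposed linkers. At the transcription start site of an *active* gene, the
promoter sits in a nucleosome-depleted region (NDR), so cfDNA fragments are
under-represented there. Low-pass whole-genome sequencing (~6X) of plasma is
enough to see this dip, and because tumours activate and silence different
promoters than blood cells do, the dip pattern across many TSSs carries a
tumour signal that does not depend on detecting somatic mutations.

The statistic this package computes per transcript $t$ and sample $s$ is the
**TSS relative coverage**

$$
R_{s,t} \;=\;
\frac{\tfrac{1}{1000}\sum_{i \in [\mathrm{tss}-500,\ \mathrm{tss}+500)} d_s(i)}
     {\tfrac{1}{2000}\left(\sum_{i \in [\mathrm{tss}-1500,\ \mathrm{tss}-500)} d_s(i)
      + \sum_{i \in [\mathrm{tss}+500,\ \mathrm{tss}+1500)} d_s(i)\right)}
$$

where $d_s(i)$ is the per-base fragment-overlap depth. $R = 1$ means the
central window looks like its flanks (closed, inactive promoter); values
well below 1 mean an accessible promoter. The ratio makes the statistic
invariant to per-sample sequencing depth, which is why a later per-feature
z-score (not a per-sample rescaling) suffices for cross-sample comparison.

**Window arithmetic.** All three windows are *half-open 1000-base*
intervals, so the three windows exactly partition
$[\mathrm{tss}-1500, \mathrm{tss}+1500)$ and the divisors 1000 and 2000 are
exact. An inclusive-endpoint variant would sum 1001 bases while dividing by
1000; we prefer the internally consistent convention and state it rather
than leave it implicit. The statistic is symmetric about the TSS, so strand
is carried in the annotation but never changes a value; two transcripts
sharing a TSS coordinate share a value.

**Depth definition.** Depth counts each *fragment* footprint once (for BAM
input the pair's outer span, reconstructed from the leftmost mate's TLEN).
cfDNA protection acts on fragments, not on reads, and this also keeps BED
and BAM inputs equivalent. BAM records are pre-filtered the way low-pass
cfDNA pipelines do: mapping quality < 2 dropped, and any record whose FLAG
intersects 3840 (secondary, QC-fail, duplicate, supplementary) dropped.

**Missing data.** A TSS whose flanks have zero coverage in a sample yields
a masked value, never an error or an infinity. At normalization time a
transcript masked in more than 20% of *training* samples is dropped
outright; remaining masked entries are imputed to the training feature mean
(z = 0). The choice is conservative: imputing to the mean can only shrink a
feature's apparent effect.

## Normalization and feature selection

Per-transcript mean and sample standard deviation are estimated on the
training cohort only and then **frozen**: validation and independent test
cohorts are transformed with the training parameters, never their own.
This is the contract that makes downstream evaluation honest, and the
package enforces it structurally (parameters are an immutable object;
evaluating a model on any training sample id raises an error).

The feature-reduction chain runs cheapest-first:

1. **Near-zero variance**: drop a feature when the ratio of its most-common
   to second-most-common value exceeds 19 (i.e. 95/5) *or* fewer than 10%
   of its values are distinct. We state the rule as a disjunction; the
   popular implementation in `caret` requires both conditions, but a
   feature failing either is useless to a forest split and is cheaper to
   drop early.
2. **High correlation**: greedy pruning of pairwise Pearson correlations
   above 0.9 — repeatedly take the worst remaining pair and drop the member
   with the larger mean absolute correlation, ties resolved by feature
   name. The rule is written out (rather than delegated) so the survivor
   set is a deterministic function of the matrix; `caret::findCorrelation`
   serves as an independent cross-check in the test suite.
3. **Group screen**: per-feature two-sided Wilcoxon rank-sum test, cancer
   vs healthy, retaining raw p < 0.01. No multiple-testing correction is
   applied — the screen is a pre-filter for a classifier, not an inference,
   and the retained count is reported instead. The rank-sum default is
   deliberate: relative-coverage ratios are right-skewed and the test is
   distribution-free; a Welch t-test is available by option.
4. **Stage-monotone selection**: group means are computed for healthy and
   stages I–IV; a feature qualifies when the five means are *strictly*
   increasing (cancer-up) or strictly decreasing (healthy-up). Strictness
   matters: with ties allowed, flat noise would qualify. Within each class,
   features are ranked by |mean(stage I) − mean(healthy)| — prioritising
   what separates *early* disease from healthy — and the top 100 per
   direction form the panel (the top-200 pre-cut per direction is kept as
   an intermediate artifact, reconciling the two published panel sizes).
   Ties in the ranking fall to lexicographic transcript order, so the
   panel is fully deterministic. A stage with zero samples is an explicit
   error: merging or dropping stages is the caller's decision, not a
   silent fallback.

## Pathway scores and the EGFR feature set

Transcript-level z-values are first averaged within genes (so a
three-transcript gene is not triple-weighted), then a pathway's **path
score** per sample is the mean over its genes present in the matrix; the
fraction of genes found is logged. Pathways are compared between
EGFR-positive and wild-type samples with the same rank-sum screen, and the
significant fractions are reported overall, for the "EGFR-related" subset
(any set containing the anchor symbol, default `EGFR`), and for the rest.
The package ships no curated pathway data; any GMT can be loaded. The gene
feature set for the EGFR mutation-status model is the p < 0.01 subset of
EGFR-pathway genes, ordered by p then symbol.

## Cohort splitting, the forest, and evaluation

The 70/30 split is stratified with **per-stratum ceiling rounding**:
exactly $\lceil 0.7 n \rceil$ of each stratum goes to training. This is the
convention of `caret::createDataPartition` and the only rounding rule that
reproduces both reference partitions — (96, 100) → 68 + 70 = 138 training /
58 validation, and (29, 36) → 21 + 26 = 47 / 18 — which the tests assert
exactly.

Classification uses a random forest with fixed hyperparameters (1500 trees,
mtry 1 for the screening model; 2500 trees, mtry 5 for the EGFR model). The
predictor score is the forest's positive-class probability. Three repeats
of stratified ten-fold cross-validation estimate prediction error with the
same fixed settings — CV here is *model assessment only*; the deployed
model is refit on all training data. When the smaller class has fewer
members than folds (realistic for small EGFR cohorts) the fold count is
reduced with a warning rather than failing.

ROC curves are computed by threshold sweep with trapezoid AUC (equal, with
ties counted ½, to the Mann–Whitney concordance probability — asserted
against an exhaustive pair-counting oracle in the tests) and a DeLong 95%
CI, via pROC. Stage subgroups (early = I/II, advanced = III/IV) restrict
the cases while keeping all controls. Degenerate inputs are handled:
constant scores give AUC 0.5; perfect separation gives AUC 1 with a
collapsed CI clamped to [0, 1].

## What the synthetic cohort generator emulates

Every stage of the pipeline is exercised on cohorts from
`simulateCohort()`, which plants known truth:

- One synthetic chromosome (`chrS`), TSSs every 4 kb (≥ 3001 bp is required
  so ±1500 bp windows never overlap; tighter spacing is rejected with a
  sizing message), 0-based half-open coordinates in all written files.
- Fragment **midpoints** are drawn from a density that is flat at
  `background_depth / frag_len_mean` everywhere except TSS ±500 bp, where
  it is scaled by that TSS's depletion fraction. Fragment lengths are
  Normal(167, 10) truncated to [80, 300] bp — the mononucleosomal cfDNA
  mode — and per-sample depth noise is log-normal (σ = 0.05), which cancels
  exactly in the coverage ratio.
- Non-informative TSSs share one class-independent depletion (0.5).
  Planted cancer-up TSSs shift their depletion by +0.10 per stage step
  (healthy → I → II → III → IV), planted healthy-up TSSs by −0.10; genes of
  the planted "EGFR" pathways shift by −0.12 in EGFR-positive samples
  (positives more accessible, hence lower coverage). All depletions clamp
  to [0, 1.5]. The informative TSSs and the pathway-effect genes are drawn
  from disjoint pools so the two planted signals never confound.
- The reference cohort is 60 healthy + 15 cancer per stage at 6X. The
  0.10 per-stage step was chosen once from a power calculation: at 6X and
  depletion 0.5 the per-sample, per-TSS standard deviation of the relative
  coverage is ≈ 0.12, so a 0.10 step gives ≈ 2σ adjacent-group separation
  for group means at n ≈ 10–15 — a regime where strict five-group
  monotonicity holds for most but not all planted features, which is what
  keeps the selection step non-trivial.

Two deliberate approximations are worth knowing. First, because depletion
is applied to *midpoints* over a flat ±500 bp window, fragment footprints
smear across the window edges and the measured relative coverage at
depletion $d$ is slightly attenuated toward 1 — approximately
$(d + (1-d)\phi_c)\,/\,(1 - (1-d)\phi_f)$ with
$\phi_c \approx \bar\ell^2/(4000\,\bar\ell) \cdot 2 \approx 0.042$ and
$\phi_f \approx 0.021$ for $\bar\ell = 167$, i.e. ≈ 0.52 observed at
$d = 0.5$. The calibration tests therefore compare against an independent
Monte-Carlo rebuild of the generative model, not against $d$ itself.
Second, the generator omits what real cfDNA has: GC and mappability bias,
nucleosome-phasing harmonics around the NDR, copy-number signal,
class-dependent fragment-size shifts, and real genome coordinates. Passing
the synthetic-recovery tests therefore demonstrates that the *machinery*
(windowing, normalization, selection, training, evaluation) is correct and
leak-free — not that the classifier's synthetic AUC transfers to clinical
cohorts, whose headline numbers require the original private data.

## Problem sizes in the test suite

The bundled suite runs the full chain at the reference scale — 2000 TSSs,
120 samples, three generator seeds — and asserts: exact split arithmetic;
an exactly 100 + 100 panel when ≥ 100 features per direction qualify (150
are planted per direction for that check, so the strict-monotonicity
attrition at training-cohort group sizes still leaves ≥ 100 candidates);
≥ 80% planted-feature recovery and held-out AUC ≥ 0.9 averaged over the
three seeds; screen and CV calibration under permuted labels; and
enrichment of planted EGFR pathways. Unit tests pin the coverage statistic
to a per-base brute-force oracle at 1e−12 and the AUC to pair counting.

## Known limitations

- BED fragment input is taken as pre-filtered; MAPQ/FLAG filtering applies
  to BAM input only.
- The high-correlation filter recomputes a dense correlation matrix; for
  panels far beyond ~20k features a blocked implementation would be needed.
- DeLong CIs degenerate under perfect separation; the package clamps them
  rather than bootstrapping by default (a bootstrap option would be the
  natural extension).
- The EGFR-related flag is purely membership of an anchor symbol in a gene
  set — a user-declared convention, not a curated pathway ontology.
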