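---
title: "Models and design choices behind the isomiR transition pipeline"
author: "mirtransit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind the isomiR transition pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtransit)
```

`mirtransit` analyses small RNA-seq of the colorectal adenoma–carcinoma
transition at isomiR resolution: three groups — healthy mucosa (HC),
adenomatous polyps (AP), colorectal carcinoma (CRC) — treated both as
pairwise contrasts and as an ordinal sequence (0, 1, 2). This vignette
records the models, the tunable parameters and their defaults, the
behaviour of the synthetic-data generator, and the numerical and design
choices that were genuinely open.

## The generative model of the synthetic study

`simulation_design()` fixes the conditions of a simulated study and
`simulate_counts()` draws miRNA counts from

$$\log_2 \mu_{is} = b_i \;+\; d_i\,\ell\,t_s\,m_i \;+\;
  \beta_{\mathrm{batch}(s)} \;+\; a\,(\mathrm{age}_s - \overline{\mathrm{age}}),
  \qquad y_{is} \sim \mathrm{NB}(\mu_{is}, \alpha),$$

with stage $t_s \in \{0,1,2\}$, a monotone indicator $m_i$ with random
direction $d_i$, and per-step log2 effect $\ell$. Defaults and why:

* `n_samples_per_group = 20` — the scale of a single profiling cohort in
  tissue biopsy studies of this design; large simulation-based checks in the
  package use 30 per group and 300 miRNAs, sizes at which the pipeline's
  statistical properties are stable yet a full run (about 2.4 million reads)
  stays around a minute.
* `baseline_log2 = c(4, 8)` — per-miRNA baseline means of 16–256 reads, the
  mid-range of a typical miRNA count distribution after removing barely
  detected features.
* `nb_dispersion = 0.1` — biological coefficient of variation of about 30%,
  ordinary for human tissue cohorts.
* `frac_monotone = 0.1`, `lfc_per_step = 1` — a minority of miRNAs drifting
  two-fold per stage step.
* `batch_levels = 2`, `batch_sd = 0.1`, `age_slope = 0.01` — mild technical
  batch effects and a per-year age effect, so the covariate-adjusted GLM has
  genuine nuisance structure to remove. Ages are drawn uniformly on 45–80
  (only group means and spreads matter downstream; the exact shape is
  immaterial), and batch effects are centered to mean zero on the log scale.
* `isomir_profile` — canonical 0.55, 5'-trim 0.08, 3'-trim 0.12, templated
  3'-extension 0.08, non-templated 3'-addition 0.12, substitution 0.05: a
  canonical-dominant mixture in which every modification class is common
  enough to test.
* `seq_error_rate = 0.001` per base and a 5% chance of a sub-Q20 read tail —
  a clean modern sequencer; the error profile is assumed uniform across
  cycles, which real sequencers violate (errors rise toward the 3' end).
* `adapter = "TGGAATTCTCGGGTGCCAAGG"` — the standard small-RNA 3' adapter;
  configurable because kits differ. Reads are 1×50: insert, adapter, then
  padding, as single-end small-RNA chemistry produces.

Reads are generated per (miRNA, sample) cell so that FASTQ read counts equal
the count matrix exactly. Non-templated tails are drawn over {A, T} with
*every* tail base differing from the templated hairpin continuation — if a
later tail base were allowed to coincide with the template, no 3'-anchored
caller could distinguish it from a templated extension, and exact round-trip
recovery would be impossible by construction, not by implementation.
Planted substitutions sit at a fixed per-miRNA mature position in 4–8:
interior (clear of the tail caller) and leaving an exact 12-mer window for
the seed index. The generator does **not** emulate: sequence-dependent
ligation or PCR bias, position-dependent error profiles, cross-mapping
between paralogous miRNA families (hairpins are random and screened for
shared mature substrings), plasma/exosome biology, or miRNAs overlapping
other small-RNA classes. Passing tests therefore demonstrate correctness of
the computational chain under a clean, known model — not robustness to every
artefact of real libraries.

## Preprocessing

Adapter removal is a semi-global, mismatch-only search (no indels): every
offset is scored by matching bases, a candidate is valid when mismatches ≤
⌊0.1 × overlap⌋, and everything 3' of the best occurrence is cut; ties go to
the leftmost occurrence. `trim_adapter()` defaults to a minimum overlap of
3 nt, the convention of common trimmers and the right default when partial
3'-terminal adapters are expected. The pipeline wrapper `preprocess_reads()`
instead defaults to half the adapter length: with 1×50 cycles and inserts
≤ 30 nt the full adapter is sequenced in essentially every read, so long
minimum overlaps cost nothing — and they make preprocessing idempotent in
practice (a 3-nt minimum would re-trim a chance suffix match on a second
pass about once per 64 reads). Quality trimming uses the standard 3'
partial-sum rule at Q20; reads shorter than 18 nt are then discarded, the
conventional lower bound for genuine miRNA inserts.

## IsomiR assignment and classification

A k-mer index (default k = 12) over the hairpins provides candidate
placements; each is verified ungapped. Detection therefore needs one exact
12-mer shared with the true locus — the usual seed-and-extend sensitivity
trade-off; with ≤ 2 substitutions allowed and reads of 18–27 nt this can in
principle miss adversarial substitution patterns, which on this problem are
vanishingly rare (the generator's substitutions are single and interior).

Conventions, chosen where the field has no single standard:

* `offset5 > 0` is 5' trimming (a seed shift); `offset5 = −1` denotes a 1-nt
  5' extension. `offset3 > 0` is templated 3' extension, `offset3 < 0` 3'
  trimming. Substitution positions are mature-relative, 1-based, signed,
  with no position 0.
* The non-templated tail is called greedily from the 3' end (maximal run of
  terminal mismatches, capped at 3 nt) *before* substitutions are recorded,
  so a terminal mismatch is never double-counted as both tail and
  substitution.
* Multi-mappers: a read is kept only when all of its minimal-substitution
  placements classify to the same mature miRNA; otherwise it is unassigned.
  This is the conservative policy — counts are never split or duplicated.
* The substitution credibility fraction is computed per sample (libraries
  are filtered independently) and the 25% threshold is inclusive
  (`fraction ≥ 0.25`): a strict-equality reading would be degenerate. Reads
  whose substitution fails the threshold are merged into the isomiR with the
  same end offsets and tail, so per-miRNA totals are conserved; only
  non-uniquely mapped substitution reads are discarded outright. Whether to
  merge or discard was an open choice; merging keeps miRNA-level counts
  loss-free.
* In positional modification profiles each tailed read is counted once, at
  its tail length; counting every tail base would let a single read
  contribute several times and push per-type abundance sums past 1.

## Normalization and differential expression

Size factors are median-of-ratios against the geometric-mean
pseudo-reference, computed over features positive in all samples. They are
identified only up to a global constant — rescaling one library rescales
every factor through the reference — so equivariance holds exactly for
factor *ratios*.

The variance-stabilizing transform is `log2(count/s + 1)`: every downstream
use (Euclidean MDS, rank-based screening) needs only a monotone
variance-flattening map, for which the shifted log is standard, transparent,
and exactly zero at zero counts. The closed-form NB transform could be added
behind a flag but would change no downstream rank or distance materially at
these dispersions.

Dispersion is method-of-moments on normalized counts,
$\hat\alpha_i = \max(0, (s_i^2-\bar\mu_i)/\bar\mu_i^2)$, shrunk 50/50 toward
the least-squares trend $\alpha(\mu)=a_1/\mu+a_0$ and floored at $10^{-8}$;
zero-variance features sit at the floor directly since they carry no
dispersion information. The estimator is design-blind, so it is applied per
contrast to the samples actually modeled: pooling all three groups would
fold planted between-group signal into the variance estimate and
systematically deflate the Wald statistics of exactly the features of
interest.

The per-feature NB GLM is fitted by Fisher scoring with weights
$\mu/(1+\alpha\mu)$ and the log size factor as offset; the linear predictor
is clamped to ±30 to survive separation, and features that still fail to
converge are flagged, given `p = NA`, and excluded from the BH adjustment
(zero-filling them would bias the FDR). The Wald reference is the standard
normal, matching mainstream NB-GLM practice; no fold-change shrinkage is
applied because the calling thresholds (FDR < 0.01, |log2FC| > 0.5, both
strict) are defined on raw Wald estimates. BH adjustment excludes `NA`
p-values from the number of tests.

## Transition statistics, validation, target scanning

Classical (Torgerson) MDS is used rather than non-metric MDS because the
input is a variance-stabilized matrix under Euclidean distance, the setting
in which classical MDS is exact; axis signs are fixed by making the
largest-magnitude coordinate positive, so embeddings are reproducible.
In the Spearman screen the boundary point |ρ| = 0.7 is assigned to the
moderate tier — the high tier is read as a strict inequality. Constant
features get `ρ = NA` and tier `none`.

Positional Kruskal–Wallis tests use the tie-corrected statistic with a
chi-squared reference and BH adjustment across (type, position) cells;
samples absent from a cell enter with abundance 0, and an all-identical cell
degenerates to p = 1. The Mann–Whitney validation test enumerates exactly
when both groups have ≤ 8 observations and no ties, and otherwise uses the
continuity- and tie-corrected normal approximation — the uncorrected
approximation can differ from the exact p by more than 0.04 at n = 8 per
group, the corrected one stays within about 0.01. ΔCt averages duplicate
wells per assay before subtraction, multiple normalizers are averaged
arithmetically, and for a contrast "A vs B" the fold change is
`mean ΔCt(B) − mean ΔCt(A)`, so positive log2FC means higher expression in
the case group (ΔCt is inverse to expression). Plasma assay batches of
different chemistry are analysed separately, never pooled.

The target scanner implements only the canonical 8-mer site (perfect
complement of miRNA positions 2–8 plus a literal `A` opposite position 1,
regardless of the miRNA's first nucleotide); weaker 7-mer site classes,
context scoring and conservation weighting are out of scope, and the scanner
is database-agnostic — it takes user-supplied UTR sequences and gene sets.
Overrepresentation uses the exact hypergeometric upper tail with enrichment
score `E = (k/n)/(K/N)`; a pathway equal to the universe has E = 1 exactly
and can never be significant under the strict `E > 1` rule.

## Problem sizes used by the test suite

The end-to-end property checks simulate 300 miRNAs at 30 samples per group
(about 2.4 million reads), 2000 null features at 20 per group for type-I
error calibration, 2000-read single-miRNA libraries for the substitution
filter, 1000 random UTRs against a brute-force scanner oracle, and the full
hypergeometric enumeration for universes up to N = 30. These sizes were
chosen as the smallest at which the quantities being checked (recovery
fractions, error rates) are stable to well within their tolerances.

## Known limitations

Ungapped alignment only (no indel isomiRs); no novel-miRNA discovery; no
A-to-I editing inference beyond raw substitution records; the NB fit has no
outlier refitting or independent filtering; the dispersion trend is a simple
two-parameter least-squares fit rather than a robust regression; and the
synthetic generator's idealizations listed above bound what a green test
suite can claim about messy real libraries.
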