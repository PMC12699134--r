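---
title: "starrmap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{starrmap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starrmap)
```

starrmap quantifies enhancer activity from STARR-seq experiments: candidate
genomic fragments are cloned downstream of a minimal promoter so that active
enhancers transcribe themselves, and activity is read out as the abundance of
a fragment in the reporter RNA library relative to the plasmid input library.
This vignette explains the statistical model behind each stage, the
parameters that matter, what the bundled simulator does and does not emulate,
and the numerical choices that were genuinely open.

## Activity model and normalization

For a target region or window, let $k_{rna}$ and $k_{in}$ be the fragment
counts overlapping it (an overlap of at least 1 bp counts; the boundary is
half-open, so a fragment ending where a window starts does not overlap it).
Targeted activity is the fold change of depth-normalized counts,

$$\mathrm{FC} = \frac{k_{rna} \cdot 10^6 / N_{rna}}
                     {k_{in} \cdot 10^6 / N_{in}},$$

reported alongside $\log_2 \mathrm{FC}$. When either raw count is zero, 0.5
is added to both raw counts so the log stays finite; targets with fewer than
`min_input_count = 10` input fragments are flagged unquantifiable rather than
silently dropped.

For genome-wide window scanning, `scan_windows()` does not use the raw
library-size ratio by default. On a compact genome densely populated with
strong enhancers, the enhancers absorb a large share of the RNA library, so
library-size scaling depresses every background window below 1 and biases
enhancer estimates downward by the same factor. The default
(`scale = "median"`) therefore estimates the background RNA:input ratio as a
median of per-window count ratios — the same idea as median-of-ratios size
factors in RNA-seq and peak-exclusion scaling in ChIP-seq. The estimate is
two-pass: windows more than 2-fold enriched under a provisional median, plus
their neighbors within `mask_expand_bp = 1500` bp (fragment-length bleed),
are excluded before the final median. `scale = "library"` restores plain
library-size normalization.

## Window-level significance

Under the null, the two window counts are independent Poisson draws with
rate ratio equal to the background scale factor $s$. The default test
(`p_method = "conditional"`) is the exact conditional Poisson ratio test:
given the window total $t = k_{in} + k_{rna}$,

$$k_{rna} \mid t \sim \mathrm{Binomial}\!\left(t, \frac{s}{1+s}\right),$$

with the upper-tail probability as the p-value. This accounts for the
sampling noise of *both* libraries. The simpler formulation that conditions
on the input rate as if it were known
($k_{rna} \sim \mathrm{Binomial}(N_{rna}, s\,k_{in}/N_{rna})$) is available
as `p_method = "direct"`, but at deep coverage it ignores the input count's
own Poisson noise and becomes anticonservative — on enhancer-free simulated
genomes its false-positive fraction at $p < 10^{-5}$ exceeded the $10^{-4}$
calibration bound, while the conditional test stays calibrated. Windows with
fewer than `min_input = 10` input fragments are flagged and excluded from
testing.

`call_peaks()` merges passing windows that overlap or are book-ended, takes
the summit as the midpoint of the best-enrichment window, and applies three
published filters: $p < 10^{-5}$, enrichment threshold 2.5, and a
regular-chromosome whitelist. The enrichment filter is interpreted on the
log2 scale by default because the reported activity range of the mapped
enhancers (six- to 117-fold, i.e. log2 2.58–6.87) is consistent with a log2
cutoff at 2.5 and not with a linear one; `enrichment_scale = "linear"`
selects the other reading.

## Strength classification by changepoint analysis

Enhancers are ranked by activity and the ranked curve is segmented by
changepoints in mean and variance under a Gaussian likelihood; the largest
changepoint value becomes the lower bound of the "strong" class and the
smallest the upper bound of the "weak" class, with "intermediate" in
between. Two implementation notes:

* `detect_changepoints()` minimizes the summed segment cost
  $m(\log 2\pi + \log\hat\sigma^2 + 1)$ plus `penalty` per changepoint
  (default $3\log n$, one parameter each for mean, variance and location),
  by PELT (exact), binary segmentation (greedy), or — when
  `max_changepoints` is finite — an exact constrained dynamic program that
  is verified against brute-force enumeration in the tests.
* On a *ranked* curve the unconstrained optimum is degenerate: sorted
  segments have artificially small within-segment variance, so the penalized
  likelihood prefers many short segments regardless of the algorithm.
  `derive_thresholds()` therefore fits at most two changepoints by default
  (the three-class scheme needs at most two thresholds, and bounded
  segmentation mirrors the common bounded-BinSeg usage); the cap is a
  parameter. Values exactly at a threshold go to the outer class by default
  (`boundary = "outer"`).

## Chromatin and positional annotation

A peak is "accessible" if it overlaps an ATAC-seq peak by at least 1 bp,
H3K27ac+ under the same rule, and H3K4me1+ if it lies within a ±3 kb flank
of an H3K4me1 peak; the flank boundary is inclusive. Genomic features are
assigned from the peak *summit* with precedence promoter-TSS > TTS > 5'UTR >
3'UTR > exon > intron > intergenic; boolean chromatin flags use whole-peak
overlap, matching the wording of the respective definitions. The promoter
and TTS windows default to ±1 kb in gene orientation (the convention of the
standard peak-annotation tooling; all windows are arguments). The nearest
gene minimizes |summit − TSS| on the same chromosome, and the signed TSS
distance is positive downstream in gene orientation. Tissue classes map
atlas categories exactly: low tissue specificity → ubiquitous;
tissue-enhanced, tissue-enriched, group-enriched → tissue-specific; genes
absent from the lookup are unknown, and unrecognized categories are an
error rather than a silent bucket.

## Motif scanning with exact p-values

`pwm_model()` regularizes a probability matrix with a background
pseudocount, converts it to log2-odds, and *discretizes* the scores to a
grid of `resolution = 1e-3` log-odds units. Scanning and the null
distribution use the same integer scores, so the p-value of any observed
score is exact for the scanned matrix: the null distribution of the score of
a random background word is built by dynamic programming (columnwise
convolution), and the tests verify it against full $4^w$ enumeration to
$|\Delta p| < 10^{-12}$ for widths up to 8. The resolution trades accuracy
of the continuous-score approximation against table size; at $10^{-3}$ a
width-10 matrix needs a table of a few tens of thousands of entries. Both
strands are scanned; same-position opposite-strand duplicates keep the
better score, and overlapping same-motif hits are collapsed greedily by
score for counting purposes.

Shifted backgrounds translate every unfiltered peak call 10 kb downstream
(strand-agnostic), then drop regions that leave the chromosome, overlap a
retained peak, or have fewer than 10 overlapping input fragments ("poor
coverage", concretized and exposed as a flag). Enrichment between sequence
sets is a one-sided Fisher's exact test on motif presence/absence with
Benjamini-Hochberg adjustment across motifs; 0.5 is added to each cell of
the fold-change ratio only when a zero occurs.

## YY1 dosage and mutagenesis

YY1 motif dosage bins enhancers by deduplicated hit count (0, 1, 2, 3, 4,
5+), summarises activity per bin, and fits both a one-way ANOVA across bins
and a least-squares slope of activity on the capped count. Mutagenesis
replaces the conserved plus-strand core `ATGG` with `CTCG` inside each hit
window (for minus-strand hits, the genomic `CCAT` becomes `CGAG`); a hit
window without the oriented core is an error, because it indicates the
supplied PWM does not carry the expected core. `mutate_yy1()` is a single
pass over the supplied hits; `select_mutagenesis_candidates()` iterates
scan → mutate (up to three rounds) before emitting a design, so the emitted
mutant carries zero YY1 hits at the scan threshold even when the trimmed
window contains an additional background-level instance that only crosses
the threshold after the first pass. The replacement string cannot create a
new core on either strand, so the iteration terminates.

## Screen design

Tiling fragments a peak into 500 bp tiles centered on the summit with 200 bp
overlap between neighbors (stride 300), up to three tiles on each side;
out-of-bounds tiles are dropped with a warning. The model-training window
dataset uses 249 bp windows at stride 100 — seven per peak — with the odd
centering placing the extra base downstream ([summit−124, summit+125)).
Windows are split 80/10/10 into train/validation/test with all windows of a
peak in one split (grouped split, preventing leakage); background windows
are uniform draws from whitelisted chromosomes excluding peaks ±1 kb.
Synthesis-ready inserts are wrapped with fixed adapters and vector homology
arms, bit-exact, in the order 5' homology arm, 5' adapter, insert, 3'
adapter, 3' homology arm.

## The synthetic experiment

`simulate_starrseq()` builds the fixture every stage is tested against:

* a three-chromosome uniform-composition genome (500 kb each) whose third
  chromosome is named `scaffold_1` and deliberately excluded from the
  default whitelist, so the regular-chromosome filter is exercised;
* 200 planted 500 bp enhancers with true log2 activities uniform on
  [2.6, 6.9] (the six- to 117-fold range), 49% accessible, and YY1 consensus
  instances embedded at `floor((a - a_min)/(a_max - a_min) * 5)` copies so
  motif count rises linearly with activity (plus 0–2 ETS instances);
  accessible enhancers are preferentially placed within ±500 bp of a TSS and
  masked enhancers away from promoters;
* fragment libraries of one million 800±50 bp fragments (clipped to
  100–1500 bp) per library and replicate. The RNA library is importance
  resampling from a dense candidate pool (8× the library size) in which a
  fragment overlapping an enhancer carries relative weight
  $2^{\text{activity}}$;
* matching chromatin tracks (ATAC/H3K27ac on accessible enhancers, H3K4me1
  within ±3 kb, optional weak H3K9me3 on masked ones) plus decoy peaks that
  avoid enhancers by 2.5 kb, emulating chromatin-predicted-but-inactive
  regions; and log-normal expression tables in which genes near accessible
  enhancers are boosted in proportion to enhancer strength.

Two generator choices deserve emphasis. First, a fragment qualifies for the
enhancer weight at ≥ 1 bp overlap — the same rule the counting stage uses.
A stricter containment rule (e.g. half the enhancer length) would make the
generative law inconsistent with the measurement rule and bias window
estimates downward by a constant ~0.7 log2; with matched rules the
best-window estimator recovers planted activities essentially unbiasedly,
which is what the recovery tests assert. Second, enhancers are spaced at
least 2.6 kb apart and planted only on whitelisted chromosomes: 800 bp
fragments bleed enrichment up to ~1.25 kb beyond a 117-fold enhancer's
edge, so closer placement would merge neighboring peaks, and enhancers on
`scaffold_1` would be removed by the very filter the scaffold exists to
exercise, making per-enhancer recovery accounting impossible.

What the simulator does *not* emulate: sequencing error, PCR duplication,
GC/mappability bias, fragment-level covariates, chromatin-dependent capture
of the input library, or any relationship between native chromatin state
and plasmid-based activity. Passing the recovery tests therefore shows the
pipeline is a consistent estimator of the simulator's generative model — a
self-consistency check, not evidence about real CHO libraries, where
covariate-corrected callers exist for good reasons.

## Problem sizes and determinism

The test suite runs most module tests on a reduced experiment (3 × 60 kb
genome, 12 enhancers, 60k fragments per library) and the end-to-end checks
at the full study conditions (3 × 500 kb, 200 enhancers, 1M fragments per
library, two replicates); `scripts/acceptance.R` re-simulates the full
conditions from scratch at the seed given on the command line. Every source
of randomness flows from a single integer seed per generator call, and
byte-identical outputs under a repeated seed are asserted in the tests.

## Known limitations

* The binomial window test models no overdispersion beyond Poisson; real
  libraries need covariate correction.
* The exact PWM p-values are exact for the *discretized* matrix; a much
  coarser resolution would visibly quantize p-values near the threshold.
* `derive_thresholds()` inherits the degeneracy of variance-based
  segmentation on ranked curves; its changepoint cap is a pragmatic guard,
  not a model of the rank curve.
* Nearest-gene assignment is purely positional; no contact or eQTL evidence
  is used.
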