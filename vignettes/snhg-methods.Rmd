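---
title: "Methods: region-resolved SNHG quantification and cis/trans effect analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-resolved SNHG quantification and cis/trans effect analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snhgtools)
```

This vignette is the package's own account of its models and the design
choices behind them: what each procedure assumes, which parameters matter,
what the synthetic-data generator does and does not emulate, and the
numerical conventions used throughout.

## The SNHG partition

A snoRNA host gene is represented by the exon structure of all its
isoforms. The partition works on the *exon union*: a base is exonic if any
isoform has an exon there; the remaining bases of the merged span are
introns. This union-merge is a deliberate choice — region classes must be
disjoint for counting, and a per-isoform scheme would double-count shared
bases. The cost is that isoform-specific intron retention is invisible at
this level.

Within a snoRNA-containing merged intron, the snoRNA body becomes a
`Snorna` segment and the flanks become `Pre` (transcriptionally upstream)
and `Post` (downstream), following the host strand. Two conventions
resolve cases the scheme's verbal definition leaves open:

- **Several snoRNAs in one intron.** The gap between adjacent snoRNAs is
  split at its midpoint, each half attributed to the nearer snoRNA. For an
  odd-length gap the extra base goes to the `Post` half in transcription
  orientation; this makes the rule exactly invariant under coordinate
  reflection plus strand flip (the identity on transcription geometry),
  which the test suite verifies base by base.
- **Partially exonic snoRNAs.** The host is excluded with a diagnostic
  rather than reclassified, since the scheme presumes intronic snoRNAs; a
  silent reclassification would contaminate `Exon` counts.

All internal coordinates are 0-based half-open; conversion to 1-based
closed GTF (and back) happens only in the I/O layer, so off-by-one risks
are confined to one file.

## Read assignment and normalization

A read overlapping a host's span is counted in exactly one region class:
the class covering the majority of its host-overlapping bases, with ties
broken by `Snorna > Pre > Post > Exon > OtherIntron` — the priority favors
the shortest, biologically focal classes, which would otherwise lose every
tie to long flanks. This is a counting rule, not an EM assignment;
fractional assignment was considered and rejected to keep per-host counts
integer and conservative (the per-host sum equals the number of
host-overlapping reads, an invariant the tests check against a brute-force
oracle). Reads are treated as unstranded by default because library
strandedness is often unknown; a stranded mode honors the host strand.

Size factors are median-of-ratios: for features with nonzero counts in
every sample, factor_j = median_i(count_ij / geometric mean_i). FPKM is
`count · 10⁹ / (length · assigned reads)`.

## Differential expression

The DE procedure is intentionally simple and fully documented: normalize
by size factors, `log2FC = log2((mean_T + c)/(mean_C + c))` with
pseudocount `c = 1`, a two-sided Welch t-test on `log2(norm + c)`, and BH
correction over the features passing the filters. The decision thresholds
are `padj < 0.05` and `|log2FC| > 0.41` — the latter corresponds to a
minimum detectable change of `(2^0.41 − 1)·100 ≈ 33%`. A negative-binomial
GLM with dispersion shrinkage would be more powerful at n = 3; the Welch
procedure was chosen because the thresholds, not the NB machinery, are the
decision rule being studied, and because its calibration is directly
testable: on all-effects-zero simulations the realized false-positive rate
at `padj < 0.05` is far below 0.05 (the BH step controls FDR and the Welch
test at n = 3 is conservative), which the acceptance suite measures over
100 seeded runs.

Degenerate features (zero variance and equal means in both groups) return
p = 1 by convention. The expression floor (mean normalized count ≥ 5) and
the 200 nt exonic-length filter apply to gene-level tests; for
region-level tests the length filter is set to 0, because the 130 nt
snoRNA body is precisely the segment of interest there. BH is applied
within each analysis (gene-level, region-level, RIP) separately, mirroring
per-experiment testing.

## Positional analysis

Gene position is the annotated TSS, not the gene midpoint — the analyses
are promoter-centric. `Cis` is defined as exactly the two TADs sharing the
focal boundary, per the positional scheme being reproduced; a radius-based
alternative is deliberately not implemented. The digital cis test is a
two-sided Fisher exact test on {significant-in-direction} × {Cis,
elsewhere}; the reported odds ratio is the sample cross-product ratio with
a Haldane 0.5 correction when a cell is zero (the conditional-MLE OR that
accompanies the exact p would be infinite in the all-concentrated case).
The contact-interval comparison is a Pearson chi-squared without
continuity correction on the 2×2 of in/out-of-interval counts, df = 1,
with a warning (not an error) when an expected cell is below 1.

## The screen and binding tiers

"Concomitantly differentially expressed" is read strictly: the lncRNA and
the element's target must be DE in the *same* condition. Direction
concordance is carried as a flag rather than a hard filter of the raw
screen, because whether the original filter or only the prioritization
required concordance is ambiguous; both behaviors are exposed
(`require_concordant`). "High-confidence element" is operationalized as a
numeric score threshold. Ranking is by support count, then lncRNA
expression, then id — fully deterministic.

The composite binding score `Σ signal · min(−log10 p, 10)` is this
package's concretization of "number, strength and confidence" of binding
sites; the cap stops a single extreme p-value from dominating. Tiers are
score-quantile bins (default K = 4, i.e. quartiles), ties going to the
lower tier; tiering is monotone in score. Expression-matched controls are
drawn by decile-histogram sampling with a fixed seed — nearest-neighbor
matching would match tighter but breaks the exact-histogram property the
tests rely on.

## Labeling kinetics

Under continuous labeling with replenished label, new RNA accumulates as
`f(t) = 1 − e^(−δt)`. Steady-state mode fits δ by weighted least squares
on observed new/total fractions (weights = totals, so deeply covered time
points dominate), then σ = δ · mean abundance. Non-steady mode fits
`T(t) = T₀e^(−δt) + (σ/δ)(1 − e^(−δt))` and `N(t) = (σ/δ)(1 − e^(−δt))`
jointly by bounded L-BFGS-B from δ₀ = ln2/8 h⁻¹. δ is constrained to
half-lives between 0.1 h and 100 h; a fit at a bound, or a fitted labeled
fraction below 0.1 at 24 h, clears the confidence flag rather than being
dropped — stable short features (snoRNAs) are exactly the case where
half-lives cannot be time-resolved and should be flagged, not silently
estimated. The 1-D steady-state objective is smooth and unimodal in δ, so
`optimize()` at tolerance 1e-12 recovers noiseless curves to better than
1e-6 relative error; the tests cross-check against a 4000-point log-grid
search. `t½ = ln 2 / δ` holds exactly by construction.

## Cellular metrics

Kurtosis is Fisher excess with population (biased) moments,
`g₂ = m₄/m₂² − 3`. Whether the original quantification used excess or raw
kurtosis is not stated; only between-condition differences matter, and the
statistic is affine-invariant either way, so the convention cannot change
a comparison. Copies per cell pools totals across imaging fields
(total maxima / total nuclei), not the mean of per-field ratios — fields
with few cells should not carry equal weight. Allele frequency requires a
depth of 50 by default and flags shallower sites instead of returning a
noisy value.

## The synthetic-data generator

The generator's defaults encode the emulated study conditions: three
biological replicates per condition, negative-binomial counts with
variance `μ + φμ²` and φ = 0.05 (a typical bulk RNA-seq dispersion scale),
effects as additive log2 offsets on the treated-condition mean only,
labeling time points 0/4/8/24 h, and a focal lncRNA placed exactly at an
inter-TAD boundary on the first of three chromosomes. Region-level
baseline means are proportional to segment length with class weights
(exon 1, snoRNA 2, intronic flanks 0.1–0.15) reflecting that mature exonic
and snoRNA signal accumulates while intronic flanks are transient nascent
signal. Per-feature sequencing depth in the labeling simulation is 200
reads per time point; `depth = Inf` is an explicit noiseless sentinel used
by the kinetics tests.

What the generator does *not* emulate: read-level errors and mappability,
isoform-level expression variation, GC or length biases in counting,
batch effects, conversion-rate estimation in labeling data, and image
formation for the pixel tables. Passing tests therefore demonstrate
correctness of the computations and their calibration under a clean NB /
binomial / log-normal world, not robustness to every artifact of real
sequencing data.

## Problem sizes and determinism

The test and acceptance workloads use 500-gene null calibrations
(100 seeded runs), 90-gene/30-host region simulations and 200-gene zone
simulations for planted-effect power (100 runs each), 200 simulated
labeling features, and 500 random gene models against the per-base
partition oracle — sizes chosen so the whole suite exercises every claim
in about a minute of compute while keeping Monte-Carlo error well inside
the asserted margins. Every generator consumes an explicit seed and
restores the caller's RNG state; identical configuration gives
byte-identical artifacts, which the pipeline tests assert literally.

## Known limitations

- The Welch-on-logs DE test is conservative at n = 3; genuine effects near
  the 0.41 cutoff need several replicates or low dispersion to reach
  `padj < 0.05` (the digital cis test consequently needs a strong
  perturbation before it has significant genes to count).
- The screen assumes the element→target map is correct; it cannot discover
  targets absent from the map.
- Synthesis-rate units are normalized (abundance per hour); absolute rates
  would require spike-in calibration, which is out of scope.
- The partition excludes hosts with partially exonic snoRNAs rather than
  modeling them.
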