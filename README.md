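# snhgtools

Region-resolved analysis of snoRNA host genes (SNHGs) and cis/trans effects
of long noncoding RNAs, with a synthetic-data module that generates every
pipeline input with known ground truth.

## The scientific problem

Many small nucleolar RNAs (snoRNAs) are encoded inside the introns of
spliced host transcripts, and some of these hosts are noncoding RNAs with
regulatory roles of their own. Dissecting such a locus requires several
bespoke computations that standard RNA-seq tooling does not provide:

- **Region-resolved host quantification.** Each host gene is split into
  disjoint segments across all of its isoforms — the exon union (`Exon`),
  the snoRNA body (`Snorna`), the parts of the snoRNA-containing intron
  transcriptionally upstream (`Pre`) and downstream (`Post`) of the snoRNA,
  and snoRNA-free introns (`OtherIntron`) — so that mature, nascent and
  snoRNA-derived signal can be followed separately after a perturbation.
- **Positional (cis) analysis.** Genes are classified relative to a focal
  lncRNA locus sitting at a TAD boundary: the two flanking TADs (`Cis`),
  the rest of the focal chromosome (`SameChromosome`), or other chromosomes
  (`Trans`). Fold-change shifts per zone are tested with Mann–Whitney and
  one-way ANOVA tests, and a Fisher-exact "digital" test asks whether
  significantly responding genes concentrate in the Cis zone.
- **A cis-lncRNA candidate screen** joining a regulatory-element/target map
  with per-condition differential-expression tables: a (lncRNA, target)
  pair qualifies when the lncRNA overlaps a high-confidence element and
  both genes are differentially expressed in the same condition.
- **Binding-confidence tiers.** Genes are scored from peak evidence
  (`score = Σ signal · min(−log10 p, 10)`), split into score-quantile
  tiers, compared against expression-matched unbound controls, and tested
  for a monotone fold-change trend (Spearman ρ plus per-tier Mann–Whitney).
- **Labeling kinetics.** Under continuous metabolic labeling, the labeled
  fraction of a transcript follows `f(t) = 1 − e^(−δt)`; `fit_kinetics()`
  estimates the decay rate δ (bounded weighted least squares), the
  synthesis rate σ = δ·abundance, and the half-life `t½ = ln 2 / δ`.
- **Defined cellular metrics**: excess kurtosis of nuclear signal
  (`g₂ = m₄/m₂² − 3`), smFISH copies per cell (pooled totals), site allele
  frequency, wound migration rate `R_M = (W_i − W_t)/t` and closure
  `(A₀ − A_t)/A₀`.

Differential expression uses median-of-ratios size factors, a Welch test
on log2 normalized counts, and Benjamini–Hochberg correction, with the
decision rule `padj < 0.05` and `|log2FC| > 0.41` (a ≥ 33% change), an
expression floor, and a 200 nt exonic-length filter for gene-level tests.

The package is aimed at computational biologists who want these
computations as tested, reusable functions, and at method developers who
need a ground-truth simulator to validate comparable pipelines.

## Worked example

Partition a host gene with an intronic snoRNA across two isoforms:

```r
library(snhgtools)
host <- gene_model("SNHG1", "chr5", "+", list(
  data.frame(start = c(1000, 9000), end = c(1400, 9600)),
  data.frame(start = c(1000, 5200, 9000), end = c(1400, 5400, 9600))))
partition_snhg(host, data.frame(sno_id = "SNORA13", start = 2600, end = 2730))
#>   host_id chrom strand start  end      region  sno_id
#> 1   SNHG1  chr5      +  1000 1400        Exon    <NA>
#> 2   SNHG1  chr5      +  1400 2600         Pre SNORA13
#> 3   SNHG1  chr5      +  2600 2730      Snorna SNORA13
#> 4   SNHG1  chr5      +  2730 5200        Post SNORA13
#> 5   SNHG1  chr5      +  5200 5400        Exon    <NA>
#> 6   SNHG1  chr5      +  5400 9000 OtherIntron    <NA>
#> 7   SNHG1  chr5      +  9000 9600        Exon    <NA>
```

Simulate a knockdown with a planted +0.5 log2FC on snoRNA regions, quantify
regions, test, and ask whether snoRNA segments shift as a group:

```r
cfg <- sim_config(seed = 1, n_genes = 200, n_snhgs = 10,
                  effects = c("zone:Cis" = -0.5, "region:Snorna" = 0.5))
ann   <- gen_annotation(cfg)
parts <- partition_all(ann$models, ann$snos)$partitions
rc    <- gen_counts(cfg, ann, level = "region", partitions = parts)
de_r  <- de_test(rc$counts, de_thresholds(min_length = 0),
                 control = "ctrl", treated = "kd")
keep  <- de_r$call != "filtered"
gs    <- group_shift(de_r$log2FC[keep], sub("^.*:", "", de_r$feature)[keep])
round(gs$medians, 3)
#>        Exon OtherIntron        Post         Pre      Snorna
#>      -0.115      -0.059      -0.138      -0.102       0.666
signif(gs$anova_p, 3)
#> [1] 0.000956
```

The planted snoRNA effect stands out (median log2FC +0.67 vs ≈ 0
elsewhere; Exon-vs-Snorna Mann–Whitney p = 0.004, global ANOVA
p = 0.00096). With a stronger knockdown of the focal lncRNA
(`effects = c("zone:Cis" = -1.5)`, 4 replicates), the digital cis test
concentrates all 31 downregulated genes in the two flanking TADs:

```r
dig <- digital_cis_test(de_g, zones, "down")
dig$table
#>         Cis elsewhere
#> sig      31         0
#> not_sig   1       164
signif(dig$p, 3)
#> [1] 2.81e-35
```

A noiseless labeling time course with a 4 h half-life is recovered
exactly:

```r
fit_kinetics(data.frame(time_h = c(0, 4, 8, 24),
                        new = c(0, 0.5, 0.75, 0.984375), total = 1))
#> <kinetic_fit> mode=steady_state  delta=0.1733 /h  t1/2=4 h  sigma=0.1733 /h
```

An end-to-end synthetic run (`run_pipeline(pipeline_config(out_dir))`)
writes per-stage artifacts (GTF, BED, count TSVs, fit tables) and a
schema-versioned JSON report, byte-identical for a fixed seed.

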