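#' Construct a TAD map around a focal locus
#'
#' Ordered, non-overlapping topologically associated domains on one
#' chromosome, with the focal boundary (the shared edge of two adjacent
#' TADs) and the id of the focal locus sitting at that boundary.
#'
#' @param chrom Chromosome of the TADs.
#' @param tads `data.frame` with `start`, `end` (0-based half-open).
#' @param boundary Position of the focal inter-TAD boundary.
#' @param focal_id Gene id of the focal locus (excluded from zone calls).
#' @return List of class `"tad_map"`.
#' @export
tad_map <- function(chrom, tads, boundary, focal_id) {
  tads <- as.data.frame(tads)[, c("start", "end")]
  tads <- tads[order(tads$start), , drop = FALSE]
  if (any(tads$end <= tads$start)) input_error("empty TAD interval")
  if (nrow(tads) > 1L && any(tads$start[-1] < tads$end[-nrow(tads)]))
    input_error("TAD intervals must not overlap")
  i <- which(tads$end == boundary)
  if (length(i) != 1L || i == nrow(tads) || tads$start[i + 1L] != boundary)
    input_error("focal boundary must be the shared edge of two adjacent TADs")
  structure(list(chrom = as.character(chrom), tads = tads,
                 boundary = boundary, focal_id = as.character(focal_id),
                 flank_left = i, flank_right = i + 1L),
            class = "tad_map")
}

#' Assign genes to positional zones relative to the focal locus
#'
#' A gene's transcription start site (TSS) inside either TAD flanking the
#' focal boundary puts it in `Cis`; elsewhere on the focal chromosome,
#' `SameChromosome`; any other chromosome, `Trans`. The focal locus itself
#' is excluded; genes lacking a TSS are skipped with a diagnostic.
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `tss`.
#' @param tads A [tad_map()].
#' @return `data.frame` with `gene_id`, `zone`; attribute `"diagnostics"`
#'   lists skipped genes.
#' @export
assign_zones <- function(genes, tads) {
  stopifnot(inherits(tads, "tad_map"))
  genes <- as.data.frame(genes)
  skipped <- genes$gene_id[is.na(genes$tss)]
  genes <- genes[!is.na(genes$tss) & genes$gene_id != tads$focal_id, ,
                 drop = FALSE]
  lo <- tads$tads$start[tads$flank_left]
  hi <- tads$tads$end[tads$flank_right]
  zone <- ifelse(genes$chrom != tads$chrom, "Trans",
                 ifelse(genes$tss >= lo & genes$tss < hi,
                        "Cis", "SameChromosome"))
  out <- data.frame(gene_id = genes$gene_id, zone = zone, row.names = NULL)
  attr(out, "diagnostics") <- if (length(skipped))
    sprintf("gene %s skipped: missing TSS", skipped) else character(0)
  out
}

#' Test for positional (zone) effects on fold changes
#'
#' Summarizes log2 fold changes by zone and delegates the pairwise
#' Mann-Whitney and global ANOVA testing to [group_shift()]. Zones with
#' fewer than `min_n` genes are flagged and excluded from the tests.
#'
#' @param de A `"de_result"` table from [de_test()].
#' @param zones Output of [assign_zones()].
#' @param min_n Minimum genes per zone (default 5).
#' @return List with `medians`, `n` (per-zone counts), `tests`
#'   (the [group_shift()] output), and `excluded_zones`.
#' @export
zone_effect_test <- function(de, zones, min_n = 5) {
  m <- merge(as.data.frame(de), zones, by.x = "feature", by.y = "gene_id")
  m <- m[m$call != "filtered" & !is.na(m$log2FC), , drop = FALSE]
  n <- table(m$zone)
  keep <- names(n)[n >= min_n]
  excluded <- setdiff(names(n), keep)
  if (length(keep) < 2L)
    input_error("fewer than two zones with enough genes for testing")
  mk <- m[m$zone %in% keep, , drop = FALSE]
  list(medians = tapply(m$log2FC, m$zone, stats::median),
       n = n,
       tests = group_shift(mk$log2FC, mk$zone),
       excluded_zones = excluded)
}

#' Digital test for a cis-acting regulator
#'
#' Asks whether significant same-direction genes are enriched in the `Cis`
#' zone: a two-sided Fisher exact test on the 2x2 table of
#' significant-same-direction status versus Cis membership. The odds ratio
#' is the sample cross-product ratio, with a Haldane correction of 0.5 added
#' to every cell when any cell is zero.
#'
#' @param de A `"de_result"` table.
#' @param zones Output of [assign_zones()].
#' @param direction `"up"` (activator) or `"down"` (repressor): the
#'   direction genes move when the regulator is *depleted* is the opposite;
#'   here `direction` names the DE call counted as a responsive gene.
#' @return List with `table` (2x2), `odds_ratio`, `p`.
#' @export
digital_cis_test <- function(de, zones, direction = c("down", "up")) {
  direction <- match.arg(direction)
  m <- merge(as.data.frame(de), zones, by.x = "feature", by.y = "gene_id")
  m <- m[m$call != "filtered", , drop = FALSE]
  if (!any(m$zone == "Cis")) input_error("no genes in the Cis zone")
  sig <- m$call == direction
  if (!any(sig)) input_error("no significant genes in the requested direction")
  cis <- m$zone == "Cis"
  tab <- matrix(c(sum(sig & cis), sum(sig & !cis),
                  sum(!sig & cis), sum(!sig & !cis)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("sig", "not_sig"), c("Cis", "elsewhere")))
  h <- if (any(tab == 0)) 0.5 else 0
  or <- ((tab[1, 1] + h) * (tab[2, 2] + h)) /
    ((tab[1, 2] + h) * (tab[2, 1] + h))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(table = tab, odds_ratio = or, p = p)
}

#' Chi-squared comparison of contact-interval counts
#'
#' Compares the fraction of contacts (e.g. UMIs) falling in a quantified
#' genomic interval between two conditions with a Pearson chi-squared test
#' on the 2x2 in-interval/out-of-interval table, df = 1, no continuity
#' correction.
#'
#' @param in1,total1 In-interval and total counts, condition 1.
#' @param in2,total2 Same for condition 2.
#' @return List with `statistic`, `p`, `table`, and `warning` (`NA` or a
#'   message when an expected cell is below 1 or a margin is degenerate).
#' @export
contact_interval_test <- function(in1, total1, in2, total2) {
  if (any(c(in1, total1, in2, total2) < 0) || in1 > total1 || in2 > total2)
    input_error("counts must satisfy 0 <= in <= total")
  tab <- matrix(c(in1, total1 - in1, in2, total2 - in2), nrow = 2,
                byrow = TRUE,
                dimnames = list(c("cond1", "cond2"), c("in", "out")))
  warn <- NA_character_
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn <- "degenerate margin: statistic set to 0"
    return(list(statistic = 0, p = 1, table = tab, warning = warn))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 1)) warn <- "expected cell count below 1"
  list(statistic = unname(ct$statistic), p = ct$p.value, table = tab,
       warning = warn)
}
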