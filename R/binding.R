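#' Composite binding score from peak evidence
#'
#' Summarizes per-gene binding-site evidence ("number, strength and
#' confidence") as `sum over peaks of signal * min(-log10 p, 10)`. Genes in
#' `genes` without peaks score 0 (unbound).
#'
#' @param evidence `data.frame` of peaks: `gene_id`, `signal` (>= 0),
#'   `p` (in (0, 1]).
#' @param genes Optional character vector of all scored genes; defaults to
#'   the genes present in `evidence`.
#' @param cap Cap on `-log10 p` (default 10).
#' @return Named numeric vector of scores.
#' @export
score_binding <- function(evidence, genes = NULL, cap = 10) {
  evidence <- as.data.frame(evidence)
  if (nrow(evidence) > 0) {
    if (any(evidence$signal < 0)) input_error("peak signal must be >= 0")
    if (any(evidence$p <= 0 | evidence$p > 1))
      input_error("peak p-values must lie in (0, 1]")
  }
  genes <- genes %||% unique(evidence$gene_id)
  sc <- stats::setNames(numeric(length(genes)), genes)
  if (nrow(evidence) > 0) {
    contrib <- evidence$signal * pmin(-log10(evidence$p), cap)
    agg <- tapply(contrib, evidence$gene_id, sum)
    sc[names(agg)] <- agg
  }
  sc
}

#' Assign genes to binding-confidence tiers
#'
#' Bound genes (score > 0) are split into `K` tiers at empirical score
#' quantiles (tier K = highest confidence); tied scores go to the lower
#' tier. Unbound genes get tier 0. When fewer distinct groups than `K` are
#' possible, `K` is reduced with a warning.
#'
#' @param scores Named numeric vector from [score_binding()].
#' @param K Number of tiers for bound genes (default 4).
#' @return `data.frame` with `gene_id`, `tier` (integer, 0 = unbound).
#' @export
assign_tiers <- function(scores, K = 4) {
  if (K < 2) input_error("K must be >= 2")
  tier <- stats::setNames(integer(length(scores)), names(scores))
  bound <- scores > 0
  nb <- sum(bound)
  if (nb > 0) {
    if (nb < K) {
      warning(sprintf("only %d bound genes: reducing K from %d", nb, K))
      K <- nb
    }
    r <- rank(scores[bound], ties.method = "min")
    tr <- as.integer(ceiling(r * K / nb))
    collapsed <- sort(unique(tr))
    if (length(collapsed) < K)
      warning("tied scores collapsed some tiers")
    tier[bound] <- match(tr, collapsed)
  }
  data.frame(gene_id = names(scores), tier = unname(tier), row.names = NULL)
}

#' Expression-matched control sets per tier
#'
#' Bins all genes into `n_bins` expression quantile bins, then, for each
#' tier of bound genes, samples (with a fixed seed) unbound genes matching
#' the tier's bin histogram. Bins where a tier has targets but no unbound
#' genes are dropped with a warning; bins with too few controls contribute
#' all they have, with a warning.
#'
#' @param tiers Output of [assign_tiers()].
#' @param expression Named numeric baseline expression for all genes.
#' @param n_bins Number of expression bins (default 10, i.e. deciles).
#' @param seed RNG seed for the sampling.
#' @return Named list (one element per tier >= 1) of control gene-id vectors.
#' @export
matched_controls <- function(tiers, expression, n_bins = 10, seed = 1) {
  expression <- expression[tiers$gene_id]
  if (anyNA(expression))
    input_error("baseline expression required for every gene")
  br <- unique(stats::quantile(expression, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(expression, breaks = br, include.lowest = TRUE, labels = FALSE)
  unbound <- split(tiers$gene_id[tiers$tier == 0L], bin[tiers$tier == 0L])
  out <- list()
  with_seed(seed, {
    for (k in sort(setdiff(unique(tiers$tier), 0L))) {
      in_tier <- tiers$tier == k
      want <- table(bin[in_tier])
      ctrl <- character(0)
      for (b in names(want)) {
        pool <- unbound[[b]] %||% character(0)
        n <- want[[b]]
        if (length(pool) == 0L) {
          warning(sprintf("tier %d: expression bin %s has no unbound genes; dropped",
                          k, b))
        } else if (length(pool) < n) {
          warning(sprintf("tier %d: expression bin %s has only %d of %d controls",
                          k, b, length(pool), n))
          ctrl <- c(ctrl, pool)
        } else {
          ctrl <- c(ctrl, sample(pool, n))
        }
      }
      out[[as.character(k)]] <- ctrl
    }
  })
  out
}

#' Tiered downregulation trend test
#'
#' Tests whether higher binding-confidence tiers shift fold changes further:
#' a Mann-Whitney test of each tier against tier 0 (unbound) and a Spearman
#' correlation between tier index and log2 fold change over all genes
#' (tie-corrected approximate p).
#'
#' @param tiers Output of [assign_tiers()].
#' @param de A `"de_result"` table from [de_test()].
#' @param min_n Minimum genes per tier to test (default 5).
#' @return List with `per_tier` (`data.frame`: `tier`, `n`, `median_lfc`,
#'   `p_vs_tier0`), `rho`, `rho_p`.
#' @export
tier_trend_test <- function(tiers, de, min_n = 5) {
  m <- merge(tiers, as.data.frame(de), by.x = "gene_id", by.y = "feature")
  m <- m[m$call != "filtered" & !is.na(m$log2FC), , drop = FALSE]
  n <- table(m$tier)
  populated <- names(n)[n >= min_n]
  if (length(populated) < 2L) input_error("need >= 2 populated tiers")
  base <- m$log2FC[m$tier == 0L]
  per <- lapply(sort(as.integer(setdiff(populated, "0"))), function(k) {
    x <- m$log2FC[m$tier == k]
    p <- if (length(base) >= 2L) suppressWarnings(
      stats::wilcox.test(x, base, exact = FALSE, correct = FALSE)$p.value)
    else NA_real_
    data.frame(tier = k, n = length(x), median_lfc = stats::median(x),
               p_vs_tier0 = p)
  })
  ct <- suppressWarnings(
    stats::cor.test(m$tier, m$log2FC, method = "spearman", exact = FALSE))
  list(per_tier = do.call(rbind, per),
       rho = unname(ct$estimate), rho_p = ct$p.value)
}

#' RIP enrichment call
#'
#' Runs the standard differential test with the IP fraction as the treated
#' condition; enriched genes are those called `up` under the thresholds.
#'
#' @param ip_counts,input_counts Count matrices (features x replicates)
#'   with shared rownames.
#' @param thresholds A [de_thresholds()].
#' @return List with `de` (the full `"de_result"`) and `enriched`
#'   (character vector of gene ids).
#' @export
rip_enrichment <- function(ip_counts, input_counts,
                           thresholds = de_thresholds()) {
  ip <- as.matrix(ip_counts); inp <- as.matrix(input_counts)
  if (!identical(rownames(ip), rownames(inp)))
    input_error("IP and input matrices must share features")
  colnames(ip) <- paste0("ip_", seq_len(ncol(ip)))
  colnames(inp) <- paste0("input_", seq_len(ncol(inp)))
  ct <- counts_table(cbind(inp, ip),
                     c(rep("input", ncol(inp)), rep("ip", ncol(ip))))
  de <- de_test(ct, thresholds, control = "input", treated = "ip")
  list(de = de, enriched = de$feature[de$call == "up"])
}

#' Promoter-overlap fraction of binding peaks
#'
#' The share of genomic peaks overlapping gene promoters, as a fraction and
#' a rounded percentage.
#'
#' @param n_promoter_peaks Number of peaks overlapping a promoter.
#' @param n_peaks Total number of peaks (> 0).
#' @return List with `fraction` and `percent` (rounded to integer).
#' @export
peak_promoter_fraction <- function(n_promoter_peaks, n_peaks) {
  assert_scalar_number(n_peaks, "n_peaks", lower = 0, strict_lower = TRUE)
  assert_scalar_number(n_promoter_peaks, "n_promoter_peaks", lower = 0,
                       upper = n_peaks)
  f <- n_promoter_peaks / n_peaks
  list(fraction = f, percent = as.integer(round(100 * f)))
}
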