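#' Differential-expression thresholds
#'
#' The decision rule applied throughout: a feature is called differentially
#' expressed when the BH-adjusted p-value is below `padj_cutoff` and the
#' absolute log2 fold change exceeds `lfc_cutoff`. The default
#' `lfc_cutoff = 0.41` corresponds to a minimum detectable change of
#' `(2^0.41 - 1) * 100` which rounds to 33%. Features with mean normalized
#' count below `min_mean` or exonic length below `min_length` (when lengths
#' are available) are filtered before testing.
#'
#' @param padj_cutoff Adjusted p-value cutoff (default 0.05).
#' @param lfc_cutoff Absolute log2 fold-change cutoff (default 0.41).
#' @param min_mean Minimum mean normalized count (default 5).
#' @param min_length Minimum exonic length in nt (default 200).
#' @param pseudocount Pseudocount added to normalized means/values (default 1).
#' @return A list of class `"de_thresholds"`.
#' @export
de_thresholds <- function(padj_cutoff = 0.05, lfc_cutoff = 0.41,
                          min_mean = 5, min_length = 200, pseudocount = 1) {
  for (v in c(padj_cutoff, lfc_cutoff, min_mean, min_length, pseudocount))
    assert_scalar_number(v, "threshold", lower = 0)
  if (padj_cutoff <= 0 || lfc_cutoff <= 0)
    input_error("cutoffs must be positive")
  structure(list(padj_cutoff = padj_cutoff, lfc_cutoff = lfc_cutoff,
                 min_mean = min_mean, min_length = min_length,
                 pseudocount = pseudocount),
            class = "de_thresholds")
}

#' Minimum detectable percent change implied by a log2 fold-change cutoff
#'
#' @param lfc_cutoff Absolute log2 fold-change cutoff.
#' @return Percent change, `(2^lfc_cutoff - 1) * 100`.
#' @export
min_detectable_change <- function(lfc_cutoff = 0.41) {
  assert_scalar_number(lfc_cutoff, "lfc_cutoff", lower = 0, strict_lower = TRUE)
  (2^lfc_cutoff - 1) * 100
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) input_error("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Vectorized two-sided Welch t-test on each row of x (group1) vs y (group2).
# Degenerate convention: both groups constant and equal -> p = 1; both
# constant but different -> p = 0.
welch_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0 & m1 == m2] <- 1
  p[se2 == 0 & m1 != m2] <- 0
  p
}

#' Two-condition differential expression test
#'
#' Normalizes by median-of-ratios size factors, computes
#' `log2FC = log2((mean_norm_treated + c) / (mean_norm_control + c))`,
#' tests each feature with a two-sided Welch t-test on `log2(norm + c)`,
#' adjusts p-values with Benjamini-Hochberg over the features passing the
#' expression/length filters, and calls features by the thresholds.
#'
#' @param counts A [counts_table()] with exactly two conditions.
#' @param thresholds A [de_thresholds()] object.
#' @param control,treated Condition labels; by default the first label in
#'   sample order is control, the other treated.
#' @return A `data.frame` of class `"de_result"` with columns `feature`,
#'   `baseMean`, `log2FC`, `p`, `padj`, `call`
#'   (`up` / `down` / `ns` / `filtered`).
#' @export
de_test <- function(counts, thresholds = de_thresholds(),
                    control = NULL, treated = NULL) {
  stopifnot(inherits(counts, "counts_table"))
  cond <- counts$condition
  levs <- unique(cond)
  if (length(levs) != 2L) input_error("exactly two conditions required")
  control <- control %||% levs[1]
  treated <- treated %||% setdiff(levs, control)
  if (sum(cond == control) < 2L || sum(cond == treated) < 2L)
    input_error("each condition needs at least 2 replicates")
  norm <- normalize_counts(counts)
  cc <- norm[, cond == control, drop = FALSE]
  tc <- norm[, cond == treated, drop = FALSE]
  base_mean <- rowMeans(norm)
  c0 <- thresholds$pseudocount
  lfc <- log2((rowMeans(tc) + c0) / (rowMeans(cc) + c0))
  p <- welch_rows(log2(cc + c0), log2(tc + c0))

  keep <- base_mean >= thresholds$min_mean & rowSums(counts$counts) > 0
  if (!is.null(counts$lengths))
    keep <- keep & counts$lengths >= thresholds$min_length
  padj <- rep(NA_real_, length(p))
  padj[keep] <- bh_adjust(p[keep])
  call <- rep("filtered", length(p))
  call[keep] <- "ns"
  sig <- keep & !is.na(padj) & padj < thresholds$padj_cutoff &
    abs(lfc) > thresholds$lfc_cutoff
  call[sig & lfc > 0] <- "up"
  call[sig & lfc < 0] <- "down"
  out <- data.frame(feature = rownames(norm), baseMean = base_mean,
                    log2FC = lfc, p = p, padj = padj, call = call,
                    row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Group-shift tests over labeled values
#'
#' Pairwise two-sided Mann-Whitney tests between classes (exact when the
#' smaller group has at most `exact_max` observations and there are no ties,
#' otherwise the normal approximation with tie correction) plus a global
#' one-way ANOVA over the same values, and per-class medians.
#'
#' @param values Numeric vector (typically log2 fold changes).
#' @param classes Class label per value (>= 2 classes, each n >= 2).
#' @param exact_max Largest group size for which the exact Mann-Whitney
#'   distribution is used (default 8).
#' @return List with `pairwise` (`data.frame`: `class1`, `class2`, `U`, `p`),
#'   `anova_p`, and `medians` (named vector).
#' @export
group_shift <- function(values, classes, exact_max = 8) {
  ok <- !is.na(values) & !is.na(classes)
  values <- values[ok]; classes <- as.character(classes[ok])
  tab <- table(classes)
  if (length(tab) < 2L) input_error("at least two classes required")
  if (any(tab < 2L)) input_error("each class needs n >= 2")
  levs <- names(tab)
  pairs <- utils::combn(levs, 2)
  res <- data.frame(class1 = pairs[1, ], class2 = pairs[2, ],
                    U = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    x <- values[classes == pairs[1, i]]
    y <- values[classes == pairs[2, i]]
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- min(length(x), length(y)) <= exact_max && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = FALSE))
    res$U[i] <- unname(wt$statistic)
    res$p[i] <- wt$p.value
  }
  av <- stats::anova(stats::lm(values ~ factor(classes)))
  list(pairwise = res,
       anova_p = av[["Pr(>F)"]][1],
       medians = vapply(levs, function(l) stats::median(values[classes == l]),
                        numeric(1)))
}

#' Concordance between two differential-expression gene sets
#'
#' For each direction, the share of set A's genes also regulated in the same
#' direction in set B, as a rounded percentage of A, with a hypergeometric
#' enrichment p-value against a supplied universe size.
#'
#' @param a_up,a_down,b_up,b_down Character vectors of gene ids.
#' @param universe Universe size for the hypergeometric test (optional).
#' @return `data.frame` with one row per direction: `n_a`, `n_concordant`,
#'   `percent` (integer, `NA` and flagged when A is empty), `p_hyper`.
#' @export
overlap_stats <- function(a_up, a_down, b_up, b_down, universe = NULL) {
  one <- function(a, b, direction) {
    n_a <- length(unique(a))
    conc <- length(intersect(a, b))
    pct <- if (n_a == 0L) NA_integer_ else as.integer(round(100 * conc / n_a))
    p <- NA_real_
    if (!is.null(universe) && n_a > 0L) {
      nb <- length(unique(b))
      p <- stats::phyper(conc - 1, nb, universe - nb, n_a, lower.tail = FALSE)
    }
    data.frame(direction = direction, n_a = n_a, n_concordant = conc,
               percent = pct, p_hyper = p,
               flagged = n_a == 0L)
  }
  rbind(one(a_up, b_up, "up"), one(a_down, b_down, "down"))
}
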