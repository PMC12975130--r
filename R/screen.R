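#' Screen for candidate cis-acting lncRNAs
#'
#' A (lncRNA, target) pair is a candidate when the lncRNA gene span overlaps
#' a regulatory element whose confidence score is at least `min_confidence`,
#' and in at least one condition both the lncRNA and the element's target
#' are differentially expressed ("concomitantly": same condition). The
#' `concordant` flag records whether some supporting condition moves both
#' genes in the same direction; with `require_concordant = TRUE` only such
#' pairs are returned.
#'
#' @param lnc_genes `data.frame` of lncRNA loci: `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @param elements `data.frame` of regulatory elements: `element_id`,
#'   `chrom`, `start`, `end`, `score`, `targets` (comma-joined gene ids or a
#'   list column).
#' @param de_tables Named list of `"de_result"` tables, one per condition.
#' @param min_confidence Minimum element score (default 1).
#' @param require_concordant Keep only direction-concordant pairs
#'   (default `FALSE`: concordance is reported as a flag).
#' @return `data.frame` with `lnc_id`, `element_id`, `target_id`,
#'   `n_conditions`, `conditions` (comma-joined), `concordant`. Empty (with
#'   a warning) when the element table is empty.
#' @export
run_screen <- function(lnc_genes, elements, de_tables, min_confidence = 1,
                       require_concordant = FALSE) {
  lnc_genes <- as.data.frame(lnc_genes)
  elements <- as.data.frame(elements)
  if (nrow(elements) == 0L) {
    warning("empty element table: no candidates")
    return(empty_candidates())
  }
  if (is.null(names(de_tables)) || any(names(de_tables) == ""))
    input_error("`de_tables` must be a named list (one table per condition)")
  if (is.list(elements$targets))
    elements$targets <- vapply(elements$targets, paste, character(1),
                               collapse = ",")
  calls <- lapply(de_tables, function(de) {
    de <- as.data.frame(de)
    stats::setNames(de$call, de$feature)
  })
  out <- list()
  for (i in seq_len(nrow(lnc_genes))) {
    g <- lnc_genes[i, ]
    ov <- elements$chrom == g$chrom & elements$score >= min_confidence &
      overlap_width(g$start, g$end, elements$start, elements$end) > 0
    for (j in which(ov)) {
      targets <- strsplit(elements$targets[j], ",", fixed = TRUE)[[1]]
      targets <- setdiff(trimws(targets), g$gene_id)
      for (tg in targets) {
        supp <- character(0); conc <- logical(0)
        for (cn in names(calls)) {
          cl <- calls[[cn]]
          lc <- cl[g$gene_id]; tc <- cl[tg]
          if (!is.na(lc) && !is.na(tc) &&
              lc %in% c("up", "down") && tc %in% c("up", "down")) {
            supp <- c(supp, cn)
            conc <- c(conc, lc == tc)
          }
        }
        if (length(supp) > 0L)
          out[[length(out) + 1L]] <- data.frame(
            lnc_id = g$gene_id, element_id = elements$element_id[j],
            target_id = tg, n_conditions = length(supp),
            conditions = paste(supp, collapse = ","),
            concordant = any(conc))
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_candidates()
  if (require_concordant) res <- res[res$concordant, , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_candidates <- function() {
  data.frame(lnc_id = character(0), element_id = character(0),
             target_id = character(0), n_conditions = integer(0),
             conditions = character(0), concordant = logical(0))
}

#' Rank screen candidates
#'
#' Orders candidates by number of supporting conditions (descending), then
#' lncRNA expression (mean `baseMean` across conditions, descending), with a
#' stable lexicographic tie-break on (lncRNA id, target id).
#'
#' @param candidates Output of [run_screen()] (nonempty).
#' @param de_tables The same named list of DE tables used for the screen.
#' @return The candidates, reordered, with an added `lnc_base_mean` column.
#' @export
rank_candidates <- function(candidates, de_tables) {
  if (nrow(candidates) == 0L) input_error("no candidates to rank")
  bm <- rowMeans(do.call(cbind, lapply(de_tables, function(de) {
    de <- as.data.frame(de)
    stats::setNames(de$baseMean, de$feature)[candidates$lnc_id]
  })), na.rm = TRUE)
  candidates$lnc_base_mean <- unname(bm)
  o <- order(-candidates$n_conditions, -candidates$lnc_base_mean,
             candidates$lnc_id, candidates$target_id)
  out <- candidates[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
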