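#' Construct a gene model
#'
#' A gene model holds the exon structure of all annotated isoforms of one
#' gene. Coordinates are 0-based half-open throughout the package; conversion
#' to/from the 1-based closed GTF convention happens only in the I/O layer.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param isoforms A list of exon tables, one per isoform; each a
#'   `data.frame` with integer columns `start` and `end` (0-based half-open).
#'   Exons within an isoform must be non-overlapping.
#' @return An object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, chrom, strand, isoforms) {
  if (!strand %in% c("+", "-")) input_error("strand must be '+' or '-'")
  if (!is.list(isoforms) || length(isoforms) == 0L)
    input_error("`isoforms` must be a non-empty list of exon tables")
  isoforms <- lapply(isoforms, function(ex) {
    ex <- as.data.frame(ex)[, c("start", "end")]
    if (any(ex$end <= ex$start)) input_error("empty exon interval")
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1] < ex$end[-nrow(ex)]))
      input_error("overlapping exons within an isoform")
    rownames(ex) <- NULL
    ex
  })
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, isoforms = isoforms),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  sp <- gene_span(x)
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d isoform(s)\n",
              x$gene_id, x$chrom, sp[1], sp[2], x$strand, length(x$isoforms)))
  invisible(x)
}

# Merged span [min start, max end) over all isoforms.
gene_span <- function(model) {
  s <- min(vapply(model$isoforms, function(e) min(e$start), numeric(1)))
  e <- max(vapply(model$isoforms, function(e) max(e$end), numeric(1)))
  c(s, e)
}

# Exon union across isoforms as merged intervals.
exon_union <- function(model) {
  allex <- do.call(rbind, model$isoforms)
  merge_intervals(allex$start, allex$end)
}

#' Region classes of the SNHG partition
#'
#' Ordered levels used in partition tables: the snoRNA body, then the parts
#' of its intron transcriptionally upstream (`Pre`) and downstream (`Post`),
#' the exon union, and snoRNA-free introns.
#' @export
REGION_CLASSES <- c("Exon", "Pre", "Snorna", "Post", "OtherIntron")

#' Partition one snoRNA host gene into quantifiable regions
#'
#' Splits the merged span of a host gene into disjoint labeled segments:
#' `Exon` (union of exons over all isoforms), `Snorna` (each hosted snoRNA
#' body), `Pre` / `Post` (the parts of a snoRNA-containing merged intron
#' transcriptionally upstream / downstream of the snoRNA, following the host
#' strand), and `OtherIntron` (merged introns without snoRNAs). When one
#' merged intron hosts several snoRNAs, the gap between adjacent snoRNAs is
#' split at its midpoint, each half attributed to the nearer snoRNA.
#'
#' @param model A [gene_model()].
#' @param snos A `data.frame` of hosted snoRNAs with columns `sno_id`,
#'   `start`, `end` (0-based half-open) and optionally `class`.
#' @return An object of class `"snhg_partition"`: a `data.frame` with columns
#'   `host_id`, `chrom`, `strand`, `start`, `end`, `region`, `sno_id`
#'   (`NA` for segments not tied to a snoRNA), ordered by `start`.
#'   If a snoRNA overlaps the exon union the host cannot be partitioned and
#'   an object of class `"snhg_excluded"` is returned, carrying a
#'   `"diagnostic"` attribute describing the problem.
#' @seealso [partition_all()] for many hosts with collected diagnostics.
#' @export
partition_snhg <- function(model, snos) {
  stopifnot(inherits(model, "gene_model"))
  snos <- as.data.frame(snos)
  if (nrow(snos) == 0L) input_error("no snoRNAs supplied for host")
  if (any(snos$end <= snos$start)) input_error("empty snoRNA interval")
  sp <- gene_span(model)
  if (any(snos$start < sp[1] | snos$end > sp[2]))
    input_error(sprintf("snoRNA outside merged span of host %s", model$gene_id))
  ex <- exon_union(model)

  # snoRNA overlapping any exon: the scheme presumes intronic snoRNAs.
  for (i in seq_len(nrow(snos))) {
    if (any(overlap_width(snos$start[i], snos$end[i], ex$start, ex$end) > 0L)) {
      return(structure(list(), class = "snhg_excluded",
                       diagnostic = sprintf(
                         "host %s excluded: snoRNA %s overlaps the exon union",
                         model$gene_id, snos$sno_id[i])))
    }
  }

  introns <- interval_gaps(ex, sp[1], sp[2])
  seg <- list()
  add <- function(start, end, region, sno_id = NA_character_) {
    if (end > start)
      seg[[length(seg) + 1L]] <<- data.frame(
        start = start, end = end, region = region, sno_id = sno_id)
  }
  for (i in seq_len(nrow(ex))) add(ex$start[i], ex$end[i], "Exon")

  plus <- model$strand == "+"
  for (i in seq_len(nrow(introns))) {
    is_ <- introns$start[i]; ie <- introns$end[i]
    inside <- which(snos$start >= is_ & snos$end <= ie)
    if (length(inside) == 0L) {
      add(is_, ie, "OtherIntron")
      next
    }
    s <- snos[inside, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    # cut points: intron edges, snoRNA edges, midpoints of inter-snoRNA gaps
    for (k in seq_len(nrow(s)))
      add(s$start[k], s$end[k], "Snorna", s$sno_id[k])
    # flank before first snoRNA and after last
    add(is_, s$start[1], if (plus) "Pre" else "Post", s$sno_id[1])
    n <- nrow(s)
    add(s$end[n], ie, if (plus) "Post" else "Pre", s$sno_id[n])
    if (n > 1L) {
      for (k in seq_len(n - 1L)) {
        gs <- s$end[k]; ge <- s$start[k + 1L]
        # split at the midpoint; an odd gap's extra base goes to the Post
        # half (in transcription orientation), keeping the rule exactly
        # symmetric under coordinate reflection + strand flip
        mid <- if (plus) ge - (ge - gs) %/% 2L else gs + (ge - gs) %/% 2L
        add(gs, mid, if (plus) "Post" else "Pre", s$sno_id[k])
        add(mid, ge, if (plus) "Pre" else "Post", s$sno_id[k + 1L])
      }
    }
  }
  out <- do.call(rbind, seg)
  out <- out[order(out$start), , drop = FALSE]
  out <- data.frame(host_id = model$gene_id, chrom = model$chrom,
                    strand = model$strand, out, row.names = NULL)
  class(out) <- c("snhg_partition", "data.frame")
  out
}

#' Partition all snoRNA host genes
#'
#' @param models A list of [gene_model()] objects (unique gene ids).
#' @param snos A `data.frame` with columns `sno_id`, `host_id`, `start`,
#'   `end` and optionally `class`; each row one snoRNA.
#' @return A list with `partitions` (named list of `"snhg_partition"`
#'   tables, ordered by gene id; hosts with no snoRNA or failing checks are
#'   absent) and `diagnostics` (character vector of messages).
#' @export
partition_all <- function(models, snos) {
  ids <- vapply(models, function(m) m$gene_id, character(1))
  if (anyDuplicated(ids)) input_error("duplicate gene ids in `models`")
  snos <- as.data.frame(snos)
  diagnostics <- character(0)
  unknown <- setdiff(unique(snos$host_id), ids)
  if (length(unknown))
    input_error(sprintf("snoRNA host(s) not in models: %s",
                        paste(unknown, collapse = ", ")))
  hosts <- sort(intersect(ids, unique(snos$host_id)))
  parts <- list()
  for (h in hosts) {
    p <- partition_snhg(models[[match(h, ids)]],
                        snos[snos$host_id == h, , drop = FALSE])
    if (inherits(p, "snhg_excluded")) {
      diagnostics <- c(diagnostics, attr(p, "diagnostic"))
    } else {
      parts[[h]] <- p
    }
  }
  list(partitions = parts, diagnostics = diagnostics)
}
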