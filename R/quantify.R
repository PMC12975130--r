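#' Construct a counts table
#'
#' The package's count container: an integer matrix of features by samples
#' with a condition label per sample and optional feature lengths.
#'
#' @param counts Integer matrix (features x samples) with dimnames.
#' @param condition Character vector of condition labels, one per sample
#'   (recycled names from `colnames(counts)` if unnamed).
#' @param lengths Optional numeric vector of feature lengths in nt, named by
#'   feature.
#' @return An object of class `"counts_table"`.
#' @export
counts_table <- function(counts, condition, lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    input_error("`counts` must have feature rownames and sample colnames")
  if (any(counts < 0)) input_error("counts must be non-negative")
  if (length(condition) != ncol(counts))
    input_error("one condition label per sample required")
  condition <- stats::setNames(as.character(condition), colnames(counts))
  if (!is.null(lengths)) {
    lengths <- lengths[rownames(counts)]
    if (anyNA(lengths) || any(lengths <= 0))
      input_error("feature lengths must be positive and cover all features")
  }
  structure(list(counts = counts, condition = condition, lengths = lengths),
            class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat(sprintf("<counts_table> %d features x %d samples; conditions: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s (n=%d)", names(table(x$condition)),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Assign read intervals to partition regions
#'
#' Each read overlapping a host's merged span is counted in exactly one
#' region class of that host: the class covering the majority of the read's
#' host-overlapping bases. Ties are broken by the priority
#' `Snorna > Pre > Post > Exon > OtherIntron` (favoring the shortest,
#' biologically focal class). Reads overlapping no host are ignored; reads
#' on chromosomes absent from the partition set are tallied in diagnostics.
#' A read overlapping several hosts is assigned to the host with the larger
#' base overlap (ties by gene id).
#'
#' @param reads `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `sample`, and optionally `strand`.
#' @param partitions Named list of `"snhg_partition"` tables
#'   (see [partition_all()]).
#' @param condition Named character vector mapping sample ids to conditions;
#'   defaults to one condition `"all"`.
#' @param stranded If `TRUE`, only reads matching the host strand count.
#' @return A [counts_table()] with one row per `host:region` present in the
#'   partitions (zero rows included), attribute `"diagnostics"` holding the
#'   tally of ignored reads.
#' @export
assign_reads <- function(reads, partitions, condition = NULL, stranded = FALSE) {
  reads <- as.data.frame(reads)
  if (nrow(reads) > 0 && any(reads$end <= reads$start))
    input_error("read intervals must have positive length")
  seg <- do.call(rbind, lapply(partitions, as.data.frame))
  if (is.null(seg) || nrow(seg) == 0L) input_error("empty partition set")
  rownames(seg) <- NULL
  region_ids <- unique(paste(seg$host_id, seg$region, sep = ":"))
  samples <- sort(unique(as.character(reads$sample)))
  if (length(samples) == 0L) samples <- "s1"
  counts <- matrix(0L, nrow = length(region_ids), ncol = length(samples),
                   dimnames = list(region_ids, samples))
  n_unknown_chrom <- 0L; n_outside <- 0L

  if (nrow(reads) > 0L) {
    seg_gr <- GenomicRanges::GRanges(
      seg$chrom, IRanges::IRanges(seg$start + 1L, seg$end))
    read_gr <- GenomicRanges::GRanges(
      reads$chrom, IRanges::IRanges(reads$start + 1L, reads$end))
    known <- as.character(reads$chrom) %in% unique(seg$chrom)
    n_unknown_chrom <- sum(!known)
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(read_gr, seg_gr, ignore.strand = TRUE))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (stranded && "strand" %in% names(reads)) {
      ok <- as.character(reads$strand)[qh] == seg$strand[sh]
      qh <- qh[ok]; sh <- sh[ok]
    }
    if (length(qh)) {
      w <- overlap_width(reads$start[qh], reads$end[qh],
                         seg$start[sh], seg$end[sh])
      host <- seg$host_id[sh]; region <- seg$region[sh]
      # per read: per-host total, pick host, then majority class with priority
      key_host <- paste(qh, host, sep = "\r")
      host_tot <- tapply(w, key_host, sum)
      key_class <- paste(qh, host, region, sep = "\r")
      class_tot <- tapply(w, key_class, sum)
      ck <- do.call(rbind, strsplit(names(class_tot), "\r", fixed = TRUE))
      cdf <- data.frame(read = as.integer(ck[, 1]), host = ck[, 2],
                        region = ck[, 3], w = as.numeric(class_tot))
      hk <- do.call(rbind, strsplit(names(host_tot), "\r", fixed = TRUE))
      hdf <- data.frame(read = as.integer(hk[, 1]), host = hk[, 2],
                        w = as.numeric(host_tot))
      # choose host per read: max overlap, tie -> smaller gene id
      hdf <- hdf[order(hdf$read, -hdf$w, hdf$host), ]
      hsel <- hdf[!duplicated(hdf$read), c("read", "host")]
      cdf <- merge(cdf, hsel, by = c("read", "host"))
      prio <- match(cdf$region, c("Snorna", "Pre", "Post", "Exon", "OtherIntron"))
      cdf <- cdf[order(cdf$read, -cdf$w, prio), ]
      csel <- cdf[!duplicated(cdf$read), ]
      rid <- paste(csel$host, csel$region, sep = ":")
      smp <- as.character(reads$sample)[csel$read]
      tab <- table(factor(rid, levels = region_ids),
                   factor(smp, levels = samples))
      counts <- counts + matrix(as.integer(tab), nrow = length(region_ids),
                                dimnames = list(region_ids, samples))
      assigned <- unique(csel$read)
      n_outside <- sum(known) - length(intersect(which(known), assigned))
    } else {
      n_outside <- sum(known)
    }
  }
  if (is.null(condition)) condition <- stats::setNames(rep("all", length(samples)), samples)
  lengths <- tapply(seg$end - seg$start,
                    paste(seg$host_id, seg$region, sep = ":"), sum)
  ct <- counts_table(counts, condition[samples],
                     lengths = stats::setNames(as.numeric(lengths), names(lengths)))
  attr(ct, "diagnostics") <- list(unknown_chrom = n_unknown_chrom,
                                  outside_hosts = n_outside)
  ct
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features (nonzero in
#' every sample) of the ratio of that feature's count to its geometric mean
#' across samples.
#'
#' @param counts A [counts_table()] or bare count matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "counts_table")) counts$counts else as.matrix(counts)
  use <- rowSums(m == 0) == 0
  if (!any(use)) stop("no feature with nonzero counts in all samples",
                      call. = FALSE)
  lm_ <- log(m[use, , drop = FALSE])
  geo <- rowMeans(lm_)
  sf <- apply(exp(lm_ - geo), 2, stats::median)
  stats::setNames(sf, colnames(m))
}

# Counts divided by size factors.
normalize_counts <- function(counts) {
  m <- if (inherits(counts, "counts_table")) counts$counts else as.matrix(counts)
  sweep(m, 2, size_factors(m), "/")
}

#' Fragments per kilobase per million assigned reads
#'
#' `fpkm = count * 1e9 / (length * total)` with `total` the number of
#' assigned reads in that sample.
#'
#' @param counts Feature x sample count matrix (or [counts_table()]).
#' @param lengths Feature lengths in nt (taken from the table if absent).
#' @param totals Per-sample totals; defaults to column sums.
#' @return Numeric matrix of FPKM values.
#' @export
fpkm <- function(counts, lengths = NULL, totals = NULL) {
  if (inherits(counts, "counts_table")) {
    lengths <- lengths %||% counts$lengths
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (is.null(lengths)) input_error("feature lengths required for FPKM")
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  totals <- totals %||% colSums(counts)
  if (any(lengths <= 0) || anyNA(lengths)) input_error("lengths must be > 0")
  if (any(totals <= 0)) input_error("per-sample totals must be > 0")
  sweep(sweep(counts * 1e9, 1, lengths, "/"), 2, totals, "/")
}
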