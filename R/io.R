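# Standard-format I/O. GTF is 1-based closed and BED 0-based half-open on
# disk; all internal coordinates are 0-based half-open, and the conversion
# happens only here.

#' Load gene models from a GTF file
#'
#' Reads exon records (grouped by transcript, then gene) and converts the
#' 1-based closed GTF coordinates to the package's 0-based half-open
#' convention.
#'
#' @param path Path to a GTF file.
#' @return Named list of [gene_model()] objects (empty for an empty file).
#' @export
load_gene_models <- function(path) {
  if (!file.exists(path)) input_error(sprintf("no such file: %s", path))
  if (length(readLines(path, n = 1L)) == 0L) return(list())
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   input_error(sprintf("malformed GTF %s: %s", path,
                                       conditionMessage(e))))
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) return(list())
  df <- data.frame(gene_id = gr$gene_id,
                   transcript_id = gr$transcript_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  models <- lapply(split(df, df$gene_id), function(g) {
    gene_model(g$gene_id[1], g$chrom[1], g$strand[1],
               lapply(split(g[, c("start", "end")], g$transcript_id),
                      identity))
  })
  models[order(names(models))]
}

#' Write gene models to GTF
#'
#' @param models Named list of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    for (tx in seq_along(m$isoforms)) {
      ex <- m$isoforms[[tx]]
      attrs <- sprintf('gene_id "%s"; transcript_id "%s.%d";',
                       m$gene_id, m$gene_id, tx)
      lines <- c(lines, sprintf("%s\tsnhgtools\texon\t%d\t%d\t.\t%s\t.\t%s",
                                m$chrom, ex$start + 1L, ex$end, m$strand,
                                attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file as a 0-based half-open interval table
#'
#' @param path Path to a BED3/BED6 file.
#' @return `data.frame` with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing BED columns filled with defaults).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) input_error(sprintf("no such file: %s", path))
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) input_error(sprintf("malformed BED %s: %s", path,
                                            conditionMessage(e))))
  if (ncol(df) < 3L) input_error(sprintf("malformed BED %s: need >= 3 columns",
                                         path))
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(df)[seq_len(min(6L, ncol(df)))] <- cols[seq_len(min(6L, ncol(df)))]
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "*"
  df[, cols]
}

#' Write a BED6 file from a 0-based half-open interval table
#'
#' @param df `data.frame` with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  df <- as.data.frame(df)
  name <- if ("name" %in% names(df)) df$name else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$chrom, df$start, df$end,
                     name, score, strand), path)
  invisible(path)
}

#' Write an SNHG partition set as BED6 (region class in the name field)
#'
#' @param partitions Named list from [partition_all()].
#' @param path Output path.
#' @export
write_partition_bed <- function(partitions, path) {
  seg <- do.call(rbind, lapply(partitions, as.data.frame))
  write_bed(data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
                       name = paste(seg$host_id, seg$region,
                                    ifelse(is.na(seg$sno_id), ".",
                                           seg$sno_id), sep = "|"),
                       score = 0, strand = seg$strand), path)
}

#' Read narrowPeak binding evidence
#'
#' Converts the standard narrowPeak columns (`signalValue`, `pValue` as
#' -log10) into the per-peak evidence table used by [score_binding()]; the
#' peak's gene is taken from the `name` column.
#'
#' @param path Path to a narrowPeak file.
#' @return `data.frame` with `gene_id`, `signal`, `p`, plus coordinates.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) input_error(sprintf("no such file: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:10] <- c("chrom", "start", "end", "name", "score", "strand",
                       "signalValue", "pValue", "qValue", "peak")[1:ncol(df)]
  data.frame(gene_id = df$name, signal = df$signalValue,
             p = 10^(-df$pValue), chrom = df$chrom, start = df$start,
             end = df$end)
}

#' Write / read a counts table as TSV
#'
#' Tab-delimited with a header row of sample ids; the first column holds
#' feature ids, and a companion `<path>.design` TSV stores the sample
#' conditions (and `<path>.lengths` the feature lengths, when present).
#'
#' @param ct A [counts_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(ct, path) {
  stopifnot(inherits(ct, "counts_table"))
  df <- data.frame(feature = rownames(ct$counts), ct$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(ct$condition),
                                condition = unname(ct$condition)),
                     paste0(path, ".design"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(ct$lengths))
    utils::write.table(data.frame(feature = names(ct$lengths),
                                  length = unname(ct$lengths)),
                       paste0(path, ".lengths"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  design <- utils::read.table(paste0(path, ".design"), sep = "\t",
                              header = TRUE)
  lengths <- NULL
  if (file.exists(paste0(path, ".lengths"))) {
    lt <- utils::read.table(paste0(path, ".lengths"), sep = "\t",
                            header = TRUE)
    lengths <- stats::setNames(lt$length, lt$feature)
  }
  counts_table(m, design$condition[match(colnames(m), design$sample)],
               lengths = lengths)
}
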