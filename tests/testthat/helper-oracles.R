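# Independent brute-force oracles and small fixture builders. These
# re-derive expected results from first principles (per-base labeling,
# exhaustive enumeration, grid search) without touching the package's
# interval or statistics code paths.

# ---- random gene models ----------------------------------------------------

# Random small gene model: <= 5 isoforms, span <= 10 kb, exon breakpoints on
# a 10 nt lattice so exons never touch.
random_gene_model <- function(id = "g", max_iso = 5) {
  n_iso <- sample(seq_len(max_iso), 1)
  span <- sample(seq(2000, 10000, by = 500), 1)
  isoforms <- lapply(seq_len(n_iso), function(i) {
    n_ex <- sample(1:4, 1)
    cuts <- sort(sample(seq(0, span, by = 10), 2 * n_ex))
    data.frame(start = cuts[seq(1, 2 * n_ex, 2)],
               end = cuts[seq(2, 2 * n_ex, 2)])
  })
  gene_model(id, "chrT", sample(c("+", "-"), 1), isoforms)
}

# Exon-occupancy mask over the merged span, built by marking bases exon by
# exon (no interval merging).
exon_base_mask <- function(model) {
  allex <- do.call(rbind, model$isoforms)
  sp <- c(min(allex$start), max(allex$end))
  mask <- rep(FALSE, sp[2] - sp[1])
  for (k in seq_len(nrow(allex)))
    mask[(allex$start[k] - sp[1] + 1):(allex$end[k] - sp[1])] <- TRUE
  list(span = sp, mask = mask)
}

# Place snoRNAs inside intronic runs of a model; returns a sno data.frame
# (possibly several snoRNAs per intron) or NULL if no intron is wide enough.
random_snos_for <- function(model, max_per_intron = 2) {
  em <- exon_base_mask(model)
  r <- rle(em$mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  introns <- which(!r$values & r$lengths >= 120)
  if (length(introns) == 0) return(NULL)
  rows <- list()
  for (j in introns) {
    is_ <- em$span[1] + starts[j] - 1L
    ie <- em$span[1] + ends[j]
    n_s <- sample(seq_len(max_per_intron), 1)
    width <- 30L
    # fit n_s snoRNAs with >= 2 nt margins and gaps
    need <- n_s * width + (n_s + 1) * 3
    if (ie - is_ < need) n_s <- 1L
    slots <- sort(sample(seq(is_ + 2L, ie - width - 2L), n_s))
    while (n_s > 1 && any(diff(slots) < width + 3)) {
      n_s <- n_s - 1L
      slots <- slots[seq_len(n_s)]
    }
    for (s0 in slots)
      rows[[length(rows) + 1]] <- data.frame(
        sno_id = sprintf("s%d", length(rows) + 1), start = s0,
        end = s0 + width)
  }
  if (length(rows) == 0) NULL else do.call(rbind, rows)
}

# ---- per-base partition oracle --------------------------------------------

# Labels every base of the merged span by the partition rules: exon-union
# bases are Exon; a base inside a snoRNA is Snorna; intronic bases attach to
# the nearest snoRNA of their intron (inter-snoRNA gaps split at the
# midpoint, the odd base going to the Post half in transcription
# orientation), labeled Pre/Post by the host strand; snoRNA-free introns
# are OtherIntron.
oracle_base_labels <- function(model, snos) {
  em <- exon_base_mask(model)
  n <- length(em$mask)
  pos <- em$span[1] + seq_len(n) - 1L
  lab <- ifelse(em$mask, "Exon", NA_character_)
  sno_of <- rep(NA_character_, n)
  plus <- model$strand == "+"
  r <- rle(em$mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (j in which(!r$values)) {
    ib <- starts[j]:ends[j]
    is_ <- pos[ib[1]]; ie <- pos[ib[length(ib)]] + 1L
    s <- snos[snos$start >= is_ & snos$end <= ie, , drop = FALSE]
    if (nrow(s) == 0) { lab[ib] <- "OtherIntron"; next }
    s <- s[order(s$start), , drop = FALSE]
    nr <- nrow(s)
    for (bi in ib) {
      b <- pos[bi]
      k <- which(s$start <= b & b < s$end)
      if (length(k) == 1) {
        lab[bi] <- "Snorna"; sno_of[bi] <- s$sno_id[k]
      } else if (b < s$start[1]) {
        lab[bi] <- if (plus) "Pre" else "Post"; sno_of[bi] <- s$sno_id[1]
      } else if (b >= s$end[nr]) {
        lab[bi] <- if (plus) "Post" else "Pre"; sno_of[bi] <- s$sno_id[nr]
      } else {
        g <- max(which(s$end <= b))
        gs <- s$end[g]; ge <- s$start[g + 1]
        mid <- if (plus) ge - (ge - gs) %/% 2L else gs + (ge - gs) %/% 2L
        if (b < mid) {
          lab[bi] <- if (plus) "Post" else "Pre"; sno_of[bi] <- s$sno_id[g]
        } else {
          lab[bi] <- if (plus) "Pre" else "Post"; sno_of[bi] <- s$sno_id[g + 1]
        }
      }
    }
  }
  data.frame(pos = pos, label = lab, sno = sno_of,
             stringsAsFactors = FALSE)
}

# Expand an interval partition into per-base labels for comparison.
partition_base_labels <- function(p) {
  idx <- rep(seq_len(nrow(p)), p$end - p$start)
  data.frame(pos = unlist(lapply(seq_len(nrow(p)),
                                 function(i) p$start[i]:(p$end[i] - 1L))),
             label = p$region[idx],
             sno = p$sno_id[idx],
             stringsAsFactors = FALSE)
}

# ---- brute-force read assignment oracle -----------------------------------

# Per-read maximal-overlap assignment, recomputed with plain loops: for each
# read, overlap per segment, summed per class within each host; host with
# the larger total wins (tie: smaller id); class with the larger sum wins
# (tie: Snorna > Pre > Post > Exon > OtherIntron).
oracle_assign <- function(reads, partitions) {
  prio <- c(Snorna = 1, Pre = 2, Post = 3, Exon = 4, OtherIntron = 5)
  out <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    best_host <- NA_character_; best_tot <- 0; best_class <- NA_character_
    for (h in sort(names(partitions))) {
      p <- partitions[[h]]
      if (p$chrom[1] != reads$chrom[i]) next
      ov <- pmax(0, pmin(reads$end[i], p$end) - pmax(reads$start[i], p$start))
      tot <- sum(ov)
      if (tot > best_tot) {
        cls <- tapply(ov, p$region, sum)
        cls <- cls[cls > 0]
        cls <- cls[order(-cls, prio[names(cls)])]
        best_host <- h; best_tot <- tot; best_class <- names(cls)[1]
      }
    }
    out[i] <- if (is.na(best_host)) NA_character_ else
      paste(best_host, best_class, sep = ":")
  }
  out
}

# ---- statistics oracles ----------------------------------------------------

# Step-up BH by direct definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in rev(seq_len(n - 1)))
    adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n); out[o] <- adj
  out
}

# Two-sided Fisher exact p by exhaustive hypergeometric tail enumeration.
oracle_fisher <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n_ <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n_):min(k, m)
  pr <- dhyper(xs, m, n_, k)
  sum(pr[pr <= dhyper(a, m, n_, k) * (1 + 1e-7)])
}

# Grid-search decay-rate oracle for the steady-state labeling model.
oracle_grid_delta <- function(tc, lo = log(2) / 100, hi = log(2) / 0.1,
                              n_grid = 4000) {
  use <- tc$total > 0 & tc$time_h > 0
  f <- tc$new[use] / tc$total[use]
  t_ <- tc$time_h[use]; w <- tc$total[use]
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  sse <- vapply(grid, function(d) sum(w * (f - (1 - exp(-d * t_)))^2),
                numeric(1))
  grid[which.min(sse)]
}

# ---- misc fixtures ---------------------------------------------------------

# Counts table straight from matrices of control / treated replicates.
make_ct <- function(ctrl, kd, lengths = NULL, feature_ids = NULL) {
  m <- cbind(ctrl, kd)
  rownames(m) <- feature_ids %||% sprintf("f%03d", seq_len(nrow(m)))
  colnames(m) <- c(paste0("c", seq_len(ncol(ctrl))),
                   paste0("k", seq_len(ncol(kd))))
  counts_table(m, rep(c("ctrl", "kd"), c(ncol(ctrl), ncol(kd))),
               lengths = lengths)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Log-uniform decay rates spanning half-lives of 1 h to 48 h.
rand_deltas <- function(seed, n) {
  set.seed(seed)
  exp(runif(n, log(log(2) / 48), log(log(2) / 1)))
}

# Self-cleaning temporary directory scoped to the calling test.
withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("snhgtest")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
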