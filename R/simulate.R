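#' Simulation configuration
#'
#' Defines the study conditions emulated by every generator: the number of
#' genes and snoRNA host genes, negative-binomial dispersion
#' (variance = mu + dispersion * mu^2), planted log2 fold-change effects,
#' replicates per condition, and per-sample library size. Effects are named
#' `"channel:value"`, e.g. `"region:Snorna"`, `"zone:Cis"`,
#' `"class:histone"`, `"tier:3"`, and enter as additive log2 offsets on the
#' mean in the treated condition only.
#'
#' @param seed Integer RNG seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @param n_genes Number of genes (>= `n_snhgs`).
#' @param n_snhgs Number of snoRNA host genes among them.
#' @param nb_dispersion NB dispersion (>= 0; 0 means Poisson counts).
#' @param effects Named numeric list/vector of log2 fold-change offsets.
#' @param n_replicates Replicates per condition (>= 2; the emulated designs
#'   use 3).
#' @param library_size Expected reads per sample.
#' @param n_chroms Number of chromosomes (>= 2, default 3).
#' @param chrom_length Optional fixed chromosome length; an error is raised
#'   if the generated genes do not fit.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1, n_genes = 200, n_snhgs = 10,
                       nb_dispersion = 0.05, effects = list(),
                       n_replicates = 3, library_size = 2e6,
                       n_chroms = 3, chrom_length = NULL) {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(n_snhgs, "n_snhgs", lower = 0)
  if (n_snhgs > n_genes - 1) input_error("n_genes must exceed n_snhgs")
  assert_scalar_number(nb_dispersion, "nb_dispersion", lower = 0)
  if (n_replicates < 2) input_error("n_replicates must be >= 2")
  assert_scalar_number(library_size, "library_size", lower = 1)
  if (n_chroms < 2) input_error("need >= 2 chromosomes")
  effects <- unlist(effects)
  if (length(effects) && (is.null(names(effects)) || !all(is.finite(effects))))
    input_error("effects must be a named list of finite log2 offsets")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_snhgs = as.integer(n_snhgs),
                 nb_dispersion = nb_dispersion, effects = effects,
                 n_replicates = as.integer(n_replicates),
                 library_size = library_size, n_chroms = as.integer(n_chroms),
                 chrom_length = chrom_length),
            class = "sim_config")
}

# Exon layout for one simulated gene, offset 0. Returns list(isoforms, sno)
# where sno is NULL or c(start, end) inside a merged intron.
sim_gene_structure <- function(is_snhg) {
  if (is_snhg) {
    n_ex <- sample(3:4, 1)
    ex_len <- sample(150:800, n_ex, replace = TRUE)
    intron_len <- sample(1500:6000, n_ex - 1, replace = TRUE)
    starts <- cumsum(c(0, ex_len[-n_ex] + intron_len))
    ex <- data.frame(start = starts, end = starts + ex_len)
    # second isoform: drop one internal exon (exon union stays isoform 1)
    iso2 <- ex[-sample(2:(n_ex - 1), 1), , drop = FALSE]
    # snoRNA strictly inside one intron of the full isoform
    k <- sample(n_ex - 1, 1)
    gap_s <- ex$end[k]; gap_e <- ex$start[k + 1]
    sno_len <- 130L
    s0 <- gap_s + sample(50:(gap_e - gap_s - sno_len - 50), 1)
    list(isoforms = list(ex, iso2), sno = c(s0, s0 + sno_len))
  } else {
    n_ex <- sample(1:3, 1)
    ex_len <- sample(150:1500, n_ex, replace = TRUE)
    intron_len <- if (n_ex > 1) sample(500:5000, n_ex - 1, replace = TRUE) else integer(0)
    starts <- cumsum(c(0, ex_len[-n_ex] + intron_len))
    ex <- data.frame(start = starts, end = starts + ex_len)
    list(isoforms = list(ex), sno = NULL)
  }
}

#' Generate gene models, snoRNA intervals, TADs and a focal locus
#'
#' Lays out `n_genes` non-overlapping genes across `n_chroms` chromosomes.
#' `n_snhgs` of them are multi-isoform snoRNA host genes, each with one
#' snoRNA strictly inside a merged intron. One lncRNA on the first
#' chromosome is the focal locus; its 3' end coincides with the shared
#' boundary of two generated TADs, and positional zones (Cis /
#' SameChromosome / Trans) are precomputed for every other gene.
#'
#' @param cfg A [sim_config()].
#' @return List of class `"snhg_annotation"`: `models` (named list of
#'   [gene_model()]), `genes` (`data.frame` with `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `tss`, `gene_class`, `zone`), `snos`
#'   (`data.frame`), `tads` (a [tad_map()]), `chrom_lengths`, `focal_id`.
#' @export
gen_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    gene_chrom <- chroms[rep_len(seq_len(cfg$n_chroms), n)]
    # roles: one focal lncRNA on chr1, n_snhgs hosts, ~5% histone, rest other
    cls <- rep("other", n)
    focal_idx <- utils::head(which(gene_chrom == "chr1"), 1)
    pool <- setdiff(seq_len(n), focal_idx)
    if (cfg$n_snhgs > 0) {
      snhg_idx <- pool[seq_len(cfg$n_snhgs)]
      cls[snhg_idx] <- "snhg"
    } else snhg_idx <- integer(0)
    rest <- setdiff(pool, snhg_idx)
    n_hist <- max(0L, round(0.05 * length(rest)))
    if (n_hist > 0) cls[sample(rest, n_hist)] <- "histone"
    cls[focal_idx] <- "focal_lnc"

    ids <- sprintf("G%04d", seq_len(n))
    models <- vector("list", n); names(models) <- ids
    genes <- data.frame(gene_id = ids, chrom = gene_chrom,
                        strand = sample(c("+", "-"), n, replace = TRUE),
                        start = NA_integer_, end = NA_integer_,
                        tss = NA_integer_, gene_class = cls,
                        zone = NA_character_)
    genes$strand[focal_idx] <- "+"
    snos <- list()
    cursor <- stats::setNames(rep(10000L, cfg$n_chroms), chroms)
    for (i in seq_len(n)) {
      st <- sim_gene_structure(cls[i] == "snhg")
      off <- cursor[[genes$chrom[i]]] + sample(5000:50000, 1)
      iso <- lapply(st$isoforms, function(e) data.frame(start = e$start + off,
                                                        end = e$end + off))
      models[[i]] <- gene_model(ids[i], genes$chrom[i], genes$strand[i], iso)
      sp <- gene_span(models[[i]])
      genes$start[i] <- sp[1]; genes$end[i] <- sp[2]
      genes$tss[i] <- if (genes$strand[i] == "+") sp[1] else sp[2]
      if (!is.null(st$sno))
        snos[[length(snos) + 1L]] <- data.frame(
          sno_id = sprintf("SNO%03d", length(snos) + 1L), host_id = ids[i],
          chrom = genes$chrom[i], start = st$sno[1] + off,
          end = st$sno[2] + off,
          class = sample(c("CD", "HACA", "scaRNA"), 1,
                         prob = c(0.5, 0.4, 0.1)))
      cursor[[genes$chrom[i]]] <- sp[2]
    }
    chrom_lengths <- cursor + 10000L
    if (!is.null(cfg$chrom_length)) {
      if (any(chrom_lengths > cfg$chrom_length))
        input_error("infeasible geometry: genes exceed chromosome length")
      chrom_lengths[] <- cfg$chrom_length
    }

    # TADs: the focal gene's 3' end is an inter-TAD boundary on chr1
    focal_id <- ids[focal_idx]
    len1 <- unname(chrom_lengths["chr1"])
    b <- genes$end[focal_idx]
    bounds <- c(0L, as.integer(b %/% 2), as.integer(b),
                as.integer((b + len1) %/% 2), as.integer(len1))
    tads1 <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
    tm <- tad_map("chr1", tads1, boundary = b, focal_id = focal_id)
    zones <- assign_zones(genes[, c("gene_id", "chrom", "tss")], tm)
    genes$zone <- zones$zone[match(genes$gene_id, zones$gene_id)]

    snos <- if (length(snos)) do.call(rbind, snos) else
      data.frame(sno_id = character(0), host_id = character(0),
                 chrom = character(0), start = integer(0), end = integer(0),
                 class = character(0))
    structure(list(models = models, genes = genes, snos = snos, tads = tm,
                   chrom_lengths = chrom_lengths, focal_id = focal_id),
              class = "snhg_annotation")
  })
}

# Per-feature truth log2FC from an effects vector and a table of channel
# values (columns named by channel).
truth_lfc <- function(channels, effects) {
  lfc <- numeric(nrow(channels))
  for (nm in names(effects)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      input_error(sprintf("effect name '%s' is not 'channel:value'", nm))
    ch <- parts[1]; val <- parts[2]
    if (ch %in% names(channels))
      lfc <- lfc + ifelse(!is.na(channels[[ch]]) & channels[[ch]] == val,
                          effects[[nm]], 0)
  }
  lfc
}

# NB (or Poisson when dispersion 0) draws for a mu matrix.
nb_draw <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion == 0) matrix(stats::rpois(n, mu), nrow = nrow(mu),
                              dimnames = dimnames(mu))
  else matrix(stats::rnbinom(n, mu = mu, size = 1 / dispersion),
              nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Generate a counts table with planted effects
#'
#' Draws negative-binomial counts for a control/knockdown two-condition
#' design. Baseline means are log-normal across features, scaled so each
#' sample's expected total equals `library_size`. Planted effects (from
#' `cfg$effects`) shift the treated-condition mean by `2^offset` for
#' features matching the effect channel. At gene level the channels are the
#' annotation's `gene_class` and `zone`; at region level additionally the
#' partition `region` class.
#'
#' @param cfg A [sim_config()].
#' @param ann A `"snhg_annotation"` from [gen_annotation()].
#' @param level `"gene"` or `"region"`.
#' @param partitions Region-level only: the `partitions` list from
#'   [partition_all()] (defaults to partitioning `ann`).
#' @return List with `counts` (a [counts_table()], conditions `ctrl` and
#'   `kd`) and `truth` (`data.frame` with `feature`, `true_lfc` and the
#'   channel columns).
#' @export
gen_counts <- function(cfg, ann, level = c("gene", "region"),
                       partitions = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ann, "snhg_annotation"))
  level <- match.arg(level)
  if (level == "gene") {
    channels <- data.frame(feature = ann$genes$gene_id,
                           class = ann$genes$gene_class,
                           zone = ann$genes$zone)
    lengths <- stats::setNames(
      vapply(ann$models, function(m) {
        ex <- exon_union(m); sum(ex$end - ex$start)
      }, numeric(1)),
      ann$genes$gene_id)
    weight <- rep(1, nrow(channels))
    seed_off <- 1L
  } else {
    if (is.null(partitions))
      partitions <- partition_all(ann$models, ann$snos)$partitions
    seg <- do.call(rbind, lapply(partitions, as.data.frame))
    seg$feature <- paste(seg$host_id, seg$region, sep = ":")
    lens <- tapply(seg$end - seg$start, seg$feature, sum)
    first <- seg[!duplicated(seg$feature), ]
    channels <- data.frame(feature = first$feature,
                           class = "snhg_region", region = first$region,
                           zone = ann$genes$zone[match(first$host_id,
                                                       ann$genes$gene_id)])
    lengths <- stats::setNames(as.numeric(lens[channels$feature]),
                               channels$feature)
    # regions are quantified within transcribed hosts: exons and the snoRNA
    # accumulate mature signal, intronic flanks are fainter nascent signal
    rw <- c(Exon = 1, Snorna = 2, Pre = 0.15, Post = 0.15, OtherIntron = 0.1)
    weight <- unname(rw[channels$region]) * lengths[channels$feature] / 1000
    seed_off <- 2L
  }
  with_seed(cfg$seed + seed_off, {
    nfeat <- nrow(channels)
    base <- stats::rlnorm(nfeat, meanlog = 0, sdlog = 1) * weight
    mu <- base / sum(base) * cfg$library_size
    lfc <- truth_lfc(channels, cfg$effects)
    nrep <- cfg$n_replicates
    mu_mat <- cbind(matrix(rep(mu, nrep), ncol = nrep),
                    matrix(rep(mu * 2^lfc, nrep), ncol = nrep))
    dimnames(mu_mat) <- list(channels$feature,
                             c(paste0("ctrl_", seq_len(nrep)),
                               paste0("kd_", seq_len(nrep))))
    counts <- nb_draw(mu_mat, cfg$nb_dispersion)
    ct <- counts_table(counts, rep(c("ctrl", "kd"), each = nrep),
                       lengths = lengths)
    truth <- cbind(channels, true_lfc = lfc, mu = mu)
    list(counts = ct, truth = truth)
  })
}

#' Generate a continuous-labeling time course
#'
#' Emulates a metabolic-labeling experiment with label replenishment:
#' the expected new fraction at time `t` is `1 - exp(-delta * t)` and is
#' exactly 0 at `t = 0`. Observed totals are Poisson around `depth` and new
#' counts binomial in the new fraction. `depth = Inf` is a noiseless
#' sentinel: totals equal the steady-state abundance `sigma / delta` and
#' new counts equal the exact expected fractions of it.
#'
#' @param cfg A [sim_config()] (provides the seed).
#' @param sigma Synthesis rates (units/h), recycled against `delta`.
#' @param delta Decay rates (1/h, > 0).
#' @param times Time points in hours; must include 0 (default
#'   `c(0, 4, 8, 24)`).
#' @param depth Expected total reads per feature and time point, or `Inf`.
#' @return List with `timecourse` (`data.frame`: `feature`, `time_h`,
#'   `new`, `total`) and `truth` (`feature`, `sigma`, `delta`,
#'   `half_life`).
#' @export
gen_label_timecourse <- function(cfg, sigma, delta, times = c(0, 4, 8, 24),
                                 depth = 200) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(delta <= 0)) input_error("delta must be > 0")
  if (!any(times == 0)) input_error("times must include 0")
  nf <- max(length(sigma), length(delta))
  sigma <- rep_len(sigma, nf); delta <- rep_len(delta, nf)
  ids <- sprintf("F%04d", seq_len(nf))
  grid <- expand.grid(i = seq_len(nf), time_h = sort(times))
  f <- 1 - exp(-delta[grid$i] * grid$time_h)
  with_seed(cfg$seed + 3L, {
    if (is.infinite(depth)) {
      total <- sigma[grid$i] / delta[grid$i]
      new <- f * total
    } else {
      total <- stats::rpois(nrow(grid), depth)
      new <- stats::rbinom(nrow(grid), total, f)
    }
    list(timecourse = data.frame(feature = ids[grid$i],
                                 time_h = grid$time_h,
                                 new = new, total = total),
         truth = data.frame(feature = ids, sigma = sigma, delta = delta,
                            half_life = log(2) / delta))
  })
}

#' Generate per-nucleus pixel intensities from a two-component mixture
#'
#' Each nucleus contributes `n_pixels` intensities drawn from
#' `(1 - w) * baseline + w * high` where both components are log-normal;
#' `w > 0` concentrates signal in bright foci and raises the kurtosis of
#' the per-nucleus intensity distribution.
#'
#' @param cfg A [sim_config()] (provides the seed).
#' @param w Mixture weight of the high-intensity component, in `[0, 1]`.
#' @param n_nuclei Number of nuclei (default 50).
#' @param n_pixels Pixels per nucleus (>= 100, default 500).
#' @param baseline,high Named vectors `c(meanlog=, sdlog=)` of the two
#'   log-normal components.
#' @return List with `pixels` (`data.frame`: `nucleus`, `intensity`) and
#'   `truth` (the mixture weight per nucleus).
#' @export
gen_nuclear_pixels <- function(cfg, w = 0, n_nuclei = 50, n_pixels = 500,
                               baseline = c(meanlog = log(100), sdlog = 0.4),
                               high = c(meanlog = log(100) + 2, sdlog = 0.4)) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_scalar_number(w, "w", lower = 0, upper = 1)
  if (n_pixels < 100) input_error("n_pixels must be >= 100")
  with_seed(cfg$seed + 4L, {
    rows <- lapply(seq_len(n_nuclei), function(i) {
      k <- stats::rbinom(1, n_pixels, w)
      x <- c(stats::rlnorm(n_pixels - k, baseline["meanlog"], baseline["sdlog"]),
             stats::rlnorm(k, high["meanlog"], high["sdlog"]))
      data.frame(nucleus = sprintf("N%03d", i), intensity = x)
    })
    list(pixels = do.call(rbind, rows),
         truth = data.frame(nucleus = sprintf("N%03d", seq_len(n_nuclei)),
                            w = w))
  })
}
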