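#' Pipeline configuration
#'
#' Collects everything an end-to-end synthetic run needs: the output
#' directory, the simulation configuration, DE thresholds, and module
#' parameters. All randomness is governed by `sim$seed`.
#'
#' @param out_dir Directory for stage artifacts (created if missing).
#' @param sim A [sim_config()].
#' @param thresholds A [de_thresholds()].
#' @param screen_min_confidence Minimum element score for [run_screen()].
#' @param tiers_K Number of binding tiers.
#' @param n_kinetic_features Features in the simulated labeling time course.
#' @param verbose Print stage timings.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(),
                            thresholds = de_thresholds(),
                            screen_min_confidence = 1, tiers_K = 4,
                            n_kinetic_features = 50, verbose = FALSE) {
  stopifnot(inherits(sim, "sim_config"), inherits(thresholds, "de_thresholds"))
  structure(list(out_dir = out_dir, sim = sim, thresholds = thresholds,
                 screen_min_confidence = screen_min_confidence,
                 tiers_K = tiers_K,
                 n_kinetic_features = n_kinetic_features, verbose = verbose),
            class = "pipeline_config")
}

PIPELINE_STAGES <- c("simulate", "partition", "quantify", "de", "zones",
                     "screen", "tiers", "kinetics", "metrics", "report")

stage_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

require_artifact <- function(cfg, file, produced_by) {
  p <- stage_path(cfg, file)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s': run stage '%s' first",
                 file, produced_by), call. = FALSE)
  p
}

write_summary <- function(cfg, stage, summary) {
  jsonlite::write_json(summary, stage_path(cfg, paste0(stage, ".summary.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages in order. Each stage reads its inputs from
#' files written by earlier stages into `cfg$out_dir`, writes its own
#' artifacts plus a JSON summary, and is therefore runnable standalone once
#' its prerequisites exist. A missing prerequisite raises an error naming
#' the stage to run first. Identical configuration and seed give
#' byte-identical artifacts and report.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Subset of
#'   `c("simulate","partition","quantify","de","zones","screen","tiers",`
#'   `"kinetics","metrics","report")`; default all, in order.
#' @return The report list (invisibly the stage summaries when `report` is
#'   not requested).
#' @export
run_pipeline <- function(cfg, stages = PIPELINE_STAGES) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- NULL
  for (st in PIPELINE_STAGES[PIPELINE_STAGES %in% stages]) {
    t0 <- proc.time()[["elapsed"]]
    out <- switch(st,
                  simulate = stage_simulate(cfg),
                  partition = stage_partition(cfg),
                  quantify = stage_quantify(cfg),
                  de = stage_de(cfg),
                  zones = stage_zones(cfg),
                  screen = stage_screen(cfg),
                  tiers = stage_tiers(cfg),
                  kinetics = stage_kinetics(cfg),
                  metrics = stage_metrics(cfg),
                  report = stage_report(cfg))
    if (cfg$verbose)
      message(sprintf("[%s] done in %.2fs", st,
                      proc.time()[["elapsed"]] - t0))
  }
  invisible(out)
}

stage_simulate <- function(cfg) {
  sim <- cfg$sim
  ann <- gen_annotation(sim)
  write_gene_models_gtf(ann$models, stage_path(cfg, "annotation.gtf"))
  utils::write.table(ann$genes, stage_path(cfg, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ann$snos, stage_path(cfg, "snos.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(data.frame(chrom = ann$tads$chrom, start = ann$tads$tads$start,
                       end = ann$tads$tads$end), stage_path(cfg, "tads.bed"))
  jsonlite::write_json(list(focal_id = ann$focal_id,
                            boundary = ann$tads$boundary),
                       stage_path(cfg, "focal.json"), auto_unbox = TRUE)
  gc_ <- gen_counts(sim, ann, level = "gene")
  write_counts_tsv(gc_$counts, stage_path(cfg, "gene_counts.tsv"))
  utils::write.table(gc_$truth, stage_path(cfg, "truth_gene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # binding evidence: peaks on a random gene subset, confidence-graded
  with_seed(sim$seed + 5L, {
    n_bound <- min(80L, max(0L, sim$n_genes - 20L))
    bound <- sample(ann$genes$gene_id, n_bound)
    peaks <- data.frame(
      gene_id = rep(bound, times = sample(1:3, n_bound, replace = TRUE)))
    peaks$signal <- stats::rlnorm(nrow(peaks), log(3), 0.6)
    peaks$p <- 10^(-stats::runif(nrow(peaks), 1, 8))
    g <- ann$genes[match(peaks$gene_id, ann$genes$gene_id), ]
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.4f\t%.4f\t-1\t-1",
                       g$chrom, g$tss, g$tss + 200L, peaks$gene_id,
                       pmin(1000L, as.integer(peaks$signal * 100)),
                       peaks$signal, -log10(peaks$p)),
               stage_path(cfg, "peaks.narrowPeak"))

    # regulatory elements over a few gene loci, each targeting another gene
    el_genes <- sample(ann$genes$gene_id, 10)
    tg_genes <- sample(setdiff(ann$genes$gene_id, el_genes), 10)
    eg <- ann$genes[match(el_genes, ann$genes$gene_id), ]
    utils::write.table(
      data.frame(element_id = sprintf("GH%02d", 1:10), chrom = eg$chrom,
                 start = eg$start, end = eg$end, score = round(stats::runif(10, 0.5, 15), 2),
                 targets = tg_genes),
      stage_path(cfg, "elements.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)

    # wound series, site base counts
    utils::write.table(
      data.frame(time_h = c(0, 8, 24), area_um2 = c(250000, 140000, 30000),
                 width_um = c(500, 280, 60)),
      stage_path(cfg, "wound.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(site = "18S:1248", A = 95L, C = 2L, G = 2L, T = 1L,
                 ref = "A"),
      stage_path(cfg, "site_counts.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  })

  tcdat <- gen_label_timecourse(
    sim,
    sigma = 1,
    delta = with_seed(sim$seed + 6L,
                      exp(stats::runif(cfg$n_kinetic_features,
                                       log(log(2) / 48), log(log(2) / 1)))),
    depth = 200)
  utils::write.table(tcdat$timecourse, stage_path(cfg, "timecourse.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tcdat$truth, stage_path(cfg, "truth_kinetics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  px <- gen_nuclear_pixels(sim, w = 0.1, n_nuclei = 30, n_pixels = 300)
  utils::write.table(px$pixels, stage_path(cfg, "pixels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  smry <- list(n_genes = sim$n_genes, n_snhgs = sim$n_snhgs,
               n_snos = nrow(ann$snos), focal_id = ann$focal_id,
               effects = as.list(sim$effects), seed = sim$seed)
  write_summary(cfg, "simulate", smry)
  smry
}

stage_partition <- function(cfg) {
  gtf <- require_artifact(cfg, "annotation.gtf", "simulate")
  snos <- utils::read.table(require_artifact(cfg, "snos.tsv", "simulate"),
                            sep = "\t", header = TRUE)
  models <- load_gene_models(gtf)
  pa <- partition_all(models, snos)
  write_partition_bed(pa$partitions, stage_path(cfg, "partition.bed"))
  seg <- do.call(rbind, lapply(pa$partitions, as.data.frame))
  smry <- list(n_hosts = length(pa$partitions),
               n_segments = if (is.null(seg)) 0L else nrow(seg),
               region_nt = if (is.null(seg)) NULL else
                 as.list(tapply(seg$end - seg$start, seg$region, sum)),
               diagnostics = pa$diagnostics)
  write_summary(cfg, "partition", smry)
  smry
}

stage_quantify <- function(cfg) {
  require_artifact(cfg, "partition.bed", "partition")
  gtf <- require_artifact(cfg, "annotation.gtf", "simulate")
  snos <- utils::read.table(stage_path(cfg, "snos.tsv"), sep = "\t",
                            header = TRUE)
  models <- load_gene_models(gtf)
  pa <- partition_all(models, snos)
  ann <- list(models = models,
              genes = utils::read.table(stage_path(cfg, "genes.tsv"),
                                        sep = "\t", header = TRUE),
              snos = snos)
  class(ann) <- "snhg_annotation"
  rc <- gen_counts(cfg$sim, ann, level = "region",
                   partitions = pa$partitions)
  write_counts_tsv(rc$counts, stage_path(cfg, "region_counts.tsv"))
  utils::write.table(rc$truth, stage_path(cfg, "truth_region.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  smry <- list(n_regions = nrow(rc$counts$counts),
               size_factors = as.list(round(size_factors(rc$counts), 4)))
  write_summary(cfg, "quantify", smry)
  smry
}

stage_de <- function(cfg) {
  gene_ct <- read_counts_tsv(require_artifact(cfg, "gene_counts.tsv",
                                              "simulate"))
  region_ct <- read_counts_tsv(require_artifact(cfg, "region_counts.tsv",
                                                "quantify"))
  de_g <- de_test(gene_ct, cfg$thresholds, control = "ctrl", treated = "kd")
  # the exonic-length filter is a gene-level rule; region segments (e.g. a
  # 130 nt snoRNA body) are quantified regardless of length
  thr_r <- cfg$thresholds
  thr_r$min_length <- 0
  de_r <- de_test(region_ct, thr_r, control = "ctrl", treated = "kd")
  utils::write.table(de_g, stage_path(cfg, "de_gene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(de_r, stage_path(cfg, "de_region.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  region_cls <- sub("^.*:", "", de_r$feature)
  shift <- tryCatch(group_shift(de_r$log2FC[de_r$call != "filtered"],
                                region_cls[de_r$call != "filtered"]),
                    error = function(e) NULL)
  smry <- list(
    gene = list(n_up = sum(de_g$call == "up"),
                n_down = sum(de_g$call == "down"),
                n_tested = sum(de_g$call != "filtered")),
    region = list(n_up = sum(de_r$call == "up"),
                  n_down = sum(de_r$call == "down"),
                  anova_p = if (is.null(shift)) NULL else shift$anova_p,
                  median_lfc_by_region = if (is.null(shift)) NULL else
                    as.list(shift$medians)))
  write_summary(cfg, "de", smry)
  smry
}

stage_zones <- function(cfg) {
  genes <- utils::read.table(require_artifact(cfg, "genes.tsv", "simulate"),
                             sep = "\t", header = TRUE)
  de_g <- utils::read.table(require_artifact(cfg, "de_gene.tsv", "de"),
                            sep = "\t", header = TRUE)
  zones <- genes[!is.na(genes$zone), c("gene_id", "zone")]
  utils::write.table(zones, stage_path(cfg, "zones.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  zt <- tryCatch(zone_effect_test(de_g, zones), error = function(e) NULL)
  dig <- tryCatch(digital_cis_test(de_g, zones, "down"),
                  error = function(e) NULL)
  smry <- list(
    n_by_zone = as.list(table(zones$zone)),
    median_lfc_by_zone = if (is.null(zt)) NULL else as.list(zt$medians),
    anova_p = if (is.null(zt)) NULL else zt$tests$anova_p,
    digital_cis = if (is.null(dig)) NULL else
      list(odds_ratio = dig$odds_ratio, p = dig$p))
  write_summary(cfg, "zones", smry)
  smry
}

stage_screen <- function(cfg) {
  genes <- utils::read.table(require_artifact(cfg, "genes.tsv", "simulate"),
                             sep = "\t", header = TRUE)
  elements <- utils::read.table(require_artifact(cfg, "elements.tsv",
                                                 "simulate"),
                                sep = "\t", header = TRUE)
  de_g <- utils::read.table(require_artifact(cfg, "de_gene.tsv", "de"),
                            sep = "\t", header = TRUE)
  cand <- suppressWarnings(
    run_screen(genes[, c("gene_id", "chrom", "start", "end")], elements,
               list(kd = de_g), min_confidence = cfg$screen_min_confidence))
  utils::write.table(cand, stage_path(cfg, "screen_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  smry <- list(n_candidates = nrow(cand),
               n_concordant = sum(cand$concordant))
  write_summary(cfg, "screen", smry)
  smry
}

stage_tiers <- function(cfg) {
  peaks <- read_narrowpeak(require_artifact(cfg, "peaks.narrowPeak",
                                            "simulate"))
  genes <- utils::read.table(stage_path(cfg, "genes.tsv"), sep = "\t",
                             header = TRUE)
  de_g <- utils::read.table(require_artifact(cfg, "de_gene.tsv", "de"),
                            sep = "\t", header = TRUE)
  sc <- score_binding(peaks[, c("gene_id", "signal", "p")],
                      genes = genes$gene_id)
  tiers <- suppressWarnings(assign_tiers(sc, K = cfg$tiers_K))
  utils::write.table(tiers, stage_path(cfg, "tiers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tt <- tryCatch(tier_trend_test(tiers, de_g), error = function(e) NULL)
  smry <- list(n_by_tier = as.list(table(tiers$tier)),
               rho = if (is.null(tt)) NULL else tt$rho,
               rho_p = if (is.null(tt)) NULL else tt$rho_p)
  write_summary(cfg, "tiers", smry)
  smry
}

stage_kinetics <- function(cfg) {
  tc <- utils::read.table(require_artifact(cfg, "timecourse.tsv", "simulate"),
                          sep = "\t", header = TRUE)
  fits <- fit_kinetics_all(tc)
  utils::write.table(fits, stage_path(cfg, "kinetics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  smry <- list(n_features = nrow(fits),
               n_confident = sum(fits$confident),
               median_half_life_h = stats::median(fits$half_life))
  write_summary(cfg, "kinetics", smry)
  smry
}

stage_metrics <- function(cfg) {
  px <- utils::read.table(require_artifact(cfg, "pixels.tsv", "simulate"),
                          sep = "\t", header = TRUE)
  wound <- utils::read.table(require_artifact(cfg, "wound.tsv", "simulate"),
                             sep = "\t", header = TRUE)
  site <- utils::read.table(require_artifact(cfg, "site_counts.tsv",
                                             "simulate"),
                            sep = "\t", header = TRUE)
  kurt <- vapply(split(px$intensity, px$nucleus), nuclear_kurtosis,
                 numeric(1))
  wc <- wound_closure(wound$area_um2[1], wound$area_um2[nrow(wound)])
  rm_ <- migration_rate(wound$width_um[1], wound$width_um[nrow(wound)],
                        wound$time_h[nrow(wound)])
  af <- allele_frequency(unlist(site[1, c("A", "C", "G", "T")]), site$ref[1])
  smry <- list(median_nuclear_kurtosis = stats::median(kurt),
               wound_closure_pct = wc$percent,
               migration_rate_um_h = rm_,
               allele_frequency = if (af$flagged) NULL else
                 unname(af$frequency))
  write_summary(cfg, "metrics", smry)
  smry
}

stage_report <- function(cfg) {
  stages <- setdiff(PIPELINE_STAGES, "report")
  have <- stages[file.exists(stage_path(cfg, paste0(stages, ".summary.json")))]
  if (length(have) == 0L)
    stop("no stage summaries found: run at least one stage first",
         call. = FALSE)
  outputs <- stats::setNames(lapply(have, function(st)
    jsonlite::read_json(stage_path(cfg, paste0(st, ".summary.json")))),
    have)
  write_report(outputs, stage_path(cfg, "report.json"))
}

#' Write the aggregated pipeline report
#'
#' Produces a schema-versioned JSON report plus a plain-text rendering in
#' which every number is taken from a stage summary.
#'
#' @param stage_outputs Named list of stage summaries (at least one).
#' @param path Output path of the JSON report (the text summary is written
#'   alongside with extension `.txt`).
#' @return The report list, invisibly.
#' @export
write_report <- function(stage_outputs, path) {
  if (length(stage_outputs) == 0L || is.null(names(stage_outputs)))
    stop("report needs at least one named stage output", call. = FALSE)
  bad <- setdiff(names(stage_outputs), PIPELINE_STAGES)
  if (length(bad))
    stop(sprintf("unknown stage(s) in report: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  report <- list(schema_version = "1.0", stages = stage_outputs)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  lines <- c("snhgtools pipeline report (schema 1.0)", "")
  for (st in names(stage_outputs)) {
    lines <- c(lines, sprintf("== %s ==", st))
    s <- stage_outputs[[st]]
    for (k in names(s)) {
      u <- unlist(s[[k]])
      val <- if (length(u) == 0L) "-"
      else if (is.null(names(u))) paste(u, collapse = ", ")
      else paste(paste(names(u), u, sep = "="), collapse = ", ")
      lines <- c(lines, sprintf("  %s: %s", k, val))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, sub("\\.json$", ".txt", path))
  invisible(report)
}
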