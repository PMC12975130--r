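test_that("every generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 1, n_genes = 40, n_snhgs = 4)
  a1 <- gen_annotation(cfg); a2 <- gen_annotation(cfg)
  expect_identical(a1, a2)
  c1 <- gen_counts(cfg, a1); c2 <- gen_counts(cfg, a2)
  expect_identical(c1, c2)
  t1 <- gen_label_timecourse(cfg, 1, c(0.1, 0.2))
  t2 <- gen_label_timecourse(cfg, 1, c(0.1, 0.2))
  expect_identical(t1, t2)
  p1 <- gen_nuclear_pixels(cfg, w = 0.2, n_nuclei = 5, n_pixels = 100)
  p2 <- gen_nuclear_pixels(cfg, w = 0.2, n_nuclei = 5, n_pixels = 100)
  expect_identical(p1, p2)
})

test_that("the generated annotation honors its own geometric contract", {
  cfg0 <- sim_config(seed = 1, n_genes = 30, n_snhgs = 0)
  ann0 <- gen_annotation(cfg0)
  expect_equal(nrow(ann0$snos), 0)
  expect_length(ann0$models, 30)

  for (seed in 1:3) {
    ann <- gen_annotation(sim_config(seed = seed, n_genes = 60, n_snhgs = 6))
    # partition of every generated SNHG succeeds with no diagnostics
    pa <- partition_all(ann$models, ann$snos)
    expect_length(pa$diagnostics, 0)
    expect_length(pa$partitions, 6)
    # focal locus abuts the shared boundary of two TADs
    expect_equal(ann$genes$end[ann$genes$gene_id == ann$focal_id],
                 ann$tads$boundary)
    # genes span at least two chromosomes, one zone per non-focal gene
    expect_gte(length(unique(ann$genes$chrom)), 2)
    expect_false(any(is.na(ann$genes$zone[ann$genes$gene_id != ann$focal_id])))
  }
  expect_error(gen_annotation(sim_config(seed = 1, n_genes = 200,
                                         n_snhgs = 5, chrom_length = 1e5)),
               class = "snhg_input_error")
})

test_that("null counts center the estimated fold changes near zero", {
  cfg <- sim_config(seed = 1, n_genes = 500, n_snhgs = 10)
  ann <- gen_annotation(cfg)
  gc_ <- gen_counts(cfg, ann)
  de <- de_test(gc_$counts, control = "ctrl", treated = "kd")
  tested <- de$call != "filtered"
  expect_gt(sum(tested), 300)
  expect_lt(abs(mean(de$log2FC[tested])), 0.05)
  # column sums within 2x of the nominal library size
  expect_true(all(colSums(gc_$counts$counts) > cfg$library_size / 2))
  expect_true(all(colSums(gc_$counts$counts) < cfg$library_size * 2))
})

test_that("a planted snoRNA-region effect doubles the KD/control count ratio at zero dispersion", {
  cfg <- sim_config(seed = 1, n_genes = 80, n_snhgs = 12, nb_dispersion = 0,
                    effects = c("region:Snorna" = 1), library_size = 5e6)
  ann <- gen_annotation(cfg)
  rc <- gen_counts(cfg, ann, level = "region")
  sno_rows <- grepl(":Snorna$", rownames(rc$counts$counts))
  cond <- rc$counts$condition
  ratio <- sum(rc$counts$counts[sno_rows, cond == "kd"]) /
    sum(rc$counts$counts[sno_rows, cond == "ctrl"])
  expect_equal(ratio, 2, tolerance = 0.05)
  expect_true(all(rc$truth$true_lfc[rc$truth$region == "Snorna"] == 1))
  expect_true(all(rc$truth$true_lfc[rc$truth$region != "Snorna"] == 0))
})

test_that("labeling time courses follow first-order accumulation", {
  cfg <- sim_config(seed = 1)
  exact <- gen_label_timecourse(cfg, sigma = 1, delta = log(2) / 4,
                                times = c(0, 4, 8, 24), depth = Inf)
  tc <- exact$timecourse
  expect_equal(tc$new[tc$time_h == 0], 0)
  expect_equal(tc$new[tc$time_h == 4] / tc$total[tc$time_h == 4], 0.5)
  expect_equal(tc$new[tc$time_h == 8] / tc$total[tc$time_h == 8], 0.75)
  # binomial Monte-Carlo mean at delta = 0.1, t = 8, depth = 200
  mc <- gen_label_timecourse(cfg, sigma = 1, delta = rep(0.1, 1e4),
                             times = c(0, 8), depth = 200)
  f8 <- with(subset(mc$timecourse, time_h == 8), new / total)
  want <- 1 - exp(-0.8)
  se <- sqrt(want * (1 - want) / 200 / 1e4)
  expect_lt(abs(mean(f8) - want), 5 * se + 1e-4)
  expect_error(gen_label_timecourse(cfg, 1, -0.1),
               class = "snhg_input_error")
  expect_error(gen_label_timecourse(cfg, 1, 0.1, times = c(4, 8)),
               class = "snhg_input_error")
})

test_that("nuclear pixel mixtures shift per-nucleus kurtosis as planted", {
  cfg <- sim_config(seed = 1)
  pure <- gen_nuclear_pixels(cfg, w = 0, n_nuclei = 1, n_pixels = 1e5)
  g2_log <- nuclear_kurtosis(log(pure$pixels$intensity))
  expect_lt(abs(g2_log), 0.05)
  base <- gen_nuclear_pixels(cfg, w = 0, n_nuclei = 50, n_pixels = 500)
  mixed <- gen_nuclear_pixels(sim_config(seed = 2), w = 0.2, n_nuclei = 50,
                              n_pixels = 500)
  k0 <- tapply(base$pixels$intensity, base$pixels$nucleus, nuclear_kurtosis)
  k2 <- tapply(mixed$pixels$intensity, mixed$pixels$nucleus,
               nuclear_kurtosis)
  expect_gt(median(k2), median(k0))
  expect_error(gen_nuclear_pixels(cfg, w = 1.2), "out of range")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_replicates = 1), class = "snhg_input_error")
  expect_error(sim_config(n_genes = 5, n_snhgs = 5),
               class = "snhg_input_error")
  expect_error(sim_config(nb_dispersion = -1))
  expect_error(sim_config(effects = c(0.5)), class = "snhg_input_error")
})
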