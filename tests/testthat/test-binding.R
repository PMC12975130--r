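test_that("the composite binding score sums signal times capped -log10 p", {
  ev <- data.frame(gene_id = c("g1", "g1", "g2"),
                   signal = c(5, 2, 1),
                   p = c(1e-3, 1e-2, 1e-15))
  sc <- score_binding(ev, genes = c("g1", "g2", "g3"))
  expect_equal(sc[["g1"]], 5 * 3 + 2 * 2)
  expect_equal(sc[["g2"]], 10)   # -log10 p capped at 10
  expect_equal(sc[["g3"]], 0)    # no peaks
  expect_error(score_binding(data.frame(gene_id = "g", signal = 1, p = 0)),
               class = "snhg_input_error")
})

test_that("quantile tiers are balanced, tie-stable and monotone in score", {
  t1 <- assign_tiers(setNames(c(1, 2, 3, 4), paste0("g", 1:4)), K = 2)
  expect_equal(t1$tier, c(1L, 1L, 2L, 2L))
  expect_warning(t2 <- assign_tiers(setNames(rep(3, 5), paste0("g", 1:5)),
                                    K = 2))
  expect_true(all(t2$tier == 1L))
  set.seed(8)
  sc <- setNames(c(rep(0, 40), runif(120)), sprintf("g%03d", 1:160))
  tt <- assign_tiers(sc, K = 4)
  sizes <- table(tt$tier[tt$tier > 0])
  expect_lte(max(sizes) - min(sizes), 1)
  expect_true(all(tt$tier[sc == 0] == 0L))
  # raising one gene's score never lowers its tier
  for (g in sample(names(sc)[sc > 0], 10)) {
    sc2 <- sc; sc2[g] <- sc2[g] + 0.3
    tt2 <- assign_tiers(sc2, K = 4)
    expect_gte(tt2$tier[tt2$gene_id == g], tt$tier[tt$gene_id == g])
  }
})

test_that("matched controls reproduce the target expression histogram and are seeded", {
  set.seed(12)
  n <- 400
  expr <- setNames(exp(rnorm(n)), sprintf("g%03d", 1:n))
  # binding correlated with expression: high-expression genes more bound
  p_bound <- plogis(scale(log(expr))[, 1])
  bound <- runif(n) < p_bound * 0.5
  tiers <- data.frame(gene_id = names(expr),
                      tier = ifelse(bound, sample(1:2, n, replace = TRUE), 0L))
  ctrl <- matched_controls(tiers, expr, n_bins = 10, seed = 4)
  ctrl_rerun <- matched_controls(tiers, expr, n_bins = 10, seed = 4)
  expect_identical(ctrl, ctrl_rerun)
  for (k in names(ctrl)) {
    tg <- tiers$gene_id[tiers$tier == as.integer(k)]
    expect_true(all(ctrl[[k]] %in% tiers$gene_id[tiers$tier == 0L]))
    # matched control median expression within 5% of the targets' median
    expect_lt(abs(log(median(expr[ctrl[[k]]]) / median(expr[tg]))),
              log(1.05))
    # histogram match: same bin counts when control supply suffices
    br <- quantile(expr[tiers$gene_id], probs = seq(0, 1, 0.1))
    bins_t <- table(cut(expr[tg], br, include.lowest = TRUE))
    bins_c <- table(cut(expr[ctrl[[k]]], br, include.lowest = TRUE))
    expect_equal(as.integer(bins_c), as.integer(bins_t))
  }
})

test_that("tier trend test recovers a planted monotone effect and is null-calibrated", {
  set.seed(14)
  n <- 400
  tiers <- data.frame(gene_id = sprintf("g%03d", 1:n),
                      tier = sample(0:4, n, replace = TRUE))
  lfc <- rnorm(n, 0, 0.3) - 0.2 * tiers$tier
  de <- data.frame(feature = tiers$gene_id, baseMean = 100, log2FC = lfc,
                   p = 0.5, padj = 0.9, call = "ns")
  tt <- tier_trend_test(tiers, de)
  expect_lt(tt$rho, 0)
  expect_lt(tt$rho_p, 0.01)
  expect_true(all(tt$per_tier$p_vs_tier0[tt$per_tier$tier >= 3] < 0.01))
  # shuffled tiers: small rho, non-significant on average
  rhos <- replicate(20, {
    sh <- tiers; sh$tier <- sample(sh$tier)
    de0 <- de; de0$log2FC <- rnorm(n, 0, 0.3)
    tier_trend_test(sh, de0)$rho
  })
  expect_lt(abs(median(rhos)), 0.1)
  single <- tiers; single$tier <- 1L
  expect_error(tier_trend_test(single, de), class = "snhg_input_error")
})

test_that("RIP enrichment applies both the FDR and effect-size gates", {
  set.seed(15)
  n <- 60
  base <- exp(rnorm(n, 5, 1))
  input <- matrix(rpois(3 * n, base), n)
  enr <- c(rep(4, 10), rep(1.25, 10), rep(1, 40))  # strong, sub-cutoff, null
  ip <- matrix(rpois(3 * n, base * enr), n)
  rownames(ip) <- rownames(input) <- sprintf("g%03d", 1:n)
  res <- rip_enrichment(ip, input)
  expect_true(all(sprintf("g%03d", 1:10) %in% res$enriched))
  # |log2FC| = 0.32 < 0.41: gated out regardless of p
  expect_false(any(sprintf("g%03d", 11:20) %in% res$enriched))
})

test_that("promoter peak fraction reproduces printed-count arithmetic", {
  got <- peak_promoter_fraction(418, 835)
  expect_equal(got$percent, 50L)
  expect_error(peak_promoter_fraction(10, 0))
})
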