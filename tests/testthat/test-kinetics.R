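test_that("noiseless fractions recover the exact half-life", {
  tc <- data.frame(time_h = c(0, 4, 8, 24),
                   new = c(0, 0.5, 0.75, 0.984375), total = 1)
  fit <- fit_kinetics(tc)
  expect_equal(fit$half_life, 4, tolerance = 1e-6)
  expect_equal(fit$delta * fit$half_life, log(2), tolerance = 1e-12)
  expect_true(fit$confident)
  expect_equal(predict(fit, 4), 0.5, tolerance = 1e-6)
  expect_equal(coef(fit)[["delta"]], fit$delta)
})

test_that("a flat zero time course pins delta at the lower bound and drops confidence", {
  tc <- data.frame(time_h = c(0, 4, 8, 24), new = 0, total = 100)
  fit <- fit_kinetics(tc)
  expect_equal(fit$delta, log(2) / 100, tolerance = 1e-9)
  expect_true(fit$at_bound)
  expect_false(fit$confident)
})

test_that("scaling all counts leaves the decay estimate unchanged", {
  set.seed(19)
  f <- 1 - exp(-0.15 * c(4, 8, 24))
  tot <- c(200, 180, 220, 210)
  tc <- data.frame(time_h = c(0, 4, 8, 24),
                   new = c(0, round(f * tot[-1])), total = tot)
  fit1 <- fit_kinetics(tc)
  tc2 <- tc; tc2$new <- tc2$new * 7; tc2$total <- tc2$total * 7
  fit2 <- fit_kinetics(tc2)
  expect_equal(fit1$delta, fit2$delta, tolerance = 1e-8)
})

test_that("steady-state fits agree with a grid-search oracle on noisy simulations", {
  cfg <- sim_config(seed = 1)
  deltas <- exp(seq(log(log(2) / 48), log(log(2) / 1), length.out = 40))
  sim <- gen_label_timecourse(cfg, sigma = 1, delta = deltas, depth = 200)
  fits <- fit_kinetics_all(sim$timecourse)
  merged <- merge(fits, sim$truth, by = "feature")
  rel_err <- abs(merged$half_life.x - merged$half_life.y) / merged$half_life.y
  expect_lt(median(rel_err), 0.15)
  # solver vs independent grid search, feature by feature
  for (f in merged$feature[seq(1, 40, by = 4)]) {
    tc <- sim$timecourse[sim$timecourse$feature == f, ]
    d_grid <- oracle_grid_delta(tc)
    d_fit <- fits$delta[fits$feature == f]
    expect_equal(d_fit, d_grid, tolerance = 5e-3)
  }
})

test_that("the non-steady model recovers parameters from noiseless synthesis/decay curves", {
  delta <- log(2) / 6; sigma <- 30; T0 <- 400  # not at steady state
  t_ <- c(0, 4, 8, 24)
  Tt <- T0 * exp(-delta * t_) + (sigma / delta) * (1 - exp(-delta * t_))
  Nt <- (sigma / delta) * (1 - exp(-delta * t_))
  fit <- fit_kinetics(data.frame(time_h = t_, new = Nt, total = Tt),
                      steady_state = FALSE)
  expect_equal(fit$delta, delta, tolerance = 1e-3)
  expect_equal(fit$sigma, sigma, tolerance = 1e-2)
})

test_that("condition comparisons report log2 ratios and detect planted synthesis shifts", {
  fits_ctrl <- data.frame(feature = c("a", "b"), delta = c(0.1, 0.2),
                          sigma = c(10, 20), half_life = log(2) / c(0.1, 0.2),
                          rss = 0, confident = TRUE)
  fits_kd <- fits_ctrl
  same <- compare_kinetics(fits_ctrl, fits_kd)
  expect_equal(same$per_feature$dlog2_sigma, c(0, 0))
  fits_kd2 <- fits_ctrl; fits_kd2$sigma <- fits_kd2$sigma / 2
  halved <- compare_kinetics(fits_ctrl, fits_kd2)
  expect_equal(halved$per_feature$dlog2_sigma, c(-1, -1))
  expect_equal(halved$per_feature$dlog2_half_life, c(0, 0))
  # missing feature skipped with diagnostic
  miss <- compare_kinetics(fits_ctrl[1, ], fits_kd)
  expect_equal(miss$skipped, "b")

  set.seed(23)
  n <- 60
  cls <- setNames(rep(c("hit", "other"), each = n / 2), sprintf("f%02d", 1:n))
  ctrl <- data.frame(feature = names(cls), delta = 0.1,
                     sigma = exp(rnorm(n, 3, 0.2)),
                     half_life = log(2) / 0.1, rss = 0, confident = TRUE)
  kd <- ctrl
  kd$sigma <- kd$sigma * 2^(rnorm(n, 0, 0.1) +
                              ifelse(cls == "hit", -0.5, 0))
  cmp <- compare_kinetics(ctrl, kd, classes = cls)
  expect_lt(cmp$tests$sigma$pairwise$p, 0.01)
})

test_that("degenerate time courses raise input errors", {
  expect_error(fit_kinetics(data.frame(time_h = c(4, 8, 24), new = 1,
                                       total = 2)),
               class = "snhg_input_error")  # no t = 0
  expect_error(fit_kinetics(data.frame(time_h = c(0, 4), new = c(0, 1),
                                       total = 2)),
               class = "snhg_input_error")  # too few points
  expect_error(fit_kinetics(data.frame(time_h = c(0, 4, 8, 24), new = 0,
                                       total = 0)),
               class = "snhg_input_error")  # all-zero totals
})
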