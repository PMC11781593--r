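test_that("the per-step resetting probability has its closed forms", {
  expect_equal(per_step_reset_prob(1, rate_ns = 0, dt_fs = 1), 0)
  expect_equal(per_step_reset_prob(0, rate_ns = 1e5, dt_fs = 1), 0)
  # r dt = ln 2 gives probability 1/2
  expect_equal(per_step_reset_prob(1, rate_ns = log(2) * 1e6, dt_fs = 1), 0.5)
})

test_that("survival curves follow the running product over the indicator", {
  dt <- 1
  r <- -log(0.9) * 1e6   # p = 0.1 per retained step
  cv <- c(0, 2, 2, 0, 2) # indicator (0,1,1,0,1) against threshold 1
  s <- survival_curve(cv, r, threshold = 1, dt_fs = dt)
  expect_equal(s$psi, c(1, 0.9, 0.81, 0.81, 0.729))
  # no indicator: survival stays 1; constant indicator: exact exponential
  expect_equal(survival_curve(rep(-5, 4), r, 1, dt)$psi, rep(1, 4))
  k <- 1:6
  expect_equal(survival_curve(rep(5, 6), 2e5, 1, dt)$psi, exp(-2e5 * 1e-6 * k))
})

test_that("the predictor matches exhaustive enumeration on hand-sized samples", {
  p <- 0.35
  r <- -log(1 - p) * 1e6 # per-step probability p at dt = 1 fs
  cv_series <- list(c(0, 2, 2, 0, 2), c(2, 2, 0, 0, 1.5), c(0, 0, 0, 2, 2, 2, 2))
  tau <- lengths(cv_series) * 1e-6
  sample <- list(cv_series = cv_series, fpt_ns = tau, stride_dt_fs = 1)
  got <- predict_mfpt(sample, r, threshold = 1)
  ref <- enum_reset_mfpt(cv_series, tau, p, threshold = 1, stride_dt_ns = 1e-6)
  expect_equal(got$mfpt_ns, ref, tolerance = 1e-12)
  # and against a Monte-Carlo simulation of the discrete process
  set.seed(8)
  mc <- mc_reset_mfpt(cv_series, tau, p, 1, 1e-6, n_rep = 40000)
  expect_lt(abs(got$mfpt_ns - mc) / got$mfpt_ns, 0.02)
})

test_that("at rate zero the prediction is the reset-free sample mean", {
  fx <- get_fixture()
  got <- predict_mfpt(fx$baseline, 0, threshold = 3)
  expect_equal(got$mfpt_ns, mean(fx$baseline$fpt_ns))
  expect_equal(got$mean_segments, 1)
})

test_that("predictions agree with direct informed-resetting simulation", {
  fx <- get_fixture()
  cfg <- sim_config(seed = 71, max_steps = 4e7)
  for (case in list(list(r = 2e3, c = 3), list(r = 2e4, c = 2.5))) {
    pred <- predict_mfpt(fx$baseline, case$r, case$c, se = "bootstrap")
    sim <- glance(simulate_fpt(fx$surface, cfg, 300,
                               protocol = reset_protocol(case$r, case$c)))
    expect_lt(zdiff(pred$mfpt_ns, sim$mfpt_ns, pred$se_ns, sim$sem_ns), 3)
  }
})

test_that("standard-resetting predictions also agree with simulation", {
  fx <- get_fixture()
  cfg <- sim_config(seed = 73, max_steps = 4e7)
  pred <- predict_mfpt(fx$baseline, 150, threshold = NULL, se = "bootstrap")
  sim <- glance(simulate_fpt(fx$surface, cfg, 300,
                             protocol = reset_protocol(150)))
  expect_lt(zdiff(pred$mfpt_ns, sim$mfpt_ns, pred$se_ns, sim$sem_ns), 3)
})

test_that("survival decreases with rate and with more permissive thresholds", {
  fx <- get_fixture()
  rates <- c(10, 100, 1e3, 1e4)
  ps <- vapply(rates, function(r)
    predict_mfpt(fx$baseline, r, 3)$mean_survival, 1)
  expect_true(all(diff(ps) < 0))
  thr <- c(4, 3, 2, 1)
  pt <- vapply(thr, function(cc)
    predict_mfpt(fx$baseline, 1e3, cc)$mean_survival, 1)
  expect_true(all(diff(pt) < 0))
})

test_that("per-trajectory decomposition of resetting FPTs is exact", {
  fx <- get_fixture()
  cfg <- sim_config(seed = 79, max_steps = 4e7)
  ens <- simulate_fpt(fx$surface, cfg, 80, protocol = reset_protocol(3e3, 3))
  with_resets <- which(vapply(ens$reset_steps, length, 1L) > 0)
  expect_gt(length(with_resets), 0)
  for (i in with_resets) {
    seg_steps <- diff(c(0L, ens$reset_steps[[i]]))
    m <- length(seg_steps) + 1L
    final_steps <- ens$n_steps[i] - max(ens$reset_steps[[i]])
    reconstructed <- (m - 1) * mean(seg_steps) + final_steps
    expect_equal(reconstructed * 1e-6, ens$fpt_ns[i], tolerance = 1e-12)
  }
})

test_that("screening grids report speedups and a sensible argmax", {
  fx <- get_fixture()
  grid <- screen_protocols(fx$baseline, c(0, 1e3, 1e4), c(-Inf, 2.5, 3))
  expect_s3_class(grid, "isr_prediction")
  expect_equal(nrow(grid), 9)
  # degenerate r = 0 cells have speedup exactly 1
  expect_equal(grid$speedup[grid$rate_ns == 0], rep(1, 3))
  best <- attr(grid, "argmax")
  expect_gt(best$speedup, 1)
  expect_true(best$valid)
  g <- glance(grid)
  expect_equal(g$n_cells, 9)
})

test_that("overly aggressive protocols fail loudly, screening marks them invalid", {
  cv_series <- list(rep(5, 400), rep(5, 380))
  sample <- list(cv_series = cv_series, fpt_ns = c(4e-4, 3.8e-4),
                 stride_dt_fs = 1)
  expect_error(predict_mfpt(sample, 1e8, 1), "aggressive")
  grid <- screen_protocols(sample, c(0, 1e8), 1)
  expect_false(grid$valid[grid$rate_ns == 1e8])
  expect_true(grid$valid[grid$rate_ns == 0])
})
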