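test_that("the fixture generator lands in its target band with working ISR", {
  fx <- get_fixture()
  # band up to sampling noise of the 50-walker probe
  expect_gt(fx$mfpt_ns, 0.003)
  expect_lt(fx$mfpt_ns, 0.12)
  expect_false(any(fx$baseline$censored))
  # informed resetting beyond the start accelerates the fixture
  cfg <- sim_config(seed = 111, max_steps = 4e7)
  isr <- glance(simulate_fpt(fx$surface, cfg, 200,
                             protocol = reset_protocol(2e4, 3)))
  sp <- speedup(fx$baseline, isr)
  expect_gt(sp$speedup - 3 * sp$se, 1)
})

test_that("the threshold rotates about the initial position with the CV", {
  expect_equal(rotated_threshold(3, 0), 3)
  expect_equal(rotated_threshold(4, 0), 4)
  # at 90 degrees the initial position projects to 0 on the CV
  expect_equal(rotated_threshold(3, 90), 0 + (3 - 3))
  th <- 24
  expect_equal(rotated_threshold(3, th), 3 * cospi(th / 180))
})

test_that("the double well is accelerated by informed but not standard resetting", {
  res <- run_experiment("double_well", seed = 7, n_accel = 250)
  tb <- res$tables$speedups
  sr <- tb[tb$method == "SR", ]
  isr <- tb[tb$method == "ISR c=2", ]
  # standard SR never beats unbiased beyond noise anywhere on the rate grid
  expect_true(all(sr$speedup - 3 * sr$se < 1))
  # informed resetting does, at its best rate
  best <- isr[which.max(isr$speedup), ]
  expect_gt(best$speedup - 3 * best$se, 1)
})

test_that("experiments are deterministic given a seed", {
  fx <- get_fixture()
  args <- list(id = "fig1b", seed = 5, n_baseline = 20, n_accel = 20,
               rates_ns = c(1e3, 2e4), thresholds = 3, surface = fx$surface)
  a <- suppressWarnings(do.call(run_experiment, args))
  b <- suppressWarnings(do.call(run_experiment, args))
  expect_identical(a$tables$speedups, b$tables$speedups)
})

test_that("speedup curves show the two threshold classes on the fixture", {
  fx <- get_fixture()
  res <- suppressWarnings(
    run_experiment("fig1b", seed = 13, n_baseline = 150, n_accel = 120,
                   rates_ns = c(2e2, 2e3, 2e4, 2e5),
                   thresholds = c(2.5, 3), surface = fx$surface,
                   baseline = fx$baseline))
  tb <- res$tables$speedups
  far <- tb[!is.na(tb$threshold) & tb$threshold == 3, ]
  # plateau class: no collapse at the highest rates
  expect_lt(zdiff(far$speedup[far$rate_ns == 2e4],
                  far$speedup[far$rate_ns == 2e5],
                  far$speedup_se[far$rate_ns == 2e4],
                  far$speedup_se[far$rate_ns == 2e5]), 3)
  # unimodal class: a threshold inside the well collapses as r -> infinity,
  # either measurably or beyond the censoring cap entirely
  near <- tb[!is.na(tb$threshold) & tb$threshold == 2.5, ]
  hi <- near[near$rate_ns == 2e5, ]
  if (is.na(hi$speedup)) {
    expect_gt(hi$censored_frac, 0)
  } else {
    expect_lt(hi$speedup + 3 * hi$speedup_se, max(near$speedup, na.rm = TRUE))
  }
})

test_that("prediction screening experiment reports its argmax cell", {
  fx <- get_fixture()
  res <- run_experiment("fig3", seed = 17, rates_ns = c(1e3, 1e4),
                        thresholds = c(2.5, 3), surface = fx$surface,
                        baseline = fx$baseline)
  expect_true(all(c("rate_ns", "threshold", "speedup") %in%
                    names(res$tables$predictions)))
  expect_gt(res$tables$argmax$speedup, 1)
})
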