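test_that("a single deposited hill has the exact Gaussian profile", {
  eng <- metad_engine()
  eng <- metad_deposit(eng, 0)
  expect_equal(metad_bias(eng, 0), 0.5)
  expect_equal(metad_bias(eng, c(-0.15, 0.15)),
               rep(0.5 * exp(-0.5), 2), tolerance = 1e-9)
  f <- metad_bias_force(eng, 0, 0)
  expect_equal(f$fx, 0, tolerance = 1e-12)
  expect_equal(f$fy, 0)
})

test_that("well-tempered damping shrinks successive hills monotonically", {
  eng <- metad_engine(height_kt = 0.5, bias_factor = 10)
  heights <- numeric(6)
  for (k in 1:6) {
    before <- metad_bias(eng, 1)
    eng <- metad_deposit(eng, 1)
    heights[k] <- metad_bias(eng, 1) - before
  }
  expect_true(all(diff(heights) < 0))
  expect_equal(heights[1], 0.5)
  expect_equal(heights[2], 0.5 * exp(-0.5 / 9), tolerance = 1e-9)
})

test_that("the tabulated bias force agrees with finite differences", {
  eng <- metad_engine()
  set.seed(3)
  for (cv in c(-1.2, 0.4, 2)) eng <- metad_deposit(eng, cv)
  x <- seq(-2.5, 2.5, by = 0.037)
  h <- 0.005
  fd <- -(metad_bias(eng, x + h) - metad_bias(eng, x - h)) / (2 * h)
  fx <- metad_bias_force(eng, x, rep(0, length(x)))$fx
  # linear interpolation of the node derivatives differs from the chord
  # slope by O((spacing/sigma)^2) ~ 0.4%
  expect_lt(max(abs(fd - fx)) / max(abs(fx)), 5e-3)
})

test_that("zeroing the bias empties the table and is idempotent", {
  eng <- metad_deposit(metad_engine(), 0.7)
  eng <- metad_zero(eng)
  expect_true(all(eng$bias == 0))
  grid <- seq(-7, 7, by = 0.5)
  expect_true(all(metad_bias_force(eng, grid, grid)$fx == 0))
  expect_identical(metad_zero(eng)$bias, eng$bias)
})

test_that("zero-height Metadynamics is bit-identical to plain dynamics", {
  fx <- get_fixture()
  cfg <- sim_config(seed = 57, max_steps = 4e7)
  plain <- simulate_fpt(fx$surface, cfg, 20)
  null_md <- simulate_fpt(fx$surface, cfg, 20,
                          metad = metad_engine(height_kt = 0))
  expect_identical(plain$fpt_ns, null_md$fpt_ns)
})

test_that("Metadynamics accelerates barrier crossing on the fixture", {
  fx <- get_fixture()
  cfg <- sim_config(seed = 59, max_steps = 4e7)
  md <- glance(simulate_fpt(fx$surface, cfg, 100, metad = metad_engine()))
  sp <- speedup(fx$baseline, md)
  expect_gt(sp$speedup - 3 * sp$se, 1)
})

test_that("the bias is zeroed at resets in combined MetaD + SR runs", {
  fx <- get_fixture()
  cfg <- sim_config(seed = 61, max_steps = 4e7)
  # resets so frequent that few hills fit between them: final bias must be
  # bounded by the hills deposited since the last reset
  ens <- simulate_fpt(fx$surface, cfg, 10, metad = metad_engine(pace = 50),
                      protocol = reset_protocol(2e4, threshold = 3),
                      keep_bias = TRUE)
  for (i in seq_len(nrow(ens))) {
    last_reset <- max(c(0L, ens$reset_steps[[i]]))
    hills_since <- floor((ens$n_steps[i] - last_reset) / 50)
    expect_lte(max(ens$bias_table[[i]]), 0.5 * (hills_since + 1))
  }
})

test_that("long sampling flattens bias plus scaled energy (well-tempered limit)", {
  surf <- double_well_surface(16, xmin = 1, ky = 4)
  eng <- metad_engine(pace = 50, grid_min = -3, grid_max = 3)
  cfg <- sim_config(seed = 67, max_steps = 4e5)
  suppressWarnings(
    ens <- simulate_fpt(surf, cfg, 1, init = c(1, 0),
                        stop = stop_condition(threshold = -50),
                        metad = eng, keep_bias = TRUE))
  bias <- ens$bias_table[[1]]
  cvs <- seq(-3, 3, by = 0.01)
  inwell <- cvs > 0.75 & cvs < 1.25
  u <- potential_energy(surf, cvs[inwell], 0)
  free_energy_scaled <- bias[inwell] + (1 - 1 / 10) * u
  expect_lt(stats::sd(free_energy_scaled), 0.3)
})
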