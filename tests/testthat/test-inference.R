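# drift-diffusion reference system: constant force toward the target, so
# the reset-free FPT is inverse-Gaussian with known Laplace transform and
# the MFPT under resetting has a closed renewal form (helper-oracles.R)
drift_system <- function() {
  gamma <- 0.5
  D <- thermal_energy(300) / (40 * gamma)
  list(surface = linear_surface(slope = 2, ky = 1), gamma = gamma,
       D = D, v = 2 * D, L = 1)
}

test_that("probing the ensemble's own rate returns its own MFPT", {
  fx <- get_fixture()
  cfg <- sim_config(seed = 83, max_steps = 4e7)
  ens <- simulate_fpt(fx$surface, cfg, 100, protocol = reset_protocol(2e3, 3),
                      record_cv_stride = 5)
  tau <- tau_at_higher_rates(ens, 2e3, se = "none")
  expect_equal(tau$mfpt_ns, mean(ens$fpt_ns))
  expect_error(tau_at_higher_rates(ens, 500), ">=")
})

test_that("reweighted estimates at higher rates match direct simulation", {
  fx <- get_fixture()
  cfg <- sim_config(seed = 89, max_steps = 4e7)
  ens <- simulate_fpt(fx$surface, cfg, 250, protocol = reset_protocol(1e3, 3),
                      record_cv_stride = 5)
  probes <- c(2e3, 4e3)
  tau <- tau_at_higher_rates(ens, probes)
  for (k in seq_along(probes)) {
    sim <- glance(simulate_fpt(fx$surface, cfg, 250,
                               protocol = reset_protocol(probes[k], 3)))
    expect_lt(zdiff(tau$mfpt_ns[k], sim$mfpt_ns, tau$se_ns[k], sim$sem_ns), 3)
  }
})

test_that("extrapolating a constant MFPT curve returns that constant", {
  inf <- extrapolate_to_zero(c(10, 20, 30), rep(2.5, 3), rep(0.1, 3), 10)
  expect_equal(inf$mfpt0_ns, 2.5, tolerance = 1e-8)
})

test_that("extrapolation recovers the closed-form zero-rate MFPT", {
  sys <- drift_system()
  tau0 <- sys$L / sys$v / 1e6
  rstar <- 12.5
  probes <- rstar * seq(1, 3, length.out = 7)
  tau <- drift_mfpt_under_sr(probes * 1e-6, sys$L, sys$v, sys$D) / 1e6
  inf <- extrapolate_to_zero(probes, tau, 0.01 * tau, rstar)
  expect_lt(abs(inf$mfpt0_ns - tau0) / tau0, 0.03)
})

test_that("the full inference loop recovers the unbiased MFPT of the solvable model", {
  sys <- drift_system()
  tau0 <- sys$L / sys$v / 1e6
  cfg <- sim_config(friction = sys$gamma, seed = 97, max_steps = 1e7)
  rstar <- 12.5
  ens <- simulate_fpt(sys$surface, cfg, 400, init = c(0, 0),
                      stop = stop_condition(threshold = -sys$L),
                      protocol = reset_protocol(rstar),
                      record_cv_stride = 5)
  # sanity: the simulated MFPT at r* agrees with the closed renewal form
  g <- glance(ens)
  ref_r <- drift_mfpt_under_sr(rstar * 1e-6, sys$L, sys$v, sys$D) / 1e6
  expect_lt(zdiff(g$mfpt_ns, ref_r, g$sem_ns, 0), 3)
  inf <- infer_mfpt(ens, reference_mfpt_ns = tau0)
  expect_lt(zdiff(inf$mfpt0_ns, tau0, inf$se0_ns, 0.02 * tau0), 3)
  expect_lt(inf$fold_error, 1.2)
  gl <- glance(inf)
  expect_equal(gl$rstar_ns, rstar)
})

test_that("direct transit times are located at the stored crossings", {
  t <- 1:8
  cv <- c(3.0, 2.5, 2.0, 2.6, 1.8, 1.2, 0.8, 0.5)
  d <- extract_dtt(cv, t, upper = 2.35, lower = 1)
  expect_equal(nrow(d), 1)
  expect_equal(d$t_start, 4) # the re-crossing resets the clock
  expect_equal(d$t_end, 7)
  expect_equal(d$dtt, 3)
  # monotone descent: single transit from the last point above to the
  # first below
  cv2 <- seq(3, 0, by = -0.5)  # last above 2.35 at t=2, first below 1 at t=6
  d2 <- extract_dtt(cv2, seq_along(cv2), 2.35, 1)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$dtt, 4)
  # two completed transits when the series re-arms above the upper surface
  cv3 <- c(3, 1.5, 0.5, 3, 1.2, 0.9)
  d3 <- extract_dtt(cv3, seq_along(cv3), 2.35, 1)
  expect_equal(nrow(d3), 2)
  # no transit at all
  expect_equal(nrow(extract_dtt(c(3, 2, 3), 1:3, 2.35, 1)), 0)
})

test_that("transit times never exceed first-passage times", {
  fx <- get_fixture()
  cfg <- sim_config(seed = 101, max_steps = 4e7)
  ens <- simulate_fpt(fx$surface, cfg, 60, record_cv_stride = 5)
  d <- ensemble_dtt(ens, upper = 1, lower = -1)
  expect_gt(d$summary$n, 0)
  joined <- merge(d$transits, as.data.frame(ens)[c("walker", "fpt_ns")])
  expect_true(all(joined$dtt <= joined$fpt_ns + 1e-12))
})

test_that("mean transit time is insensitive to the bias deposition pace", {
  fx <- get_fixture()
  cfg <- sim_config(seed = 103, max_steps = 4e7)
  res <- lapply(c(100, 500), function(pc) {
    ens <- simulate_fpt(fx$surface, cfg, 150,
                        metad = metad_engine(pace = pc),
                        record_cv_stride = 5)
    ensemble_dtt(ens, upper = 1, lower = -1)$summary
  })
  expect_lt(zdiff(res[[1]]$mean_dtt_ns, res[[2]]$mean_dtt_ns,
                  res[[1]]$sem_ns, res[[2]]$sem_ns), 3)
})
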