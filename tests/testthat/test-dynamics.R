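test_that("Maxwell-Boltzmann sampling has the right moments and is seeded", {
  set.seed(11)
  v <- sample_maxwell_boltzmann(1e6)
  s2 <- thermal_energy(300) / 40
  expect_lt(abs(mean(v$vx)), 4 * sqrt(s2 / 1e6))
  expect_lt(abs(var(v$vx) / s2 - 1), 0.01)
  expect_lt(abs(var(v$vy) / s2 - 1), 0.01)
  set.seed(11)
  expect_identical(sample_maxwell_boltzmann(10), {
    set.seed(11)
    sample_maxwell_boltzmann(10)
  })
})

test_that("runs are deterministic and independent of batch size", {
  fx <- get_fixture()
  cfg <- sim_config(seed = 77, max_steps = 2e7)
  a <- simulate_fpt(fx$surface, cfg, 8)
  b <- simulate_fpt(fx$surface, cfg, 8)
  expect_identical(a$fpt_ns, b$fpt_ns)
  c1 <- simulate_fpt(fx$surface, cfg, 4)
  c2 <- simulate_fpt(fx$surface, cfg, 4, walker_offset = 4)
  expect_identical(a$fpt_ns, c(c1$fpt_ns, c2$fpt_ns))
})

test_that("with zero friction the integrator conserves energy (Verlet limit)", {
  surf <- linear_surface(slope = 0, ky = 3)
  cfg <- sim_config(friction = 0, seed = 5)
  tr <- simulate_trajectory(surf, cfg, 1e5, init = c(0, 1.2), record_stride = 1)
  kT <- thermal_energy(300)
  e <- 0.5 * 40 * (tr$vx^2 + tr$vy^2) + kT * potential_energy(surf, tr$x, tr$y)
  # no secular drift; bounded shadow-Hamiltonian oscillation of order (w dt)^2
  drift <- (mean(utils::tail(e, 1000)) - mean(utils::head(e, 1000))) / mean(e)
  expect_lt(abs(drift), 1e-6)
  expect_lt(diff(range(e)) / abs(mean(e)), 1e-5)
})

test_that("long runs reproduce equipartition and the Boltzmann marginal", {
  surf <- linear_surface(slope = 0, ky = 4)
  cfg <- sim_config(seed = 13)
  tr <- simulate_trajectory(surf, cfg, 2e7, init = c(0, 0), record_stride = 10)
  kT_m <- thermal_energy(300) / 40
  expect_lt(abs(mean(tr$vx^2) / kT_m - 1), 0.01)
  expect_lt(abs(mean(tr$vy^2) / kT_m - 1), 0.01)
  # y-marginal variance against direct quadrature of exp(-U)
  z <- stats::integrate(function(y) exp(-4 * y^2 / 2), -Inf, Inf)$value
  v_ref <- stats::integrate(function(y) y^2 * exp(-4 * y^2 / 2), -Inf, Inf)$value / z
  expect_lt(abs(var(tr$y) / v_ref - 1), 0.03)
})

test_that("walkers starting past the target report first passage immediately", {
  fx <- get_fixture()
  cfg <- sim_config(seed = 3, max_steps = 100)
  ens <- simulate_fpt(fx$surface, cfg, 5, init = c(-2, 0))
  expect_true(all(ens$fpt_ns <= 2e-6))
  expect_true(all(!ens$censored))
})

test_that("free diffusion under resetting matches the closed-form MFPT", {
  # overdamped regime: gamma = 0.5/fs, flat x, harmonic y
  surf <- linear_surface(slope = 0, ky = 1)
  gamma <- 0.5
  D <- thermal_energy(300) / (40 * gamma)
  r_ns <- 100
  ref <- free_mfpt_under_sr(r_ns * 1e-6, L = 1, D = D) / 1e6 # ns
  cfg <- sim_config(friction = gamma, seed = 19, max_steps = 5e7)
  ens <- simulate_fpt(surf, cfg, 300, init = c(0, 0),
                      stop = stop_condition(threshold = -1),
                      protocol = reset_protocol(r_ns))
  g <- glance(ens)
  expect_lt(zdiff(g$mfpt_ns, ref, g$sem_ns, 0), 3)
})

test_that("walkers exceeding max_steps are censored with a warning", {
  surf <- double_well_surface(30, xmin = 1)
  cfg <- sim_config(seed = 2, max_steps = 1e4)
  expect_warning(
    ens <- simulate_fpt(surf, cfg, 3, init = c(1, 0),
                        stop = stop_condition(threshold = -0.9)),
    "censored")
  expect_true(all(ens$censored))
  expect_warning(expect_true(is.nan(mfpt(ens)) || is.na(mfpt(ens))),
                 "censored")
})
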