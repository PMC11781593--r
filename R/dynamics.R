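KB_KJMOL <- 0.0083144621
# 1 internal energy unit (g/mol * A^2/fs^2) = 1e4 kJ/mol
KB_INTERNAL <- KB_KJMOL * 1e-4

#' Thermal energy in internal units
#'
#' `k_BT` expressed in the package's internal unit system
#' (g/mol * Angstrom^2 / fs^2).
#'
#' @param temperature temperature in Kelvin.
#' @return numeric scalar.
#' @export
thermal_energy <- function(temperature = 300) KB_INTERNAL * temperature

#' Simulation configuration
#'
#' Parameters of the underdamped Langevin integrator. Defaults follow the
#' single-particle setup used for the modified Faradjian--Elber surface:
#' an argon-like particle (40 g/mol) at 300 K with friction 0.01 fs^-1 and
#' a 1 fs time step.
#'
#' @param temperature Kelvin.
#' @param friction Langevin friction coefficient, fs^-1. `0` gives
#'   deterministic (NVE, velocity-Verlet) dynamics.
#' @param timestep integration time step, fs.
#' @param mass particle mass, g/mol.
#' @param max_steps censoring cap on trajectory length, steps. Walkers that
#'   exceed it are flagged censored and excluded from MFPT estimates with a
#'   warning.
#' @param fpt_check_stride how often (in steps) the stop condition is
#'   evaluated; 1 checks every step.
#' @param seed integer seed. Each walker derives an independent stream from
#'   `(seed, walker_id)`, so results do not depend on batch size or order.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(temperature = 300, friction = 0.01, timestep = 1,
                       mass = 40, max_steps = 1e9, fpt_check_stride = 1,
                       seed = 1) {
  stopifnot(temperature > 0, friction >= 0, timestep > 0, mass > 0,
            max_steps >= 1, fpt_check_stride >= 1)
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, mass = mass,
                 max_steps = as.double(max_steps),
                 fpt_check_stride = as.integer(fpt_check_stride),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Stop (first-passage) condition
#'
#' First passage occurs when a collective variable
#' `cv = x cos(theta) + y sin(theta)` crosses a threshold. The default is
#' the raw `x` coordinate dropping below -1 Angstrom.
#'
#' @param threshold CV value defining the target, Angstrom.
#' @param direction `"below"` or `"above"`: which side of the threshold
#'   counts as arrival.
#' @param cv_theta rotation angle of the CV in degrees; 0 is the raw `x`
#'   coordinate.
#' @return An object of class `stop_condition`.
#' @export
stop_condition <- function(threshold = -1, direction = c("below", "above"),
                           cv_theta = 0) {
  direction <- match.arg(direction)
  structure(list(threshold = threshold, below = direction == "below",
                 ct = cospi(cv_theta / 180), st = sinpi(cv_theta / 180)),
            class = "stop_condition")
}

#' Sample velocities from the Maxwell-Boltzmann distribution
#'
#' Each Cartesian component is Gaussian with mean zero and variance
#' `k_BT / m`. Uses R's RNG; set a seed with [set.seed()] for
#' reproducibility.
#'
#' @param n number of samples.
#' @param temperature Kelvin.
#' @param mass g/mol.
#' @return A tibble with columns `vx`, `vy` in Angstrom/fs.
#' @export
sample_maxwell_boltzmann <- function(n, temperature = 300, mass = 40) {
  stopifnot(temperature > 0, mass > 0)
  sd <- sqrt(thermal_energy(temperature) / mass)
  tibble::tibble(vx = stats::rnorm(n, 0, sd), vy = stats::rnorm(n, 0, sd))
}

#' Run a batch of walkers until first passage
#'
#' Propagates `n_walkers` independent underdamped Langevin trajectories
#' (BAOAB splitting) from a common initial position until each satisfies
#' the stop condition, optionally under a resetting protocol and/or a
#' well-tempered Metadynamics bias. Walkers retire from the batch as they
#' finish; each walker has its own RNG stream derived from
#' `(config$seed, walker_offset + walker)`.
#'
#' @param surface a `potential_surface`.
#' @param config a [sim_config()].
#' @param n_walkers number of trajectories.
#' @param init initial position `c(x, y)` in Angstrom; resets return the
#'   walker here with thermally resampled momenta.
#' @param stop a [stop_condition()].
#' @param protocol optional [reset_protocol()].
#' @param metad optional [metad_engine()] template; each walker carries its
#'   own bias, zeroed at every reset.
#' @param record_cv_stride if positive, record the collective variable every
#'   this many steps (value at the first-passage step included when the
#'   stride divides it). Needed for the reweighting predictor and DTT
#'   extraction.
#' @param record_cv_theta rotation angle (degrees) of the recorded CV;
#'   defaults to the protocol's CV when one is supplied, else 0 (raw `x`).
#' @param walker_offset id offset so that ensembles can be grown without
#'   replaying streams.
#' @param keep_bias return each walker's final Metadynamics bias table as a
#'   list column (requires `metad`).
#' @return A tibble of class `fpt_ensemble` with one row per walker:
#'   `walker`, `fpt_ns`, `n_steps`, `n_resets`, `censored`, plus list
#'   columns `cv_series` (when recording) and `reset_steps` (when
#'   resetting). Simulation metadata is carried in attributes
#'   (`dt_fs`, `record_stride`, `config`, `protocol`, `stop`, `surface`).
#' @export
simulate_fpt <- function(surface, config, n_walkers, init = c(3, 0),
                         stop = stop_condition(), protocol = NULL,
                         metad = NULL, record_cv_stride = 0,
                         record_cv_theta = NULL, walker_offset = 0,
                         keep_bias = FALSE) {
  check_surface(surface)
  stopifnot(inherits(config, "sim_config"), inherits(stop, "stop_condition"),
            n_walkers >= 1, length(init) == 2)
  proto_list <- list()
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "reset_protocol"))
    proto_list <- unclass(protocol)
  }
  metad_list <- list()
  if (!is.null(metad)) {
    stopifnot(inherits(metad, "metad_engine"))
    metad_list <- metad[c("pace", "height", "sigma", "biasfactor", "grid_min",
                          "grid_max", "grid_spacing", "ct", "st")]
    metad_list$keep_bias <- isTRUE(keep_bias)
  }
  if (is.null(record_cv_theta))
    record_cv_theta <- if (!is.null(protocol)) protocol$theta_deg else 0
  rct <- cospi(record_cv_theta / 180)
  rst <- sinpi(record_cv_theta / 180)

  res <- cpp_run_until_fpt(surface, unclass(config), unclass(stop),
                           proto_list, metad_list, as.integer(n_walkers),
                           init[1], init[2], as.integer(record_cv_stride),
                           rct, rst, config$seed, as.integer(walker_offset))

  out <- tibble::tibble(
    walker = walker_offset + seq_len(n_walkers),
    fpt_ns = res$fpt_fs / 1e6,
    n_steps = res$n_steps,
    n_resets = res$n_resets,
    censored = res$censored
  )
  if (record_cv_stride > 0) out$cv_series <- res$cv_series
  if (length(res$reset_steps) > 0) out$reset_steps <- res$reset_steps
  if (length(res$bias_tables) > 0) out$bias_table <- res$bias_tables
  if (any(out$censored))
    warning(sum(out$censored), " walker(s) exceeded max_steps and were censored")
  structure(out,
            class = c("fpt_ensemble", class(out)),
            dt_fs = config$timestep,
            record_stride = record_cv_stride,
            record_cv_theta = record_cv_theta,
            config = config, protocol = protocol, stop = stop,
            surface = surface, metad = metad, init = init)
}

#' Sample a fixed-length trajectory
#'
#' Propagates a single trajectory for `n_steps` without any stopping
#' condition, recording phase-space points at a stride. Used for
#' thermodynamic fidelity checks and to produce CV series.
#'
#' @inheritParams simulate_fpt
#' @param n_steps number of integration steps.
#' @param record_stride recording stride in steps.
#' @param walker_id stream id for the RNG.
#' @return A tibble with columns `time_fs`, `x`, `y`, `vx`, `vy`.
#' @export
simulate_trajectory <- function(surface, config, n_steps, init = c(3, 0),
                                record_stride = 1, walker_id = 0) {
  check_surface(surface)
  stopifnot(inherits(config, "sim_config"))
  res <- cpp_sample_trajectory(surface, unclass(config), init[1], init[2],
                               as.double(n_steps), as.integer(record_stride),
                               config$seed, as.integer(walker_id))
  k <- length(res$x)
  tibble::tibble(time_fs = seq_len(k) * record_stride * config$timestep,
                 x = res$x, y = res$y, vx = res$vx, vy = res$vy)
}

#' Summarize a first-passage ensemble
#'
#' @param x an `fpt_ensemble`.
#' @param ... unused.
#' @return A one-row tibble: `n`, `n_censored`, `mfpt_ns`, `sem_ns`,
#'   `cv` (coefficient of variation of the FPTs), `mean_resets`.
#' @exportS3Method generics::glance
glance.fpt_ensemble <- function(x, ...) {
  ok <- !x$censored
  f <- x$fpt_ns[ok]
  tibble::tibble(
    n = nrow(x),
    n_censored = sum(!ok),
    mfpt_ns = mean(f),
    sem_ns = stats::sd(f) / sqrt(length(f)),
    cv = stats::sd(f) / mean(f),
    mean_resets = if ("n_resets" %in% names(x)) mean(x$n_resets[ok]) else 0
  )
}

#' Drop censored walkers from an ensemble
#'
#' Returns the uncensored subset with ensemble attributes preserved.
#' Useful when a handful of censored walkers would otherwise block
#' downstream reweighting (which requires completed first passages); the
#' censored fraction should always be reported alongside any such use.
#'
#' @param ensemble an `fpt_ensemble`.
#' @return the uncensored `fpt_ensemble`.
#' @export
drop_censored <- function(ensemble) {
  stopifnot(inherits(ensemble, "fpt_ensemble"))
  keep_attrs <- c("dt_fs", "record_stride", "record_cv_theta", "config",
                  "protocol", "stop", "surface", "metad", "init")
  out <- ensemble[!ensemble$censored, ]
  class(out) <- class(ensemble)
  for (a in keep_attrs) attr(out, a) <- attr(ensemble, a)
  out
}

#' Mean first-passage time of an ensemble
#'
#' @param ensemble an `fpt_ensemble`.
#' @return MFPT in ns (censored walkers excluded, with a warning).
#' @export
mfpt <- function(ensemble) {
  stopifnot(inherits(ensemble, "fpt_ensemble"))
  if (any(ensemble$censored))
    warning("excluding ", sum(ensemble$censored), " censored walker(s)")
  mean(ensemble$fpt_ns[!ensemble$censored])
}
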