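#' Threshold line rotated with the collective variable
#'
#' When the CV is rotated by `theta` about the x-axis, the resetting
#' threshold line `x = c` is rotated by the same angle about the initial
#' position `(x0, 0)`, giving a threshold `c' = x0 cos(theta) + (c - x0)`
#' on the rotated CV.
#'
#' @param threshold threshold `c` on the raw `x` coordinate, Angstrom.
#' @param theta_deg CV rotation angle, degrees.
#' @param x0 x-coordinate of the initial position.
#' @return threshold value on the rotated CV.
#' @export
rotated_threshold <- function(threshold, theta_deg, x0 = 3) {
  x0 * cospi(theta_deg / 180) + (threshold - x0)
}

default_rate_grid <- function() c(5, 20, 100, 500, 1000, 5000, 1e4, 1e5)

#' Scripted experiments on the model potentials
#'
#' Reproduces the package's headline phenomenology at configurable
#' ensemble sizes. Available experiments:
#'
#' * `"fig1b"` -- speedup vs resetting rate for standard SR and informed
#'   resetting at thresholds 1..5 Angstrom on the modified
#'   Faradjian--Elber surface, by direct simulation.
#' * `"fig3"` -- the same speedup curves *predicted* from a single
#'   reset-free ensemble by the reweighting predictor.
#' * `"fig2"` -- maximal speedup of MetaD, MetaD+SR and MetaD+ISR as the
#'   CV is rotated away from the optimal `x` axis, with resetting rates
#'   screened from reset-free MetaD trajectories.
#' * `"fig4"` -- unbiased-MFPT inference by extrapolation from ISR/SR
#'   ensembles at a range of sampling rates `r*`.
#' * `"dtt_toy"` -- mean direct transit time across MetaD bias paces on
#'   the model surface.
#' * `"double_well"` -- a system standard SR cannot accelerate but
#'   informed resetting can.
#'
#' @param id experiment identifier.
#' @param seed integer seed.
#' @param n_baseline unbiased-trajectory count.
#' @param n_accel accelerated-trajectory count per protocol.
#' @param rates_ns,thresholds,thetas_deg grids (sensible defaults per
#'   experiment).
#' @param baseline optional precomputed unbiased `fpt_ensemble` on the
#'   default surface (with recorded CV), reused across experiments.
#' @param surface surface to run on; defaults to [mfe_surface()].
#' @param out_dir optional directory; when given, result tables are
#'   written as CSV, figures as PNG, and a JSON manifest records inputs.
#' @return A list with `tables` (named list of tibbles) and `manifest`.
#' @export
run_experiment <- function(id = c("fig1b", "fig3", "fig2", "fig4",
                                  "dtt_toy", "double_well"),
                           seed = 1, n_baseline = 200, n_accel = 500,
                           rates_ns = NULL, thresholds = 1:5,
                           thetas_deg = c(0, 8, 16, 24),
                           baseline = NULL, surface = mfe_surface(),
                           out_dir = NULL) {
  id <- match.arg(id)
  res <- switch(id,
    fig1b = exp_fig1b(surface, seed, n_baseline, n_accel,
                      rates_ns %||% default_rate_grid(), thresholds, baseline),
    fig3 = exp_fig3(surface, seed, n_baseline,
                    rates_ns %||% default_rate_grid(), thresholds, baseline),
    fig2 = exp_fig2(surface, seed, n_baseline, n_accel, thetas_deg, baseline),
    fig4 = exp_fig4(surface, seed, n_baseline, n_accel,
                    rates_ns %||% c(10, 100, 1000), baseline),
    dtt_toy = exp_dtt_toy(surface, seed, n_accel),
    double_well = exp_double_well(seed, n_accel))
  res$manifest <- list(id = id, seed = seed, n_baseline = n_baseline,
                       n_accel = n_accel, surface = unclass(surface),
                       timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(out_dir)) write_experiment(res, out_dir, id)
  invisible(res)
}

baseline_config <- function(seed) sim_config(seed = seed, max_steps = 5e8)

ensure_baseline <- function(baseline, surface, seed, n_baseline, stride = 100) {
  if (!is.null(baseline)) return(baseline)
  simulate_fpt(surface, baseline_config(seed), n_baseline,
               record_cv_stride = stride)
}

accel_config <- function(seed, base_mfpt_ns) {
  # censoring cap: 25x the unbiased scale; protocols slower than that are
  # reported as unresolved rather than simulated to exhaustion
  sim_config(seed = seed, max_steps = min(25 * base_mfpt_ns * 1e6, 5e9))
}

one_protocol_row <- function(surface, cfg, n, proto, base_glance,
                             metad = NULL, label, record_stride = 0) {
  ens <- suppressWarnings(
    simulate_fpt(surface, cfg, n, protocol = proto, metad = metad,
                 record_cv_stride = record_stride))
  g <- glance(ens)
  # censored walkers bias the MFPT; report the protocol as unresolved
  ok <- g$n_censored == 0
  sp <- if (ok) speedup(base_glance, g) else
    tibble::tibble(speedup = NA_real_, se = NA_real_)
  tibble::tibble(method = label, rate_ns = proto$rate_ns,
                 threshold = if (proto$conditional) proto$threshold else NA,
                 mfpt_ns = if (ok) g$mfpt_ns else NA_real_,
                 sem_ns = if (ok) g$sem_ns else NA_real_,
                 speedup = sp$speedup, speedup_se = sp$se,
                 mean_resets = g$mean_resets,
                 censored_frac = g$n_censored / g$n)
}

exp_fig1b <- function(surface, seed, n_baseline, n_accel, rates, thresholds,
                      baseline) {
  base <- ensure_baseline(baseline, surface, seed, n_baseline)
  bg <- glance(base)
  cfg <- accel_config(seed + 1, bg$mfpt_ns)
  grid <- tidyr::expand_grid(threshold = c(NA, thresholds), rate_ns = rates)
  rows <- purrr::pmap_dfr(grid, function(threshold, rate_ns) {
    proto <- if (is.na(threshold)) reset_protocol(rate_ns)
             else reset_protocol(rate_ns, threshold = threshold)
    label <- if (is.na(threshold)) "SR" else paste0("ISR c=", threshold)
    one_protocol_row(surface, cfg, n_accel, proto, bg, label = label)
  })
  if (any(rows$censored_frac > 0.01))
    warning("some protocols censored more than 1% of walkers")
  list(tables = list(speedups = rows, baseline = glance(base)),
       baseline_ensemble = base)
}

exp_fig3 <- function(surface, seed, n_baseline, rates, thresholds, baseline) {
  base <- ensure_baseline(baseline, surface, seed, n_baseline)
  pred <- screen_protocols(base, rates, c(-Inf, thresholds))
  list(tables = list(predictions = tibble::as_tibble(pred),
                     argmax = attr(pred, "argmax"),
                     baseline = glance(base)),
       prediction = pred, baseline_ensemble = base)
}

metad_grid_bounds <- function(theta_deg) {
  # rotated CVs pick up the stretched y direction; keep the grid edge
  # beyond any thermally reachable projection
  if (abs(theta_deg) < 1e-9) c(-12, 12) else c(-60, 60)
}

exp_fig2 <- function(surface, seed, n_baseline, n_accel, thetas, baseline) {
  base <- ensure_baseline(baseline, surface, seed, n_baseline)
  bg <- glance(base)
  screen_rates <- c(100, 1000, 5000, 1e4, 5e4, 1e5)
  rows <- purrr::map_dfr(thetas, function(th) {
    gb <- metad_grid_bounds(th)
    eng <- metad_engine(cv_theta = th, grid_min = gb[1], grid_max = gb[2],
                        grid_spacing = 0.01)
    cfg <- accel_config(seed + 2 + round(th), bg$mfpt_ns)
    # reset-free MetaD ensemble: both the MetaD-alone measurement and the
    # sample from which useful rates are screened
    md <- suppressWarnings(
      simulate_fpt(surface, cfg, n_accel, metad = eng,
                   record_cv_stride = 10, record_cv_theta = th))
    md <- drop_censored(md)
    gmd <- glance(md)
    sp_md <- speedup(bg, gmd)
    cth <- rotated_threshold(3, th)
    scr_isr <- screen_protocols(md, screen_rates, cth)
    scr_sr <- screen_protocols(md, screen_rates, -Inf)
    r_isr <- attr(scr_isr, "argmax")$rate_ns
    r_sr <- attr(scr_sr, "argmax")$rate_ns
    isr_row <- one_protocol_row(surface, cfg, n_accel,
                                reset_protocol(r_isr, cth, cv_theta = th),
                                bg, metad = eng, label = "MetaD+ISR")
    sr_row <- one_protocol_row(surface, cfg, n_accel,
                               reset_protocol(r_sr, cv_theta = th),
                               bg, metad = eng, label = "MetaD+SR")
    dplyr::bind_rows(
      tibble::tibble(method = "MetaD", rate_ns = 0, threshold = NA,
                     mfpt_ns = gmd$mfpt_ns, sem_ns = gmd$sem_ns,
                     speedup = sp_md$speedup, speedup_se = sp_md$se,
                     mean_resets = 0, censored_frac = gmd$n_censored / gmd$n),
      sr_row, isr_row) |>
      dplyr::mutate(theta_deg = th, .before = 1)
  })
  list(tables = list(speedups = rows, baseline = glance(base)),
       baseline_ensemble = base)
}

exp_fig4 <- function(surface, seed, n_baseline, n_accel, rstars, baseline) {
  base <- ensure_baseline(baseline, surface, seed, n_baseline)
  bg <- glance(base)
  grid <- tidyr::expand_grid(method = c("SR", "ISR c=3", "ISR c=4"),
                             rstar = rstars)
  rows <- purrr::pmap_dfr(grid, function(method, rstar) {
    thr <- switch(method, "SR" = NULL, "ISR c=3" = 3, "ISR c=4" = 4)
    proto <- reset_protocol(rstar, threshold = thr)
    cfg <- accel_config(seed + 3, bg$mfpt_ns)
    ens <- simulate_fpt(surface, cfg, n_accel, protocol = proto,
                        record_cv_stride = 10)
    g <- glance(ens)
    inf <- infer_mfpt(ens, reference_mfpt_ns = bg$mfpt_ns)
    tibble::tibble(method = method, rstar_ns = rstar,
                   mfpt_r_ns = g$mfpt_ns,
                   speedup = bg$mfpt_ns / g$mfpt_ns,
                   inferred_mfpt_ns = inf$mfpt0_ns,
                   inferred_se_ns = inf$se0_ns,
                   fold_error = inf$fold_error)
  })
  list(tables = list(inference = rows, baseline = glance(base)),
       baseline_ensemble = base)
}

exp_dtt_toy <- function(surface, seed, n_accel, paces = c(100, 300, 1000),
                        upper = 1, lower = -1) {
  rows <- purrr::map_dfr(paces, function(pc) {
    eng <- metad_engine(pace = pc)
    cfg <- sim_config(seed = seed + pc, max_steps = 1e8)
    ens <- simulate_fpt(surface, cfg, n_accel, metad = eng,
                        record_cv_stride = 10)
    d <- ensemble_dtt(ens, upper, lower)
    g <- glance(ens)
    tibble::tibble(pace = pc, mfpt_ns = g$mfpt_ns,
                   n_transits = d$summary$n,
                   mean_dtt_ns = d$summary$mean_dtt_ns,
                   dtt_sem_ns = d$summary$sem_ns)
  })
  list(tables = list(dtt = rows))
}

exp_double_well <- function(seed, n_accel, barrier_kt = 4) {
  # a wide, soft well: informed resetting prunes the outer half of the
  # well, standard resetting only interrupts crossings
  surf <- double_well_surface(barrier_kt, xmin = 2)
  cfg <- sim_config(seed = seed, max_steps = 2e8)
  stop <- stop_condition(threshold = -1.6)
  init <- c(2, 0)
  base <- simulate_fpt(surf, cfg, n_accel, init = init, stop = stop)
  bg <- glance(base)
  isr_rates <- c(1e3, 1e4, 1e5)
  sr_rates <- c(1e2, 1e3)  # beyond this standard SR stalls the dynamics
  rows <- dplyr::bind_rows(
    purrr::map_dfr(sr_rates, function(r)
      dplyr::mutate(
        speedup(bg, glance(simulate_fpt(surf, cfg, n_accel, init = init,
                                        stop = stop,
                                        protocol = reset_protocol(r)))),
        method = "SR", rate_ns = r)),
    purrr::map_dfr(isr_rates, function(r)
      dplyr::mutate(
        speedup(bg, glance(simulate_fpt(surf, cfg, n_accel, init = init,
                                        stop = stop,
                                        protocol = reset_protocol(r, 2)))),
        method = "ISR c=2", rate_ns = r)))
  list(tables = list(speedups = rows, baseline = bg))
}

write_experiment <- function(res, out_dir, id) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(res$tables)) {
    readr::write_csv(res$tables[[nm]],
                     file.path(out_dir, paste0(id, "_", nm, ".csv")))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, paste0(id, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  tb <- res$tables[[1]]
  if (all(c("rate_ns", "speedup") %in% names(tb))) {
    p <- ggplot2::ggplot(dplyr::filter(tb, .data$rate_ns > 0),
                         ggplot2::aes(.data$rate_ns, .data$speedup,
                                      colour = .data$method)) +
      ggplot2::geom_point() + ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "resetting rate (1/ns)", y = "speedup")
    try(ggplot2::ggsave(file.path(out_dir, paste0(id, "_speedup.png")), p,
                        width = 6, height = 4, dpi = 150), silent = TRUE)
  }
  invisible(res)
}

#' Fast-converging fixture system for tests
#'
#' Builds a scaled-down modified Faradjian--Elber surface (reduced ridge
#' and saddle barriers) whose unbiased MFPT falls in a target band, so
#' that full resetting phenomenology -- plateauing speedup for thresholds
#' beyond the start, unimodal speedup for tighter ones -- can be exercised
#' in seconds. If the measured MFPT misses the band the barrier is
#' adjusted geometrically and the measurement repeated.
#'
#' @param seed integer seed.
#' @param n_baseline walkers in the cached reference ensemble.
#' @param target_band_ns acceptable `c(min, max)` unbiased MFPT, ns.
#' @param ridge_kt,saddle_kt starting barrier heights, `k_BT`.
#' @param yscale y-direction rescale factor of the fixture surface.
#' @param record_stride CV recording stride of the cached ensemble, steps.
#' @return A list: `surface`, `config`, `baseline` (an `fpt_ensemble` with
#'   recorded CV series), `mfpt_ns`.
#' @export
generate_fixture <- function(seed = 1, n_baseline = 200,
                             target_band_ns = c(0.005, 0.08),
                             ridge_kt = 3.5, saddle_kt = 1.2, yscale = 0.6,
                             record_stride = 10) {
  ridge <- ridge_kt
  for (attempt in 1:6) {
    surf <- mfe_surface(A2 = ridge, B = 1 - saddle_kt / ridge,
                        yscale = yscale)
    cfg <- sim_config(seed = seed, max_steps = 2e7)
    probe <- simulate_fpt(surf, cfg, min(50, n_baseline))
    m <- mfpt(probe)
    if (m <= target_band_ns[2] && m >= target_band_ns[1]) break
    ridge <- if (m > target_band_ns[2]) ridge * 0.8 else ridge * 1.25
    saddle_kt <- min(saddle_kt, ridge * 0.5)
  }
  baseline <- simulate_fpt(surf, cfg, n_baseline,
                           record_cv_stride = record_stride)
  list(surface = surf, config = cfg, baseline = baseline,
       mfpt_ns = mfpt(baseline))
}
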