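#' Evaluate the MFPT at rates above the sampling rate
#'
#' Trajectories simulated with informed resetting at a rate `r*` can be
#' reweighted to any higher rate `r > r*` without new simulations: by the
#' memorylessness of exponential clocks, superposing an independent clock
#' of rate `r - r*` on the `r*` process yields exactly the `r` process.
#' Each stored trajectory (including its internal resets) therefore serves
#' as a reset-free sample with respect to the *added* clock, and the
#' reset-free predictor applies with rate `r - r*`.
#'
#' @param ensemble an `fpt_ensemble` produced by [simulate_fpt()] with a
#'   resetting protocol and `record_cv_stride > 0`.
#' @param probe_rates_ns rates `r >= r*` at which to evaluate the MFPT,
#'   ns^-1.
#' @param se `"bootstrap"` (default) or `"none"`.
#' @param boot_n bootstrap replicates.
#' @return A tibble: `rate_ns`, `mfpt_ns`, `se_ns` (when requested).
#' @export
tau_at_higher_rates <- function(ensemble, probe_rates_ns,
                                se = c("bootstrap", "none"), boot_n = 200) {
  se <- match.arg(se)
  stopifnot(inherits(ensemble, "fpt_ensemble"))
  proto <- attr(ensemble, "protocol")
  if (is.null(proto)) stop("ensemble was not simulated with resetting")
  rstar <- proto$rate_ns
  if (any(probe_rates_ns < rstar))
    stop("probe rates must be >= the ensemble's own rate r* = ", rstar)
  thr <- if (proto$conditional) proto$threshold else NULL
  dirn <- if (proto$greater) "above" else "below"
  purrr::map_dfr(probe_rates_ns, function(r) {
    p <- predict_mfpt(ensemble, r - rstar, thr, direction = dirn,
                      se = se, boot_n = boot_n)
    tibble::tibble(rate_ns = r, mfpt_ns = p$mfpt_ns,
                   se_ns = if (se == "bootstrap") p$se_ns else NA_real_)
  })
}

#' Extrapolate the MFPT-vs-rate curve to zero resetting rate
#'
#' Fits a quadratic in `r` to `log(tau(r))` over the probe rates, weighted
#' by the relative variances of the estimates, and evaluates the fit at
#' `r = 0` to infer the MFPT without resetting. The uncertainty comes from
#' the fit covariance, propagated through the exponential.
#'
#' @param rates_ns probe rates, ns^-1 (at least 3).
#' @param tau_ns MFPT estimates at those rates.
#' @param se_ns standard errors of the estimates (optional; equal weights
#'   when missing).
#' @param rstar_ns the sampling rate `r*` the estimates were derived from
#'   (metadata only).
#' @param reference_mfpt_ns optional known unbiased MFPT; when supplied the
#'   fold-error of the extrapolation is reported.
#' @return An object of class `isr_inference`.
#' @export
extrapolate_to_zero <- function(rates_ns, tau_ns, se_ns = NULL,
                                rstar_ns = NA_real_,
                                reference_mfpt_ns = NULL) {
  stopifnot(length(rates_ns) >= 3, length(tau_ns) == length(rates_ns),
            all(tau_ns > 0))
  w <- if (is.null(se_ns) || all(!is.finite(se_ns))) {
    rep(1, length(rates_ns))
  } else {
    rel <- pmax(se_ns / tau_ns, 1e-6)
    1 / rel^2
  }
  df <- data.frame(r = rates_ns, logtau = log(tau_ns), w = w)
  fit <- stats::lm(logtau ~ r + I(r^2), data = df, weights = w)
  if (any(!is.finite(stats::coef(fit))) || fit$df.residual < 0)
    stop("ill-conditioned extrapolation fit")
  pr <- stats::predict(fit, newdata = data.frame(r = 0), se.fit = TRUE)
  mfpt0 <- unname(exp(pr$fit))
  se0 <- mfpt0 * unname(pr$se.fit)
  fold <- if (is.null(reference_mfpt_ns)) NA_real_ else {
    e <- mfpt0 / reference_mfpt_ns
    max(e, 1 / e)
  }
  structure(list(fit = fit, rates_ns = rates_ns, tau_ns = tau_ns,
                 se_ns = se_ns, rstar_ns = rstar_ns, mfpt0_ns = mfpt0,
                 se0_ns = se0, reference_mfpt_ns = reference_mfpt_ns,
                 fold_error = fold),
            class = "isr_inference")
}

#' Infer the unbiased MFPT from a resetting-accelerated ensemble
#'
#' Convenience wrapper: evaluates the MFPT at probe rates above the
#' ensemble's own rate `r*` with [tau_at_higher_rates()] and extrapolates
#' the curve to `r = 0` with [extrapolate_to_zero()].
#'
#' @inheritParams tau_at_higher_rates
#' @param probe_rates_ns probe rates; default is 7 points spanning
#'   `[r*, 3 r*]`.
#' @param reference_mfpt_ns optional known unbiased MFPT for reporting the
#'   fold-error.
#' @return An `isr_inference` object.
#' @export
infer_mfpt <- function(ensemble, probe_rates_ns = NULL, boot_n = 200,
                       reference_mfpt_ns = NULL) {
  proto <- attr(ensemble, "protocol")
  if (is.null(proto)) stop("ensemble was not simulated with resetting")
  rstar <- proto$rate_ns
  if (is.null(probe_rates_ns))
    probe_rates_ns <- rstar * seq(1, 3, length.out = 7)
  tau <- tau_at_higher_rates(ensemble, probe_rates_ns, boot_n = boot_n)
  extrapolate_to_zero(tau$rate_ns, tau$mfpt_ns, tau$se_ns, rstar,
                      reference_mfpt_ns)
}

#' @export
print.isr_inference <- function(x, ...) {
  cat("<isr_inference: r* = ", x$rstar_ns, " /ns>\n", sep = "")
  cat("  extrapolated unbiased MFPT: ", signif(x$mfpt0_ns, 4), " +/- ",
      signif(x$se0_ns, 3), " ns\n", sep = "")
  if (!is.na(x$fold_error))
    cat("  fold-error vs reference (", x$reference_mfpt_ns, " ns): ",
        signif(x$fold_error, 3), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.isr_inference <- function(x, ...) {
  tibble::tibble(rate_ns = x$rates_ns, mfpt_ns = x$tau_ns,
                 se_ns = x$se_ns %||% NA_real_,
                 fitted_ns = exp(stats::fitted(x$fit)))
}

#' @exportS3Method generics::glance
glance.isr_inference <- function(x, ...) {
  tibble::tibble(rstar_ns = x$rstar_ns, mfpt0_ns = x$mfpt0_ns,
                 se0_ns = x$se0_ns, n_probes = length(x$rates_ns),
                 fold_error = x$fold_error)
}

#' Extract direct transit times from a CV time series
#'
#' A direct transit is the final committed barrier crossing: the segment
#' from the *last* sample beyond the upper surface to the *first*
#' subsequent sample beyond the lower surface. Excursions that recross the
#' upper surface before committing are not counted; after a completed
#' transit the series must return beyond the upper surface before a new
#' transit can begin. Crossings are located at stored samples (no sub-step
#' interpolation).
#'
#' @param cv numeric CV series (decreasing through the transition region
#'   for the default direction).
#' @param time time stamps of the samples, same length as `cv` (any unit;
#'   the transit times inherit it).
#' @param upper,lower the two surfaces bounding the transition region,
#'   `upper > lower`. A transit runs from above `upper` to below `lower`.
#' @return A tibble with one row per completed transit: `t_start`, `t_end`,
#'   `dtt`. Empty (zero rows) when no transit completes.
#' @export
extract_dtt <- function(cv, time, upper, lower) {
  stopifnot(upper > lower, length(cv) == length(time))
  last_above <- NA_integer_
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_along(cv)) {
    if (cv[i] > upper) {
      last_above <- i
    } else if (cv[i] < lower && !is.na(last_above)) {
      starts <- c(starts, last_above)
      ends <- c(ends, i)
      last_above <- NA_integer_
    }
  }
  tibble::tibble(t_start = time[starts], t_end = time[ends],
                 dtt = time[ends] - time[starts])
}

#' Direct transit times of a recorded first-passage ensemble
#'
#' Applies [extract_dtt()] to every recorded CV series of an ensemble and
#' summarizes the mean direct transit time.
#'
#' @param ensemble an `fpt_ensemble` with recorded CV series.
#' @param upper,lower transition-region surfaces on the recorded CV,
#'   Angstrom.
#' @return A list with `transits` (tibble: `walker`, `t_start`, `t_end`,
#'   `dtt`, in ns) and `summary` (tibble: `n`, `mean_dtt_ns`, `sem_ns`).
#' @export
ensemble_dtt <- function(ensemble, upper, lower) {
  s <- as_reset_free_sample(ensemble)
  dt_ns <- s$stride_dt_fs / 1e6
  tr <- purrr::imap_dfr(s$cv_series, function(v, i) {
    d <- extract_dtt(v, seq_along(v) * dt_ns, upper, lower)
    if (nrow(d)) d$walker <- ensemble$walker[i]
    d
  })
  n <- nrow(tr)
  list(transits = tr,
       summary = tibble::tibble(
         n = n,
         mean_dtt_ns = if (n) mean(tr$dtt) else NA_real_,
         sem_ns = if (n > 1) stats::sd(tr$dtt) / sqrt(n) else NA_real_))
}
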