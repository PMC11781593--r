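#' Stochastic resetting protocols
#'
#' A resetting protocol draws waiting times from an exponential
#' distribution with rate `rate_ns` and, at each resetting epoch, returns
#' the walker to its initial position with thermally resampled momenta.
#' *Standard* stochastic resetting (SR) resets unconditionally
#' (`threshold = NULL`); *informed* resetting (ISR) resets only when the
#' collective variable `x cos(theta) + y sin(theta)` is beyond a threshold
#' `c` at the epoch. If the condition fails, the simulation continues to
#' the next epoch and rechecks. Elapsed time keeps accumulating across
#' resets, so first-passage times include all discarded segments.
#'
#' @param rate_ns resetting rate `r` in ns^-1; 0 disables resetting.
#' @param threshold threshold `c` in Angstrom on the CV, or `NULL` for
#'   standard (unconditional) SR.
#' @param cv_theta CV rotation angle, degrees; 0 is the raw `x` coordinate.
#' @param direction reset when the CV is `"above"` (default) or `"below"`
#'   the threshold. The comparison is strict.
#' @return An object of class `reset_protocol`.
#' @export
#' @examples
#' reset_protocol(100)                   # standard SR at r = 100 / ns
#' reset_protocol(1e4, threshold = 3)    # ISR: reset only when x > 3 A
reset_protocol <- function(rate_ns, threshold = NULL, cv_theta = 0,
                           direction = c("above", "below")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(rate_ns), rate_ns >= 0)
  structure(list(rate_ns = rate_ns,
                 conditional = !is.null(threshold),
                 threshold = if (is.null(threshold)) -Inf else threshold,
                 greater = direction == "above",
                 theta_deg = cv_theta,
                 ct = cospi(cv_theta / 180),
                 st = sinpi(cv_theta / 180)),
            class = "reset_protocol")
}

#' @export
print.reset_protocol <- function(x, ...) {
  if (x$conditional) {
    cat("<reset_protocol: informed, r = ", x$rate_ns, " /ns, reset if cv ",
        if (x$greater) ">" else "<", " ", x$threshold, " A (theta = ",
        x$theta_deg, " deg)>\n", sep = "")
  } else {
    cat("<reset_protocol: standard, r = ", x$rate_ns, " /ns>\n", sep = "")
  }
  invisible(x)
}

#' Draw exponential resetting waiting times
#'
#' @param n number of draws.
#' @param rate_ns resetting rate in ns^-1; `0` returns `Inf` (never reset).
#' @return waiting times in ns.
#' @export
draw_reset_time <- function(n, rate_ns) {
  stopifnot(rate_ns >= 0)
  if (rate_ns == 0) return(rep(Inf, n))
  stats::rexp(n, rate = rate_ns)
}

#' Speedup of an accelerated ensemble over a baseline
#'
#' The ratio of mean first-passage times, `MFPT(baseline) /
#' MFPT(accelerated)`, with a delta-method standard error from the two
#' standard errors of the means.
#'
#' @param baseline,accelerated `fpt_ensemble` objects (uncensored), or
#'   one-row tibbles as returned by [glance.fpt_ensemble()].
#' @return A one-row tibble: `speedup`, `se`, `mfpt_baseline_ns`,
#'   `mfpt_accelerated_ns`.
#' @export
speedup <- function(baseline, accelerated) {
  b <- ensemble_summary(baseline)
  a <- ensemble_summary(accelerated)
  if (b$n_censored > 0 || a$n_censored > 0)
    stop("speedup requires uncensored ensembles")
  if (a$mfpt_ns <= 0) stop("accelerated MFPT is zero")
  s <- b$mfpt_ns / a$mfpt_ns
  se <- s * sqrt((b$sem_ns / b$mfpt_ns)^2 + (a$sem_ns / a$mfpt_ns)^2)
  tibble::tibble(speedup = s, se = se,
                 mfpt_baseline_ns = b$mfpt_ns, mfpt_accelerated_ns = a$mfpt_ns)
}

ensemble_summary <- function(x) {
  if (inherits(x, "fpt_ensemble")) return(glance(x))
  stopifnot(is.data.frame(x), all(c("mfpt_ns", "sem_ns") %in% names(x)))
  if (!"n_censored" %in% names(x)) x$n_censored <- 0L
  x
}
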