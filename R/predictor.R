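#' Per-step resetting probability
#'
#' Under informed resetting at rate `r`, the probability that a resetting
#' epoch falls within one retained step of duration `dt` *and* finds the
#' condition satisfied is `(1 - exp(-r dt)) * indicator`.
#'
#' @param indicator 0/1 (or logical) condition indicator(s).
#' @param rate_ns resetting rate, ns^-1.
#' @param dt_fs duration of one retained step, fs (the recording stride
#'   times the integration time step).
#' @return numeric vector of probabilities.
#' @export
per_step_reset_prob <- function(indicator, rate_ns, dt_fs) {
  stopifnot(rate_ns >= 0, dt_fs > 0)
  (1 - exp(-rate_ns * 1e-6 * dt_fs)) * as.numeric(indicator)
}

#' Survival probability of a reset-free trajectory under hypothetical
#' resetting
#'
#' For a recorded CV series with resetting trials at times `k * dt`
#' (`k = 1, 2, ...`), returns the running probability `Psi(k)` that the
#' trajectory would have escaped resetting through trial `k`:
#' `Psi(k) = prod_{j <= k} (1 - p_j)` with `Psi(0) = 1`, where `p_j` is the
#' per-step resetting probability at the recorded position `j`.
#'
#' @param cv recorded CV series (one value per retained step).
#' @param rate_ns resetting rate, ns^-1.
#' @param threshold resetting threshold `c`, Angstrom.
#' @param dt_fs time between retained steps, fs.
#' @param direction reset when the CV is strictly `"above"` (default) or
#'   `"below"` the threshold.
#' @return A tibble with columns `step`, `time_ns`, `psi`.
#' @export
survival_curve <- function(cv, rate_ns, threshold, dt_fs,
                           direction = c("above", "below")) {
  direction <- match.arg(direction)
  ind <- if (direction == "above") cv > threshold else cv < threshold
  p <- per_step_reset_prob(ind, rate_ns, dt_fs)
  tibble::tibble(step = seq_along(cv),
                 time_ns = seq_along(cv) * dt_fs / 1e6,
                 psi = cumprod(1 - p))
}

# Normalize predictor input into list(cv_series, fpt_ns, stride_dt_fs,
# direction-free). Accepts an fpt_ensemble with recorded CV series or a
# bare list with those fields.
as_reset_free_sample <- function(sample) {
  if (inherits(sample, "fpt_ensemble")) {
    if (!"cv_series" %in% names(sample))
      stop("ensemble has no recorded CV series; rerun simulate_fpt() with ",
           "record_cv_stride > 0")
    if (any(sample$censored)) stop("sample contains censored walkers")
    dt <- attr(sample, "dt_fs") * attr(sample, "record_stride")
    return(list(cv_series = sample$cv_series, fpt_ns = sample$fpt_ns,
                stride_dt_fs = dt))
  }
  stopifnot(is.list(sample),
            all(c("cv_series", "fpt_ns", "stride_dt_fs") %in% names(sample)))
  sample
}

# per-trajectory pieces: Psi_i at first passage and the Eq-style sum
# sum_j (j dt) Psi_i(j-1) p_ij, computed in C++
sample_terms <- function(s, rate_ns, threshold, direction = "above") {
  p <- 1 - exp(-rate_ns * 1e-6 * s$stride_dt_fs)
  greater <- direction == "above"
  m <- vapply(s$cv_series, function(v)
    cpp_survival_terms(v, p, threshold, greater, s$stride_dt_fs),
    numeric(2))
  list(psi = m[1, ], jsum_fs = m[2, ], tau_ns = s$fpt_ns)
}

# assemble the predicted MFPT from per-trajectory terms over index set idx
assemble_mfpt <- function(terms, idx = seq_along(terms$psi)) {
  psi <- terms$psi[idx]
  jsum <- terms$jsum_fs[idx] / 1e6
  tau <- terms$tau_ns[idx]
  mean_psi <- mean(psi)
  if (mean_psi <= 0)
    stop("survival probability underflow: rate/threshold too aggressive ",
         "for this sample")
  m_seg <- 1 / mean_psi
  t_final <- sum(tau * psi) / sum(psi)
  reset_mass <- sum(1 - psi)
  t_reset <- if (reset_mass > 0) sum(jsum) / reset_mass else 0
  list(mfpt_ns = (m_seg - 1) * t_reset + t_final,
       mean_segments = m_seg, mean_final_ns = t_final,
       mean_reset_seg_ns = t_reset, mean_survival = mean_psi)
}

#' Predict the MFPT under resetting from reset-free trajectories
#'
#' Evaluates the mean first-passage time that an informed-resetting
#' protocol (rate `r`, threshold `c`) *would* have produced, using only
#' trajectories sampled without resetting. Each trajectory's recorded CV
#' series yields its survival probability against the hypothetical
#' resetting clock; the MFPT is assembled from the survival-reweighted
#' final-segment duration, the mean number of segments, and the mean
#' duration of segments ending in resetting.
#'
#' @param sample an `fpt_ensemble` with recorded CV series (see
#'   [simulate_fpt()]'s `record_cv_stride`), or a list with fields
#'   `cv_series`, `fpt_ns`, `stride_dt_fs`.
#' @param rate_ns resetting rate, ns^-1.
#' @param threshold resetting threshold, Angstrom; `NULL` emulates standard
#'   (unconditional) resetting.
#' @param direction reset when the CV is `"above"` or `"below"` the
#'   threshold.
#' @param se `"none"` or `"bootstrap"`: attach a trajectory-resampling
#'   bootstrap standard error.
#' @param boot_n bootstrap replicates.
#' @return A one-row tibble: `rate_ns`, `threshold`, `mfpt_ns`,
#'   `mean_segments`, `mean_final_ns`, `mean_reset_seg_ns`,
#'   `mean_survival`, and `se_ns` when requested.
#' @export
predict_mfpt <- function(sample, rate_ns, threshold,
                         direction = c("above", "below"),
                         se = c("none", "bootstrap"), boot_n = 200) {
  direction <- match.arg(direction)
  se <- match.arg(se)
  s <- as_reset_free_sample(sample)
  if (is.null(threshold)) {
    threshold <- -Inf
    if (direction == "below") threshold <- Inf
  }
  terms <- sample_terms(s, rate_ns, threshold, direction)
  out <- assemble_mfpt(terms)
  res <- tibble::tibble(rate_ns = rate_ns, threshold = threshold,
                        mfpt_ns = out$mfpt_ns,
                        mean_segments = out$mean_segments,
                        mean_final_ns = out$mean_final_ns,
                        mean_reset_seg_ns = out$mean_reset_seg_ns,
                        mean_survival = out$mean_survival)
  if (se == "bootstrap") {
    n <- length(terms$psi)
    reps <- vapply(seq_len(boot_n), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(assemble_mfpt(terms, idx)$mfpt_ns, error = function(e) NA_real_)
    }, numeric(1))
    res$se_ns <- stats::sd(reps, na.rm = TRUE)
  }
  res
}

#' Screen resetting rates and thresholds on a reset-free sample
#'
#' Evaluates [predict_mfpt()] over a grid of rates and thresholds and
#' reports the predicted speedup of every protocol relative to the
#' sample's own (reset-free) MFPT. Cells where the survival probability
#' underflows are marked invalid rather than failing the scan.
#'
#' @inheritParams predict_mfpt
#' @param rates_ns vector of resetting rates, ns^-1.
#' @param thresholds vector of thresholds, Angstrom. Use `-Inf` to include
#'   standard (unconditional) resetting in the scan.
#' @param baseline_mfpt_ns reference MFPT for the speedup; defaults to the
#'   sample mean of the reset-free FPTs.
#' @return A tibble of class `isr_prediction` with one row per grid cell:
#'   `rate_ns`, `threshold`, `mfpt_ns`, `speedup`, `mean_segments`,
#'   `mean_survival`, `valid`. The best valid cell is stored in the
#'   `argmax` attribute.
#' @export
screen_protocols <- function(sample, rates_ns, thresholds,
                             direction = c("above", "below"),
                             baseline_mfpt_ns = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(rates_ns) >= 1, length(thresholds) >= 1)
  s <- as_reset_free_sample(sample)
  if (is.null(baseline_mfpt_ns)) baseline_mfpt_ns <- mean(s$fpt_ns)
  grid <- tidyr::expand_grid(rate_ns = sort(rates_ns),
                             threshold = thresholds)
  rows <- purrr::pmap(grid, function(rate_ns, threshold) {
    out <- tryCatch({
      terms <- sample_terms(s, rate_ns, threshold, direction)
      assemble_mfpt(terms)
    }, error = function(e) NULL)
    if (is.null(out)) {
      tibble::tibble(mfpt_ns = NA_real_, speedup = NA_real_,
                     mean_segments = NA_real_, mean_survival = NA_real_,
                     valid = FALSE)
    } else {
      tibble::tibble(mfpt_ns = out$mfpt_ns,
                     speedup = baseline_mfpt_ns / out$mfpt_ns,
                     mean_segments = out$mean_segments,
                     mean_survival = out$mean_survival, valid = TRUE)
    }
  })
  res <- dplyr::bind_cols(grid, dplyr::bind_rows(rows))
  best <- dplyr::slice_max(dplyr::filter(res, .data$valid), .data$speedup,
                           n = 1, with_ties = FALSE)
  structure(res, class = c("isr_prediction", class(res)),
            argmax = best, baseline_mfpt_ns = baseline_mfpt_ns)
}

#' @exportS3Method generics::glance
glance.isr_prediction <- function(x, ...) {
  cbind(attr(x, "argmax"),
        tibble::tibble(baseline_mfpt_ns = attr(x, "baseline_mfpt_ns"),
                       n_valid = sum(x$valid), n_cells = nrow(x)))[
          , c("rate_ns", "threshold", "mfpt_ns", "speedup",
              "baseline_mfpt_ns", "n_valid", "n_cells")]
}
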