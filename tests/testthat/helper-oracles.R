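# Independent oracles used by the predictor and inference tests.

# Brute-force enumeration of the resetting process on a finite sample of
# recorded trajectories. Trials happen at recorded steps where the
# indicator holds; each fires independently with probability p. For every
# trajectory all 2^m outcome vectors are enumerated to get the exact
# distribution of (first firing trial | no firing), and the ensemble MFPT
# follows from the renewal equation
#   E = mean_i [ sum_j P_i(fire at j) (j dt + E) + P_i(survive) tau_i ].
enum_reset_mfpt <- function(cv_series, tau_ns, p, threshold, stride_dt_ns) {
  n <- length(cv_series)
  A <- numeric(n)   # expected time spent before a firing, per trajectory
  B <- numeric(n)   # probability that a firing occurs
  S <- numeric(n)   # survival probability
  for (i in seq_len(n)) {
    idx <- which(cv_series[[i]] > threshold)
    m <- length(idx)
    if (m == 0) {
      S[i] <- 1
      next
    }
    if (m > 20) stop("enumeration oracle limited to 20 active steps")
    for (mask in 0:(2^m - 1)) {
      fires <- bitwAnd(bitwShiftR(mask, seq_len(m) - 1), 1L) == 1L
      prob <- prod(ifelse(fires, p, 1 - p))
      first <- which(fires)[1]
      if (is.na(first)) {
        S[i] <- S[i] + prob
      } else {
        A[i] <- A[i] + prob * idx[first] * stride_dt_ns
        B[i] <- B[i] + prob
      }
    }
  }
  mean(A + S * tau_ns) / (1 - mean(B))
}

# Monte-Carlo simulation of the same discrete resampling process.
mc_reset_mfpt <- function(cv_series, tau_ns, p, threshold, stride_dt_ns,
                          n_rep = 20000) {
  n <- length(cv_series)
  total <- 0
  for (rep in seq_len(n_rep)) {
    t <- 0
    repeat {
      i <- sample.int(n, 1)
      act <- which(cv_series[[i]] > threshold)
      fired <- FALSE
      if (length(act) > 0) {
        u <- stats::runif(length(act)) < p
        j <- which(u)[1]
        if (!is.na(j)) {
          t <- t + act[j] * stride_dt_ns
          fired <- TRUE
        }
      }
      if (!fired) {
        t <- t + tau_ns[i]
        break
      }
    }
    total <- total + t
  }
  total / n_rep
}

# Laplace transform of the reset-free FPT density for 1D drift-diffusion
# to a target at distance L (drift v > 0 toward the target), and the
# resulting closed-form MFPT under resetting at rate r (renewal theory):
#   <tau>_r = (1/ T~(r) - 1) / r,  r -> 0 limit L / v.
drift_fpt_laplace <- function(s, L, v, D) {
  exp((v * L / (2 * D)) * (1 - sqrt(1 + 4 * D * s / v^2)))
}

drift_mfpt_under_sr <- function(r, L, v, D) {
  ifelse(r == 0, L / v, (1 / drift_fpt_laplace(r, L, v, D) - 1) / r)
}

# Free diffusion (no drift): MFPT under resetting at rate r,
# (exp(L sqrt(r/D)) - 1) / r.
free_mfpt_under_sr <- function(r, L, D) (exp(L * sqrt(r / D)) - 1) / r
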