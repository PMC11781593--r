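#' Well-tempered Metadynamics engine on a 1D collective variable
#'
#' A minimal well-tempered Metadynamics bias acting on
#' `cv = x cos(theta) + y sin(theta)`. Repulsive Gaussians of width `sigma`
#' are deposited every `pace` steps; the deposition height is damped by the
#' accumulated bias, `h = height * exp(-V(cv) / (k_BT (gamma - 1)))` with
#' bias factor `gamma`. The bias and its analytic derivative are tabulated
#' on a regular grid and interpolated linearly; beyond the grid bounds the
#' CV is clamped to the boundary node. When combined with resetting, the
#' bias table and the deposition clock are zeroed at every reset, so each
#' post-reset segment is an independent replica.
#'
#' @param pace deposition period in integration steps.
#' @param height_kt initial Gaussian height in `k_BT`.
#' @param sigma Gaussian width in Angstrom.
#' @param bias_factor well-tempered bias factor (dimensionless, > 1).
#' @param grid_min,grid_max,grid_spacing CV grid, Angstrom.
#' @param cv_theta CV rotation angle in degrees.
#' @return An object of class `metad_engine` holding the (initially empty)
#'   bias table.
#' @export
metad_engine <- function(pace = 100, height_kt = 0.5, sigma = 0.15,
                         bias_factor = 10, grid_min = -12, grid_max = 12,
                         grid_spacing = 0.01, cv_theta = 0) {
  stopifnot(pace >= 1, height_kt >= 0, sigma > 0, bias_factor > 1,
            grid_max > grid_min, grid_spacing > 0)
  ng <- round((grid_max - grid_min) / grid_spacing) + 1L
  structure(list(pace = as.integer(pace), height = height_kt, sigma = sigma,
                 biasfactor = bias_factor, grid_min = grid_min,
                 grid_max = grid_max, grid_spacing = grid_spacing,
                 theta_deg = cv_theta,
                 ct = cospi(cv_theta / 180), st = sinpi(cv_theta / 180),
                 bias = numeric(ng), dbias = numeric(ng)),
            class = "metad_engine")
}

#' @export
print.metad_engine <- function(x, ...) {
  cat("<metad_engine: pace ", x$pace, ", height ", x$height, " k_BT, sigma ",
      x$sigma, " A, bias factor ", x$biasfactor, ", grid [", x$grid_min, ", ",
      x$grid_max, "] by ", x$grid_spacing, ", theta ", x$theta_deg,
      " deg>\n", sep = "")
  cat("  hills deposited: bias max ", max(x$bias), " k_BT\n", sep = "")
  invisible(x)
}

#' Deposit one well-tempered Gaussian
#'
#' @param engine a [metad_engine()].
#' @param cv the current CV value (Angstrom). Values beyond the grid are
#'   clamped to the boundary.
#' @return The engine with the Gaussian added to its bias table.
#' @export
metad_deposit <- function(engine, cv) {
  stopifnot(inherits(engine, "metad_engine"))
  res <- cpp_metad_deposit(engine$bias, engine$dbias,
                           engine[c("height", "sigma", "biasfactor",
                                    "grid_min", "grid_max", "grid_spacing")],
                           cv)
  engine$bias <- res$bias
  engine$dbias <- res$dbias
  engine
}

#' Evaluate the Metadynamics bias and its force
#'
#' `metad_bias()` interpolates the accumulated bias (in `k_BT`) at CV
#' values; `metad_bias_force()` returns the Cartesian force components
#' `-dV/d(cv) * (cos(theta), sin(theta))` in `k_BT` per Angstrom at
#' positions `(x, y)`.
#'
#' @param engine a [metad_engine()].
#' @param cv CV values (Angstrom).
#' @param x,y positions (Angstrom).
#' @return `metad_bias()`: numeric vector. `metad_bias_force()`: a tibble
#'   with columns `fx`, `fy`.
#' @export
metad_bias <- function(engine, cv) {
  stopifnot(inherits(engine, "metad_engine"))
  cpp_metad_interp(engine$bias,
                   engine[c("grid_min", "grid_max", "grid_spacing")],
                   as.double(cv))
}

#' @rdname metad_bias
#' @export
metad_bias_force <- function(engine, x, y) {
  stopifnot(inherits(engine, "metad_engine"))
  cv <- engine$ct * x + engine$st * y
  dv <- cpp_metad_interp(engine$dbias,
                         engine[c("grid_min", "grid_max", "grid_spacing")],
                         as.double(cv))
  tibble::tibble(fx = -dv * engine$ct, fy = -dv * engine$st)
}

#' Zero the Metadynamics bias
#'
#' Clears the bias table (and derivative table). Inside [simulate_fpt()]
#' this happens automatically at every resetting event, together with a
#' restart of the deposition clock.
#'
#' @param engine a [metad_engine()].
#' @return The engine with an empty bias.
#' @export
metad_zero <- function(engine) {
  stopifnot(inherits(engine, "metad_engine"))
  engine$bias[] <- 0
  engine$dbias[] <- 0
  engine
}

#' CV grid of a Metadynamics engine
#'
#' @param engine a [metad_engine()].
#' @return A tibble with columns `cv`, `bias` (k_BT), `dbias`.
#' @exportS3Method generics::tidy
tidy.metad_engine <- function(x, ...) {
  tibble::tibble(cv = seq(x$grid_min, x$grid_max, by = x$grid_spacing),
                 bias = x$bias, dbias = x$dbias)
}
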