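#' Analytic 2D model potentials
#'
#' Constructors for the analytic energy surfaces used throughout the package.
#' Energies are expressed in multiples of `k_BT` at the simulation
#' temperature; lengths are in Angstrom. `mfe_surface()` builds the modified
#' Faradjian--Elber surface: a symmetric double well along `x` whose two
#' minima are separated by a Gaussian ridge at `x = 0`. The ridge is `A2`
#' `k_BT` high for most `y` values but carries a narrow saddle of height
#' `A2 * (1 - B)` around `y = 0`:
#'
#' \deqn{U(x, y) = A_1 (x^6 + y'^6) +
#'   A_2 e^{-x^2/\sigma_1^2} (1 - B e^{-y'^2/\sigma_2^2}), \quad y' = s\, y}
#'
#' where `y' = s y` is the rescaled (stretched) slow coordinate. With the
#' default parameters the minima sit near `x = \pm 3` Angstrom, the ridge
#' is 12 `k_BT` and the saddle 3 `k_BT`.
#'
#' @param A1 sextic confinement coefficient (`k_BT` per Angstrom^6).
#' @param A2 ridge height (`k_BT`).
#' @param B fractional depth of the saddle notch in the ridge.
#' @param sigma1 ridge width along `x` (Angstrom).
#' @param sigma2 saddle-notch width along the rescaled coordinate (Angstrom).
#' @param saddle_yscale rescale factor used inside the saddle Gaussian;
#'   defaults to `yscale` (one common rescaled coordinate).
#' @param yscale rescale factor `s` in `y' = s y`; values below 1 stretch the
#'   surface along `y`, slowing that degree of freedom.
#' @return An object of class `potential_surface`.
#' @export
#' @examples
#' surf <- mfe_surface()
#' potential_energy(surf, c(0, 3), c(0, 0))
mfe_surface <- function(A1 = 1.2e-5, A2 = 12, B = 0.75, sigma1 = 1,
                        sigma2 = 0.5, yscale = 0.1, saddle_yscale = yscale) {
  stopifnot(A1 > 0, A2 > 0, B > 0, B < 1, sigma1 > 0, sigma2 > 0, yscale > 0,
            saddle_yscale > 0)
  new_surface("mfe", list(A1 = A1, A2 = A2, B = B, sigma1 = sigma1,
                          sigma2 = sigma2, yscale = yscale,
                          saddle_yscale = saddle_yscale))
}

#' @describeIn mfe_surface Symmetric quartic double well
#'   `U = h ((x/a)^2 - 1)^2 + ky y^2 / 2` with barrier `h` at `x = 0` and
#'   minima at `x = \pm a`.
#' @param barrier_kt barrier height `h` at `x = 0` (`k_BT`).
#' @param xmin half-spacing `a` of the minima (Angstrom).
#' @param ky harmonic confinement along `y` (`k_BT` per Angstrom^2).
#' @export
double_well_surface <- function(barrier_kt, xmin = 1, ky = 1) {
  if (!is.numeric(barrier_kt) || barrier_kt <= 0)
    stop("`barrier_kt` must be a positive barrier height in k_BT")
  stopifnot(xmin > 0, ky >= 0)
  new_surface("double_well", list(barrier = barrier_kt, xmin = xmin, ky = ky))
}

#' @describeIn mfe_surface Linear (tilted-plane) surface
#'   `U = slope * x + ky y^2 / 2`; with `slope = 0` it is flat along `x`,
#'   giving free diffusion. Used mainly for closed-form oracles.
#' @param slope constant force term along `x` (`k_BT` per Angstrom).
#' @export
linear_surface <- function(slope = 0, ky = 0) {
  stopifnot(is.numeric(slope), ky >= 0)
  new_surface("linear", list(slope = slope, ky = ky))
}

new_surface <- function(name, params) {
  structure(list(name = name, params = params), class = "potential_surface")
}

#' @export
print.potential_surface <- function(x, ...) {
  cat("<potential_surface: ", x$name, ">\n", sep = "")
  cat("  ", paste(names(x$params), unlist(x$params), sep = " = ",
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate a model potential
#'
#' `potential_energy()` returns the energy in `k_BT`; `potential_gradient()`
#' returns the analytic partial derivatives (`k_BT` per Angstrom). Both
#' vectorize over positions.
#'
#' @param surface a [mfe_surface()], [double_well_surface()] or
#'   [linear_surface()] object.
#' @param x,y positions in Angstrom (recycled to common length).
#' @return `potential_energy()`: a numeric vector. `potential_gradient()`:
#'   a tibble with columns `dUdx`, `dUdy`. The deterministic force on a
#'   particle is the negative gradient.
#' @export
potential_energy <- function(surface, x, y) {
  check_surface(surface)
  n <- max(length(x), length(y))
  cpp_surface_energy(surface, rep_len(as.double(x), n), rep_len(as.double(y), n))
}

#' @rdname potential_energy
#' @export
potential_gradient <- function(surface, x, y) {
  check_surface(surface)
  n <- max(length(x), length(y))
  g <- cpp_surface_gradient(surface, rep_len(as.double(x), n),
                            rep_len(as.double(y), n))
  tibble::tibble(dUdx = g[, 1], dUdy = g[, 2])
}

check_surface <- function(surface) {
  if (!inherits(surface, "potential_surface"))
    stop("`surface` must be a potential_surface object")
  invisible(surface)
}

#' Locate minima and measure the barrier profile of a surface
#'
#' Scans a grid for local minima, refines each candidate by gradient-based
#' optimization, and builds the barrier profile along `x`: for a given `y`,
#' the barrier is the maximum energy over the ridge window `x` in
#' `[-ridge_window, ridge_window]` minus the minimum energy along `x` at
#' that same `y` (the additive `y`-confinement cancels, so the profile
#' isolates the crossing barrier).
#'
#' @param surface a `potential_surface`.
#' @param xlim,ylim ranges bracketing the stationary points of interest.
#' @param spacing grid spacing for the candidate scan (Angstrom).
#' @param ridge_window half-width of the window around `x = 0` searched for
#'   the ridge top.
#' @param grad_tol gradient-norm tolerance for a refined minimum.
#' @return An object of class `landscape_report`: a list with `minima`
#'   (tibble of refined minima with energies and gradient norms) and
#'   `barrier_profile`, a vectorized function of `y` returning barrier
#'   heights in `k_BT`.
#' @export
#' @examples
#' rep <- analyze_landscape(mfe_surface())
#' rep$minima
#' rep$barrier_profile(c(0, 50))
analyze_landscape <- function(surface, xlim = c(-5, 5), ylim = c(-5, 5),
                              spacing = 0.25, ridge_window = 1,
                              grad_tol = 1e-8) {
  check_surface(surface)
  xs <- seq(xlim[1], xlim[2], by = spacing)
  ys <- seq(ylim[1], ylim[2], by = spacing)
  grid <- expand.grid(x = xs, y = ys)
  e <- matrix(potential_energy(surface, grid$x, grid$y),
              nrow = length(xs), ncol = length(ys))

  # interior grid points lower than their 4-neighbourhood are candidates
  nx <- length(xs); ny <- length(ys)
  cand <- list()
  for (i in 2:(nx - 1)) {
    for (j in 2:(ny - 1)) {
      if (e[i, j] < e[i - 1, j] && e[i, j] <= e[i + 1, j] &&
          e[i, j] < e[i, j - 1] && e[i, j] <= e[i, j + 1])
        cand[[length(cand) + 1L]] <- c(xs[i], ys[j])
    }
  }
  if (length(cand) == 0)
    stop("no minimum found in the scanned range; widen xlim/ylim")

  refine <- function(p0) {
    fn <- function(p) potential_energy(surface, p[1], p[2])
    gr <- function(p) unlist(potential_gradient(surface, p[1], p[2]))
    opt <- stats::optim(p0, fn, gr, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    opt$par
  }
  pts <- unique(do.call(rbind, lapply(cand, refine)))
  # deduplicate refined points that collapsed to the same minimum
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(pts))) {
      if (j > i && keep[j] && sum((pts[i, ] - pts[j, ])^2) < 1e-6)
        keep[j] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  gn <- sqrt(rowSums(as.matrix(potential_gradient(surface, pts[, 1], pts[, 2]))^2))
  minima <- tibble::tibble(
    x = pts[, 1], y = pts[, 2],
    energy = potential_energy(surface, pts[, 1], pts[, 2]),
    grad_norm = gn
  )
  minima <- minima[minima$grad_norm < grad_tol * 10, , drop = FALSE]
  if (nrow(minima) == 0)
    stop("grid candidates failed to refine below the gradient tolerance")

  xfine <- seq(xlim[1], xlim[2], by = 0.002)
  xridge <- seq(-ridge_window, ridge_window, by = 0.002)
  barrier_profile <- function(y) {
    vapply(y, function(yy) {
      ridge <- max(potential_energy(surface, xridge, yy))
      floor_ <- min(potential_energy(surface, xfine, yy))
      ridge - floor_
    }, numeric(1))
  }

  structure(list(minima = minima, barrier_profile = barrier_profile,
                 surface = surface),
            class = "landscape_report")
}

#' @export
print.landscape_report <- function(x, ...) {
  cat("<landscape_report>\nminima:\n")
  print(x$minima)
  cat("barrier at y = 0:", round(x$barrier_profile(0), 3), "k_BT\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.landscape_report <- function(x, ...) x$minima
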