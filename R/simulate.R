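#' Split a total initial density into the two compartments
#'
#' The subpopulation initial conditions are taken proportional to the
#' observed total initial density: `u10 = alpha * u0`,
#' `u20 = (1 - alpha) * u0`.
#'
#' @param u0 Radial density profile (numeric vector). Small negative
#'   entries (observation noise) are clamped to 0 with a warning.
#' @param alpha Fraction assigned to compartment 1, in \[0, 1\].
#' @return List with components `u10` and `u20`; `u10 + u20 == u0` exactly
#'   (after clamping).
#' @export
split_initial_condition <- function(u0, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
  if (!all(is.finite(u0))) stop("u0 must be finite")
  if (any(u0 < 0)) {
    warning("negative entries in u0 clamped to 0 (observation noise)")
    u0 <- pmax(u0, 0)
  }
  list(u10 = alpha * u0, u20 = (1 - alpha) * u0)
}

#' Simulate a spheroid model on a radial spherical grid
#'
#' Integrates the selected model variant with the method of lines: central
#' (finite-volume) differencing of the spherical radial Laplacian, central
#' differencing of the advection term, no-flux boundaries at r = 0 and
#' r = L, and a stiff-capable variable-order integrator (`lsoda`,
#' rtol = 1e-6, atol = 1e-8 by default).
#'
#' @param params A [model_params()] object.
#' @param u0 Total initial density profile on `grid$r` (length `N_r`).
#' @param grid A [radial_grid()].
#' @param times Output times in weeks, ascending; `times[1]` is the time of
#'   `u0`.
#' @param rtol,atol Integrator tolerances.
#' @return A `density_series` object with fields `times`, `grid`, and
#'   matrices `u`, `u1`, `u2` of shape (N_t, N_r). Densities are clipped at
#'   0 on output (integrator overshoot below `-1e-6` before clipping is an
#'   error).
#' @export
simulate_model <- function(params, u0, grid, times, rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(params, "model_params"))
  assert_grid(grid)
  if (length(u0) != grid$N_r) stop("u0 must have length grid$N_r")
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly ascending")
  }
  # ARD advects its single population, which lives in compartment 1
  A1 <- if (params$model_id == "ARD") params$A2 else 0
  A2 <- if (params$model_id %in% c("RD_ARD")) params$A2 else 0
  ic <- split_initial_condition(u0, params$alpha)
  # K = 0 is only admissible for a compartment carrying no mass and no growth
  for (c in 1:2) {
    K <- if (c == 1) params$K1 else params$K2
    rho <- if (c == 1) params$rho1 else params$rho2
    uc0 <- if (c == 1) ic$u10 else ic$u20
    if (K == 0 && rho > 0 && any(uc0 > 0)) {
      stop(sprintf("K%d = 0 with nonzero growth and a populated compartment %d",
                   c, c))
    }
  }
  N <- grid$N_r
  y0 <- numeric(2 * N)
  y0[seq(1, 2 * N, by = 2)] <- ic$u10
  y0[seq(2, 2 * N, by = 2)] <- ic$u20
  rhs <- function(t, y, p) {
    list(rhs_radial_two_pop(t, y, params$D1, params$D2, params$rho1,
                            params$rho2, params$K1, params$K2, A1, A2,
                            grid$h, N))
  }
  single_time <- length(times) == 1L
  tt <- if (single_time) c(times, times + 1e-9) else times
  sol <- deSolve::ode(y = y0, times = tt, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      jactype = "bandint", bandup = 2L, banddown = 2L)
  if (!is.matrix(sol) || nrow(sol) < length(tt)) {
    stop(sprintf("integrator failed for %s params (D1=%g, D2=%g, rho1=%g, rho2=%g, K1=%g, K2=%g, A2=%g, alpha=%g)",
                 params$model_id, params$D1, params$D2, params$rho1,
                 params$rho2, params$K1, params$K2, params$A2, params$alpha))
  }
  Y <- sol[seq_along(times), -1, drop = FALSE]
  u1 <- Y[, seq(1, 2 * N, by = 2), drop = FALSE]
  u2 <- Y[, seq(2, 2 * N, by = 2), drop = FALSE]
  if (min(u1, u2) < -1e-6) {
    stop("simulated density fell below -1e-6; integration unreliable")
  }
  u1 <- pmax(u1, 0)
  u2 <- pmax(u2, 0)
  density_series(times = times, grid = grid, u = u1 + u2, u1 = u1, u2 = u2)
}

#' Radial density time series container
#'
#' @param times Observation times, weeks, ascending.
#' @param grid A [radial_grid()].
#' @param u Total density matrix, shape (N_t, N_r).
#' @param u1,u2 Optional per-compartment densities (simulations only);
#'   when both are present `u` must equal `u1 + u2`.
#' @return Object of class `density_series`.
#' @export
density_series <- function(times, grid, u, u1 = NULL, u2 = NULL) {
  assert_grid(grid)
  u <- as.matrix(u)
  dimnames(u) <- NULL
  if (!is.null(u1)) { u1 <- as.matrix(u1); dimnames(u1) <- NULL }
  if (!is.null(u2)) { u2 <- as.matrix(u2); dimnames(u2) <- NULL }
  if (nrow(u) != length(times) || ncol(u) != grid$N_r) {
    stop("u must have shape (N_t, N_r)")
  }
  if (!is.null(u1) && !is.null(u2)) {
    stopifnot(all(dim(u1) == dim(u)), all(dim(u2) == dim(u)))
    if (max(abs(u1 + u2 - u)) > 1e-8) stop("u must equal u1 + u2")
  }
  structure(list(times = as.numeric(times), grid = grid, u = u,
                 u1 = u1, u2 = u2),
            class = "density_series")
}

#' @export
print.density_series <- function(x, ...) {
  cat(sprintf("<density_series> %d times in [%g, %g] wk x %d radii on [0, %g] mm; max density %.3g\n",
              length(x$times), min(x$times), max(x$times),
              x$grid$N_r, x$grid$L, max(x$u)))
  invisible(x)
}

#' Spherical mass of a radial density profile
#'
#' Trapezoid quadrature of \eqn{4 \pi \int r^2 u(r) dr} on the grid; used
#' as the conservation diagnostic for pure-diffusion runs.
#'
#' @param u Radial profile on `grid$r`.
#' @param grid A [radial_grid()].
#' @return Scalar mass.
#' @export
spherical_mass <- function(u, grid) {
  assert_grid(grid)
  r <- grid$r
  f <- 4 * pi * r^2 * u
  sum((f[-1] + f[-length(f)]) / 2) * grid$h
}
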