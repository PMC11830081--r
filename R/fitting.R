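#' Default parameter bounds for fitting
#'
#' The admissible box: diffusion coefficients in \[0, 0.2\] mm^2/week,
#' growth rates in \[0, 15\] week^-1, carrying capacities in \[0, 1\]
#' density units, advection rate in \[0, 3\] mm/week, and the
#' initial-condition split alpha in \[0, 1\].
#'
#' @param model_id One of `MODEL_IDS`.
#' @return List with named numeric vectors `lower` and `upper` in the
#'   model's fitting order.
#' @export
default_bounds <- function(model_id) {
  lo_all <- c(D1 = 0, rho1 = 0, K1 = 0, alpha = 0, D2 = 0, rho2 = 0,
              K2 = 0, A2 = 0)
  hi_all <- c(D1 = 0.2, rho1 = 15, K1 = 1, alpha = 1, D2 = 0.2, rho2 = 15,
              K2 = 1, A2 = 3)
  nm <- model_param_names(model_id)
  list(lower = lo_all[nm], upper = hi_all[nm])
}

#' Sum-of-squares error between observed data and a model simulation
#'
#' Simulates the model from the observed initial profile (linearly
#' interpolated onto the solver grid) at the observed times, interpolates
#' the simulated total density back to the observed radii, and sums the
#' squared residuals over all (time, radius) points including the initial
#' slice.
#'
#' @param observed A `density_series` of observations.
#' @param params A [model_params()].
#' @param sim_grid Solver grid; defaults to 400 nodes on the observed
#'   domain.
#' @return Scalar SSE.
#' @export
sse <- function(observed, params, sim_grid = NULL) {
  stopifnot(inherits(observed, "density_series"))
  if (is.null(sim_grid)) sim_grid <- radial_grid(observed$grid$L, 400)
  uhat <- simulate_on_observed(observed, params, sim_grid)
  sum((observed$u - uhat)^2)
}

# simulate and linearly interpolate the total density to the observed radii
simulate_on_observed <- function(observed, params, sim_grid) {
  u0 <- stats::approx(observed$grid$r, pmax(observed$u[1, ], 0),
                      xout = sim_grid$r, rule = 2)$y
  sim <- simulate_model(params, u0, sim_grid, observed$times)
  t(apply(sim$u, 1, function(row) {
    stats::approx(sim_grid$r, row, xout = observed$grid$r, rule = 2)$y
  }))
}

#' Least-squares Akaike information criterion
#'
#' \deqn{AIC = n [\ln(2\pi) + 1] + n \ln(SSE/n) + 2(\kappa + 1)}
#' with n the number of observations (N_t x N_r) and kappa the number of
#' estimated parameters.
#'
#' @param sse Sum of squared residuals (>= 0).
#' @param n_obs Number of observations (>= 1).
#' @param kappa_q Number of estimated parameters.
#' @return AIC value; `-Inf` with a warning if `sse == 0`.
#' @export
aic <- function(sse, n_obs, kappa_q) {
  stopifnot(sse >= 0, n_obs >= 1, kappa_q >= 0)
  if (sse == 0) {
    warning("sse is exactly 0; AIC is -Inf")
    return(-Inf)
  }
  n_obs * (log(2 * pi) + 1) + n_obs * log(sse / n_obs) + 2 * (kappa_q + 1)
}

# objective with the K=0/populated-compartment guard: candidate vectors the
# simulator rejects get a large penalty instead of aborting the search
PENALTY_SSE <- 1e10

fit_objective <- function(model_id, observed, sim_grid) {
  force(model_id); force(observed); force(sim_grid)
  function(theta) {
    p <- params_from_vector(model_id, theta)
    tryCatch(sse(observed, p, sim_grid), error = function(e) PENALTY_SSE)
  }
}

#' Fit one model to a density series
#'
#' Two-stage least squares: a DIRECT global search over the bounds box,
#' then bounded local refinement (L-BFGS-B with finite-difference
#' gradients) started from the DIRECT optimum. The returned SSE never
#' exceeds the stage-1 SSE.
#'
#' @param model_id One of `MODEL_IDS`.
#' @param observed A `density_series` with at least 2 time points.
#' @param bounds Bounds as from [default_bounds()].
#' @param direct_evals DIRECT evaluation budget; default 2000 for the
#'   single-population models and 10000 for the two-population models.
#' @param local_maxit Iteration cap for the local stage.
#' @param sim_grid Solver grid used for every objective evaluation
#'   (default 400 nodes).
#' @return Object of class `fit_result`: `model_id`, `params`, `sse`,
#'   `aic`, `kappa_q`, `n_obs`, `diagnostics` (evaluation counts per
#'   stage and a budget flag).
#' @export
fit_model <- function(model_id, observed, bounds = default_bounds(model_id),
                      direct_evals = NULL, local_maxit = 200,
                      sim_grid = NULL) {
  model_id <- match.arg(model_id, MODEL_IDS)
  stopifnot(inherits(observed, "density_series"))
  if (length(observed$times) < 2L) stop("observed must contain >= 2 time points")
  nm <- model_param_names(model_id)
  stopifnot(identical(names(bounds$lower), nm), all(bounds$lower <= bounds$upper))
  if (is.null(direct_evals)) {
    direct_evals <- if (model_id %in% c("RD", "ARD")) 2000 else 10000
  }
  if (is.null(sim_grid)) sim_grid <- radial_grid(observed$grid$L, 400)
  obj <- fit_objective(model_id, observed, sim_grid)
  g <- direct_optim(obj, bounds$lower, bounds$upper, max_evals = direct_evals)
  # local refinement in unit-box coordinates so finite-difference steps are
  # a fixed fraction of each parameter's admissible range
  width <- bounds$upper - bounds$lower
  free <- width > 0
  to_par <- function(z) {
    x <- bounds$lower
    x[free] <- bounds$lower[free] + z * width[free]
    x
  }
  obj_unit <- function(z) obj(to_par(z))
  z0 <- (g$par[free] - bounds$lower[free]) / width[free]
  loc <- tryCatch(
    stats::optim(z0, obj_unit, method = "L-BFGS-B", lower = rep(0, sum(free)),
                 upper = rep(1, sum(free)),
                 control = list(maxit = local_maxit, factr = 1e7)),
    error = function(e) list(par = z0, value = g$value,
                             counts = c(`function` = 0L, gradient = NA)))
  if (is.finite(loc$value) && loc$value <= g$value) {
    best_par <- to_par(loc$par); best_val <- loc$value
  } else {
    best_par <- g$par; best_val <- g$value
  }
  if (best_val >= PENALTY_SSE) stop("all objective evaluations failed")
  n_obs <- length(observed$times) * observed$grid$N_r
  kappa <- model_kappa(model_id)
  structure(list(
    model_id = model_id,
    params = params_from_vector(model_id, pmin(pmax(best_par, bounds$lower),
                                               bounds$upper)),
    sse = best_val,
    aic = aic(best_val, n_obs, kappa),
    kappa_q = kappa,
    n_obs = n_obs,
    bounds = bounds,
    diagnostics = list(direct_evals = g$evals, direct_sse = g$value,
                       local_evals = unname(loc$counts[1]),
                       budget_exhausted = isTRUE(g$budget_exhausted))),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: sse = %.6g, aic = %.6g (kappa = %d, n = %d)\n",
              x$model_id, x$sse, x$aic, x$kappa_q, x$n_obs))
  invisible(x)
}

#' Fit all model variants and rank them by AIC
#'
#' @param observed A `density_series`.
#' @param models Subset of `MODEL_IDS` to fit.
#' @param direct_evals Optional named vector/list of DIRECT budgets per
#'   model id (defaults per [fit_model()]).
#' @param local_maxit,sim_grid Passed to [fit_model()].
#' @return List with `table` (data.frame: model_id, sse, aic, kappa_q,
#'   rank, ordered by ascending AIC with ties broken by fewer parameters),
#'   `fits` (named list of `fit_result`), and `failures` (named list of
#'   error messages for models that could not be fitted).
#' @export
compare_models <- function(observed, models = MODEL_IDS, direct_evals = NULL,
                           local_maxit = 200, sim_grid = NULL) {
  models <- match.arg(models, MODEL_IDS, several.ok = TRUE)
  fits <- list()
  failures <- list()
  for (mid in models) {
    de <- if (!is.null(direct_evals) && !is.null(direct_evals[[mid]])) {
      direct_evals[[mid]]
    } else NULL
    res <- tryCatch(fit_model(mid, observed, direct_evals = de,
                              local_maxit = local_maxit, sim_grid = sim_grid),
                    error = function(e) e)
    if (inherits(res, "error")) failures[[mid]] <- conditionMessage(res)
    else fits[[mid]] <- res
  }
  if (length(fits) == 0) stop("all model fits failed")
  tab <- data.frame(
    model_id = vapply(fits, `[[`, "", "model_id"),
    sse = vapply(fits, `[[`, 0, "sse"),
    aic = vapply(fits, `[[`, 0, "aic"),
    kappa_q = vapply(fits, `[[`, 0L, "kappa_q"),
    row.names = NULL)
  ord <- order(tab$aic, tab$kappa_q)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(table = tab, fits = fits, failures = failures)
}
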