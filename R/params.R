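#' Model identifiers
#'
#' The four model variants: single-population reaction-diffusion (`RD`),
#' single-population advection-reaction-diffusion (`ARD`), two-population
#' reaction-diffusion (`RD_RD`), and the two-population model whose second
#' compartment also advects (`RD_ARD`).
#' @export
MODEL_IDS <- c("RD", "ARD", "RD_RD", "RD_ARD")

#' Number of estimated parameters per model
#'
#' RD estimates (D1, rho1, K1); ARD adds the advection rate A2; RD_RD
#' estimates (D1, rho1, K1, alpha, D2, rho2, K2); RD_ARD adds A2.
#'
#' @param model_id One of `MODEL_IDS`.
#' @return Integer count of free parameters.
#' @export
model_kappa <- function(model_id) {
  model_id <- match.arg(model_id, MODEL_IDS)
  switch(model_id, RD = 3L, ARD = 4L, RD_RD = 7L, RD_ARD = 8L)
}

#' Names of the free parameters of a model
#' @param model_id One of `MODEL_IDS`.
#' @return Character vector of parameter names in fitting order.
#' @export
model_param_names <- function(model_id) {
  model_id <- match.arg(model_id, MODEL_IDS)
  switch(model_id,
         RD     = c("D1", "rho1", "K1"),
         ARD    = c("D1", "rho1", "K1", "A2"),
         RD_RD  = c("D1", "rho1", "K1", "alpha", "D2", "rho2", "K2"),
         RD_ARD = c("D1", "rho1", "K1", "alpha", "D2", "rho2", "K2", "A2"))
}

#' Parameter vector for one model variant
#'
#' Constructs and validates the parameter set for a model. Single-population
#' models (`RD`, `ARD`) use only `D1`, `rho1`, `K1` (plus `A2` for `ARD`)
#' with `alpha` fixed at 1; the unused second-compartment entries are kept
#' at 0.
#'
#' @param model_id One of `MODEL_IDS`.
#' @param D1,D2 Diffusion coefficients, mm^2/week.
#' @param rho1,rho2 Growth rates, week^-1.
#' @param K1,K2 Carrying capacities, density units.
#' @param A2 Advection rate of the migratory compartment, mm/week
#'   (for `ARD` this is the advection rate of the single population).
#' @param alpha Fraction of the initial total density assigned to
#'   compartment 1, in \[0, 1\].
#' @return An object of class `model_params`.
#' @export
model_params <- function(model_id, D1 = 0, rho1 = 0, K1 = 0,
                         D2 = 0, rho2 = 0, K2 = 0, A2 = 0, alpha = 1) {
  model_id <- match.arg(model_id, MODEL_IDS)
  vals <- c(D1 = D1, rho1 = rho1, K1 = K1, D2 = D2, rho2 = rho2, K2 = K2,
            A2 = A2, alpha = alpha)
  if (!all(is.finite(vals)) || any(vals < 0)) {
    stop("all model parameters must be finite and >= 0")
  }
  if (alpha > 1) stop("alpha must lie in [0, 1]")
  if (model_id %in% c("RD", "ARD")) {
    alpha <- 1
    D2 <- rho2 <- K2 <- 0
    if (model_id == "RD") A2 <- 0
  }
  if (model_id == "RD_RD") A2 <- 0
  structure(list(model_id = model_id, D1 = D1, rho1 = rho1, K1 = K1,
                 D2 = D2, rho2 = rho2, K2 = K2, A2 = A2, alpha = alpha),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> %s\n", x$model_id))
  nm <- model_param_names(x$model_id)
  v <- unlist(x[nm])
  cat(paste(sprintf("  %-5s = %g", nm, v), collapse = "\n"), "\n")
  invisible(x)
}

#' Build model_params from a named vector of free parameters
#'
#' Inverse of [model_param_names()]: takes the free-parameter vector in
#' fitting order and expands it into a full `model_params` object.
#'
#' @param model_id One of `MODEL_IDS`.
#' @param theta Named or positional numeric vector matching
#'   `model_param_names(model_id)`.
#' @return A `model_params` object.
#' @export
params_from_vector <- function(model_id, theta) {
  nm <- model_param_names(model_id)
  if (length(theta) != length(nm)) {
    stop(sprintf("expected %d parameters for %s", length(nm), model_id))
  }
  names(theta) <- nm
  do.call(model_params, c(list(model_id = model_id), as.list(theta)))
}
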