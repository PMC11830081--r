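#' Uniform radial grid for spherically symmetric simulation
#'
#' Builds the node-centered uniform grid on \eqn{[0, L]} used by the
#' method-of-lines solver. The first node sits at the spheroid center
#' (r = 0) and the last at the outer domain boundary r = L.
#'
#' @param L Domain length in mm (default 5, the radial extent used
#'   throughout the spheroid analyses).
#' @param N_r Number of grid nodes (>= 16). The default 400 keeps central
#'   differencing of the advection term oscillation-free for advection
#'   rates up to about 3 mm/week.
#' @return An object of class `radial_grid` with elements `r` (node
#'   coordinates, mm), `L`, `N_r`, and `h` (node spacing, mm).
#' @export
radial_grid <- function(L = 5, N_r = 400) {
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L), L > 0)
  if (!is.numeric(N_r) || length(N_r) != 1L || N_r < 16 || N_r != round(N_r)) {
    stop("N_r must be an integer >= 16")
  }
  N_r <- as.integer(N_r)
  r <- seq(0, L, length.out = N_r)
  structure(list(r = r, L = L, N_r = N_r, h = r[2] - r[1]),
            class = "radial_grid")
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("<radial_grid> %d nodes on [0, %g] mm (h = %.4g mm)\n",
              x$N_r, x$L, x$h))
  invisible(x)
}

is_radial_grid <- function(x) inherits(x, "radial_grid")

assert_grid <- function(grid) {
  if (!is_radial_grid(grid)) stop("grid must be a radial_grid object")
  invisible(grid)
}
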