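#' Write a density series as long-format CSV
#'
#' Columns `time_weeks,radius_mm,density`, one row per (time, radius) cell.
#' Values are written with full round-trip precision.
#'
#' @param series A `density_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_density_csv <- function(series, path) {
  stopifnot(inherits(series, "density_series"))
  # %.17g preserves doubles exactly across a write/read cycle
  dt <- data.table::data.table(
    time_weeks = sprintf("%.17g", rep(series$times, each = series$grid$N_r)),
    radius_mm = sprintf("%.17g", rep(series$grid$r,
                                     times = length(series$times))),
    density = sprintf("%.17g", as.vector(t(series$u))))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a long-format density CSV back into a density series
#'
#' Expects the dialect written by [write_density_csv()]; the radial grid is
#' reconstructed from the unique radii (which must be uniform and start
#' near 0).
#'
#' @param path CSV path with header `time_weeks,radius_mm,density`.
#' @return A `density_series` (total density only).
#' @export
read_density_csv <- function(path) {
  dt <- data.table::fread(path)
  need <- c("time_weeks", "radius_mm", "density")
  if (!all(need %in% names(dt))) {
    stop("density CSV must have columns time_weeks,radius_mm,density")
  }
  times <- sort(unique(dt$time_weeks))
  radii <- sort(unique(dt$radius_mm))
  grid <- radial_grid(L = max(radii), N_r = length(radii))
  if (max(abs(grid$r - radii)) > 1e-8 * max(radii)) {
    stop("radii in CSV are not a uniform grid starting at 0")
  }
  data.table::setorder(dt, time_weeks, radius_mm)
  u <- matrix(dt$density, nrow = length(times), ncol = length(radii),
              byrow = TRUE)
  if (any(u < 0)) {
    message(sprintf("observed data contains %d negative density values (noise)",
                    sum(u < 0)))
  }
  density_series(times = times, grid = grid, u = u)
}

#' Write a density series in wide format
#'
#' Companion writer: rows are times, columns radii; the first column is
#' `time_weeks` and the remaining column names carry the radii in mm.
#'
#' @param series A `density_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_density_wide_csv <- function(series, path) {
  stopifnot(inherits(series, "density_series"))
  wide <- data.table::data.table(time_weeks = series$times)
  m <- data.table::as.data.table(series$u)
  data.table::setnames(m, sprintf("r_%.6g", series$grid$r))
  data.table::fwrite(cbind(wide, m), path)
  invisible(path)
}
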