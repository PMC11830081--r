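#' Track the outermost level crossing of a density front over time
#'
#' For each time in the window, finds the outermost radius where the total
#' density crosses the given level from above (the leading invasive
#' front), localized by linear interpolation between the two bracketing
#' grid nodes. Times where the level is never attained, or where the
#' profile has not fallen back below the level inside the domain, are
#' omitted.
#'
#' @param series A `density_series`.
#' @param level Density threshold (> 0).
#' @param t_window Length-2 numeric `(t_start, t_end)`; defaults to the
#'   full series.
#' @return data.frame with columns `t`, `r`. Attribute `insufficient` is
#'   TRUE when fewer than 3 crossings were found (speed undefined).
#' @export
track_level_set <- function(series, level, t_window = range(series$times)) {
  stopifnot(inherits(series, "density_series"), level > 0)
  keep <- which(series$times >= t_window[1] - 1e-12 &
                  series$times <= t_window[2] + 1e-12)
  r <- series$grid$r
  ts <- c(); rs <- c()
  for (i in keep) {
    u <- series$u[i, ]
    cross <- which(u[-length(u)] >= level & u[-1] < level)
    if (length(cross) == 0) next
    j <- max(cross) # outermost down-crossing
    frac <- (u[j] - level) / (u[j] - u[j + 1])
    ts <- c(ts, series$times[i])
    rs <- c(rs, r[j] + frac * (r[j + 1] - r[j]))
  }
  out <- data.frame(t = ts, r = rs)
  attr(out, "insufficient") <- nrow(out) < 3L
  out
}

#' Front speed at one density level
#'
#' Ordinary least-squares slope of the tracked front radius against time
#' (fitting the line \eqn{r = ct + b}).
#'
#' @inheritParams track_level_set
#' @return Speed in mm/week, or `NA` when fewer than 3 crossings exist.
#' @export
wave_speed_at_level <- function(series, level, t_window = range(series$times)) {
  pts <- track_level_set(series, level, t_window)
  if (attr(pts, "insufficient")) return(NA_real_)
  unname(stats::coef(stats::lm(r ~ t, data = pts))[2])
}

#' Wave parameters: per-level speeds and heterogeneity summaries
#'
#' Computes front speeds at `M` equally spaced density levels, then the
#' summaries c_max, c_min, c_diff = c_max - c_min (the intra-tumor
#' heterogeneity proxy) and c_shape, the magnitude of the slope of the
#' straight line through the final-time front positions of the levels at
#' which c_max and c_min occur.
#'
#' @param series A `density_series` (typically a simulation at fitted
#'   parameters, which denoises the data before speed estimation).
#' @param M Number of density levels (default 100).
#' @param level_range Default 0.02 to 0.8 x the maximum density in the
#'   series.
#' @param t_window Default the last quarter of the series,
#'   `(0.75 t_f, t_f)`; must contain at least 4 time samples.
#' @return Object of class `wave_params`: `levels`, `speeds` (NA where
#'   undefined), `c_max`, `c_min`, `c_diff`, `c_shape`, `t_window`.
#' @export
wave_parameters <- function(series, M = 100,
                            level_range = c(0.02, 0.8 * max(series$u)),
                            t_window = c(0.75 * max(series$times),
                                         max(series$times))) {
  stopifnot(inherits(series, "density_series"), M >= 2)
  if (sum(series$times >= t_window[1] - 1e-12 &
            series$times <= t_window[2] + 1e-12) < 4L) {
    stop("t_window must contain at least 4 time samples")
  }
  levels <- seq(level_range[1], level_range[2], length.out = M)
  speeds <- vapply(levels, function(lv) {
    wave_speed_at_level(series, lv, t_window)
  }, numeric(1))
  ok <- is.finite(speeds)
  if (!any(ok)) stop("no trackable front: all levels undefined")
  if (!all(ok)) {
    message(sprintf("%d of %d levels had insufficient crossings and were dropped",
                    sum(!ok), M))
  }
  i_max <- which(speeds == max(speeds[ok]))[1]
  i_min <- which(speeds == min(speeds[ok]))[1]
  c_max <- speeds[i_max]; c_min <- speeds[i_min]
  # c_shape: |slope| through the final-time front positions of the two levels
  final <- density_series(times = max(series$times), grid = series$grid,
                          u = series$u[nrow(series$u), , drop = FALSE])
  r_of <- function(lv) {
    pts <- track_level_set(final, lv, rep(max(series$times), 2))
    if (nrow(pts) == 0) NA_real_ else pts$r[1]
  }
  r_max <- r_of(levels[i_max]); r_min <- r_of(levels[i_min])
  c_shape <- if (is.na(r_max) || is.na(r_min) || r_max == r_min) {
    NA_real_
  } else {
    abs((levels[i_max] - levels[i_min]) / (r_max - r_min))
  }
  structure(list(levels = levels, speeds = speeds, c_max = c_max,
                 c_min = c_min, c_diff = c_max - c_min, c_shape = c_shape,
                 t_window = t_window),
            class = "wave_params")
}

#' @export
print.wave_params <- function(x, ...) {
  cat(sprintf("<wave_params> c_max = %.4f, c_min = %.4f, c_diff = %.4f mm/wk; c_shape = %.4g\n",
              x$c_max, x$c_min, x$c_diff, x$c_shape))
  invisible(x)
}
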