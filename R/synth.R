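#' Smooth compact initial spheroid profile
#'
#' A logistic (smoothed-step) radial profile emulating the processed
#' density of a freshly seeded spheroid: a plateau at `peak_density` for
#' r well inside `core_radius`, decaying to ~0 over a shell of width
#' ~`edge_width`.
#'
#' @param grid A [radial_grid()].
#' @param core_radius Core radius, mm (default 0.5, a typical spheroid
#'   core at the first imaging time).
#' @param peak_density Plateau density (default 0.5, the upper end of the
#'   processed-intensity range).
#' @param edge_width Transition width, mm (default 0.1).
#' @return Numeric profile on `grid$r`, monotone non-increasing.
#' @export
make_initial_profile <- function(grid, core_radius = 0.5, peak_density = 0.5,
                                 edge_width = 0.1) {
  assert_grid(grid)
  if (!(core_radius > 0) || core_radius >= grid$L) {
    stop("core_radius must lie in (0, L)")
  }
  if (!(edge_width > 0)) stop("edge_width must be > 0")
  peak_density / (1 + exp((grid$r - core_radius) / (edge_width / 4)))
}

#' Noise specification for synthetic density series
#'
#' @param kind `"none"` or `"additive_gaussian"`.
#' @param sigma Noise standard deviation in density units (>= 0). Default
#'   0.01, roughly 2-5% of typical peak densities 0.2-0.5.
#' @param seed Integer RNG seed.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("none", "additive_gaussian"), sigma = 0.01,
                       seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0)
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate a synthetic radial density series with known ground truth
#'
#' Simulates the requested model from a smooth compact initial profile and
#' adds i.i.d. observation noise per the noise specification (clipped at
#' 0). The generating parameters and profile settings are attached as the
#' ground-truth record.
#'
#' @param params A [model_params()] (ground truth).
#' @param grid A [radial_grid()].
#' @param times Observation times, weeks.
#' @param noise A [noise_spec()].
#' @param core_radius,peak_density,edge_width Initial-profile settings
#'   passed to [make_initial_profile()].
#' @return A `density_series` with attribute `ground_truth` (list with
#'   `params`, `profile`, `noise`). With `kind = "none"` the output equals
#'   the simulation bit-for-bit.
#' @export
generate_density_series <- function(params, grid, times,
                                    noise = noise_spec("none"),
                                    core_radius = 0.5, peak_density = 0.5,
                                    edge_width = 0.1) {
  stopifnot(inherits(noise, "noise_spec"))
  u0 <- make_initial_profile(grid, core_radius, peak_density, edge_width)
  sim <- simulate_model(params, u0, grid, times)
  u <- sim$u
  if (noise$kind == "additive_gaussian" && noise$sigma > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(noise$seed)
    u <- pmax(u + matrix(stats::rnorm(length(u), sd = noise$sigma),
                         nrow = nrow(u)), 0)
  }
  out <- density_series(times = times, grid = grid, u = u)
  attr(out, "ground_truth") <- list(
    params = params,
    profile = list(core_radius = core_radius, peak_density = peak_density,
                   edge_width = edge_width),
    noise = noise)
  out
}

# save/restore global RNG state so generators are seed-isolated
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Specification of a synthetic spheroid-like grayscale image
#'
#' Geometry defaults follow the 1536 x 1152 px brightfield frames
#' (4.33 x 3.24 mm). The object is dark on a light background, so
#' `1 - image` is high on the spheroid.
#'
#' @param height,width Image size in pixels.
#' @param center `(row, col)` of the spheroid center, pixels.
#' @param core_radius Core radius, pixels.
#' @param halo_decay Exponential decay length of the invasive halo, pixels.
#' @param core_intensity,background_intensity Grayscale levels in \[0, 1\];
#'   `core_intensity < background_intensity` gives brightfield polarity.
#' @param noise_sigma Additive Gaussian pixel noise sd.
#' @param n_distractors Number of small elongated dark objects added away
#'   from the spheroid.
#' @param seed Integer RNG seed.
#' @return Object of class `spheroid_image_spec`.
#' @export
spheroid_image_spec <- function(height = 1152, width = 1536,
                                center = c(height / 2, width / 2),
                                core_radius = 80, halo_decay = 40,
                                core_intensity = 0.25,
                                background_intensity = 0.85,
                                noise_sigma = 0, n_distractors = 0,
                                seed = 1L) {
  stopifnot(height >= 64, width >= 64, core_radius > 0, halo_decay > 0,
            core_intensity >= 0, core_intensity <= 1,
            background_intensity >= 0, background_intensity <= 1,
            noise_sigma >= 0, n_distractors >= 0)
  if (center[1] < 1 || center[1] > height || center[2] < 1 || center[2] > width) {
    stop("center must lie inside the image")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 center = as.numeric(center), core_radius = core_radius,
                 halo_decay = halo_decay, core_intensity = core_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma,
                 n_distractors = as.integer(n_distractors),
                 seed = as.integer(seed)),
            class = "spheroid_image_spec")
}

# radial shape of 1 - image relative to background: 1 inside the core,
# exponential halo outside
spheroid_shape <- function(d, core_radius, halo_decay) {
  ifelse(d <= core_radius, 1, exp(-(d - core_radius) / halo_decay))
}

#' Generate a synthetic spheroid-like grayscale image
#'
#' Renders a radially symmetric dark core-plus-halo object on a light
#' background, optionally adding elongated dark distractor objects and
#' Gaussian pixel noise. Deterministic for a given seed.
#'
#' @param spec A [spheroid_image_spec()].
#' @return Numeric matrix (height x width) with values clipped to \[0, 1\].
#' @export
generate_spheroid_image <- function(spec) {
  stopifnot(inherits(spec, "spheroid_image_spec"))
  rows <- matrix(seq_len(spec$height), spec$height, spec$width)
  cols <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  d <- sqrt((rows - spec$center[1])^2 + (cols - spec$center[2])^2)
  contrast <- spec$background_intensity - spec$core_intensity
  im <- spec$background_intensity -
    contrast * spheroid_shape(d, spec$core_radius, spec$halo_decay)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  if (spec$n_distractors > 0) {
    for (k in seq_len(spec$n_distractors)) {
      # elongated bar placed away from the spheroid center
      repeat {
        cr <- stats::runif(1, 0.1, 0.9) * spec$height
        cc <- stats::runif(1, 0.1, 0.9) * spec$width
        if (sqrt((cr - spec$center[1])^2 + (cc - spec$center[2])^2) >
            spec$core_radius + 6 * spec$halo_decay) break
      }
      ang <- stats::runif(1, 0, pi)
      len <- stats::runif(1, 80, 140)
      wid <- stats::runif(1, 8, 14)
      xr <- (rows - cr) * cos(ang) + (cols - cc) * sin(ang)
      yr <- -(rows - cr) * sin(ang) + (cols - cc) * cos(ang)
      inside <- abs(xr) <= len / 2 & abs(yr) <= wid / 2
      im[inside] <- spec$core_intensity
    }
  }
  if (spec$noise_sigma > 0) {
    im <- im + matrix(stats::rnorm(length(im), sd = spec$noise_sigma),
                      nrow = spec$height)
  }
  pmin(pmax(im, 0), 1)
}

#' Write and read grayscale spheroid images
#'
#' Images are stored as 16-bit TIFF or 8-bit PNG depending on the file
#' extension; pixel values are in \[0, 1\].
#'
#' @param im Numeric matrix (rows x cols) in \[0, 1\].
#' @param path Output path ending in `.tiff`/`.tif` or `.png`.
#' @return `path` (writer) or the image matrix (reader).
#' @export
write_spheroid_image <- function(im, path) {
  stopifnot(is.matrix(im), min(im) >= 0, max(im) <= 1)
  bits <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) 16L else 8L
  EBImage::writeImage(EBImage::Image(t(im)), path, bits.per.sample = bits)
  invisible(path)
}

#' @rdname write_spheroid_image
#' @export
read_spheroid_image <- function(path) {
  t(EBImage::imageData(EBImage::readImage(path)))
}

#' Write the ground-truth record of a synthetic density series
#'
#' JSON sidecar with the generating parameters, initial-profile settings
#' and noise specification attached by [generate_density_series()].
#'
#' @param series A series produced by [generate_density_series()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(series, path) {
  gt <- attr(series, "ground_truth")
  if (is.null(gt)) stop("series carries no ground-truth record")
  jsonlite::write_json(
    list(params = unclass(gt$params), profile = gt$profile,
         noise = unclass(gt$noise)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
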