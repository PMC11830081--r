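test_that("initial profile is a smooth monotone step with the right plateau", {
  g <- radial_grid(5, 401)
  prof <- make_initial_profile(g, core_radius = 1, peak_density = 0.4,
                               edge_width = 0.1)
  expect_true(all(diff(prof) <= 0))
  expect_gte(prof[1], 0.99 * 0.4) # core_radius = 10 x edge_width
  expect_lt(prof[g$N_r], 1e-6)
  # sharp-step limit approaches the indicator of r < core_radius
  sharp <- make_initial_profile(g, core_radius = 1, peak_density = 0.4,
                                edge_width = 1e-4)
  indicator <- 0.4 * (g$r < 1)
  expect_lt(mean(abs(sharp - indicator) > 1e-6), 0.01)
  expect_error(make_initial_profile(g, core_radius = 6), "core_radius")
})

test_that("noiseless generation equals the bare simulation and is seed-stable", {
  g <- radial_grid(5, 101)
  times <- seq(0, 1, length.out = 4)
  p <- model_params("RD", D1 = 0.02, rho1 = 2, K1 = 0.5)
  clean <- generate_density_series(p, g, times, noise_spec("none"))
  sim <- simulate_model(p, make_initial_profile(g), g, times)
  expect_identical(clean$u, sim$u)
  n1 <- generate_density_series(p, g, times, noise_spec("additive_gaussian", 0.01, seed = 7))
  n2 <- generate_density_series(p, g, times, noise_spec("additive_gaussian", 0.01, seed = 7))
  n3 <- generate_density_series(p, g, times, noise_spec("additive_gaussian", 0.01, seed = 8))
  expect_identical(n1$u, n2$u)
  expect_false(identical(n1$u, n3$u))
  expect_gte(min(n1$u), 0)
})

test_that("noise amplitude matches the generating sigma (moment oracle)", {
  g <- radial_grid(5, 601)
  times <- seq(0, 1, length.out = 25) # 15025 residuals
  p <- model_params("RD", D1 = 0.02, rho1 = 2, K1 = 0.5)
  clean <- generate_density_series(p, g, times, noise_spec("none"),
                                   core_radius = 2)
  noisy <- generate_density_series(p, g, times,
                                   noise_spec("additive_gaussian", 0.01, seed = 5),
                                   core_radius = 2)
  res <- (noisy$u - clean$u)[clean$u > 0.05] # away from the clip at 0
  expect_gt(length(res), 5000)
  expect_lt(abs(stats::sd(res) - 0.01) / 0.01, 0.05)
})

test_that("density CSV round-trips exactly in both directions", {
  g <- radial_grid(5, 51)
  times <- seq(0, 1, length.out = 4)
  p <- model_params("RD", D1 = 0.013, rho1 = 2.7, K1 = 0.43)
  s <- generate_density_series(p, g, times,
                               noise_spec("additive_gaussian", 0.01, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_density_csv(s, path)
  back <- read_density_csv(path)
  expect_identical(back$u, s$u)
  expect_equal(back$times, s$times)
  expect_equal(back$grid$r, s$grid$r)
  unlink(path)
})

test_that("image files and ground-truth sidecars round-trip", {
  spec <- spheroid_image_spec(height = 128, width = 128, core_radius = 20,
                              halo_decay = 10, noise_sigma = 0.01, seed = 6)
  im <- generate_spheroid_image(spec)
  tif <- tempfile(fileext = ".tiff")
  write_spheroid_image(im, tif)
  back <- read_spheroid_image(tif)
  expect_equal(dim(back), dim(im))
  expect_lt(max(abs(back - im)), 1 / 65535 + 1e-9) # 16-bit quantization
  unlink(tif)
  g <- radial_grid(5, 101)
  s <- generate_density_series(model_params("RD", D1 = 0.02, rho1 = 2, K1 = 0.5),
                               g, c(0, 0.5, 1))
  gt_path <- tempfile(fileext = ".json")
  write_ground_truth(s, gt_path)
  gt <- jsonlite::read_json(gt_path)
  expect_equal(gt$params$D1, 0.02)
  expect_equal(gt$params$model_id, "RD")
  expect_equal(gt$profile$core_radius, 0.5)
  unlink(gt_path)
  expect_error(write_ground_truth(density_series(c(0, 1), g, matrix(0, 2, 101)),
                                  tempfile()), "ground-truth")
})

test_that("synthetic spheroid images are radially symmetric with correct contrast", {
  spec <- spheroid_image_spec(height = 256, width = 256, center = c(128, 128),
                              core_radius = 40, halo_decay = 15)
  im <- generate_spheroid_image(spec)
  # pixels at equal radius agree
  rows <- matrix(seq_len(256), 256, 256)
  cols <- matrix(seq_len(256), 256, 256, byrow = TRUE)
  d <- sqrt((rows - 128)^2 + (cols - 128)^2)
  ring <- abs(d - 20) < 0.5
  expect_lt(diff(range(im[ring])), 1e-6)
  # dark object on light background: 1 - im is high on the object
  expect_lt(im[128, 128], im[1, 1])
  # degenerate contrast gives a constant image
  flat <- generate_spheroid_image(
    spheroid_image_spec(height = 128, width = 128, core_intensity = 0.5,
                        background_intensity = 0.5))
  expect_equal(diff(range(flat)), 0)
})

test_that("annulus averages of 1 - image recover the generating profile within 2%", {
  spec <- spheroid_image_spec(height = 384, width = 512, center = c(192, 256),
                              core_radius = 60, halo_decay = 25)
  im <- generate_spheroid_image(spec)
  prof <- suppressWarnings(radial_density_profile(im, c(192, 256)))
  contrast <- spec$background_intensity - spec$core_intensity
  expected <- contrast * spherowave:::spheroid_shape(prof$bin_centers_px,
                                                     60, 25)
  inside <- prof$bin_centers_px < 60 + 25
  got <- prof$y - (1 - spec$background_intensity)
  expect_lt(max(abs(got[inside] - expected[inside]) / expected[inside]), 0.02)
})
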