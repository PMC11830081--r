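test_that("initial-condition split is proportional and exact", {
  u0 <- c(0.4, 0.2, 0)
  s <- split_initial_condition(u0, 1)
  expect_identical(s$u10, u0)
  expect_identical(s$u20, c(0, 0, 0))
  s <- split_initial_condition(u0, 0.5)
  expect_equal(s$u10, c(0.2, 0.1, 0))
  expect_equal(s$u20, c(0.2, 0.1, 0))
  s <- split_initial_condition(0.5, 0.3)
  expect_equal(s$u10, 0.15)
  expect_equal(s$u20, 0.35)
  expect_equal(s$u10 + s$u20, 0.5)
  expect_error(split_initial_condition(u0, 1.2), "alpha")
  expect_warning(split_initial_condition(c(0.2, -0.01), 0.5), "clamped")
})

test_that("zero initial density is a fixed point", {
  g <- radial_grid(5, 64)
  p <- table2_params("a")
  s <- simulate_model(p, rep(0, g$N_r), g, c(0, 0.5, 1))
  expect_equal(max(abs(s$u)), 0)
})

test_that("an unpopulated second compartment decouples: RD_ARD at alpha=1 equals RD", {
  g <- radial_grid(5, 101)
  u0 <- make_initial_profile(g)
  times <- seq(0, 1, length.out = 5)
  p_rd <- model_params("RD", D1 = 0.05, rho1 = 3, K1 = 0.5)
  p_full <- model_params("RD_ARD", D1 = 0.05, rho1 = 3, K1 = 0.5,
                         D2 = 0.1, rho2 = 7, K2 = 0.8, A2 = 2, alpha = 1)
  s1 <- simulate_model(p_rd, u0, g, times)
  s2 <- simulate_model(p_full, u0, g, times)
  expect_equal(max(abs(s2$u2)), 0)
  expect_lt(max(abs(s1$u - s2$u)) / max(s1$u), 1e-6)
})

test_that("pure diffusion conserves spherical mass to 0.1% (trapezoid oracle)", {
  g <- radial_grid(5, 201)
  u0 <- make_initial_profile(g)
  p <- model_params("RD", D1 = 0.05, rho1 = 0, K1 = 0.5)
  s <- simulate_model(p, u0, g, c(0, 1))
  m0 <- spherical_mass(s$u[1, ], g)
  m1 <- spherical_mass(s$u[2, ], g)
  expect_lt(abs(m1 - m0) / m0, 1e-3)
})

test_that("densities stay nonnegative and the front advances for Table 2 cases", {
  g <- radial_grid(5, 201)
  u0 <- make_initial_profile(g)
  times <- seq(0, 5, length.out = 11)
  for (case in c("a", "b", "c", "d")) {
    s <- simulate_model(table2_params(case), u0, g, times)
    expect_gte(min(s$u), 0) # clipped output; overshoot beyond -1e-6 errors
    # front radius at density 0.1 is monotone increasing
    front <- track_level_set(s, 0.1)
    expect_true(all(diff(front$r) > 0), info = paste("case", case))
  }
})

test_that("grid refinement is converged: doubling N_r changes the final profile < 1%", {
  times <- c(0, 2.5, 5)
  for (case in c("a", "d")) {
    g1 <- radial_grid(5, 200)
    g2 <- radial_grid(5, 400)
    s1 <- simulate_model(table2_params(case), make_initial_profile(g1), g1, times)
    s2 <- simulate_model(table2_params(case), make_initial_profile(g2), g2, times)
    u1_on_2 <- stats::approx(g1$r, s1$u[3, ], xout = g2$r)$y
    expect_lt(max(abs(u1_on_2 - s2$u[3, ])) / max(s2$u[3, ]), 0.01,
              label = paste("case", case, "refinement change"))
  }
})

test_that("no-flux boundaries: one-sided derivatives vanish at both ends", {
  g <- radial_grid(5, 201)
  u0 <- make_initial_profile(g, core_radius = 2, edge_width = 0.3)
  s <- simulate_model(table2_params("b"), u0, g, c(0, 1, 2))
  for (m in list(s$u1, s$u2)) {
    u_end <- m[3, ]
    grad <- abs(diff(u_end)) / g$h
    expect_lt(grad[1], 0.02 * max(grad) + 1e-8)
    expect_lt(grad[g$N_r - 1], 0.02 * max(grad) + 1e-8)
  }
})

test_that("a zero carrying capacity with a populated growing compartment is rejected", {
  g <- radial_grid(5, 64)
  u0 <- make_initial_profile(g)
  bad <- model_params("RD_ARD", D1 = 0.01, rho1 = 1, K1 = 0.5,
                      D2 = 0.01, rho2 = 1, K2 = 0, alpha = 0.5)
  expect_error(simulate_model(bad, u0, g, c(0, 1)), "K2")
  # K2 = 0 with an empty second compartment (alpha = 1) is allowed
  ok <- table2_params("d")
  expect_silent(simulate_model(ok, u0, g, c(0, 1)))
})

test_that("parameter containers validate their invariants", {
  expect_error(model_params("RD", D1 = -0.1, rho1 = 1, K1 = 0.5), "finite")
  expect_error(model_params("RD_RD", alpha = 1.5), "alpha")
  expect_equal(model_kappa("RD"), 3L)
  expect_equal(model_kappa("ARD"), 4L)
  expect_equal(model_kappa("RD_RD"), 7L)
  expect_equal(model_kappa("RD_ARD"), 8L)
  expect_error(radial_grid(5, 8), "N_r")
  p <- params_from_vector("ARD", c(0.01, 2, 0.5, 1.5))
  expect_equal(p$A2, 1.5)
  expect_equal(p$alpha, 1)
})
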