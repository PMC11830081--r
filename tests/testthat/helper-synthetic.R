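# shared fixtures: Table-2-style parameter sets and small observed datasets

table2_params <- function(case = c("a", "b", "c", "d")) {
  case <- match.arg(case)
  switch(case,
         a = model_params("RD_ARD", D1 = 0.007, D2 = 0.07, rho1 = 2.5,
                          rho2 = 1.5, K1 = 0.65, K2 = 0.4, A2 = 0.4,
                          alpha = 0.5),
         b = model_params("RD_ARD", D1 = 0.007, D2 = 0.07, rho1 = 2.5,
                          rho2 = 1.5, K1 = 0.65, K2 = 0.4, A2 = 0,
                          alpha = 0.5),
         c = model_params("RD_ARD", D1 = 0.007, D2 = 0.007, rho1 = 2.5,
                          rho2 = 1.5, K1 = 0.65, K2 = 0.4, A2 = 0,
                          alpha = 0.5),
         d = model_params("RD_ARD", D1 = 0.007, D2 = 0, rho1 = 2.5,
                          rho2 = 0, K1 = 0.65, K2 = 0, A2 = 0, alpha = 1))
}

# observed dataset: simulate on a fine grid, interpolate to a coarse
# observation grid (emulating radial binning), optionally add noise
make_observed <- function(params, n_obs_r = 41, times = seq(0, 1, length.out = 8),
                          sigma = 0, seed = 1, zero_background = FALSE,
                          fine_N = 401, ...) {
  fine <- radial_grid(5, fine_N)
  sim <- generate_density_series(params, fine, times, noise_spec("none"), ...)
  g_obs <- radial_grid(5, n_obs_r)
  u <- t(apply(sim$u, 1, function(row) {
    stats::approx(fine$r, row, xout = g_obs$r)$y
  }))
  truth <- u
  if (sigma > 0) {
    set.seed(seed)
    noise <- matrix(stats::rnorm(length(u), sd = sigma), nrow = nrow(u))
    if (zero_background) noise <- noise * (u > 0.01)
    u <- pmax(u + noise, 0)
  }
  obs <- density_series(times, g_obs, u)
  attr(obs, "u_noiseless") <- truth
  obs
}
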