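fake_params <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(seq_along(rows), function(i) {
    p <- rows[[i]]
    data.frame(cell_line = sprintf("L%02d", i), D1 = p[1], D2 = p[2],
               rho1 = p[3], rho2 = p[4], A2 = p[5])
  }))
}

test_that("normalization reproduces hand arithmetic and self-normalizes", {
  # two lines, D pairs (0.1, 0.3) and (0.2, 0.4): D-bar = (0.2 + 0.3)/2 = 0.25
  tab <- normalize_parameters(fake_params(c(0.1, 0.3, 1, 2, 0.5),
                                          c(0.2, 0.4, 3, 4, 1.5)))
  agg <- attr(tab, "aggregates")
  expect_equal(unname(agg["D_bar"]), 0.25)
  expect_equal(tab$Dbar1[1], 0.1 / 0.25) # = 0.4
  expect_equal(unname(agg["rho_bar"]), 2.5)
  expect_equal(unname(agg["A_bar"]), 1)
  # identical lines normalize to exactly 1
  same <- normalize_parameters(fake_params(c(0.1, 0.1, 2, 2, 0.7),
                                           c(0.1, 0.1, 2, 2, 0.7)))
  expect_equal(same$Dbar1, c(1, 1))
  expect_equal(same$rhobar2, c(1, 1))
  expect_equal(same$Abar2, c(1, 1))
  # rescaling every A2 by a common factor leaves the normalized A unchanged
  p1 <- fake_params(c(0.1, 0.3, 1, 2, 0.5), c(0.2, 0.4, 3, 4, 1.5))
  p2 <- p1; p2$A2 <- p2$A2 * 10
  expect_equal(normalize_parameters(p1)$Abar2, normalize_parameters(p2)$Abar2)
  # degenerate aggregate errors
  z <- p1; z$A2 <- 0
  expect_error(normalize_parameters(z), "degenerate")
})

test_that("Go-or-Grow conditions classify constructed cases correctly", {
  tab <- normalize_parameters(fake_params(
    c(0.1, 1.0, 10, 1, 0.0),   # pop 2 migrates, pop 1 grows
    c(1.0, 0.1, 1, 10, 0.0),   # pop 1 migrates, pop 2 grows
    c(0.5, 0.5, 5, 5, 0.5)))   # balanced
  lab <- classify_go_or_grow(tab, k = 5)
  expect_equal(lab$label[3], "not_go_or_grow")
  # explicit normalized table: Dbar1=1, Dbar2+Abar2=10, rhobar1=10, rhobar2=1
  t2 <- tab
  t2$Dbar1 <- c(1, 10, 1); t2$Dbar2 <- c(10, 1, 1); t2$Abar2 <- c(0, 0, 0)
  t2$rhobar1 <- c(10, 1, 1); t2$rhobar2 <- c(1, 10, 1)
  l2 <- classify_go_or_grow(t2, k = 5)
  expect_equal(l2$label, c("go_or_grow_pop2_migrates",
                           "go_or_grow_pop1_migrates", "not_go_or_grow"))
  # boundary: exact equality fails the strict inequality
  t3 <- t2[1, ]
  t3$Dbar2 <- 5; t3$Abar2 <- 0; t3$Dbar1 <- 1 # Dbar2 + Abar2 = 5 * Dbar1
  expect_equal(classify_go_or_grow(t3, k = 5)$label, "not_go_or_grow")
})

test_that("swapping subpopulation roles maps condition (10) to condition (11)", {
  tab <- normalize_parameters(fake_params(c(1.0, 0.05, 0.5, 9, 0.05),
                                          c(0.3, 0.3, 3, 3, 0.5)))
  lab <- classify_go_or_grow(tab, k = 5)
  expect_equal(lab$label[1], "go_or_grow_pop1_migrates")
  # relabel 1 <-> 2, folding advection into the migratory side's diffusion
  sw <- tab
  sw$Dbar1 <- tab$Dbar2 + tab$Abar2
  sw$Dbar2 <- tab$Dbar1; sw$Abar2 <- 0
  sw$rhobar1 <- tab$rhobar2; sw$rhobar2 <- tab$rhobar1
  lsw <- classify_go_or_grow(sw, k = 5)
  expect_equal(lsw$label[1], "go_or_grow_pop2_migrates")
})

test_that("labels are invariant to a common rescaling of the aggregates", {
  set.seed(42)
  for (rep in 1:20) {
    vals <- matrix(stats::runif(15, 0.01, 2), 3, 5)
    tab <- normalize_parameters(fake_params(vals[1, ], vals[2, ], vals[3, ]))
    lab1 <- classify_go_or_grow(tab, k = 5)$label
    # bare sums over n lines instead of means: all barred values scale by 1/n
    scaled <- tab
    for (cl in c("Dbar1", "Dbar2", "rhobar1", "rhobar2", "Abar2")) {
      scaled[[cl]] <- scaled[[cl]] / 3
    }
    expect_equal(classify_go_or_grow(scaled, k = 5)$label, lab1)
  }
})

test_that("classification agrees with a direct evaluation of the conditions", {
  set.seed(7)
  for (k in c(1, 5)) {
    vals <- matrix(stats::runif(6 * 5, 0.01, 2), 6, 5)
    tab <- normalize_parameters(do.call(fake_params, asplit(vals, 1)))
    got <- classify_go_or_grow(tab, k = k)$label
    mig2 <- tab$Dbar2 + tab$Abar2
    c10 <- tab$Dbar1 > k * mig2 & tab$rhobar2 > k * tab$rhobar1
    c11 <- mig2 > k * tab$Dbar1 & tab$rhobar1 > k * tab$rhobar2
    expect_false(any(c10 & c11)) # conditions are mutually exclusive at k >= 1
    want <- ifelse(c10, "go_or_grow_pop1_migrates",
                   ifelse(c11, "go_or_grow_pop2_migrates", "not_go_or_grow"))
    expect_equal(got, want)
  }
})

test_that("clustering recovers well-separated parameter blobs", {
  set.seed(5)
  blob <- function(center, n) {
    t(replicate(n, center + stats::rnorm(3, sd = 0.02)))
  }
  X <- rbind(blob(c(0.02, 1, 0.2), 4), blob(c(0.15, 9, 2.5), 4))
  df <- data.frame(cell_line = sprintf("L%02d", 1:8), D1 = X[, 1],
                   rho1 = X[, 2], A2 = X[, 3])
  cl <- cluster_cell_lines(df, 2)
  expect_equal(length(unique(cl$labels[1:4])), 1)
  expect_equal(length(unique(cl$labels[5:8])), 1)
  expect_false(cl$labels[1] == cl$labels[5])
  # degenerate cut: n_clusters = n_lines gives singletons
  expect_equal(length(unique(cluster_cell_lines(df, 8)$labels)), 8)
  # duplicating every line leaves flat labels invariant up to duplication
  df2 <- rbind(df, transform(df, cell_line = paste0(cell_line, "b")))
  cl2 <- cluster_cell_lines(df2, 2)
  expect_equal(unname(cl2$labels[1:8]), unname(cl2$labels[9:16]))
  # zero-variance feature is dropped with a warning
  df$K1 <- 0.5
  expect_warning(cluster_cell_lines(df, 2), "zero-variance")
})

test_that("partial correlation matches the closed form and guards its domain", {
  expect_equal(partial_correlation(0.3, 0, 0), 0.3)
  expect_equal(partial_correlation(0.5, 0.5, 0.5), 1 / 3)
  expect_error(partial_correlation(0.5, 1, 0.2), "undefined")
  expect_error(partial_correlation(0.5, 0.2, -1), "undefined")
  # output clamped to [-1, 1] on valid inputs
  set.seed(3)
  for (rep in 1:100) {
    v <- stats::runif(3, -0.99, 0.99)
    out <- partial_correlation(v[1], v[2], v[3])
    expect_gte(out, -1)
    expect_lte(out, 1)
  }
  # oracle: partial correlation computed from data via residuals
  set.seed(8)
  C <- stats::rnorm(200)
  A <- 0.6 * C + stats::rnorm(200)
  B <- -0.4 * C + stats::rnorm(200)
  direct <- partial_correlation(stats::cor(A, B), stats::cor(A, C),
                                stats::cor(B, C))
  via_resid <- stats::cor(stats::resid(stats::lm(A ~ C)),
                          stats::resid(stats::lm(B ~ C)))
  expect_equal(direct, via_resid, tolerance = 1e-10)
})
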