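#' DIRECT (DIviding RECTangles) global minimization over a box
#'
#' Derivative-free global optimizer: the unit hypercube image of the
#' bounds box is recursively trisected, and at each iteration the
#' potentially optimal hyper-rectangles (lower convex hull of the
#' (size, best value) cloud, with the usual epsilon improvement condition)
#' are subdivided along their longest sides. Used as the global stage of
#' model fitting before local refinement.
#'
#' @param fn Objective, called with a numeric vector in `[lower, upper]`.
#' @param lower,upper Bounds (finite, `lower <= upper`). Dimensions with
#'   `lower == upper` are held fixed.
#' @param max_evals Budget of objective evaluations (default 2000).
#' @param eps Improvement parameter of the potential-optimality test
#'   (default 1e-4).
#' @return List with `par` (best point), `value`, `evals`, and
#'   `budget_exhausted` (TRUE when the loop stopped on the evaluation
#'   budget rather than exhausting subdivision).
#' @export
direct_optim <- function(fn, lower, upper, max_evals = 2000, eps = 1e-4) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(lower <= upper), max_evals >= 1)
  free <- which(upper > lower)
  n <- length(free)
  to_x <- function(c_unit) {
    x <- lower
    x[free] <- lower[free] + c_unit * (upper[free] - lower[free])
    x
  }
  if (n == 0L) {
    return(list(par = lower, value = fn(lower), evals = 1L,
                budget_exhausted = FALSE))
  }
  evals <- 0L
  f_of <- function(c_unit) {
    evals <<- evals + 1L
    v <- fn(to_x(c_unit))
    if (!is.finite(v)) v <- .Machine$double.xmax
    v
  }
  # rectangle store: centers (n x m), values, per-dim trisection counts
  cap <- 512L
  centers <- matrix(NA_real_, n, cap)
  ks <- matrix(NA_integer_, n, cap)
  fs <- rep(NA_real_, cap)
  m <- 1L
  centers[, 1] <- rep(0.5, n)
  ks[, 1] <- 0L
  fs[1] <- f_of(centers[, 1])
  grow <- function(need) {
    while (need > ncol(centers)) {
      add <- ncol(centers)
      centers <<- cbind(centers, matrix(NA_real_, n, add))
      ks <<- cbind(ks, matrix(NA_integer_, n, add))
      fs <<- c(fs, rep(NA_real_, add))
    }
  }
  rect_size <- function(idx) {
    # half-diagonal of the rectangle in unit coordinates
    sqrt(colSums(matrix(3^(-2 * ks[, idx, drop = FALSE]), nrow = n))) / 2
  }
  budget_exhausted <- FALSE
  while (evals < max_evals) {
    sizes <- rect_size(seq_len(m))
    fmin <- min(fs[seq_len(m)])
    # best rectangle per distinct size
    ds <- sort(unique(round(sizes, 12)))
    best_i <- integer(length(ds))
    for (q in seq_along(ds)) {
      cand <- which(abs(sizes - ds[q]) < 1e-12)
      best_i[q] <- cand[which.min(fs[cand])]
    }
    # lower convex hull from largest size downward (potentially optimal set)
    sel <- integer(0)
    j <- length(ds)
    while (j >= 1) {
      sel <- c(sel, best_i[j])
      if (j == 1) break
      # next hull point: maximize slope (f_j - f_q)/(d_j - d_q) over q < j
      slopes <- (fs[best_i[j]] - fs[best_i[seq_len(j - 1)]]) /
        (ds[j] - ds[seq_len(j - 1)])
      j_next <- which.max(slopes)
      # epsilon condition: hull point must allow sufficient improvement
      K <- slopes[j_next]
      if (fs[best_i[j_next]] - K * ds[j_next] > fmin - eps * max(abs(fmin), 1e-12)) {
        break
      }
      j <- j_next
    }
    if (length(sel) == 0) break
    for (p in sel) {
      if (evals >= max_evals) { budget_exhausted <- TRUE; break }
      kmin <- min(ks[, p])
      dims <- which(ks[, p] == kmin)
      delta <- 3^(-(kmin + 1))
      # sample both neighbors along each longest dimension
      wvals <- matrix(NA_real_, 2, length(dims))
      new_centers <- vector("list", length(dims))
      for (q in seq_along(dims)) {
        if (evals + 2L > max_evals) { budget_exhausted <- TRUE; break }
        d <- dims[q]
        cp <- centers[, p]; cp[d] <- cp[d] + delta
        cm <- centers[, p]; cm[d] <- cm[d] - delta
        wvals[1, q] <- f_of(cp)
        wvals[2, q] <- f_of(cm)
        new_centers[[q]] <- list(plus = cp, minus = cm)
      }
      done <- which(!is.na(wvals[1, ]))
      if (length(done) == 0) next
      ord <- done[order(apply(wvals[, done, drop = FALSE], 2, min))]
      # divide in order of increasing best neighbor value
      kcur <- ks[, p]
      for (q in ord) {
        d <- dims[q]
        kcur[d] <- kcur[d] + 1L
        grow(m + 2L)
        centers[, m + 1L] <- new_centers[[q]]$plus
        ks[, m + 1L] <- kcur
        fs[m + 1L] <- wvals[1, q]
        centers[, m + 2L] <- new_centers[[q]]$minus
        ks[, m + 2L] <- kcur
        fs[m + 2L] <- wvals[2, q]
        m <- m + 2L
      }
      ks[, p] <- kcur
    }
    if (budget_exhausted) break
  }
  best <- which.min(fs[seq_len(m)])
  list(par = to_x(centers[, best]), value = fs[best], evals = evals,
       budget_exhausted = budget_exhausted || evals >= max_evals)
}
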