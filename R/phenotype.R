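#' Normalize fitted coefficients by population aggregates
#'
#' Computes the population aggregates D-bar (mean over cell lines of
#' (D1 + D2)/2), rho-bar (mean of (rho1 + rho2)/2) and A-bar (mean of A2),
#' then divides each line's coefficients by the matching aggregate,
#' rendering them dimensionless fold-of-average values. Labels are unset
#' until [classify_go_or_grow()] is applied.
#'
#' @param params Data frame with one row per cell line and columns
#'   `cell_line`, `D1`, `D2`, `rho1`, `rho2`, `A2` (extra columns are
#'   ignored).
#' @return Object of class `gogrow_table`: data frame of normalized
#'   coefficients `Dbar1`, `Dbar2`, `rhobar1`, `rhobar2`, `Abar2` plus
#'   attribute `aggregates`.
#' @export
normalize_parameters <- function(params) {
  need <- c("cell_line", "D1", "D2", "rho1", "rho2", "A2")
  stopifnot(is.data.frame(params), all(need %in% names(params)))
  if (nrow(params) < 2L) stop("need at least 2 cell lines")
  D_bar <- mean((params$D1 + params$D2) / 2)
  rho_bar <- mean((params$rho1 + params$rho2) / 2)
  A_bar <- mean(params$A2)
  if (D_bar == 0 || rho_bar == 0 || A_bar == 0) {
    stop("degenerate normalization: a population aggregate is exactly 0")
  }
  out <- data.frame(cell_line = params$cell_line,
                    Dbar1 = params$D1 / D_bar,
                    Dbar2 = params$D2 / D_bar,
                    rhobar1 = params$rho1 / rho_bar,
                    rhobar2 = params$rho2 / rho_bar,
                    Abar2 = params$A2 / A_bar,
                    label = NA_character_)
  attr(out, "aggregates") <- c(D_bar = D_bar, rho_bar = rho_bar, A_bar = A_bar)
  class(out) <- c("gogrow_table", "data.frame")
  out
}

#' Go-or-Grow classification of cell lines
#'
#' A line is Go-or-Grow when one subpopulation is predominantly migrating
#' and the other predominantly proliferating, by factor k (strict
#' inequalities): either
#' `Dbar1 > k (Dbar2 + Abar2)` and `rhobar2 > k rhobar1`
#' (population 1 migrates), or
#' `(Dbar2 + Abar2) > k Dbar1` and `rhobar1 > k rhobar2`
#' (population 2 migrates). Advection counts toward the second
#' population's motility.
#'
#' @param table A `gogrow_table` from [normalize_parameters()].
#' @param k Multiplicative separation factor (default 5).
#' @return The table with the `label` column set to one of
#'   `"go_or_grow_pop1_migrates"`, `"go_or_grow_pop2_migrates"`,
#'   `"not_go_or_grow"`, and attribute `k`.
#' @export
classify_go_or_grow <- function(table, k = 5) {
  stopifnot(inherits(table, "gogrow_table"), k > 0)
  mig2 <- table$Dbar2 + table$Abar2
  cond1 <- table$Dbar1 > k * mig2 & table$rhobar2 > k * table$rhobar1
  cond2 <- mig2 > k * table$Dbar1 & table$rhobar1 > k * table$rhobar2
  table$label <- ifelse(cond1, "go_or_grow_pop1_migrates",
                        ifelse(cond2, "go_or_grow_pop2_migrates",
                               "not_go_or_grow"))
  attr(table, "k") <- k
  table
}

#' Hierarchical clustering of cell lines on fitted parameters
#'
#' Agglomerative average-linkage clustering on standardized Euclidean
#' distances: each feature is divided by its across-line sample standard
#' deviation (ddof = 1) before computing Euclidean distances.
#' Zero-variance features are dropped with a warning.
#'
#' @param params Data frame with `cell_line` plus numeric feature columns
#'   (by default the fitted model parameters).
#' @param n_clusters Number of flat clusters to cut the tree into.
#' @param features Optional character vector naming the feature columns;
#'   defaults to all numeric columns.
#' @return Object of class `cluster_result`: `tree` (hclust), `labels`
#'   (named integer vector), `standardization` (per-feature sd used),
#'   `features`.
#' @export
cluster_cell_lines <- function(params, n_clusters, features = NULL) {
  stopifnot(is.data.frame(params), "cell_line" %in% names(params))
  if (is.null(features)) {
    features <- names(params)[vapply(params, is.numeric, TRUE)]
  }
  X <- as.matrix(params[, features, drop = FALSE])
  rownames(X) <- params$cell_line
  if (n_clusters < 1 || n_clusters > nrow(X)) {
    stop("n_clusters must lie in [1, number of lines]")
  }
  sds <- apply(X, 2, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(features[drop], collapse = ", ")))
    X <- X[, !drop, drop = FALSE]
    sds <- sds[!drop]
    features <- features[!drop]
  }
  if (ncol(X) == 0) stop("no informative features left")
  Xs <- sweep(X, 2, sds, "/")
  tree <- stats::hclust(stats::dist(Xs, method = "euclidean"),
                        method = "average")
  labels <- stats::cutree(tree, k = n_clusters)
  structure(list(tree = tree, labels = labels, standardization = sds,
                 features = features),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d lines, %d clusters on %d features\n",
              length(x$labels), length(unique(x$labels)), length(x$features)))
  invisible(x)
}

#' First-order partial correlation
#'
#' Correlation between A and B controlling for C:
#' \deqn{\rho_{AB.C} = (\rho_{AB} - \rho_{AC}\rho_{BC}) /
#'   (\sqrt{1-\rho_{AC}^2}\sqrt{1-\rho_{BC}^2})}
#' clamped to \[-1, 1\] against rounding.
#'
#' @param rho_AB,rho_AC,rho_BC Pairwise Pearson correlations, each in
#'   (-1, 1) for the controlled pair.
#' @return Partial correlation in \[-1, 1\].
#' @export
partial_correlation <- function(rho_AB, rho_AC, rho_BC) {
  vals <- c(rho_AB, rho_AC, rho_BC)
  stopifnot(all(is.finite(vals)), all(abs(vals) <= 1))
  if (abs(rho_AC) == 1 || abs(rho_BC) == 1) {
    stop("partial correlation undefined: |rho_AC| or |rho_BC| equals 1")
  }
  v <- (rho_AB - rho_AC * rho_BC) /
    (sqrt(1 - rho_AC^2) * sqrt(1 - rho_BC^2))
  min(max(v, -1), 1)
}
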