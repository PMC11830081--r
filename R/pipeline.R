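#' Build and validate a run configuration
#'
#' @param inputs Data frame (or list coercible to one) with columns
#'   `cell_line` and `path` (long-format density CSVs, one per replicate).
#' @param models Model variants to fit (subset of `MODEL_IDS`).
#' @param direct_evals Named list of DIRECT budgets per model id (optional).
#' @param local_maxit Local-stage iteration cap.
#' @param sim_N_r Solver grid nodes used during fitting.
#' @param wave List of wave settings: `M`, `horizon_weeks` (simulation
#'   horizon for wave estimation), `N_t` (output times over the horizon).
#' @param k Go-or-Grow separation factor.
#' @param n_clusters Flat cluster count.
#' @param seed Global seed; per-stage child seeds are derived from it.
#' @param output_dir Directory for result tables.
#' @param force Overwrite existing outputs.
#' @return Validated `run_config` object.
#' @export
run_config <- function(inputs, models = MODEL_IDS, direct_evals = NULL,
                       local_maxit = 200, sim_N_r = 400,
                       wave = list(M = 100, horizon_weeks = 5, N_t = 51),
                       k = 5, n_clusters = 2, seed = 1L,
                       output_dir = "spherowave_out", force = FALSE) {
  inputs <- as.data.frame(inputs)
  stopifnot(all(c("cell_line", "path") %in% names(inputs)))
  if (nrow(inputs) == 0) stop("empty input set")
  missing <- !file.exists(inputs$path)
  if (any(missing)) {
    stop(sprintf("input path(s) do not exist: %s",
                 paste(inputs$path[missing], collapse = ", ")))
  }
  bad <- setdiff(models, MODEL_IDS)
  if (length(bad) > 0) {
    stop(sprintf("unknown model name(s): %s", paste(bad, collapse = ", ")))
  }
  if (!("RD_ARD" %in% models)) {
    stop("the model set must include RD_ARD (wave and phenotype stages use it)")
  }
  structure(list(inputs = inputs, models = models,
                 direct_evals = direct_evals, local_maxit = local_maxit,
                 sim_N_r = sim_N_r, wave = wave, k = k,
                 n_clusters = n_clusters, seed = as.integer(seed),
                 output_dir = output_dir, force = isTRUE(force)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `inputs` is a list of
#' `{cell_line, path}` mappings, with relative paths resolved against the
#' YAML file's directory.
#'
#' @param path YAML file path.
#' @return A validated `run_config` object.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$inputs)) stop("config must declare inputs")
  inputs <- do.call(rbind, lapply(cfg$inputs, function(x) {
    data.frame(cell_line = x$cell_line, path = x$path)
  }))
  rel <- !grepl("^(/|[A-Za-z]:)", inputs$path)
  inputs$path[rel] <- file.path(dirname(path), inputs$path[rel])
  args <- cfg[setdiff(names(cfg), "inputs")]
  known <- names(formals(run_config))
  bad <- setdiff(names(args), known)
  if (length(bad) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  do.call(run_config, c(list(inputs = inputs), args))
}

# stable child-seed derivation so stages are individually reproducible
child_seed <- function(seed, stage) {
  (as.integer(seed) * 7919L + as.integer(stage)) %% 2147483647L
}

#' Run the full spheroid analysis pipeline
#'
#' density CSVs -> per-replicate model fits -> per-line parameter
#' aggregates (arithmetic mean over replicates of the RD-ARD fits) ->
#' wave parameters from simulations at the fitted parameters ->
#' Go-or-Grow classification -> hierarchical clustering. All tables are
#' written under `config$output_dir` together with a JSON provenance
#' record and a plain-text log; per-replicate failures are isolated and
#' reported without aborting the run.
#'
#' @param config A [run_config()].
#' @return List with `fits` (per-replicate data frame), `line_params`,
#'   `waves`, `gogrow`, `clusters`, `comparison` (model-comparison table
#'   across replicates), `failures`, and `output_dir`, invisibly written
#'   to disk.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  out_files <- file.path(out_dir, c("fits.csv", "line_params.csv",
                                    "waves.csv", "gogrow.csv",
                                    "clusters.csv", "model_comparison.csv",
                                    "provenance.json", "run.log"))
  if (!config$force && any(file.exists(out_files))) {
    stop("output files already exist; use force = TRUE to overwrite")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  sim_grid <- radial_grid(N_r = config$sim_N_r)
  fit_rows <- list(); comp_rows <- list(); failures <- list()
  for (i in seq_len(nrow(config$inputs))) {
    line <- config$inputs$cell_line[i]
    path <- config$inputs$path[i]
    logf("fitting replicate %d/%d (%s)", i, nrow(config$inputs), line)
    res <- tryCatch({
      obs <- read_density_csv(path)
      compare_models(obs, models = config$models,
                     direct_evals = config$direct_evals,
                     local_maxit = config$local_maxit, sim_grid = sim_grid)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[path]] <- conditionMessage(res)
      logf("  FAILED: %s", conditionMessage(res))
      next
    }
    tab <- res$table
    tab$cell_line <- line
    tab$replicate <- path
    comp_rows[[length(comp_rows) + 1L]] <- tab
    fit <- res$fits[["RD_ARD"]]
    p <- fit$params
    fit_rows[[length(fit_rows) + 1L]] <- data.frame(
      cell_line = line, replicate = path,
      D1 = p$D1, rho1 = p$rho1, K1 = p$K1, alpha = p$alpha,
      D2 = p$D2, rho2 = p$rho2, K2 = p$K2, A2 = p$A2,
      sse = fit$sse, aic = fit$aic)
  }
  if (length(fit_rows) == 0) stop("all replicates failed; nothing to analyze")
  fits <- do.call(rbind, fit_rows)
  comparison <- do.call(rbind, comp_rows)
  # per-line aggregation: arithmetic mean of the RD-ARD fits over replicates
  par_cols <- c("D1", "rho1", "K1", "alpha", "D2", "rho2", "K2", "A2")
  line_params <- stats::aggregate(fits[par_cols],
                                  by = list(cell_line = fits$cell_line),
                                  FUN = mean)
  # wave parameters from simulations at the fitted per-line parameters
  logf("computing wave parameters for %d cell line(s)", nrow(line_params))
  wave_rows <- list()
  for (i in seq_len(nrow(line_params))) {
    lp <- line_params[i, ]
    params <- model_params("RD_ARD", D1 = lp$D1, rho1 = lp$rho1, K1 = lp$K1,
                           D2 = lp$D2, rho2 = lp$rho2, K2 = lp$K2,
                           A2 = lp$A2, alpha = lp$alpha)
    wp <- tryCatch({
      times <- seq(0, config$wave$horizon_weeks,
                   length.out = config$wave$N_t)
      sim <- generate_density_series(params, sim_grid, times)
      wave_parameters(sim, M = config$wave$M)
    }, error = function(e) e)
    if (inherits(wp, "error")) {
      failures[[paste0("waves:", lp$cell_line)]] <- conditionMessage(wp)
      logf("  wave stage FAILED for %s: %s", lp$cell_line,
           conditionMessage(wp))
      next
    }
    wave_rows[[length(wave_rows) + 1L]] <- data.frame(
      cell_line = lp$cell_line, c_max = wp$c_max, c_min = wp$c_min,
      c_diff = wp$c_diff, c_shape = wp$c_shape)
  }
  waves <- if (length(wave_rows)) do.call(rbind, wave_rows) else NULL
  gogrow <- if (nrow(line_params) >= 2) {
    classify_go_or_grow(normalize_parameters(line_params), k = config$k)
  } else NULL
  clusters <- if (nrow(line_params) >= config$n_clusters &&
                    nrow(line_params) >= 2) {
    cl <- cluster_cell_lines(line_params, config$n_clusters,
                             features = par_cols)
    data.frame(cell_line = names(cl$labels), cluster = unname(cl$labels))
  } else NULL
  # write bundle
  wr <- function(x, f) if (!is.null(x)) {
    data.table::fwrite(x, file.path(out_dir, f))
  }
  wr(fits, "fits.csv")
  wr(line_params, "line_params.csv")
  wr(waves, "waves.csv")
  wr(if (is.null(gogrow)) NULL else as.data.frame(gogrow), "gogrow.csv")
  wr(clusters, "clusters.csv")
  wr(comparison, "model_comparison.csv")
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "inputs")],
                               auto_unbox = TRUE, digits = NA)
  provenance <- list(
    seed = config$seed,
    child_seeds = vapply(1:4, function(s) child_seed(config$seed, s), 0L),
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_json) *
                                        seq_along(utf8ToInt(cfg_json))) %%
                            .Machine$integer.max),
    n_replicates = nrow(config$inputs),
    n_failures = length(failures),
    package_version = as.character(utils::packageVersion("spherowave")),
    r_version = R.version.string)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  if (length(failures) > 0) {
    logf("run finished with %d failure(s)", length(failures))
  } else {
    logf("run finished cleanly")
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(fits = fits, line_params = line_params, waves = waves,
                 gogrow = gogrow, clusters = clusters,
                 comparison = comparison, failures = failures,
                 output_dir = out_dir))
}
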