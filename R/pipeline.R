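#' Load a model configuration from file
#'
#' Reads a YAML or JSON configuration (dispatch on file extension) into a
#' validated spec plus run parameters.  The schema has three blocks:
#' `model` (either `type: "ei"`/`"network"` with `weights`, `drive`,
#' `decay`, `gamma`, `F0`, `N`, `chi`, `sigma`, or `type: "depression"` with
#' `k_plus`, `k_minus`, `h`, `w_self`, `gamma`, `F0`, `N`, `sigma`),
#' optional `run` (`n_oscillators`, `horizon`, `dt`, `seed`, `n_grid`), and
#' optionally `preset: "ei"|"depression"` instead of `model` (with `model`
#' entries acting as overrides).  Unknown keys anywhere are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `spec` and `run`.
#' @examples
#' cfg <- load_config(system.file("extdata", "ei-example.yaml",
#'                                package = "popsync"))
#' cfg$spec$N
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    # identity handlers keep bare keys like `N` from being read as booleans
    yaml = , yml = yaml::read_yaml(path, handlers = list(
      "bool#no" = function(x) x, "bool#yes" = function(x) x)),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config extension: ", ext))
  allowed_top <- c("preset", "model", "run")
  bad <- setdiff(names(cfg), allowed_top)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  model <- cfg$model
  if (!is.null(cfg$preset)) {
    spec <- preset_spec(cfg$preset)
    if (!is.null(model)) {
      ov <- setdiff(names(model), c("N", "sigma", "chi"))
      if (length(ov)) stop("preset overrides limited to N, sigma, chi; got: ",
                           paste(ov, collapse = ", "))
      spec <- preset_spec(cfg$preset, N = model$N, sigma = model$sigma,
                          chi = model$chi)
    }
  } else {
    if (is.null(model)) stop("config needs a `model` or `preset` block")
    type <- model$type
    if (is.null(type)) stop("model block needs a `type`")
    if (type %in% c("ei", "network")) {
      allowed <- c("type", "weights", "drive", "decay", "gamma", "F0", "N",
                   "chi", "sigma")
      bad <- setdiff(names(model), allowed)
      if (length(bad)) stop("unknown model keys: ",
                            paste(bad, collapse = ", "))
      W <- matrix(unlist(model$weights), nrow = length(model$drive),
                  byrow = TRUE)
      spec <- network_spec(
        weights = W, drive = model$drive,
        decay = model$decay %||% rep(1, nrow(W)),
        gain = gain_params(model$gamma %||% 1, model$F0 %||% 1),
        N = model$N %||% 1e5,
        chi = model$chi %||% rep(1 / nrow(W), nrow(W)),
        sigma = model$sigma %||% 0)
    } else if (type == "depression") {
      allowed <- c("type", "k_plus", "k_minus", "h", "w_self", "gamma",
                   "F0", "N", "sigma", "decay")
      bad <- setdiff(names(model), allowed)
      if (length(bad)) stop("unknown model keys: ",
                            paste(bad, collapse = ", "))
      spec <- depression_spec(
        k_plus = model$k_plus, k_minus = model$k_minus, h = model$h,
        w_self = model$w_self %||% 1,
        gain = gain_params(model$gamma %||% 20, model$F0 %||% 1),
        decay = model$decay %||% 1,
        N = model$N %||% 1e4, sigma = model$sigma %||% 0)
    } else {
      stop("unknown model type: ", type)
    }
  }
  run <- cfg$run %||% list()
  allowed_run <- c("n_oscillators", "horizon", "dt", "seed", "n_grid",
                   "n_bins")
  bad <- setdiff(names(run), allowed_run)
  if (length(bad)) stop("unknown run keys: ", paste(bad, collapse = ", "))
  list(spec = spec, run = run)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full theory-to-simulation chain
#'
#' Orchestrates limit-cycle location, the adjoint PRC, the stochastic phase
#' law, the cycle-averaged correlation functions and the stationary
#' phase-difference distribution; optionally simulates a phase-oscillator
#' ensemble and bins its pairwise differences for comparison.  When
#' `out_dir` is given, every artifact is written as TSV alongside a JSON
#' run manifest from which the outputs can be regenerated.
#'
#' @param spec A spec, or a preset name (`"ei"`, `"depression"`).
#' @param sigma,N,chi Optional noise overrides (see [build_phase_law()]).
#' @param n_grid Phase-grid resolution.
#' @param simulate If `TRUE`, run the phase-ensemble simulation and
#'   histogram.
#' @param n_oscillators,horizon,dt Simulation parameters (defaults chosen
#'   from the law's period when `NULL`).
#' @param n_bins Histogram bins.
#' @param seed RNG seed for the simulation stage.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return A `popsync_pipeline` list: `spec`, `limit_cycle`, `prc`, `law`,
#'   `correlation`, `distribution`, `peaks`, and (if simulated)
#'   `trajectory`, `histogram`, `l1`; plus `manifest`.
#' @export
run_pipeline <- function(spec, sigma = NULL, N = NULL, chi = NULL,
                         n_grid = 1024, simulate = FALSE,
                         n_oscillators = 100, horizon = NULL, dt = NULL,
                         n_bins = 50, seed = 1, out_dir = NULL) {
  if (is.character(spec)) spec <- preset_spec(spec)
  lc <- find_limit_cycle(spec, n_grid = n_grid)
  prc <- compute_prc(lc)
  law <- build_phase_law(lc, prc, sigma = sigma, N = N, chi = chi)
  corr <- correlation_functions(law)
  dist <- stationary_distribution(corr)
  out <- list(spec = attr(law, "spec"), limit_cycle = lc, prc = prc,
              law = law, correlation = corr, distribution = dist,
              peaks = attr(dist, "peaks"))
  if (simulate) {
    Tper <- attr(lc, "period")
    if (is.null(horizon)) horizon <- 250 * Tper
    if (is.null(dt)) dt <- Tper / 4000
    traj <- simulate_phase_ensemble(law, n_osc = n_oscillators,
                                    horizon = horizon, dt = dt, seed = seed)
    hst <- histogram_phase_differences(traj, n_bins = n_bins)
    out$trajectory <- traj
    out$histogram <- hst
    out$l1 <- l1_distance(hst, dist)
  }
  out$manifest <- list(
    package = "popsync",
    version = as.character(utils::packageVersion("popsync")),
    spec = spec_as_list(out$spec), n_grid = n_grid, seed = seed,
    simulate = simulate,
    n_oscillators = if (simulate) n_oscillators else NULL,
    horizon = if (simulate) horizon else NULL,
    dt = if (simulate) dt else NULL, n_bins = if (simulate) n_bins else NULL)
  class(out) <- "popsync_pipeline"
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.popsync_pipeline <- function(x, ...) {
  cat("<popsync_pipeline>\n")
  cat(sprintf("  period %.6g, omega %.6g\n",
              attr(x$limit_cycle, "period"), attr(x$limit_cycle, "omega")))
  cat(sprintf("  epsilon %.4g, sigma %.4g\n",
              attr(x$law, "epsilon"), attr(x$law, "sigma")))
  cat(sprintf("  %d stationary peak(s) at: %s\n", nrow(x$peaks),
              paste(sprintf("%.3f", x$peaks$location), collapse = ", ")))
  if (!is.null(x$l1)) {
    cat(sprintf("  simulation vs theory L1 distance: %.4f\n", x$l1))
  }
  invisible(x)
}

spec_as_list <- function(spec) {
  out <- unclass(spec)
  out$gain <- unclass(out$gain)
  out$type <- if (inherits(spec, "depression_spec")) "depression" else
    "network"
  out$weights <- if (!is.null(out$weights)) {
    apply(out$weights, 1, identity, simplify = FALSE)
  }
  out
}

# TSV + JSON artifact writers; every file is regenerable from the manifest
write_pipeline <- function(pipe, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    utils::write.table(as.data.frame(df), file.path(out_dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wtsv(pipe$limit_cycle, "limit_cycle.tsv")
  wtsv(pipe$prc, "prc.tsv")
  wtsv(pipe$law, "phase_law.tsv")
  wtsv(pipe$distribution, "distribution.tsv")
  wtsv(pipe$peaks, "peaks.tsv")
  if (!is.null(pipe$histogram)) wtsv(pipe$histogram, "histogram.tsv")
  meta <- pipe$manifest
  meta$period <- attr(pipe$limit_cycle, "period")
  meta$omega <- attr(pipe$limit_cycle, "omega")
  meta$l1 <- pipe$l1
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
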