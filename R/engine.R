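#' Grid configuration for the full factorial simulation
#'
#' Defaults reproduce the evaluation grid: the 12 main scenarios, series
#' lengths 24, 32, 40, 48, 56, 72, 88, 120, 184 and 312, the full model
#' catalog and 300 replicates per cell.
#'
#' @param scenarios list of [scenario_spec()] objects.
#' @param n_points integer vector of series lengths.
#' @param models list of [model_spec()] objects.
#' @param n_reps replicates per cell (>= 1).
#' @param root_seed integer root seed; per-cell seeds derive from it by cell
#'   index so any cell can be reproduced in isolation.
#' @param params a [dgp_params()] shared by all cells (its `n_points` is
#'   overridden per cell).
#' @param output optional path for the results CSV.
#' @return An object of class `grid_config`.
#' @export
grid_config <- function(scenarios = default_scenarios(),
                        n_points = c(24L, 32L, 40L, 48L, 56L, 72L, 88L,
                                     120L, 184L, 312L),
                        models = model_catalog(),
                        n_reps = 300L, root_seed = 1L,
                        params = dgp_params(), output = NULL) {
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  if (inherits(models, "model_spec")) models <- list(models)
  stopifnot(all(vapply(scenarios, inherits, TRUE, "scenario_spec")),
            all(vapply(models, inherits, TRUE, "model_spec")),
            inherits(params, "dgp_params"))
  if (!is.numeric(n_reps) || n_reps < 1)
    stop("n_reps must be >= 1", call. = FALSE)
  if (any(n_points < 4) || any(n_points %% 2 != 0))
    stop("all n_points must be even and >= 4", call. = FALSE)
  structure(list(scenarios = scenarios, n_points = as.integer(n_points),
                 models = models, n_reps = as.integer(n_reps),
                 root_seed = as.integer(root_seed), params = params,
                 output = output),
            class = "grid_config")
}

# scenario-driven SE-method adaptation:
#  * heteroscedastic cells: classical SEs switch to the White estimator;
#  * autocorrelated cells: single ITS designs (control-as-covariate and
#    uncontrolled) switch to the AR(1)-ML correction.
.adapt_specs <- function(model_specs, scenario) {
  lapply(model_specs, function(sp) {
    if (scenario$error_regime == "ar1" &&
        sp$design %in% c("OLS_C", "UNCONTROLLED") &&
        sp$se_method %in% c("classical", "white"))
      sp$se_method <- "arma"
    if (scenario$variance_regime != "homoscedastic" &&
        sp$se_method == "classical")
      sp$se_method <- "white"
    sp
  })
}

# shared replicate loop: every model consumes the identical panel per
# replicate (paired comparison); returns per-model matrices of estimates
.run_replicates <- function(scenario, n_points, model_specs, n_reps, seed,
                            params, conf_level = 0.95, adapt_se = TRUE) {
  p <- update_params(params, n_points = n_points)
  specs <- if (adapt_se) .adapt_specs(model_specs, scenario) else model_specs
  # resolve spline knot counts once per cell (on the first replicate's
  # panel) so replicates within a cell share a fixed model; re-selecting
  # per replicate mixes model-selection variability into the empirical SE
  # that the per-fit model SEs cannot reflect, distorting coverage
  if (any(vapply(specs, function(sp)
        sp$time_term == "spline" && is.null(sp$spline_k), logical(1)))) {
    pan1 <- simulate_panel(p, scenario, seed = derive_seed(seed, 1L))
    specs <- lapply(specs, function(sp) {
      if (sp$time_term == "spline" && is.null(sp$spline_k)) {
        des <- build_design(sp, pan1)
        sp$spline_k <- length(des$knots)
      }
      sp
    })
  }
  m <- length(specs)
  est <- se <- lo <- hi <- matrix(NA_real_, n_reps, m)
  for (r in seq_len(n_reps)) {
    pan <- simulate_panel(p, scenario, seed = derive_seed(seed, r))
    for (j in seq_len(m)) {
      f <- fit_model(specs[[j]], pan, conf_level = conf_level)
      if (f$converged) {
        est[r, j] <- f$tau_hat; se[r, j] <- f$se_tau
        lo[r, j] <- f$ci_low; hi[r, j] <- f$ci_high
      }
    }
  }
  list(specs = specs, est = est, se = se, lo = lo, hi = hi,
       true_tau = p$tau)
}

.cell_rows <- function(rr, scenario, n_points, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(rr$est))
  rows <- lapply(seq_along(rr$specs), function(j) {
    s <- summarise_performance(rr$est[idx, j], rr$se[idx, j],
                               rr$lo[idx, j], rr$hi[idx, j], rr$true_tau)
    cbind(data.frame(variance_regime = scenario$variance_regime,
                     trend_regime = scenario$trend_regime,
                     error_regime = scenario$error_regime,
                     n_points = n_points,
                     model = rr$specs[[j]]$label,
                     design = rr$specs[[j]]$design,
                     se_method = rr$specs[[j]]$se_method), s)
  })
  do.call(rbind, rows)
}

#' Run one simulation cell
#'
#' Generates `n_reps` panels (one seed-derived stream per replicate, shared
#' across models so every estimator sees identical data), fits every model
#' and summarises performance. In heteroscedastic cells, models with
#' classical SEs automatically adopt the White estimator; in autocorrelated
#' cells, single-series designs adopt the AR(1)-ML correction. Per-replicate
#' fit failures are excluded and counted in `n_converged`, never fatal.
#'
#' @param scenario a [scenario_spec()].
#' @param n_points series length for this cell.
#' @param model_specs list of [model_spec()] objects (or a single one).
#' @param n_reps replicates.
#' @param seed cell seed.
#' @param params a [dgp_params()] (its `n_points` is overridden).
#' @param conf_level CI level.
#' @param adapt_se apply the scenario-driven SE switching described above.
#' @return data.frame with one row per model: scenario axes, `n_points`,
#'   `model`, `design`, `se_method`, and the [summarise_performance()]
#'   columns.
#' @export
run_cell <- function(scenario, n_points, model_specs, n_reps = 300L,
                     seed = 1L, params = dgp_params(), conf_level = 0.95,
                     adapt_se = TRUE) {
  if (inherits(model_specs, "model_spec")) model_specs <- list(model_specs)
  rr <- .run_replicates(scenario, n_points, model_specs, n_reps, seed,
                        params, conf_level, adapt_se)
  out <- .cell_rows(rr, scenario, n_points)
  rownames(out) <- NULL
  out
}

#' Run the full factorial grid
#'
#' Loops over scenarios x series lengths, deriving an independent seed per
#' cell from the root seed so cells are reproducible in isolation and
#' results are invariant to execution order. Failures are isolated per
#' cell.
#'
#' @param config a [grid_config()].
#' @param verbose log per-cell progress and timing to stderr.
#' @return data.frame of concatenated cell rows (also written to
#'   `config$output` as CSV when set).
#' @export
run_grid <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "grid_config"))
  rows <- list()
  cell_index <- 0L
  for (scen in config$scenarios) {
    for (np in config$n_points) {
      cell_index <- cell_index + 1L
      t0 <- proc.time()[["elapsed"]]
      cell <- tryCatch(
        run_cell(scen, np, config$models, n_reps = config$n_reps,
                 seed = derive_seed(config$root_seed, cell_index),
                 params = config$params),
        error = function(e) {
          warning(sprintf("cell %s n=%d failed: %s", scenario_id(scen),
                          np, conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (verbose)
        message(sprintf("[citsim] cell %d (%s, n=%d): %.1fs", cell_index,
                        scenario_id(scen), np,
                        proc.time()[["elapsed"]] - t0))
      rows[[cell_index]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(config$output)) {
    utils::write.csv(out, config$output, row.names = FALSE)
    if (verbose) message("[citsim] results written to ", config$output)
  }
  out
}

#' Replicate-count stability check
#'
#' Recomputes bias and coverage on nested replicate subsets of one cell and
#' flags models whose bias at the reference count (300 by default) differs
#' from the bias at the largest count by more than twice the Monte Carlo SE
#' — an indicator that more replicates are needed to smooth the bias
#' profile.
#'
#' @param scenario a [scenario_spec()].
#' @param n_points series length.
#' @param model_specs list of [model_spec()] objects.
#' @param rep_counts increasing vector of replicate counts.
#' @param seed cell seed.
#' @param params a [dgp_params()].
#' @param reference replicate count whose bias is compared against the
#'   largest count (default 300, clamped to the available counts).
#' @return data.frame with one row per (model, rep_count): `model`,
#'   `n_reps`, `bias`, `coverage`, `mcse_bias`, `unstable`.
#' @export
stability_check <- function(scenario, n_points, model_specs,
                            rep_counts = c(100L, 300L), seed = 1L,
                            params = dgp_params(), reference = 300L) {
  if (inherits(model_specs, "model_spec")) model_specs <- list(model_specs)
  rep_counts <- sort(as.integer(rep_counts))
  if (any(diff(rep_counts) <= 0)) stop("rep_counts must be increasing",
                                       call. = FALSE)
  rr <- .run_replicates(scenario, n_points, model_specs,
                        max(rep_counts), seed, params)
  rows <- lapply(rep_counts, function(k)
    cbind(.cell_rows(rr, scenario, n_points, idx = seq_len(k)),
          rep_count = k))
  out <- do.call(rbind, rows)
  ref <- max(rep_counts[rep_counts <= max(reference, min(rep_counts))])
  big <- max(rep_counts)
  out$unstable <- FALSE
  for (lab in unique(out$model)) {
    b_ref <- out$bias[out$model == lab & out$rep_count == ref]
    b_big <- out$bias[out$model == lab & out$rep_count == big]
    mcse <- out$mcse_bias[out$model == lab & out$rep_count == big]
    if (length(b_ref) && length(b_big) && is.finite(mcse) && mcse > 0)
      out$unstable[out$model == lab] <- abs(b_ref - b_big) > 2 * mcse
  }
  rownames(out) <- NULL
  out
}
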