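#' @title Structured-text configuration
#' @name config
#' @description
#' A flat `key: value` text format (one pair per line, `#` comments, vectors
#' comma-separated) mirroring the DGP parameters and the simulation grid.
#' Scenarios are written as dotted identifiers
#' `variance.trend.error` (e.g. `homoscedastic.parallel.iid`); models by
#' their catalog labels. Unknown keys are rejected; missing keys fall back
#' to the package defaults.
NULL

.config_numeric_keys <- c("tau", "beta1", "beta2", "mu_treat", "mu_ctrl",
                          "sigma_base", "rho", "delta",
                          "irregular_amplitude", "x_mean", "x_sd")
.config_keys <- c(.config_numeric_keys,
                  "n_points", "n_reps", "root_seed", "scenarios", "models",
                  "output")

#' Load a simulation configuration
#'
#' @param path path to a `key: value` text file; an empty file yields the
#'   full package defaults (tau = 2, rho in \{0, 0.7\}, sigma 0.1, sizes
#'   24..312, 300 replicates, full model catalog).
#' @return A [grid_config()] (whose `params` element carries the
#'   [dgp_params()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  errors <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) { errors <- c(errors, paste("unparseable line:", ln));
      next }
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% .config_keys) {
      errors <- c(errors, paste("unknown key:", key)); next
    }
    kv[[key]] <- val
  }
  num <- function(key, len1 = TRUE) {
    v <- suppressWarnings(as.numeric(strsplit(kv[[key]], ",")[[1]]))
    if (any(is.na(v)) || (len1 && length(v) != 1))
      errors <<- c(errors, paste("invalid numeric value for", key))
    v
  }
  pargs <- list()
  for (key in .config_numeric_keys)
    if (!is.null(kv[[key]])) pargs[[key]] <- num(key)
  gargs <- list()
  if (!is.null(kv$n_points)) gargs$n_points <- num("n_points", len1 = FALSE)
  if (!is.null(kv$n_reps)) gargs$n_reps <- num("n_reps")
  if (!is.null(kv$root_seed)) gargs$root_seed <- num("root_seed")
  if (!is.null(kv$output)) gargs$output <- kv$output
  if (!is.null(kv$scenarios)) {
    ids <- trimws(strsplit(kv$scenarios, ",")[[1]])
    gargs$scenarios <- lapply(ids, function(id) {
      parts <- strsplit(id, ".", fixed = TRUE)[[1]]
      if (length(parts) != 3) {
        errors <<- c(errors, paste("invalid scenario id:", id))
        return(scenario_spec())
      }
      tryCatch(scenario_spec(parts[1], parts[2], parts[3]),
               error = function(e) {
                 errors <<- c(errors, paste("invalid scenario id:", id))
                 scenario_spec()
               })
    })
  }
  if (!is.null(kv$models)) {
    labs <- trimws(strsplit(kv$models, ",")[[1]])
    cat_specs <- model_catalog()
    bad <- setdiff(labs, names(cat_specs))
    if (length(bad))
      errors <- c(errors, paste("unknown model label(s):",
                                paste(bad, collapse = "; ")))
    else gargs$models <- cat_specs[labs]
  }
  if (length(errors))
    stop("configuration errors:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  params <- tryCatch(do.call(dgp_params, pargs), error = function(e)
    stop("configuration errors:\n  - ", conditionMessage(e), call. = FALSE))
  gargs$params <- params
  tryCatch(do.call(grid_config, gargs), error = function(e)
    stop("configuration errors:\n  - ", conditionMessage(e), call. = FALSE))
}

#' Write a configuration back to its text form
#'
#' Inverse of [load_config()]: `load_config(dump_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config a [grid_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "grid_config"))
  p <- config$params
  lines <- c(
    sprintf("%s: %.15g", .config_numeric_keys,
            unlist(p[.config_numeric_keys])),
    paste0("n_points: ", paste(config$n_points, collapse = ",")),
    paste0("n_reps: ", config$n_reps),
    paste0("root_seed: ", config$root_seed),
    paste0("scenarios: ",
           paste(vapply(config$scenarios, scenario_id, ""), collapse = ",")),
    paste0("models: ",
           paste(vapply(config$models, `[[`, "", "label"), collapse = ",")),
    if (!is.null(config$output)) paste0("output: ", config$output))
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic test fixtures
#'
#' Small panels (or error series) with analytically known targets, used by
#' the oracle tests.
#'
#' * `tiny_2x2`: 4-point noiseless panel whose 2x2
#'   difference-in-means equals tau exactly.
#' * `noiseless_parallel`: 24-point noiseless parallel panel
#'   (pre-trend slope exactly 0; outcomes equal the systematic mean).
#' * `noiseless_unparallel`: as above with a linear divergence
#'   (pre-period difference an exact line in t).
#' * `ar1_long`: 10,000 AR(1) errors with rho = 0.7 and innovation SD 0.1
#'   (lag-1 autocorrelation ~ 0.7, stationary SD ~ 0.1/sqrt(1 - 0.49)).
#'
#' @param kind fixture name.
#' @param seed integer seed.
#' @return List with elements `panel` (or `errors`) and `expected` (named
#'   list of analytic targets).
#' @export
make_fixture <- function(kind = c("noiseless_parallel",
                                  "noiseless_unparallel", "tiny_2x2",
                                  "ar1_long"), seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "ar1_long") {
    e <- make_errors(10000L, "ar1", 0.1, rho = 0.7, seed = seed)
    return(list(errors = e,
                expected = list(rho = 0.7,
                                stationary_sd = 0.1 / sqrt(1 - 0.49))))
  }
  base <- dgp_params(sigma_base = 0, x_sd = 0)
  cfg <- switch(kind,
    tiny_2x2 = list(p = update_params(base, n_points = 4),
                    s = scenario_spec()),
    noiseless_parallel = list(p = update_params(base, n_points = 24),
                              s = scenario_spec()),
    noiseless_unparallel = list(
      p = update_params(base, n_points = 24),
      s = scenario_spec(trend_regime = "unparallel_linear")))
  pan <- simulate_panel(cfg$p, cfg$s, seed = seed)
  expected <- list(tau = cfg$p$tau, beta2 = cfg$p$beta2,
                   pre_slope = if (cfg$s$trend_regime == "parallel") 0 else
                     cfg$p$delta * (cfg$p$mu_treat - cfg$p$mu_ctrl))
  if (kind == "tiny_2x2") {
    ds <- difference_series(pan)
    expected$did_of_means <- mean(ds$diff_y[ds$post == 1]) -
      mean(ds$diff_y[ds$post == 0])
  }
  list(panel = pan, expected = expected)
}
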