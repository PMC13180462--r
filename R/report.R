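#' Summary tables from a results table
#'
#' Reshapes the long results of [run_grid()] into one wide table per
#' performance measure: rows are (scenario, n_points) facets, columns are
#' models. Values are rounded to 4 decimals in the wide rendering; the long
#' rendering keeps full precision.
#'
#' @param results results data.frame from [run_grid()] (or read back from
#'   its CSV).
#' @param measure one of `"bias"`, `"coverage"`, `"se_ratio"`, `"emp_se"`,
#'   `"avg_mod_se"`.
#' @return A `report_table`: list with `long` (facet keys, model, value) and
#'   `wide` (one column per model).
#' @export
report_table <- function(results, measure = c("bias", "coverage",
                                              "se_ratio", "emp_se",
                                              "avg_mod_se")) {
  measure <- match.arg(measure)
  keys <- c("variance_regime", "trend_regime", "error_regime", "n_points")
  if (!all(c(keys, "model", measure) %in% names(results)))
    stop("results table is missing required columns", call. = FALSE)
  long <- results[, c(keys, "model", measure)]
  names(long)[names(long) == measure] <- "value"
  wide <- stats::reshape(long, idvar = keys, timevar = "model",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  mod_cols <- setdiff(names(wide), keys)
  wide[mod_cols] <- lapply(wide[mod_cols], round, digits = 4)
  rownames(wide) <- NULL
  structure(list(measure = measure, long = long, wide = wide),
            class = "report_table")
}

#' @export
print.report_table <- function(x, ...) {
  cat(sprintf("report_table (%s): %d facet rows x %d models\n", x$measure,
              nrow(x$wide), ncol(x$wide) - 4L))
  print(utils::head(x$wide, 10))
  invisible(x)
}

.cli_usage <- function() {
  cat("usage: Rscript -e 'citsim::cits_cli()' <command> [options]\n",
      "commands:\n",
      "  simulate --config FILE --out panel.csv [--seed N] [--n-points N]\n",
      "  run --config FILE --out results.csv\n",
      "  report --results results.csv --measure bias --out table.csv\n",
      "  pretrend-power --config FILE --n-points N [--seed N]\n",
      "  stability --config FILE --n-points N --reps 100,300 --out t.csv\n",
      sep = "")
}

.cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args)) stop("missing value for ", a, call. = FALSE)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Subcommand dispatcher for use with `Rscript -e 'citsim::cits_cli()'`:
#' `simulate` writes one simulated panel to CSV, `run` executes a grid from
#' a config file, `report` converts a results CSV into a wide summary table,
#' `pretrend-power` estimates parallel-trend test power, and `stability`
#' runs the replicate-count stability check. Exit status: 0 on success, 1 on
#' validation errors, 2 on runtime errors.
#'
#' @param args character vector of arguments (default: the command line).
#' @param quit_on_exit terminate the R session with the exit status (the
#'   behaviour wanted under `Rscript`); set `FALSE` to get the status back
#'   as a return value instead.
#' @return Invisibly, the integer exit status (also reported via [quit()]
#'   when `quit_on_exit` is `TRUE`).
#' @export
cits_cli <- function(args = commandArgs(trailingOnly = TRUE),
                     quit_on_exit = FALSE) {
  finish <- function(status) {
    if (quit_on_exit && !interactive()) quit(status = status, save = "no")
    invisible(status)
  }
  if (length(args) == 0L) { .cli_usage(); return(finish(1L)) }
  cmd <- args[1]
  res <- tryCatch({
    opts <- .cli_opts(args[-1])
    cfg <- if (!is.null(opts$config)) load_config(opts$config)
           else grid_config()
    switch(cmd,
      simulate = {
        np <- if (!is.null(opts$n_points)) as.integer(opts$n_points)
              else cfg$params$n_points
        seed <- if (!is.null(opts$seed)) as.integer(opts$seed)
                else cfg$root_seed
        pan <- simulate_panel(update_params(cfg$params, n_points = np),
                              cfg$scenarios[[1]], seed = seed)
        write_panel_csv(pan, opts$out)
        message("panel written to ", opts$out)
      },
      run = {
        cfg$output <- opts$out
        run_grid(cfg)
      },
      report = {
        results <- utils::read.csv(opts$results, check.names = FALSE)
        measure <- if (!is.null(opts$measure)) opts$measure else "bias"
        tab <- report_table(results, measure)
        utils::write.csv(tab$wide, opts$out, row.names = FALSE)
        message("report written to ", opts$out)
      },
      `pretrend-power` = {
        np <- as.integer(opts$n_points)
        seed <- if (!is.null(opts$seed)) as.integer(opts$seed)
                else cfg$root_seed
        scen <- cfg$scenarios[[1]]
        pw <- pretrend_power(scen, np, n_reps = cfg$n_reps, seed = seed,
                             params = cfg$params)
        cat(sprintf("rejection fraction at n=%d (%s): %.4f\n", np,
                    scenario_id(scen), pw))
      },
      stability = {
        np <- as.integer(opts$n_points)
        reps <- as.integer(strsplit(opts$reps, ",")[[1]])
        tab <- stability_check(cfg$scenarios[[1]], np, cfg$models,
                               rep_counts = reps, seed = cfg$root_seed,
                               params = cfg$params)
        utils::write.csv(tab, opts$out, row.names = FALSE)
        message("stability table written to ", opts$out)
      },
      { .cli_usage(); stop("unknown command: ", cmd, call. = FALSE) })
    0L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("configuration errors|unknown|missing value|unexpected",
              conditionMessage(e))) 1L else 2L
  })
  finish(res)
}
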