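#' Monte Carlo performance measures for one cell
#'
#' Summarises replicate estimates of the intervention coefficient with the
#' standard simulation-study measures: bias (reported in absolute value, the
#' signed version retained), empirical SE (the SD of the estimator across
#' replicates), average model SE (the arithmetic mean of the reported SEs),
#' their ratio (a diagnostic of variance-estimation accuracy), coverage of
#' the nominal 95% interval, and the Monte Carlo SE of the bias
#' (\eqn{EmpSE/\sqrt{n_{reps}}}). Non-converged replicates (NA estimates)
#' are dropped and counted.
#'
#' @param estimates replicate point estimates (NA = non-converged).
#' @param ses replicate model SEs.
#' @param ci_low,ci_high replicate CI bounds.
#' @param true_tau true intervention effect.
#' @return One-row data.frame with columns `n_reps`, `n_converged`, `bias`,
#'   `bias_signed`, `mean_tau`, `emp_se`, `avg_mod_se`, `se_ratio`,
#'   `coverage`, `mcse_bias`. With fewer than 2 converged replicates the
#'   dispersion measures are `NA` (flagged, not an error).
#' @examples
#' summarise_performance(c(1.8, 2.2), c(0.2, 0.2), c(1.4, 1.8),
#'                       c(2.2, 2.6), true_tau = 2)
#' @export
summarise_performance <- function(estimates, ses, ci_low, ci_high, true_tau) {
  stopifnot(length(ses) == length(estimates),
            length(ci_low) == length(estimates),
            length(ci_high) == length(estimates))
  ok <- is.finite(estimates) & is.finite(ses)
  est <- estimates[ok]; se <- ses[ok]
  lo <- ci_low[ok]; hi <- ci_high[ok]
  n_conv <- sum(ok)
  if (n_conv == 0)
    return(data.frame(n_reps = length(estimates), n_converged = 0L,
                      bias = NA_real_, bias_signed = NA_real_,
                      mean_tau = NA_real_, emp_se = NA_real_,
                      avg_mod_se = NA_real_, se_ratio = NA_real_,
                      coverage = NA_real_, mcse_bias = NA_real_))
  bias_signed <- mean(est) - true_tau
  emp_se <- if (n_conv >= 2) stats::sd(est) else NA_real_
  avg_mod_se <- mean(se)
  data.frame(n_reps = length(estimates), n_converged = n_conv,
             bias = abs(bias_signed), bias_signed = bias_signed,
             mean_tau = mean(est), emp_se = emp_se,
             avg_mod_se = avg_mod_se,
             se_ratio = if (!is.na(emp_se) && emp_se > 0)
               avg_mod_se / emp_se else NA_real_,
             coverage = mean(lo <= true_tau & true_tau <= hi),
             mcse_bias = if (!is.na(emp_se)) emp_se / sqrt(n_conv)
               else NA_real_)
}

#' Meta-regression of bias on scenario characteristics
#'
#' For each design family, regresses per-cell absolute bias on indicator
#' covariates for the scenario axes (heteroscedasticity, unparallel trend,
#' error autocorrelation) and log sample size, quantifying which violations
#' drive each family's bias. Factors constant across the supplied cells are
#' dropped with a warning.
#'
#' @param cell_table results table as produced by [run_grid()] (needs
#'   columns `variance_regime`, `trend_regime`, `error_regime`, `n_points`,
#'   `design`, `bias`).
#' @param response name of the dependent column (default `"bias"`).
#' @return Named list (one element per design family) of coefficient
#'   data.frames with columns `term`, `estimate`, `se`, `t`, `p_value`.
#' @export
bias_regression <- function(cell_table, response = "bias") {
  need <- c("variance_regime", "trend_regime", "error_regime", "n_points",
            "design", response)
  if (!all(need %in% names(cell_table)))
    stop("cell_table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  covs <- data.frame(
    hetero = as.numeric(cell_table$variance_regime != "homoscedastic"),
    hetero_ctrl = as.numeric(cell_table$variance_regime ==
                               "hetero_ctrl_high"),
    unparallel = as.numeric(cell_table$trend_regime != "parallel"),
    ar1 = as.numeric(cell_table$error_regime == "ar1"),
    log_n = log(cell_table$n_points))
  out <- list()
  for (fam in unique(cell_table$design)) {
    idx <- cell_table$design == fam & is.finite(cell_table[[response]])
    y <- cell_table[[response]][idx]
    Z <- covs[idx, , drop = FALSE]
    keep <- vapply(Z, function(cl) length(unique(cl)) > 1L, logical(1))
    if (any(!keep))
      warning("dropping constant factor(s) for ", fam, ": ",
              paste(names(Z)[!keep], collapse = ", "), call. = FALSE)
    X <- cbind(`(Intercept)` = 1, as.matrix(Z[, keep, drop = FALSE]))
    if (length(y) <= ncol(X)) {
      warning("too few cells to regress bias for ", fam, call. = FALSE)
      next
    }
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      warning("collinear factors dropped for ", fam, call. = FALSE)
      X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
      qx <- qr(X)
    }
    beta <- qr.coef(qx, y)
    resid <- y - X %*% beta
    df <- length(y) - ncol(X)
    s2 <- sum(resid^2) / df
    se <- sqrt(diag(s2 * chol2inv(qr.R(qx))))
    tval <- beta / se
    out[[fam]] <- data.frame(term = colnames(X), estimate = unname(beta),
                             se = unname(se), t = unname(tval),
                             p_value = 2 * stats::pt(-abs(unname(tval)), df))
  }
  out
}
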