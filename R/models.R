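#' @title Segmented-regression model formulations embedding a control series
#' @name estimators
#' @description
#' Five designs for estimating a level-change intervention effect from a
#' two-group panel, each identified by where the control series enters:
#'
#' * `CITS` — panel segmented regression with group fixed effect, common
#'   time trend and a group x time interaction allowing diverging
#'   pre-intervention trends; the effect is the coefficient on D x Post.
#' * `DID` — the same panel regression without the group x time interaction
#'   (parallel-trend assumption).
#' * `DIFF` — a single ITS fitted to the between-series difference
#'   \eqn{Diff_t = Y_{treat,t} - Y_{ctrl,t}}; the effect is the Post
#'   coefficient.
#' * `OLS_C` — single ITS of the intervention series with the control
#'   series as a covariate.
#' * `UNCONTROLLED` — single ITS of the intervention series alone.
#'
#' Each design may include no time term, a linear trend, or a restricted
#' cubic spline of time; standard errors may be classical, White,
#' Driscoll-Kraay, feasible GLS or AR(1) maximum likelihood.
NULL

.designs <- c("CITS", "DID", "DIFF", "OLS_C", "UNCONTROLLED")
.time_terms <- c("none", "linear", "spline")
.se_methods <- c("classical", "white", "driscoll_kraay", "fgls", "arma")

#' Model specification
#'
#' A single formulation: design, time term, optional differenced covariate
#' (DIFF only), and SE method. Compatibility rules: `fgls` and
#' `driscoll_kraay` apply only to the panel designs (CITS, DID); `arma` only
#' to the single-series designs (DIFF, OLS_C, UNCONTROLLED). CITS always
#' carries the group x time interaction; DID never does.
#'
#' @param design one of `"CITS"`, `"DID"`, `"DIFF"`, `"OLS_C"`,
#'   `"UNCONTROLLED"`.
#' @param time_term `"none"`, `"linear"` or `"spline"`.
#' @param diff_covariate include the differenced covariate series (DIFF
#'   design only).
#' @param se_method one of `"classical"`, `"white"`, `"driscoll_kraay"`,
#'   `"fgls"`, `"arma"`.
#' @param label stable public identifier; defaults to a family-prefixed
#'   abbreviation.
#' @param spline_k fixed knot count; `NULL` (default) selects by information
#'   criterion among `spline_candidates`.
#' @param spline_candidates candidate knot counts for selection.
#' @param criterion information criterion for knot selection.
#' @param dk_lag Driscoll-Kraay lag; `NULL` uses [dk_default_lag()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(design, time_term = "none", diff_covariate = FALSE,
                       se_method = "classical", label = NULL,
                       spline_k = NULL, spline_candidates = 3:5,
                       criterion = "AIC", dk_lag = NULL) {
  design <- match.arg(design, .designs)
  time_term <- match.arg(time_term, .time_terms)
  se_method <- match.arg(se_method, .se_methods)
  panel <- design %in% c("CITS", "DID")
  if (se_method %in% c("fgls", "driscoll_kraay") && !panel)
    stop(se_method, " is only valid for panel designs (CITS, DID)",
         call. = FALSE)
  if (se_method == "arma" && panel)
    stop("arma correction is only valid for single-series designs",
         call. = FALSE)
  if (diff_covariate && design != "DIFF")
    stop("diff_covariate applies to the DIFF design only", call. = FALSE)
  if (is.null(label)) {
    fam <- switch(design, CITS = "CITS", DID = "DiD", DIFF = "Diff",
                  OLS_C = "OLS C", UNCONTROLLED = "OLS")
    bits <- c(fam,
              if (design == "DIFF" && diff_covariate) "X",
              switch(time_term, none = NULL, linear = "T", spline = "splnT"))
    label <- paste(bits, collapse = " ")
  }
  structure(list(design = design, time_term = time_term,
                 diff_covariate = diff_covariate, se_method = se_method,
                 label = label, spline_k = spline_k,
                 spline_candidates = spline_candidates,
                 criterion = criterion, dk_lag = dk_lag),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s': design=%s, time=%s%s, se=%s\n", x$label,
              x$design, x$time_term,
              if (x$diff_covariate) " + diffX" else "", x$se_method))
  invisible(x)
}

#' The full model catalog
#'
#' All 21 formulations of the evaluation grid, with family-prefixed stable
#' labels: four CITS estimations (FE with trend, Driscoll-Kraay, FE with
#' spline, FGLS), five DiD estimations, six difference-series ITS
#' specifications, three control-as-covariate and three uncontrolled single
#' ITS specifications.
#'
#' @return Named list of [model_spec()] objects, keyed by label.
#' @export
model_catalog <- function() {
  specs <- list(
    model_spec("CITS", "linear", se_method = "classical", label = "CITS FE T"),
    model_spec("CITS", "linear", se_method = "driscoll_kraay",
               label = "CITS DK T"),
    model_spec("CITS", "spline", se_method = "classical",
               label = "CITS splnT"),
    model_spec("CITS", "linear", se_method = "fgls", label = "CITS FGLS T"),
    model_spec("DID", "none", se_method = "classical", label = "DiD FE"),
    model_spec("DID", "linear", se_method = "classical", label = "DiD FE T"),
    model_spec("DID", "none", se_method = "driscoll_kraay", label = "DiD DK"),
    model_spec("DID", "spline", se_method = "classical", label = "DiD splnT"),
    model_spec("DID", "linear", se_method = "fgls", label = "DiD FGLS T"),
    model_spec("DIFF", "none", label = "Diff"),
    model_spec("DIFF", "none", diff_covariate = TRUE, label = "Diff X"),
    model_spec("DIFF", "linear", label = "Diff T"),
    model_spec("DIFF", "linear", diff_covariate = TRUE, label = "Diff X T"),
    model_spec("DIFF", "spline", label = "Diff splnT"),
    model_spec("DIFF", "spline", diff_covariate = TRUE,
               label = "Diff X splnT"),
    model_spec("OLS_C", "none", label = "OLS C"),
    model_spec("OLS_C", "linear", label = "OLS C T"),
    model_spec("OLS_C", "spline", label = "OLS C splnT"),
    model_spec("UNCONTROLLED", "none", label = "OLS"),
    model_spec("UNCONTROLLED", "linear", label = "OLS T"),
    model_spec("UNCONTROLLED", "spline", label = "OLS splnT"))
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}

#' Collapse a panel to the between-series difference
#'
#' \eqn{Diff_t = Y_{treat,t} - Y_{ctrl,t}} and
#' \eqn{diffX_t = X_{treat,t} - X_{ctrl,t}}; the sign convention keeps the
#' Post coefficient on the same scale and sign as the panel intervention
#' effect.
#'
#' @param panel a `cits_panel`.
#' @return data.frame with columns `time`, `post`, `diff_y`, `diff_x`.
#' @export
difference_series <- function(panel) {
  tr <- panel[panel$d == 1L, ]
  ct <- panel[panel$d == 0L, ]
  tr <- tr[order(tr$time), ]; ct <- ct[order(ct$time), ]
  if (nrow(tr) != nrow(ct) || !all(tr$time == ct$time))
    stop("unbalanced panel: both groups must cover every time point",
         call. = FALSE)
  data.frame(time = tr$time, post = tr$post,
             diff_y = tr$y - ct$y, diff_x = tr$x - ct$x)
}

# time-term columns for a design matrix; selects the spline knot count by
# information criterion when spline_k is NULL
.time_columns <- function(spec, time_values, y, base_design) {
  switch(spec$time_term,
    none = list(cols = NULL, knots = NULL),
    linear = list(cols = cbind(time = time_values), knots = NULL),
    spline = {
      k <- spec$spline_k
      if (is.null(k))
        k <- select_knot_count(y, base_design, time_values,
                               candidates = spec$spline_candidates,
                               criterion = spec$criterion)
      knots <- harrell_knots(time_values, as.integer(k))
      list(cols = rcs_basis(time_values, knots), knots = knots)
    })
}

#' Build the regression design for a model specification
#'
#' Returns the response, the regressor matrix and the name of the
#' intervention-effect column (`d_post` for panel designs, `post` for
#' single-series designs). Panel designs use the full panel in long format
#' with an explicit group-dummy fixed effect; DIFF consumes the differenced
#' series; OLS_C and UNCONTROLLED use the intervention series rows (OLS_C
#' adds the control outcome as a covariate).
#'
#' @param spec a [model_spec()].
#' @param panel a `cits_panel`.
#' @return List with `y`, `X`, `tau_col`, `group`, `time`, `knots`.
#' @export
build_design <- function(spec, panel) {
  out <- .build_design_raw(spec, panel)
  # degenerate covariates (e.g. a constant X in noiseless fixtures) are
  # dropped rather than left to trip the rank check; the intercept and the
  # effect column always stay
  keep <- colnames(out$X) == "(Intercept)" |
    apply(out$X, 2, function(cl) stats::sd(cl) > 0)
  keep[colnames(out$X) == out$tau_col] <- TRUE
  out$X <- out$X[, keep, drop = FALSE]
  out
}

.build_design_raw <- function(spec, panel) {
  if (spec$design %in% c("CITS", "DID")) {
    pan <- panel[order(panel$d == 0L, panel$time), ]  # treat block first
    y <- pan$y
    base <- cbind(`(Intercept)` = 1, d = pan$d, x = pan$x, post = pan$post,
                  d_post = pan$d * pan$post)
    extra <- if (spec$design == "CITS") cbind(d_time = pan$d * pan$time)
    tc <- .time_columns(spec, pan$time, y, cbind(base, extra))
    X <- cbind(base, tc$cols, extra)
    return(list(y = y, X = X, tau_col = "d_post", group = pan$group,
                time = pan$time, knots = tc$knots))
  }
  if (spec$design == "DIFF") {
    ds <- difference_series(panel)
    y <- ds$diff_y
    base <- cbind(`(Intercept)` = 1, post = ds$post)
    if (spec$diff_covariate) base <- cbind(base, diff_x = ds$diff_x)
    tc <- .time_columns(spec, ds$time, y, base)
    return(list(y = y, X = cbind(base, tc$cols), tau_col = "post",
                group = rep(1L, nrow(ds)), time = ds$time, knots = tc$knots))
  }
  tr <- panel[panel$d == 1L, ]; tr <- tr[order(tr$time), ]
  y <- tr$y
  base <- cbind(`(Intercept)` = 1, x = tr$x, post = tr$post)
  if (spec$design == "OLS_C") {
    ct <- panel[panel$d == 0L, ]; ct <- ct[order(ct$time), ]
    if (nrow(ct) != nrow(tr) || !all(ct$time == tr$time))
      stop("unbalanced panel: control series missing time points",
           call. = FALSE)
    base <- cbind(`(Intercept)` = 1, control = ct$y, x = tr$x, post = tr$post)
  }
  tc <- .time_columns(spec, tr$time, y, base)
  list(y = y, X = cbind(base, tc$cols), tau_col = "post",
       group = rep(1L, nrow(tr)), time = tr$time, knots = tc$knots)
}

.failed_fit <- function(spec, n_obs) {
  structure(list(tau_hat = NA_real_, se_tau = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, converged = FALSE,
                 model_label = spec$label, n_obs = n_obs, aux = list()),
            class = "cits_fit")
}

#' Fit a model formulation to a panel
#'
#' Estimates the intervention coefficient with the specification's SE method
#' and a 95% confidence interval (t critical values with residual degrees of
#' freedom for least-squares methods, normal critical values for FGLS and
#' AR(1)-ML). Deterministic given the data. Rank-deficient designs and
#' FGLS/ARMA non-convergence yield `converged = FALSE` rather than an error.
#'
#' @param spec a [model_spec()].
#' @param panel a `cits_panel`.
#' @param conf_level confidence level (default 0.95).
#' @return A `cits_fit`: list with `tau_hat`, `se_tau`, `ci_low`, `ci_high`,
#'   `converged`, `model_label`, `n_obs`, and `aux` (nuisance coefficients,
#'   knots, SE method, estimated AR coefficient where applicable).
#' @export
fit_model <- function(spec, panel, conf_level = 0.95) {
  stopifnot(inherits(spec, "model_spec"))
  des <- tryCatch(build_design(spec, panel), error = function(e) e)
  if (inherits(des, "error")) stop(des)
  y <- des$y; X <- des$X
  n <- length(y); p <- ncol(X)
  alpha <- 1 - conf_level

  if (spec$se_method == "fgls") {
    fg <- panel_fgls(X, y, group = des$group, time = des$time)
    if (!fg$converged) return(.failed_fit(spec, n))
    tau <- unname(fg$coefficients[des$tau_col])
    se <- sqrt(fg$vcov$vcov[des$tau_col, des$tau_col])
    crit <- stats::qnorm(1 - alpha / 2)
    return(structure(list(tau_hat = tau, se_tau = se,
                          ci_low = tau - crit * se, ci_high = tau + crit * se,
                          converged = TRUE, model_label = spec$label,
                          n_obs = n,
                          aux = list(coefficients = fg$coefficients,
                                     rho_hat = fg$rho_hat,
                                     se_method = "fgls", knots = des$knots)),
                     class = "cits_fit"))
  }
  if (spec$se_method == "arma") {
    ar <- arma_ols(X, y)
    if (!ar$converged) return(.failed_fit(spec, n))
    tau <- unname(ar$coefficients[des$tau_col])
    se <- sqrt(ar$vcov$vcov[des$tau_col, des$tau_col])
    crit <- stats::qnorm(1 - alpha / 2)
    return(structure(list(tau_hat = tau, se_tau = se,
                          ci_low = tau - crit * se, ci_high = tau + crit * se,
                          converged = TRUE, model_label = spec$label,
                          n_obs = n,
                          aux = list(coefficients = ar$coefficients,
                                     rho_hat = ar$rho_hat,
                                     se_method = "arma", knots = des$knots)),
                     class = "cits_fit"))
  }

  qx <- qr(X)
  if (qx$rank < p) return(.failed_fit(spec, n))
  beta <- qr.coef(qx, y)
  resid <- as.numeric(y - X %*% beta)
  vc <- switch(spec$se_method,
    classical = {
      s2 <- sum(resid^2) / (n - p)
      v <- s2 * chol2inv(qr.R(qx))
      dimnames(v) <- list(colnames(X), colnames(X))
      structure(list(vcov = v, method = "classical", meta = list()),
                class = "cov_estimate")
    },
    white = white_vcov(X, resid),
    driscoll_kraay = driscoll_kraay_vcov(X, resid, des$group, des$time,
                                         lag = spec$dk_lag))
  tau <- unname(beta[des$tau_col])
  se <- sqrt(vc$vcov[des$tau_col, des$tau_col])
  crit <- stats::qt(1 - alpha / 2, df = n - p)
  structure(list(tau_hat = tau, se_tau = se,
                 ci_low = tau - crit * se, ci_high = tau + crit * se,
                 converged = TRUE, model_label = spec$label, n_obs = n,
                 aux = list(coefficients = beta,
                            se_method = spec$se_method, knots = des$knots,
                            vcov_meta = vc$meta)),
            class = "cits_fit")
}

#' @export
print.cits_fit <- function(x, ...) {
  cat(sprintf("%s: tau_hat = %.4f (SE %.4f), 95%% CI [%.4f, %.4f]%s\n",
              x$model_label, x$tau_hat, x$se_tau, x$ci_low, x$ci_high,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Two separate single-series ITS, effect by subtraction
#'
#' Fits the uncontrolled single ITS separately to the intervention and the
#' control series and estimates the intervention effect as the difference of
#' the two Post coefficients. Because the post-period common confounder
#' enters both series, it cancels in the subtraction. The SE combines the
#' two model SEs under an independence assumption
#' (\eqn{\sqrt{se_1^2 + se_2^2}}) with a normal-quantile CI; this is a
#' base-case reporting device, not a recommended design.
#'
#' @param panel a `cits_panel`.
#' @param time_term `"none"`, `"linear"` or `"spline"`.
#' @param conf_level confidence level.
#' @return A `cits_fit` with label `"2xITS"`.
#' @export
fit_two_single_its <- function(panel, time_term = "none", conf_level = 0.95) {
  spec <- model_spec("UNCONTROLLED", time_term = time_term)
  swap <- panel
  swap$d <- 1L - swap$d  # refit the "uncontrolled" ITS on the control series
  f_tr <- fit_model(spec, panel, conf_level)
  f_ct <- fit_model(spec, swap, conf_level)
  if (!f_tr$converged || !f_ct$converged)
    return(.failed_fit(list(label = "2xITS"), f_tr$n_obs + f_ct$n_obs))
  tau <- f_tr$tau_hat - f_ct$tau_hat
  se <- sqrt(f_tr$se_tau^2 + f_ct$se_tau^2)
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(tau_hat = tau, se_tau = se, ci_low = tau - crit * se,
                 ci_high = tau + crit * se, converged = TRUE,
                 model_label = "2xITS", n_obs = f_tr$n_obs + f_ct$n_obs,
                 aux = list(tau_treat = f_tr$tau_hat, tau_ctrl = f_ct$tau_hat,
                            se_method = "independent_combination")),
            class = "cits_fit")
}
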