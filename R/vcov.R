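#' White heteroskedasticity-consistent covariance
#'
#' Sandwich estimator \eqn{(X'X)^{-1} X' diag(e^2) X (X'X)^{-1}} with the
#' small-sample HC1 factor \eqn{n/(n-k)}. Coefficient estimates are
#' untouched; only standard errors change.
#'
#' @param X full-rank design matrix (n x k).
#' @param residuals OLS residual vector of length n.
#' @return A `cov_estimate`: list with `vcov` (k x k symmetric matrix),
#'   `method`, and `meta`.
#' @export
white_vcov <- function(X, residuals) {
  X <- as.matrix(X)
  residuals <- as.numeric(residuals)
  n <- nrow(X); k <- ncol(X)
  qx <- qr(X)
  if (qx$rank < k) stop("design matrix is rank deficient", call. = FALSE)
  bread <- chol2inv(qr.R(qx))
  meat <- crossprod(X * residuals)
  v <- n / (n - k) * bread %*% meat %*% bread
  v <- (v + t(v)) / 2
  dimnames(v) <- list(colnames(X), colnames(X))
  structure(list(vcov = v, method = "white", meta = list(hc = "HC1")),
            class = "cov_estimate")
}

#' Default Driscoll-Kraay lag
#'
#' Standard plug-in bandwidth `floor(4 * (T/100)^(2/9))`.
#'
#' @param T_periods number of time periods.
#' @return Integer lag.
#' @export
dk_default_lag <- function(T_periods) {
  as.integer(floor(4 * (T_periods / 100)^(2 / 9)))
}

#' Driscoll-Kraay panel covariance
#'
#' Standard errors robust to general cross-sectional and temporal
#' correlation: moment vectors \eqn{h_{it} = x_{it} e_{it}} are summed across
#' groups within each period, their autocovariances up to `lag` are combined
#' with Bartlett-kernel weights, and the result is sandwiched between
#' \eqn{(X'X)^{-1}}. The same \eqn{n/(n-k)} small-sample factor as
#' [white_vcov()] is applied, so with `lag = 0` and a single group the two
#' estimators coincide exactly.
#'
#' @param X design matrix, rows ordered consistently with `group`/`time`.
#' @param residuals OLS residuals.
#' @param group group identifier per row.
#' @param time integer time identifier per row (balanced panel).
#' @param lag maximum autocovariance lag; default [dk_default_lag()].
#' @return A `cov_estimate` with `meta$lag`.
#' @export
driscoll_kraay_vcov <- function(X, residuals, group, time, lag = NULL) {
  X <- as.matrix(X)
  residuals <- as.numeric(residuals)
  n <- nrow(X); k <- ncol(X)
  times <- sort(unique(time))
  T_periods <- length(times)
  if (is.null(lag)) lag <- dk_default_lag(T_periods)
  if (lag >= T_periods) stop("lag must be < number of periods", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < k) stop("design matrix is rank deficient", call. = FALSE)
  bread <- chol2inv(qr.R(qx))
  H <- X * residuals
  # cross-sectional sum of moment vectors per period
  ht <- rowsum(H, group = match(time, times))
  S <- crossprod(ht)
  if (lag > 0) {
    for (j in seq_len(lag)) {
      w <- 1 - j / (lag + 1)
      omega <- crossprod(ht[(j + 1):T_periods, , drop = FALSE],
                         ht[1:(T_periods - j), , drop = FALSE])
      S <- S + w * (omega + t(omega))
    }
  }
  v <- n / (n - k) * bread %*% S %*% bread
  v <- (v + t(v)) / 2
  dimnames(v) <- list(colnames(X), colnames(X))
  structure(list(vcov = v, method = "driscoll_kraay",
                 meta = list(lag = lag)), class = "cov_estimate")
}

#' Newey-West covariance for a single series
#'
#' Convenience wrapper: the Driscoll-Kraay estimator with one cross-sectional
#' unit reduces to Newey-West. Not part of the core model grid; provided as
#' an optional extra for practice.
#'
#' @inheritParams driscoll_kraay_vcov
#' @param time optional time index (defaults to row order).
#' @return A `cov_estimate`.
#' @export
newey_west_vcov <- function(X, residuals, lag = NULL, time = NULL) {
  if (is.null(time)) time <- seq_len(nrow(as.matrix(X)))
  out <- driscoll_kraay_vcov(X, residuals, group = rep(1L, length(time)),
                             time = time, lag = lag)
  out$method <- "newey_west"
  out
}

#' Two-step feasible GLS for a balanced two-group panel
#'
#' Error correction allowing for heteroscedasticity across panels, a common
#' AR(1) coefficient within panels, and contemporaneous cross-panel
#' correlation. Step 1 estimates per-panel variances, the pooled AR(1)
#' coefficient and the cross-panel covariance from OLS residuals; step 2 runs
#' GLS with the assembled error covariance (group-level covariance matrix
#' Kronecker an AR(1) correlation over time); the estimation is then iterated
#' once from the GLS residuals.
#'
#' @param X design matrix with rows sorted group-major (all rows of group 1
#'   by time, then group 2).
#' @param y response vector.
#' @param group group identifier per row (exactly 2 levels, balanced).
#' @param time integer time per row.
#' @param panel_het,ar1_within,cross_corr logical switches for the three
#'   components of the error model.
#' @param iterate number of FGLS re-estimation passes after the first
#'   (default 1).
#' @return List with `coefficients`, `vcov` (a `cov_estimate`), `rho_hat`,
#'   `sigma2_groups`, `cross_cov`, `converged`.
#' @export
panel_fgls <- function(X, y, group, time, panel_het = TRUE,
                       ar1_within = TRUE, cross_corr = TRUE, iterate = 1L) {
  X <- as.matrix(X)
  k <- ncol(X)
  gs <- unique(group)
  if (length(gs) != 2L) stop("panel_fgls expects exactly 2 groups",
                             call. = FALSE)
  times <- sort(unique(time))
  T_periods <- length(times)
  if (nrow(X) != 2L * T_periods) stop("unbalanced panel", call. = FALSE)
  if (T_periods < k + 3L)
    stop("too few periods relative to parameters", call. = FALSE)
  ord <- order(match(group, gs), time)
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  g_sorted <- group[ord]
  i1 <- which(g_sorted == gs[1]); i2 <- which(g_sorted == gs[2])

  beta <- qr.coef(qr(X), y)
  res <- list(converged = TRUE)
  for (pass in seq_len(iterate + 1L)) {
    e <- y - X %*% beta
    e1 <- e[i1]; e2 <- e[i2]
    rho_hat <- 0
    if (ar1_within) {
      num <- sum(e1[-1] * e1[-T_periods]) + sum(e2[-1] * e2[-T_periods])
      den <- sum(e1^2) + sum(e2^2)
      rho_hat <- if (den > 0) num / den else 0
      rho_hat <- max(min(rho_hat, 0.99), -0.99)
    }
    s1 <- mean(e1^2); s2 <- mean(e2^2)
    if (!panel_het) s1 <- s2 <- (s1 + s2) / 2
    s12 <- if (cross_corr) mean(e1 * e2) else 0
    # keep the group covariance positive definite
    lim <- 0.99 * sqrt(s1 * s2)
    s12 <- max(min(s12, lim), -lim)
    if (s1 <= 0 || s2 <= 0) return(list(coefficients = beta, vcov = NULL,
                                        rho_hat = rho_hat, converged = FALSE))
    sigma_g <- matrix(c(s1, s12, s12, s2), 2)
    # innovation variance scaling: residual variance already includes the
    # AR(1) inflation, so use it directly as the stationary variance
    R <- rho_hat^abs(outer(times, times, "-"))
    V <- kronecker(sigma_g, R)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(list(coefficients = beta, vcov = NULL,
                                 rho_hat = rho_hat, converged = FALSE))
    Xs <- backsolve(ch, X, transpose = TRUE)
    ys <- backsolve(ch, y, transpose = TRUE)
    qx <- qr(Xs)
    if (qx$rank < k) return(list(coefficients = beta, vcov = NULL,
                                 rho_hat = rho_hat, converged = FALSE))
    beta <- qr.coef(qx, ys)
    vcov <- chol2inv(qr.R(qx))
    dimnames(vcov) <- list(colnames(X), colnames(X))
    res <- list(coefficients = beta,
                vcov = structure(list(vcov = vcov, method = "fgls",
                                      meta = list(rho_hat = rho_hat)),
                                 class = "cov_estimate"),
                rho_hat = rho_hat,
                sigma2_groups = c(s1, s2), cross_cov = s12,
                converged = TRUE)
  }
  names(res$coefficients) <- colnames(X)
  res
}

#' Regression with AR(1) errors by maximum likelihood
#'
#' Linear regression whose errors follow \eqn{e_t = \rho e_{t-1} + \nu_t},
#' estimated jointly with the coefficients by Gaussian maximum likelihood
#' (via [stats::arima()]). The AR order is fixed at 1 to match the
#' generating process; order selection on two dozen points is unstable.
#'
#' @param X design matrix including an intercept column named
#'   `"(Intercept)"` (or a constant first column).
#' @param y response vector.
#' @param ar_order autoregressive order (default 1).
#' @return List with `coefficients`, `vcov` (a `cov_estimate`), `rho_hat`,
#'   `converged`.
#' @export
arma_ols <- function(X, y, ar_order = 1L) {
  X <- as.matrix(X)
  n <- length(y)
  if (n <= ncol(X) + ar_order)
    stop("series too short for the requested AR order", call. = FALSE)
  const <- apply(X, 2, function(cl) all(cl == cl[1] & cl[1] != 0))
  xreg <- X[, !const, drop = FALSE]
  fit <- tryCatch(
    stats::arima(y, order = c(ar_order, 0L, 0L), xreg = xreg,
                 include.mean = any(const), method = "ML"),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || any(!is.finite(diag(fit$var.coef))))
    return(list(coefficients = NULL, vcov = NULL, rho_hat = NA_real_,
                converged = FALSE))
  cf <- stats::coef(fit)
  vc <- fit$var.coef
  keep <- !grepl("^ar[0-9]+$", names(cf))
  beta <- cf[keep]
  names(beta)[names(beta) == "intercept"] <- "(Intercept)"
  v <- vc[keep, keep, drop = FALSE]
  dimnames(v) <- list(names(beta), names(beta))
  list(coefficients = beta,
       vcov = structure(list(vcov = v, method = "arma",
                             meta = list(ar_order = ar_order)),
                        class = "cov_estimate"),
       rho_hat = unname(cf[grepl("^ar1$", names(cf))][1]),
       converged = TRUE)
}
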