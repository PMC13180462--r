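#' @title Data-generating process for controlled interrupted time series panels
#' @name dgp
#' @description
#' Two-group (intervention + control) panels of equally spaced outcomes with a
#' level-change-only intervention at the series midpoint. The outcome model is
#'
#' \deqn{Y_{it} = X_{it}\beta_1 + Post_t\beta_2 + \tau (D_i \times Post_t)
#'   + \lambda_t \mu_i + \varepsilon_{it}}
#'
#' where \eqn{X} is an observed covariate, \eqn{Post} a common post-period
#' confounder entering both series, \eqn{D} the treatment dummy, and
#' \eqn{\lambda_t \mu_i} a group-specific unobservable whose time profile
#' generates parallel or diverging trends. Errors are Gaussian, independent or
#' AR(1), homoscedastic or with level-dependent heteroscedasticity.
NULL

#' Deterministic seed derivation
#'
#' Mixes a root seed with integer indices (cell, replicate, group) into a new
#' seed below 2^31, so every cell/replicate/group has an independently
#' reproducible stream.
#'
#' @param seed integer root seed.
#' @param ... further non-negative integers to mix in.
#' @return A single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  s <- 0
  for (k in ks) {
    stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
    # 69069: classic LCG multiplier; modulus 2^31 - 1 keeps the state a valid
    # 32-bit R integer. All arithmetic stays below 2^53 so doubles are exact.
    s <- (s * 69069 + (abs(k) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(s)
}

#' DGP parameter set
#'
#' Constructs and validates the full parameter set of the data-generating
#' process. Defaults are the package's calibrated base case: intervention
#' effect `tau = 2` on a series with no underlying trend, a post-period common
#' confounder `beta2 = 1`, group levels `mu_treat = 1 > mu_ctrl = 0.5` so the
#' intervention series sits above the control, and homoscedastic error SD
#' `sigma_base = 0.1`. The trend-divergence magnitude `delta` is calibrated so
#' the pre-trend test rejects in about 80% of homoscedastic unparallel
#' replicates at 24 time points (see [calibrate_delta()]).
#'
#' @param tau intervention (level-change) effect.
#' @param beta1 coefficient of the observed covariate X.
#' @param beta2 post-period common confounder effect (enters both groups).
#' @param mu_treat,mu_ctrl group-specific unobserved confounder levels.
#' @param sigma_base baseline error SD under homoscedasticity (>= 0; zero
#'   yields noiseless panels, useful for exact oracle tests).
#' @param rho AR(1) error coefficient in \[0, 1); used only under the
#'   autocorrelated error regime.
#' @param delta trend-divergence magnitude per time step under the linearly
#'   unparallel regime.
#' @param irregular_amplitude peak deviation of the irregular control-series
#'   trend profile (see [make_lambda()]); the default 4 makes the control's
#'   unobservable component wander by about twice the intervention effect in
#'   outcome units.
#' @param x_mean,x_sd distribution of the observed covariate
#'   \eqn{X_{it} \sim N(x_mean, x_sd^2)}, drawn independently per group/time.
#' @param n_points total number of time points (even, >= 4).
#' @return An object of class `dgp_params` (a named list).
#' @examples
#' p <- dgp_params(n_points = 24)
#' p$intervention_index  # 13: first post-intervention time point
#' @export
dgp_params <- function(tau = 2, beta1 = 0.5, beta2 = 1,
                       mu_treat = 1, mu_ctrl = 0.5,
                       sigma_base = 0.1, rho = 0.7,
                       delta = 0.0775, irregular_amplitude = 4,
                       x_mean = 1, x_sd = 0.05,
                       n_points = 312) {
  stopifnot(is.numeric(n_points), length(n_points) == 1L)
  n_points <- as.integer(n_points)
  if (n_points < 4L || n_points %% 2L != 0L)
    stop("n_points must be an even integer >= 4", call. = FALSE)
  if (!is.numeric(sigma_base) || sigma_base < 0)
    stop("sigma_base must be >= 0", call. = FALSE)
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(delta) || delta < 0)
    stop("delta must be >= 0", call. = FALSE)
  if (!is.numeric(irregular_amplitude) || irregular_amplitude < 0)
    stop("irregular_amplitude must be >= 0", call. = FALSE)
  if (!is.numeric(x_sd) || x_sd < 0)
    stop("x_sd must be >= 0", call. = FALSE)
  p <- list(tau = tau, beta1 = beta1, beta2 = beta2,
            mu_treat = mu_treat, mu_ctrl = mu_ctrl,
            sigma_base = sigma_base, rho = rho, delta = delta,
            irregular_amplitude = irregular_amplitude,
            x_mean = x_mean, x_sd = x_sd,
            n_points = n_points,
            intervention_index = n_points %/% 2L + 1L)
  class(p) <- "dgp_params"
  p
}

#' @export
print.dgp_params <- function(x, ...) {
  cat("DGP parameters (level-change CITS panel)\n")
  cat(sprintf("  tau = %g, beta1 = %g, beta2 = %g\n", x$tau, x$beta1, x$beta2))
  cat(sprintf("  mu_treat = %g, mu_ctrl = %g\n", x$mu_treat, x$mu_ctrl))
  cat(sprintf("  sigma_base = %g, rho = %g, delta = %g\n",
              x$sigma_base, x$rho, x$delta))
  cat(sprintf("  X ~ N(%g, %g^2); n_points = %d, intervention at t = %d\n",
              x$x_mean, x$x_sd, x$n_points, x$intervention_index))
  invisible(x)
}

.variance_regimes <- c("homoscedastic", "hetero_treat_high", "hetero_ctrl_high")
.trend_regimes <- c("parallel", "unparallel_linear", "unparallel_irregular")
.error_regimes <- c("iid", "ar1")

#' Scenario specification
#'
#' One cell of the scenario space: an error-variance regime, a trend regime
#' and an error-dependence regime. The main factorial grid crosses the three
#' variance regimes with \{parallel, unparallel_linear\} and \{iid, ar1\}
#' (12 combinations); `unparallel_irregular` is a sensitivity regime in which
#' a sign-alternating piecewise-linear trend perturbs the control series only.
#'
#' @param variance_regime one of `"homoscedastic"`, `"hetero_treat_high"`,
#'   `"hetero_ctrl_high"`.
#' @param trend_regime one of `"parallel"`, `"unparallel_linear"`,
#'   `"unparallel_irregular"`.
#' @param error_regime one of `"iid"`, `"ar1"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(variance_regime = "homoscedastic",
                          trend_regime = "parallel",
                          error_regime = "iid") {
  s <- list(variance_regime = match.arg(variance_regime, .variance_regimes),
            trend_regime = match.arg(trend_regime, .trend_regimes),
            error_regime = match.arg(error_regime, .error_regimes))
  class(s) <- "scenario_spec"
  s
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario: %s / %s / %s\n",
              x$variance_regime, x$trend_regime, x$error_regime))
  invisible(x)
}

#' Short scenario identifier, e.g. "homoscedastic.parallel.iid"
#' @param scenario a [scenario_spec()].
#' @return A single string.
#' @export
scenario_id <- function(scenario) {
  paste(scenario$variance_regime, scenario$trend_regime,
        scenario$error_regime, sep = ".")
}

#' The 12-cell main scenario grid
#'
#' @return A list of [scenario_spec()] objects: 3 variance regimes x
#'   \{parallel, unparallel_linear\} x \{iid, ar1\}.
#' @export
default_scenarios <- function() {
  out <- list()
  for (v in .variance_regimes)
    for (tr in c("parallel", "unparallel_linear"))
      for (e in .error_regimes)
        out[[length(out) + 1L]] <- scenario_spec(v, tr, e)
  out
}

#' Time profile of the unobserved group effect
#'
#' Builds the sequence \eqn{\lambda_1..\lambda_n} multiplying the unobserved
#' group level \eqn{\mu_i}. Parallel trends: constant 1. Linear divergence:
#' \eqn{\lambda_t = 1 + \delta (t - 1)}, a per-step slope, so the total
#' divergence grows with the series length (and with it the power to detect
#' the violation). Irregular divergence: a fixed *shape* in rescaled time
#' \eqn{u = t/n} — piecewise linear, rising and falling between `amplitude`
#' and `-amplitude` with direction changes at irregularly spaced fractions
#' of the series (defaults 20/45/85%) — so the violation has the same
#' magnitude at every series length; in [simulate_panel()] this profile
#' perturbs the control series only.
#'
#' @param trend_regime one of the trend regimes of [scenario_spec()].
#' @param n_points number of time points (>= 4).
#' @param delta divergence magnitude per time step (>= 0; linear regime).
#' @param change_fractions fractions of the series at which the irregular
#'   profile changes direction (strictly increasing, in (0, 1)).
#' @param amplitude peak deviation of the irregular profile from its
#'   baseline of 1 (irregular regime).
#' @return Numeric vector of length `n_points`.
#' @examples
#' make_lambda("unparallel_linear", 4, 0.01)  # 1.00 1.01 1.02 1.03
#' @export
make_lambda <- function(trend_regime, n_points, delta = 0,
                        change_fractions = c(0.2, 0.45, 0.85),
                        amplitude = 4) {
  trend_regime <- match.arg(trend_regime, .trend_regimes)
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 4)
    stop("n_points must be a single number >= 4", call. = FALSE)
  n_points <- as.integer(n_points)
  if (!is.numeric(delta) || delta < 0)
    stop("delta must be >= 0", call. = FALSE)
  t <- seq_len(n_points)
  switch(trend_regime,
    parallel = rep(1, n_points),
    unparallel_linear = 1 + delta * (t - 1),
    unparallel_irregular = {
      if (any(diff(change_fractions) <= 0) || any(change_fractions <= 0) ||
          any(change_fractions >= 1))
        stop("change_fractions must be strictly increasing within (0, 1)",
             call. = FALSE)
      if (!is.numeric(amplitude) || amplitude < 0)
        stop("amplitude must be >= 0", call. = FALSE)
      # smooth prototype: natural cubic through nodes alternating between
      # +1 and -1 at the change fractions
      s_nodes <- (-1)^(seq_along(change_fractions) + 1L)
      proto <- stats::splinefun(c(0, change_fractions, 1),
                                c(0, s_nodes, utils::tail(s_nodes, 1) / 4),
                                method = "natural")
      target <- proto(t / n_points)
      # represent the curve inside the smooth time basis the estimators use
      # (k = 5 restricted cubic spline span), so the regime probes whether a
      # design can deploy that flexibility group-specifically rather than
      # the basis' ability to approximate an arbitrary function
      B <- cbind(1, rcs_basis(t, harrell_knots(t, 5L)))
      smooth <- as.numeric(B %*% qr.coef(qr(B), target))
      1 + amplitude * smooth
    })
}

#' Error standard deviation profile
#'
#' Under homoscedasticity every observation has SD `sigma_base`. Under the
#' heteroscedastic regimes the SD of the high-variance group is half the
#' absolute systematic mean level \eqn{|m_{it}|/2}, and the low-variance
#' group's SD is half of that again, so SDs grow with the level of the series
#' and the high-variance group's SD is twice the low-variance group's at
#' matched levels. SDs are floored at `floor_sd` to avoid degenerate
#' zero-variance draws.
#'
#' @param mean_level numeric vector of systematic mean levels
#'   \eqn{m_{it} = X\beta_1 + Post\beta_2 + \tau D Post + \lambda_t \mu_i}.
#' @param variance_regime one of the variance regimes of [scenario_spec()].
#' @param group `"treat"` or `"ctrl"`.
#' @param sigma_base homoscedastic SD.
#' @param floor_sd lower bound on the returned SD.
#' @return Numeric vector of SDs, same length as `mean_level`.
#' @export
sigma_profile <- function(mean_level, variance_regime, group,
                          sigma_base = 0.1, floor_sd = 1e-6) {
  variance_regime <- match.arg(variance_regime, .variance_regimes)
  group <- match.arg(group, c("treat", "ctrl"))
  stopifnot(all(is.finite(mean_level)))
  if (variance_regime == "homoscedastic")
    return(rep(sigma_base, length(mean_level)))
  high <- switch(variance_regime,
                 hetero_treat_high = "treat",
                 hetero_ctrl_high = "ctrl")
  sd <- abs(mean_level) / 2
  if (group != high) sd <- 0.5 * sd
  pmax(sd, floor_sd)
}

#' Gaussian error series, independent or AR(1)
#'
#' Independent regime: \eqn{\varepsilon_t \sim N(0, sd_t^2)}. AR(1) regime:
#' \eqn{\varepsilon_t = \rho\varepsilon_{t-1} + N(0, sd_t^2)}, with the first
#' error drawn from the stationary distribution
#' \eqn{N(0, sd_1^2 / (1 - \rho^2))} so there is no warm-up bias. With a
#' constant innovation SD \eqn{\sigma}, the stationary SD of the series is
#' \eqn{\sigma/\sqrt{1-\rho^2}}.
#'
#' @param n_points series length.
#' @param error_regime `"iid"` or `"ar1"`.
#' @param sd_sequence positive innovation SDs, length `n_points` (or scalar,
#'   recycled).
#' @param rho AR(1) coefficient, |rho| < 1.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return Numeric vector of length `n_points`.
#' @export
make_errors <- function(n_points, error_regime, sd_sequence, rho = 0,
                        seed = NULL) {
  error_regime <- match.arg(error_regime, .error_regimes)
  n_points <- as.integer(n_points)
  sd_sequence <- rep_len(sd_sequence, n_points)
  stopifnot(all(sd_sequence >= 0))
  if (abs(rho) >= 1)
    stop("|rho| must be < 1 for a stationary AR(1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (error_regime == "iid")
    return(stats::rnorm(n_points, 0, sd_sequence))
  e <- numeric(n_points)
  e[1] <- stats::rnorm(1, 0, sd_sequence[1] / sqrt(1 - rho^2))
  innov <- stats::rnorm(n_points - 1L, 0, sd_sequence[-1L])
  for (t in 2:n_points) e[t] <- rho * e[t - 1L] + innov[t - 1L]
  e
}

#' Simulate a two-group interrupted-time-series panel
#'
#' Assembles the outcome for both groups on a common 1-based time grid with
#' the intervention starting at `params$intervention_index` (the midpoint).
#' The post-period confounder `beta2` enters both groups; `tau` enters only
#' treated post-period observations. Under `unparallel_irregular` the
#' irregular lambda profile applies to the control series only (the treated
#' series keeps a flat profile).
#'
#' @param params a [dgp_params()] object.
#' @param scenario a [scenario_spec()] object.
#' @param seed integer replicate seed; per-group sub-streams are derived
#'   deterministically from it, so the same seed reproduces the panel exactly.
#' @return A `cits_panel`: a long-format data.frame with one row per
#'   (group, time) and columns `group` ("treat"/"ctrl"), `time`, `post`,
#'   `d` (treatment dummy), `x`, `lambda`, `y`. Attributes `true_tau`,
#'   `params`, `scenario` record the generating configuration.
#' @examples
#' pan <- simulate_panel(dgp_params(n_points = 24), scenario_spec(), seed = 1)
#' head(pan)
#' @export
simulate_panel <- function(params, scenario, seed) {
  stopifnot(inherits(params, "dgp_params"), inherits(scenario, "scenario_spec"))
  n <- params$n_points
  t <- seq_len(n)
  post <- as.integer(t >= params$intervention_index)
  lam_common <- switch(scenario$trend_regime,
    parallel = make_lambda("parallel", n),
    unparallel_linear = make_lambda("unparallel_linear", n, params$delta),
    unparallel_irregular = make_lambda("parallel", n))
  rows <- lapply(c("treat", "ctrl"), function(g) {
    d <- as.integer(g == "treat")
    lam <- lam_common
    if (scenario$trend_regime == "unparallel_irregular" && g == "ctrl")
      lam <- make_lambda("unparallel_irregular", n,
                         amplitude = params$irregular_amplitude)
    mu <- if (g == "treat") params$mu_treat else params$mu_ctrl
    set.seed(derive_seed(seed, match(g, c("treat", "ctrl"))))
    x <- stats::rnorm(n, params$x_mean, params$x_sd)
    m <- x * params$beta1 + post * params$beta2 +
      params$tau * d * post + lam * mu
    sd_seq <- sigma_profile(m, scenario$variance_regime, g,
                            sigma_base = params$sigma_base)
    rho <- if (scenario$error_regime == "ar1") params$rho else 0
    eps <- make_errors(n, scenario$error_regime, sd_seq, rho)
    data.frame(group = g, time = t, post = post, d = d,
               x = x, lambda = lam, y = m + eps)
  })
  panel <- do.call(rbind, rows)
  panel$group <- factor(panel$group, levels = c("treat", "ctrl"))
  rownames(panel) <- NULL
  attr(panel, "true_tau") <- params$tau
  attr(panel, "params") <- params
  attr(panel, "scenario") <- scenario
  class(panel) <- c("cits_panel", "data.frame")
  panel
}

#' Write / read a panel as long-format CSV
#'
#' The on-disk schema is the six typed columns
#' `group,time,post,treated,x,y` with a header row (RFC-4180); `time` is
#' 1-based.
#'
#' @param panel a `cits_panel` (or any data.frame with the panel columns).
#' @param path file path.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   returns a `cits_panel` data.frame.
#' @export
write_panel_csv <- function(panel, path) {
  out <- data.frame(group = as.character(panel$group), time = panel$time,
                    post = panel$post, treated = panel$d,
                    x = panel$x, y = panel$y)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "time", "post", "treated", "x", "y")
  if (!all(need %in% names(df)))
    stop("panel CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  panel <- data.frame(group = factor(df$group, levels = c("treat", "ctrl")),
                      time = as.integer(df$time), post = as.integer(df$post),
                      d = as.integer(df$treated), x = df$x, lambda = NA_real_,
                      y = df$y)
  class(panel) <- c("cits_panel", "data.frame")
  panel
}
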