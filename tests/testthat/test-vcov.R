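test_that("white_vcov equals the brute-force sandwich oracle", {
  set.seed(2)
  X <- cbind(1, rnorm(5), runif(5))
  y <- rnorm(5)
  beta <- qr.coef(qr(X), y)
  e <- as.numeric(y - X %*% beta)
  expect_equal(white_vcov(X, e)$vcov, white_oracle(X, e),
               ignore_attr = TRUE)
  expect_equal(white_vcov(X, rep(0, 5))$vcov, matrix(0, 3, 3),
               ignore_attr = TRUE)
  expect_error(white_vcov(cbind(1, 1:5, 2 * (1:5)), rnorm(5)),
               "rank deficient")
})

test_that("White correction leaves coefficients unchanged", {
  pan <- simulate_panel(dgp_params(n_points = 48),
                        scenario_spec("hetero_treat_high"), seed = 3)
  f_cl <- fit_model(model_spec("DID", "linear", se_method = "classical"), pan)
  f_wh <- fit_model(model_spec("DID", "linear", se_method = "white"), pan)
  expect_equal(f_wh$tau_hat, f_cl$tau_hat)
  expect_false(isTRUE(all.equal(f_wh$se_tau, f_cl$se_tau)))
})

test_that("driscoll_kraay_vcov matches oracles and degenerates to White", {
  set.seed(5)
  # 3-period, 2-group toy
  X <- cbind(1, rnorm(6))
  e <- rnorm(6)
  g <- rep(1:2, each = 3); tt <- rep(1:3, 2)
  for (lag in 0:2)
    expect_equal(driscoll_kraay_vcov(X, e, g, tt, lag = lag)$vcov,
                 dk_oracle(X, e, g, tt, lag), ignore_attr = TRUE)

  # lag 0, single group: exactly the White sandwich
  X1 <- cbind(1, rnorm(9)); e1 <- rnorm(9)
  expect_equal(driscoll_kraay_vcov(X1, e1, rep(1, 9), 1:9, lag = 0)$vcov,
               white_vcov(X1, e1)$vcov, ignore_attr = TRUE)

  expect_error(driscoll_kraay_vcov(X1, e1, rep(1, 9), 1:9, lag = 9), "lag")
  expect_equal(dk_default_lag(100), 4L)
})

test_that("all covariance estimates are symmetric PSD", {
  pan <- simulate_panel(dgp_params(n_points = 48),
                        scenario_spec(error_regime = "ar1"), seed = 6)
  des <- build_design(model_spec("CITS", "linear"), pan)
  beta <- qr.coef(qr(des$X), des$y)
  e <- as.numeric(des$y - des$X %*% beta)
  for (v in list(white_vcov(des$X, e)$vcov,
                 driscoll_kraay_vcov(des$X, e, des$group, des$time)$vcov)) {
    expect_equal(v, t(v))
    expect_gte(min(eigen(v, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("DK standard errors exceed classical ones under autocorrelation", {
  p <- dgp_params(n_points = 88)
  scen <- scenario_spec(error_regime = "ar1")
  se_cl <- se_dk <- numeric(100)
  for (r in 1:100) {
    pan <- simulate_panel(p, scen, seed = derive_seed(7, r))
    se_cl[r] <- fit_model(model_spec("DID", "linear"), pan)$se_tau
    se_dk[r] <- fit_model(model_spec("DID", "linear",
                                     se_method = "driscoll_kraay"),
                          pan)$se_tau
  }
  expect_gt(mean(se_dk), mean(se_cl))
})

test_that("panel FGLS reduces to OLS under spherical errors and recovers rho", {
  p <- dgp_params(n_points = 312)
  pan <- simulate_panel(p, scenario_spec(), seed = 8)
  des <- build_design(model_spec("CITS", "linear"), pan)
  ols <- qr.coef(qr(des$X), des$y)
  fg <- panel_fgls(des$X, des$y, des$group, des$time)
  expect_true(fg$converged)
  expect_equal(unname(fg$coefficients), unname(ols), tolerance = 0.02)

  # AR(1) coefficient recovery, averaged over replicates
  rho_hat <- vapply(1:20, function(r) {
    pan <- simulate_panel(p, scenario_spec(error_regime = "ar1"),
                          seed = derive_seed(9, r))
    des <- build_design(model_spec("CITS", "linear"), pan)
    panel_fgls(des$X, des$y, des$group, des$time)$rho_hat
  }, numeric(1))
  expect_equal(mean(rho_hat), 0.7, tolerance = 0.05)
})

test_that("FGLS is no less efficient than OLS under panel heteroscedasticity", {
  p <- dgp_params(n_points = 88)
  scen <- scenario_spec("hetero_treat_high")
  tau_ols <- tau_fgls <- numeric(200)
  for (r in 1:200) {
    pan <- simulate_panel(p, scen, seed = derive_seed(11, r))
    tau_ols[r] <- fit_model(model_spec("DID", "linear"), pan)$tau_hat
    tau_fgls[r] <- fit_model(model_spec("DID", "linear",
                                        se_method = "fgls"), pan)$tau_hat
  }
  expect_lte(sd(tau_fgls, na.rm = TRUE), sd(tau_ols) * 1.05)
})

test_that("AR(1)-ML regression recovers white-noise and AR limits", {
  p <- dgp_params(n_points = 312)
  pan <- simulate_panel(p, scenario_spec(), seed = 12)
  f_arma <- fit_model(model_spec("UNCONTROLLED", "linear",
                                 se_method = "arma"), pan)
  f_ols <- fit_model(model_spec("UNCONTROLLED", "linear"), pan)
  expect_true(f_arma$converged)
  expect_equal(f_arma$aux$rho_hat, 0, tolerance = 0.12)
  expect_equal(f_arma$tau_hat, f_ols$tau_hat, tolerance = 0.02)

  # rho recovery vs a Yule-Walker oracle on the true errors
  rho_hat <- yw <- numeric(20)
  for (r in 1:20) {
    seed <- derive_seed(13, r)
    pan <- simulate_panel(p, scenario_spec(error_regime = "ar1"),
                          seed = seed)
    f <- fit_model(model_spec("UNCONTROLLED", "linear",
                              se_method = "arma"), pan)
    rho_hat[r] <- f$aux$rho_hat
    tr <- pan[pan$d == 1, ]
    m <- tr$x * p$beta1 + tr$post * p$beta2 + p$tau * tr$post +
      tr$lambda * p$mu_treat
    e <- tr$y - m
    yw[r] <- sum(e[-1] * e[-length(e)]) / sum(e^2)
  }
  expect_equal(mean(rho_hat), mean(yw), tolerance = 0.05)
})

test_that("AR(1)-ML CIs cover under strong autocorrelation", {
  p <- dgp_params(n_points = 312)
  scen <- scenario_spec(error_regime = "ar1")
  hits <- vapply(1:300, function(r) {
    pan <- simulate_panel(p, scen, seed = derive_seed(15, r))
    f <- fit_model(model_spec("UNCONTROLLED", "linear",
                              se_method = "arma"), pan)
    # uncontrolled tau estimates tau + beta2 = 3 by construction
    f$converged && f$ci_low <= 3 && 3 <= f$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.98)
})
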