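test_that("difference_series subtracts control from intervention", {
  mk <- function(y_tr, y_ct) {
    n <- length(y_tr)
    structure(data.frame(
      group = factor(rep(c("treat", "ctrl"), each = n),
                     levels = c("treat", "ctrl")),
      time = rep(seq_len(n), 2), post = rep(0L, 2 * n),
      d = rep(c(1L, 0L), each = n), x = 0, lambda = 1,
      y = c(y_tr, y_ct)), class = c("cits_panel", "data.frame"))
  }
  expect_equal(difference_series(mk(c(3, 5), c(1, 2)))$diff_y, c(2, 3))
  expect_equal(difference_series(mk(c(4, 4), c(4, 4)))$diff_y, c(0, 0))

  # noiseless parallel panel: Diff_t = (mu_t - mu_c) + beta1 diffX + tau post
  p <- dgp_params(sigma_base = 0, n_points = 24)  # x still random
  pan <- simulate_panel(p, scenario_spec(), seed = 5)
  ds <- difference_series(pan)
  expect_equal(ds$diff_y,
               (p$mu_treat - p$mu_ctrl) + p$beta1 * ds$diff_x +
                 p$tau * ds$post)

  # unbalanced panel is a structural error
  bad <- pan[-1, ]
  class(bad) <- class(pan)
  expect_error(difference_series(bad), "unbalanced")
})

test_that("build_design produces exactly the documented regressor sets", {
  pan <- simulate_panel(dgp_params(n_points = 24), scenario_spec(), seed = 1)

  d1 <- build_design(model_spec("DID", "none"), pan)
  expect_setequal(colnames(d1$X),
                  c("(Intercept)", "d", "x", "post", "d_post"))
  expect_equal(d1$tau_col, "d_post")

  d2 <- build_design(model_spec("DIFF", "none"), pan)
  expect_setequal(colnames(d2$X), c("(Intercept)", "post"))
  expect_equal(d2$tau_col, "post")

  d3 <- build_design(model_spec("CITS", "spline", spline_k = 3), pan)
  expect_true(all(c("d_time", "t", "rcs1") %in% colnames(d3$X)))
  expect_equal(ncol(d3$X), 8)  # 1, d, x, post, d_post, t, rcs1, d_time

  d4 <- build_design(model_spec("OLS_C", "linear"), pan)
  expect_setequal(colnames(d4$X),
                  c("(Intercept)", "control", "x", "post", "time"))

  d5 <- build_design(model_spec("DIFF", "linear", diff_covariate = TRUE), pan)
  expect_setequal(colnames(d5$X),
                  c("(Intercept)", "post", "diff_x", "time"))
})

test_that("model_spec enforces design/SE compatibility", {
  expect_error(model_spec("DIFF", se_method = "fgls"), "panel")
  expect_error(model_spec("UNCONTROLLED", se_method = "driscoll_kraay"),
               "panel")
  expect_error(model_spec("CITS", se_method = "arma"), "single-series")
  expect_error(model_spec("DID", diff_covariate = TRUE), "DIFF")
  expect_equal(length(model_catalog()), 21L)
  expect_true(all(c("DiD FE", "CITS FE T", "Diff X splnT", "OLS C T",
                    "OLS splnT") %in% names(model_catalog())))
})

test_that("fit recovers exact oracle values on noiseless panels", {
  pan <- simulate_panel(noiseless_params(24), scenario_spec(), seed = 3)

  # DiD equals the 2x2 difference of period-by-group means
  f <- fit_model(model_spec("DID", "none"), pan)
  expect_equal(f$tau_hat, did_of_means(pan))
  expect_equal(f$tau_hat, 2)

  # DIFF with Post only is the post-pre mean difference (also on noisy data)
  noisy <- simulate_panel(dgp_params(n_points = 48), scenario_spec(),
                          seed = 4)
  ds <- difference_series(noisy)
  f2 <- fit_model(model_spec("DIFF", "none"), noisy)
  expect_equal(f2$tau_hat,
               mean(ds$diff_y[ds$post == 1]) - mean(ds$diff_y[ds$post == 0]))

  # uncontrolled ITS estimates tau + beta2 by construction
  f3 <- fit_model(model_spec("UNCONTROLLED", "none"), pan)
  expect_equal(f3$tau_hat, 3)
})

test_that("panel fixed effect equals the within-transformation oracle", {
  pan <- simulate_panel(dgp_params(n_points = 48), scenario_spec(), seed = 6)
  f <- fit_model(model_spec("CITS", "linear"), pan)
  expect_equal(f$tau_hat, within_tau_oracle(pan), tolerance = 1e-9)
})

test_that("adding the group-time interaction changes nothing under parallel noiseless trends", {
  pan <- simulate_panel(noiseless_params(24), scenario_spec(), seed = 8)
  f_did <- fit_model(model_spec("DID", "linear"), pan)
  f_cits <- fit_model(model_spec("CITS", "linear"), pan)
  expect_equal(f_cits$tau_hat, f_did$tau_hat, tolerance = 1e-8)
  expect_equal(unname(f_cits$aux$coefficients["d_time"]), 0,
               tolerance = 1e-8)
})

test_that("tau_hat is equivariant under outcome shifts", {
  pan <- simulate_panel(dgp_params(n_points = 48), scenario_spec(), seed = 10)
  shift_all <- pan; shift_all$y <- shift_all$y + 5
  shift_tp <- pan
  idx <- shift_tp$d == 1 & shift_tp$post == 1
  shift_tp$y[idx] <- shift_tp$y[idx] + 5
  for (lab in c("DiD FE", "CITS FE T", "Diff T", "OLS T", "OLS C T")) {
    sp <- model_catalog()[[lab]]
    base <- fit_model(sp, pan)$tau_hat
    expect_equal(fit_model(sp, shift_all)$tau_hat, base, tolerance = 1e-8,
                 label = paste(lab, "constant shift"))
    expect_equal(fit_model(sp, shift_tp)$tau_hat, base + 5,
                 tolerance = 1e-8, label = paste(lab, "treated-post shift"))
  }
})

test_that("two single ITS subtract the common confounder away", {
  pan <- simulate_panel(noiseless_params(24), scenario_spec(), seed = 12)
  f <- fit_two_single_its(pan)
  expect_equal(f$tau_hat, 2)

  # identical groups, tau = 0 -> exactly 0
  p0 <- noiseless_params(24, tau = 0, mu_treat = 0.5)
  f0 <- fit_two_single_its(simulate_panel(p0, scenario_spec(), seed = 13))
  expect_equal(f0$tau_hat, 0)

  # replicate mean close to tau on noisy baseline panels
  p <- dgp_params(n_points = 312)
  est <- vapply(1:30, function(r)
    fit_two_single_its(simulate_panel(p, scenario_spec(), seed = r),
                       "linear")$tau_hat, numeric(1))
  expect_equal(mean(est), 2, tolerance = 0.05)
})

test_that("correctly specified CIs attain nominal coverage", {
  p <- dgp_params(n_points = 48)
  hits <- vapply(1:300, function(r) {
    pan <- simulate_panel(p, scenario_spec(), seed = derive_seed(99, r))
    f <- fit_model(model_spec("DID", "none"), pan)
    f$ci_low <= 2 && 2 <= f$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("rank-deficient designs are flagged, not fatal", {
  pan <- simulate_panel(dgp_params(n_points = 24), scenario_spec(), seed = 1)
  pan$x <- pan$time  # x collinear with the trend
  f <- fit_model(model_spec("DID", "linear"), pan)
  expect_false(f$converged)
  expect_true(is.na(f$tau_hat))
})
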