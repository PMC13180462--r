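test_that("lambda profiles match their closed forms", {
  expect_equal(make_lambda("parallel", 6), rep(1, 6))
  expect_equal(make_lambda("unparallel_linear", 4, 0), rep(1, 4))
  expect_equal(make_lambda("unparallel_linear", 4, 0.01),
               c(1, 1.01, 1.02, 1.03))
  lam <- make_lambda("unparallel_linear", 50, 0.05)
  expect_true(all(diff(lam) > 0))  # strictly monotone

  irr <- make_lambda("unparallel_irregular", 312, amplitude = 2)
  expect_length(irr, 312)
  expect_true(any(diff(irr) > 0) && any(diff(irr) < 0))
  # the amplitude parameter scales the profile linearly
  irr1 <- make_lambda("unparallel_irregular", 312, amplitude = 1)
  expect_equal(irr - 1, 2 * (irr1 - 1))
  expect_gt(max(abs(irr - 1)), 1.5)

  expect_error(make_lambda("parallel", 2), "n_points")
  expect_error(make_lambda("unparallel_linear", 10, -0.1), "delta")
  expect_error(make_lambda("unparallel_irregular", 10,
                           change_fractions = c(0.5, 0.2)),
               "change_fractions")
})

test_that("sigma_profile implements the level-dependent SD rules", {
  expect_equal(sigma_profile(c(-3, 0, 7), "homoscedastic", "treat"),
               rep(0.1, 3))
  expect_equal(sigma_profile(4, "hetero_treat_high", "treat"), 2)
  expect_equal(sigma_profile(4, "hetero_treat_high", "ctrl"), 1)
  expect_equal(sigma_profile(4, "hetero_ctrl_high", "ctrl"), 2)
  expect_equal(sigma_profile(-4, "hetero_treat_high", "treat"), 2)
  # degenerate-level guard: floored, never zero
  expect_gt(sigma_profile(0, "hetero_treat_high", "treat"), 0)
  expect_error(sigma_profile(Inf, "homoscedastic", "treat"))
})

test_that("error generator matches its stated moments", {
  expect_error(make_errors(10, "ar1", 0.1, rho = 1), "stationary")

  e0 <- make_errors(10000, "iid", 0.1, seed = 11)
  expect_lt(abs(cor(e0[-1], e0[-10000])), 0.05)
  expect_equal(sd(e0), 0.1, tolerance = 0.03)

  e1 <- make_errors(10000, "ar1", 0.1, rho = 0.7, seed = 11)
  expect_equal(cor(e1[-1], e1[-10000]), 0.7, tolerance = 0.03)
  # stationary SD: sigma / sqrt(1 - rho^2)
  expect_equal(sd(e1), 0.1 / sqrt(1 - 0.49), tolerance = 0.03)

  expect_identical(make_errors(50, "ar1", 0.1, 0.7, seed = 3),
                   make_errors(50, "ar1", 0.1, 0.7, seed = 3))
})

test_that("AR(1) stationary initialisation is indistinguishable from burn-in", {
  # burn-in oracle: run the recursion 100 steps before keeping draws
  burnin_sd <- function(seed) {
    set.seed(seed)
    e <- 0
    for (t in 1:100) e <- 0.7 * e + rnorm(1, 0, 0.1)
    out <- numeric(5000)
    for (t in 1:5000) { e <- 0.7 * e + rnorm(1, 0, 0.1); out[t] <- e }
    sd(out)
  }
  expect_equal(sd(make_errors(5000, "ar1", 0.1, 0.7, seed = 21)),
               burnin_sd(22), tolerance = 0.05)
})

test_that("simulate_panel assembles the outcome model exactly", {
  # noiseless identity: Y = beta2 Post + tau D Post + mu_i (x degenerate 0)
  p <- dgp_params(sigma_base = 0, x_sd = 0, x_mean = 0, n_points = 24)
  pan <- simulate_panel(p, scenario_spec(), seed = 1)
  expect_equal(pan$y,
               p$beta2 * pan$post + p$tau * pan$d * pan$post +
                 ifelse(pan$d == 1, p$mu_treat, p$mu_ctrl))

  # structure invariants
  expect_equal(nrow(pan), 48)
  expect_true(all(pan$post[pan$time < p$intervention_index] == 0))
  expect_true(all(pan$post[pan$time >= p$intervention_index] == 1))
  expect_true(all(pan$d[pan$group == "ctrl"] == 0))
  expect_false(anyNA(pan))

  # determinism: same seed byte-identical, different seed differs in y only
  # through the stochastic components
  p2 <- dgp_params(n_points = 48)
  a <- simulate_panel(p2, scenario_spec(), seed = 7)
  b <- simulate_panel(p2, scenario_spec(), seed = 7)
  expect_identical(a, b)
  c2 <- simulate_panel(p2, scenario_spec(), seed = 8)
  expect_false(identical(a$y, c2$y))
  expect_identical(a$post, c2$post)
  expect_identical(a$lambda, c2$lambda)
})

test_that("baseline panels carry the designed effect and confounding", {
  p <- dgp_params()  # n = 312
  pan <- simulate_panel(p, scenario_spec(), seed = 42)
  expect_equal(did_of_means(pan), 2, tolerance = 0.1)
  # uncontrolled pre/post contrast on the treated series confounds tau with
  # beta2
  tr <- pan[pan$d == 1, ]
  expect_equal(mean(tr$y[tr$post == 1]) - mean(tr$y[tr$post == 0]),
               p$tau + p$beta2, tolerance = 0.1)
})

test_that("trend regimes shape the between-series difference as designed", {
  p <- noiseless_params(n_points = 24)
  par_pan <- simulate_panel(p, scenario_spec(), seed = 1)
  d_par <- difference_series(par_pan)
  expect_equal(diff(d_par$diff_y[d_par$post == 0]), rep(0, 11))
  expect_equal(diff(d_par$diff_y[d_par$post == 1]), rep(0, 11))
  expect_equal(d_par$diff_y[13] - d_par$diff_y[12], p$tau)

  un_pan <- simulate_panel(p, scenario_spec(trend_regime =
                                              "unparallel_linear"), seed = 1)
  d_un <- difference_series(un_pan)
  pre <- d_un$diff_y[d_un$post == 0]
  slopes <- diff(pre)
  expect_equal(slopes, rep(p$delta * (p$mu_treat - p$mu_ctrl), 11))

  # irregular regime perturbs the control series only
  irr_pan <- simulate_panel(p, scenario_spec(trend_regime =
                                               "unparallel_irregular"),
                            seed = 1)
  expect_equal(irr_pan$lambda[irr_pan$d == 1], rep(1, 24))
  expect_false(all(irr_pan$lambda[irr_pan$d == 0] == 1))
})

test_that("heteroscedastic groups have a 2:1 error-SD ratio at matched levels", {
  p <- dgp_params(x_sd = 0, n_points = 24)
  scen <- scenario_spec("hetero_treat_high")
  resid_tr <- resid_ct <- NULL
  for (r in 1:200) {
    pan <- simulate_panel(p, scen, seed = r)
    m <- p$x_mean * p$beta1 + pan$post * p$beta2 + p$tau * pan$d * pan$post +
      pan$lambda * ifelse(pan$d == 1, p$mu_treat, p$mu_ctrl)
    e <- pan$y - m
    # compare at matched systematic levels: pre-intervention only
    resid_tr <- c(resid_tr, e[pan$d == 1 & pan$post == 0])
    resid_ct <- c(resid_ct, e[pan$d == 0 & pan$post == 0])
  }
  # SDs scale with |level|/2 in the high group and half that in the low;
  # pre-period levels are 1.5 (treat) and 1.0 (ctrl)
  expect_equal(sd(resid_tr), 1.5 / 2, tolerance = 0.05)
  expect_equal(sd(resid_ct), 0.5 * 1.0 / 2, tolerance = 0.05)
})

test_that("panel CSV round-trips", {
  pan <- simulate_panel(dgp_params(n_points = 8), scenario_spec(), seed = 2)
  f <- tempfile(fileext = ".csv")
  write_panel_csv(pan, f)
  back <- read_panel_csv(f)
  expect_equal(back$y, pan$y)
  expect_equal(back$x, pan$x)
  expect_equal(back$d, pan$d)
  expect_identical(levels(back$group), c("treat", "ctrl"))
  expect_error(read_panel_csv({
    f2 <- tempfile(); writeLines("a,b\n1,2", f2); f2
  }), "columns")
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(dgp_params(n_points = 7), "even")
  expect_error(dgp_params(n_points = 2), "even")
  expect_error(dgp_params(rho = 1), "rho")
  expect_error(dgp_params(sigma_base = -1), "sigma_base")
  expect_error(dgp_params(delta = -0.1), "delta")
  # intervention at the midpoint, 1-based
  expect_equal(dgp_params(n_points = 312)$intervention_index, 157)
  expect_equal(dgp_params(n_points = 24)$intervention_index, 13)
})
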