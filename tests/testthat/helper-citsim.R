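# shared fixtures and independent oracles

# noiseless parameter set: zero error SD and a degenerate covariate so the
# outcome equals the systematic mean exactly
noiseless_params <- function(n_points = 24, ...) {
  dgp_params(sigma_base = 0, x_sd = 0, n_points = n_points, ...)
}

# hand-rolled 2x2 difference-in-means oracle
did_of_means <- function(panel) {
  m <- function(d, post) mean(panel$y[panel$d == d & panel$post == post])
  (m(1, 1) - m(1, 0)) - (m(0, 1) - m(0, 0))
}

# brute-force restricted truncated-power evaluation (independent of
# rcs_basis): term-by-term formula for one nonlinear column
rcs_term_oracle <- function(x, knots, j) {
  k <- length(knots)
  p3 <- function(u) ifelse(u > 0, u^3, 0)
  (p3(x - knots[j]) -
     p3(x - knots[k - 1]) * (knots[k] - knots[j]) /
       (knots[k] - knots[k - 1]) +
     p3(x - knots[k]) * (knots[k - 1] - knots[j]) /
       (knots[k] - knots[k - 1])) / (knots[k] - knots[1])^2
}

# element-by-element sandwich oracle: loops over observations
white_oracle <- function(X, e) {
  n <- nrow(X); k <- ncol(X)
  meat <- matrix(0, k, k)
  for (i in seq_len(n))
    meat <- meat + e[i]^2 * tcrossprod(X[i, ])
  bread <- solve(t(X) %*% X)
  n / (n - k) * bread %*% meat %*% bread
}

# hand-summed Driscoll-Kraay oracle: explicit period sums and Bartlett
# weights, loop-based
dk_oracle <- function(X, e, group, time, lag) {
  n <- nrow(X); k <- ncol(X)
  times <- sort(unique(time))
  Tn <- length(times)
  ht <- matrix(0, Tn, k)
  for (s in seq_len(Tn))
    for (i in which(time == times[s]))
      ht[s, ] <- ht[s, ] + X[i, ] * e[i]
  S <- matrix(0, k, k)
  for (s in seq_len(Tn)) S <- S + tcrossprod(ht[s, ])
  if (lag > 0)
    for (j in seq_len(lag)) {
      w <- 1 - j / (lag + 1)
      Om <- matrix(0, k, k)
      for (s in (j + 1):Tn) Om <- Om + ht[s, ] %*% t(ht[s - j, ])
      S <- S + w * (Om + t(Om))
    }
  bread <- solve(t(X) %*% X)
  n / (n - k) * bread %*% S %*% bread
}

# within-transformation (group-demeaning) fixed-effect oracle
within_tau_oracle <- function(panel, tau_col_cols) {
  pan <- panel[order(panel$d == 0L, panel$time), ]
  y <- pan$y
  X <- cbind(x = pan$x, post = pan$post, d_post = pan$d * pan$post,
             time = pan$time, d_time = pan$d * pan$time)
  for (g in unique(pan$group)) {
    idx <- pan$group == g
    y[idx] <- y[idx] - mean(y[idx])
    X[idx, ] <- sweep(X[idx, , drop = FALSE], 2,
                      colMeans(X[idx, , drop = FALSE]))
  }
  unname(qr.coef(qr(X), y)["d_post"])
}
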