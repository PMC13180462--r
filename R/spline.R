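#' Harrell percentile knot placement
#'
#' Knot positions for a restricted cubic spline at the percentiles Harrell
#' recommends for k = 3..7 knots: 3 -> 10/50/90; 4 -> 5/35/65/95;
#' 5 -> 5/27.5/50/72.5/95; 6 -> 5/23/41/59/77/95;
#' 7 -> 2.5/18.33/34.17/50/65.83/81.67/97.5. Quantiles use R's default
#' (type 7) interpolation; percentile interpolation rules differ across
#' software, so the convention is fixed here and logged with every fit.
#'
#' @param time_values numeric vector of observed time values.
#' @param k number of knots, in 3..7.
#' @return Strictly increasing numeric vector of `k` knot positions.
#' @examples
#' harrell_knots(1:100, 3)
#' @export
harrell_knots <- function(time_values, k) {
  if (!k %in% 3:7) stop("k must be in 3..7", call. = FALSE)
  probs <- switch(as.character(k),
    "3" = c(.10, .50, .90),
    "4" = c(.05, .35, .65, .95),
    "5" = c(.05, .275, .50, .725, .95),
    "6" = c(.05, .23, .41, .59, .77, .95),
    "7" = c(.025, .1833, .3417, .50, .6583, .8167, .975))
  kn <- unname(stats::quantile(time_values, probs, type = 7))
  if (any(diff(kn) <= 0))
    stop("degenerate input: knots are not strictly increasing ",
         "(too few distinct time values)", call. = FALSE)
  kn
}

#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline basis with k knots: k - 1 columns,
#' the first being time itself and the remaining k - 2 cubic terms
#' constrained so the represented function is linear below the first and
#' above the last knot, with continuous first and second derivatives at every
#' knot. Terms are normalised by the squared boundary-knot span, the usual
#' scaling that keeps columns on comparable magnitude.
#'
#' For knots \eqn{t_1 < ... < t_k} column \eqn{j + 1} (j = 1..k-2) is
#' \deqn{\big[(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k - t_{k-1})
#'  + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})\big] / (t_k - t_1)^2.}
#'
#' @param time_values numeric vector at which to evaluate the basis (any
#'   reals; the basis is defined on the whole line).
#' @param knots strictly increasing numeric vector of >= 3 knots.
#' @return Numeric matrix with `length(time_values)` rows and
#'   `length(knots) - 1` columns, named `t`, `rcs1`, `rcs2`, ...
#' @export
rcs_basis <- function(time_values, knots) {
  k <- length(knots)
  if (k < 3 || any(diff(knots) <= 0))
    stop("knots must be >= 3 strictly increasing values", call. = FALSE)
  x <- as.numeric(time_values)
  pos3 <- function(u) pmax(u, 0)^3
  span2 <- (knots[k] - knots[1])^2
  out <- matrix(0, length(x), k - 1L,
                dimnames = list(NULL, c("t", if (k > 2)
                  paste0("rcs", seq_len(k - 2L)))))
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    out[, j + 1L] <- (pos3(x - knots[j]) -
      pos3(x - knots[k - 1L]) * (knots[k] - knots[j]) /
        (knots[k] - knots[k - 1L]) +
      pos3(x - knots[k]) * (knots[k - 1L] - knots[j]) /
        (knots[k] - knots[k - 1L])) / span2
  }
  out
}

#' Information-criterion selection of the knot count
#'
#' Fits one least-squares model per candidate knot count, each with the
#' supplied non-spline design columns plus the restricted cubic spline basis
#' of time, and returns the candidate minimising the criterion. Ties break
#' toward the smallest k (parsimony). The default candidate set \{3, 4, 5\}
#' is deliberately small: splines are noise-sensitive at the short series
#' lengths this framework targets.
#'
#' @param y response vector.
#' @param design_without_spline numeric matrix of non-spline regressors
#'   (including the intercept column), or `NULL`.
#' @param time_values time variable from which knots are placed.
#' @param candidates integer vector, subset of 3..7.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @return The selected knot count (integer scalar) with attribute
#'   `"criterion_values"` (named numeric, one per candidate).
#' @export
select_knot_count <- function(y, design_without_spline, time_values,
                              candidates = 3:5, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (!all(candidates %in% 3:7))
    stop("candidates must be a subset of 3..7", call. = FALSE)
  candidates <- sort(unique(as.integer(candidates)))
  n <- length(y)
  crit <- rep(NA_real_, length(candidates))
  names(crit) <- candidates
  errs <- character(0)
  for (i in seq_along(candidates)) {
    kc <- candidates[i]
    val <- tryCatch({
      B <- rcs_basis(time_values, harrell_knots(time_values, kc))
      X <- cbind(design_without_spline, B)
      if (is.null(design_without_spline) ||
          !any(apply(X, 2, function(c) all(c == c[1]))))
        X <- cbind(`(Intercept)` = 1, X)
      f <- stats::lm.fit(X, y)
      p <- f$rank
      rss <- sum(f$residuals^2)
      # Gaussian log-likelihood profile; +1 parameter for sigma^2
      ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
      pen <- if (criterion == "AIC") 2 else log(n)
      -2 * ll + pen * (p + 1)
    }, error = function(e) {
      errs <<- c(errs, sprintf("k=%d: %s", kc, conditionMessage(e)))
      NA_real_
    })
    crit[i] <- val
  }
  if (all(is.na(crit)))
    stop("knot-count selection failed for every candidate: ",
         paste(errs, collapse = "; "), call. = FALSE)
  best <- candidates[which.min(crit)]  # which.min takes the first minimum
  structure(as.integer(best), criterion_values = crit)
}
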