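#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1. Invariant to input
#' order (the result is returned in the original order).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  check_pvec(p)
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p)
  q <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

check_pvec <- function(p) {
  if (!is.numeric(p)) ml_stop_value("p-values must be numeric")
  if (anyNA(p)) ml_stop_value("NA p-values are not supported")
  if (any(p < 0 | p > 1)) ml_stop_value("p-values outside [0, 1]")
  invisible(p)
}

#' Estimate the proportion of true null hypotheses (pi0)
#'
#' Storey's estimator: `pi0(lambda) = #(p > lambda) / (m * (1 - lambda))`
#' over a lambda grid, smoothed with a cubic smoothing spline (df = 3) and
#' evaluated at the largest lambda. The estimate is clamped to
#' `[1/m, 1]`; fewer than 20 p-values fall back to `pi0 = 1` with a
#' warning. Sensible only when the null p-value distribution is roughly
#' uniform; otherwise prefer plain BH.
#'
#' @param p Numeric vector of p-values.
#' @param lambdas Evaluation grid, default `seq(0.05, 0.95, by = 0.05)`.
#' @return Scalar pi0 estimate in (0, 1\].
#' @export
storey_pi0 <- function(p, lambdas = seq(0.05, 0.95, by = 0.05)) {
  check_pvec(p)
  m <- length(p)
  if (m < 20L) {
    warning("fewer than 20 p-values; pi0 set to 1")
    return(1)
  }
  lambdas <- sort(lambdas)
  pi0_l <- vapply(lambdas, function(l) sum(p > l) / (m * (1 - l)), 0)
  pi0 <- tryCatch({
    fit <- stats::smooth.spline(lambdas, pi0_l, df = 3)
    stats::predict(fit, x = max(lambdas))$y
  }, error = function(e) pi0_l[length(pi0_l)])
  max(min(pi0, 1), 1 / m)
}

#' Storey q-values
#'
#' `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`, i.e. BH scaled by the
#' estimated null proportion; with `pi0 = 1` this reduces to BH exactly,
#' and q-values are never larger than BH-adjusted p-values.
#'
#' @param p Numeric vector of p-values.
#' @param pi0 Optional fixed pi0; estimated by [storey_pi0()] when `NULL`.
#' @param lambdas Grid passed to [storey_pi0()].
#' @return List of class `QValueResult`: `qvalues` (aligned to `p`), `pi0`,
#'   `lambdas`, `pi0_lambda` (raw per-lambda estimates; `NULL` when `pi0`
#'   was supplied).
#' @export
storey_qvalue <- function(p, pi0 = NULL, lambdas = seq(0.05, 0.95, by = 0.05)) {
  check_pvec(p)
  m <- length(p)
  pi0_l <- NULL
  if (is.null(pi0)) {
    pi0 <- storey_pi0(p, lambdas)
    if (m >= 20L)
      pi0_l <- vapply(lambdas, function(l) sum(p > l) / (m * (1 - l)), 0)
  } else {
    if (pi0 <= 0 || pi0 > 1) ml_stop_value("pi0 must be in (0, 1]")
  }
  structure(list(qvalues = pmin(pi0 * bh_adjust(p), 1), pi0 = pi0,
                 lambdas = lambdas, pi0_lambda = pi0_l),
            class = "QValueResult")
}
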