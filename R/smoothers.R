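# P-spline machinery: B-spline bases on equally spaced knots, difference
# penalties, privacy-preserving anonymized knot ranges and the local
# maximum-likelihood update of the smoothing parameter.

#' Evaluate a B-spline basis
#'
#' Thin wrapper around [splines::splineDesign()] with explicit domain checks.
#' Rows form a partition of unity on the interior knot span and have at most
#' `degree + 1` nonzero entries.
#'
#' @param x Covariate values.
#' @param knots Full (interior plus boundary) nondecreasing knot vector.
#' @param degree Spline degree (0 = piecewise constant, 3 = cubic).
#' @return An `n x q` basis matrix with `q = length(knots) - degree - 1`.
#' @seealso [fg_default_knots()]
#' @export
fg_bspline_basis <- function(x, knots, degree = 3) {
  if (is.unsorted(knots)) stop("knots must be nondecreasing", call. = FALSE)
  ord <- degree + 1L
  lo <- knots[ord]
  hi <- knots[length(knots) - ord + 1L]
  bad <- which(x < lo | x > hi)
  if (length(bad)) {
    stop(sprintf("covariate value outside the knot-supported domain [%g, %g]: x[%d] = %g",
                 lo, hi, bad[1L], x[bad[1L]]), call. = FALSE)
  }
  splines::splineDesign(knots, x, ord = ord)
}

#' Difference penalty matrix
#'
#' Returns `G = t(D) %*% D` where `D` is the `order`-th difference operator on
#' `q` coefficients. `G` is symmetric positive semidefinite with rank
#' `q - order`; its null space contains polynomial coefficient sequences of
#' degree below `order`.
#'
#' @param q Basis dimension (number of spline coefficients).
#' @param order Difference order (2 = classic P-spline penalty).
#' @return A `q x q` penalty matrix.
#' @export
fg_diff_penalty <- function(q, order = 2) {
  if (order >= q) stop("penalty order must be smaller than the basis dimension", call. = FALSE)
  D <- diff(diag(q), differences = order)
  crossprod(D)
}

#' Equally spaced P-spline knots
#'
#' Places `n_intervals` equal-width interior intervals on `[xmin, xmax]` and
#' extends the grid by `degree` equally spaced knots on each side (no boundary
#' multiplicity), giving a proper P-spline basis of dimension
#' `n_intervals + degree`.
#'
#' @param xmin,xmax Domain endpoints, `xmin < xmax`.
#' @param n_intervals Number of interior intervals.
#' @param degree Spline degree.
#' @return Knot vector of length `n_intervals + 1 + 2 * degree`.
#' @export
fg_default_knots <- function(xmin, xmax, n_intervals = 20, degree = 3) {
  if (!(xmin < xmax)) stop("xmin must be smaller than xmax", call. = FALSE)
  h <- (xmax - xmin) / n_intervals
  seq(xmin - degree * h, xmax + degree * h, by = h)[seq_len(n_intervals + 1 + 2 * degree)]
}

#' Anonymized covariate range
#'
#' Combines per-node extremes into a shared covariate range without revealing
#' the exact minima and maxima: the pooled extremes are rounded outward to a
#' multiple of `granularity`. Every node must hold at least `k_anonymity`
#' observations for its extremes to be used at all.
#'
#' @param node_stats A list with one element per node, each a list or named
#'   vector with entries `min`, `max` and `n`.
#' @param granularity Rounding step (> 0). If `NULL`, one significant digit of
#'   1/32 of the pooled range is used.
#' @param k_anonymity Minimum per-node sample size.
#' @return Numeric vector `c(min, max)`, both multiples of `granularity`,
#'   covering the pooled range.
#' @examples
#' fg_anonymized_range(list(c(min = 2.0, max = 17.9, n = 1258),
#'                          c(min = 2.3, max = 15.0, n = 806)), granularity = 0.5)
#' @export
fg_anonymized_range <- function(node_stats, granularity = NULL, k_anonymity = 3) {
  ns <- vapply(node_stats, function(s) as.numeric(s[["n"]]), numeric(1))
  small <- which(ns < k_anonymity)
  if (length(small)) {
    stop(sprintf("disclosure: node %d holds %d observation(s), fewer than k-anonymity threshold %d",
                 small[1L], ns[small[1L]], k_anonymity), call. = FALSE)
  }
  lo <- min(vapply(node_stats, function(s) as.numeric(s[["min"]]), numeric(1)))
  hi <- max(vapply(node_stats, function(s) as.numeric(s[["max"]]), numeric(1)))
  if (is.null(granularity)) granularity <- signif((hi - lo) / 32, 1)
  if (granularity <= 0) stop("granularity must be positive", call. = FALSE)
  c(floor(lo / granularity + 1e-9) * granularity,
    ceiling(hi / granularity - 1e-9) * granularity)
}

#' Local maximum-likelihood update of a smoothing parameter
#'
#' Performs the random-effects variance-ratio fixed point used inside the
#' backfitting step: with `H(lambda) = ZtWZ + lambda * G`, coefficient solve
#' `gamma(lambda) = H^{-1} ZtWe` and effective degrees of freedom
#' `edf = tr(H^{-1} ZtWZ)`, iterate
#' `lambda <- sigma2_e / sigma2_b` with
#' `sigma2_e = wRSS / (n_eff - edf)` and
#' `sigma2_b = gamma' G gamma / (edf - order)`
#' until relative convergence. All inputs are low-dimensional aggregates, so
#' the update runs entirely on the client in a federated fit.
#'
#' @param ZtWZ Aggregated weighted cross-product of the smooth basis (q x q).
#' @param ZtWe Aggregated weighted basis-by-partial-residual product (length q).
#' @param etWe Aggregated weighted sum of squared partial residuals (scalar).
#' @param G Penalty matrix.
#' @param n_eff Effective number of observations (total n).
#' @param order Penalty order (dimension of the unpenalized null space).
#' @param lambda Starting value.
#' @param max_iter,tol Fixed-point iteration controls.
#' @param range Allowed `c(min, max)` for lambda; the estimate is clamped and
#'   a perfectly smooth fit (zero penalty energy) is capped at the maximum
#'   with a warning.
#' @param warn Emit the cap warning (the fitting engine collects caps and
#'   warns once per fit instead).
#' @return List with `lambda`, `gamma`, `edf`, `iterations` and `capped`.
#' @export
fg_lambda_ml <- function(ZtWZ, ZtWe, etWe, G, n_eff, order = 2,
                         lambda = 10, max_iter = 30, tol = 1e-3,
                         range = c(1e-7, 1e7), warn = TRUE) {
  lambda <- min(max(lambda, range[1]), range[2])
  capped <- FALSE
  null_space <- FALSE
  gamma <- NULL
  edf <- NA_real_
  for (it in seq_len(max_iter)) {
    H <- ZtWZ + lambda * G
    R <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(R)) {
      H <- H + diag(1e-8 * mean(diag(ZtWZ)), nrow(ZtWZ))
      R <- chol(H)
    }
    gamma <- backsolve(R, forwardsolve(t(R), ZtWe))
    edf <- sum(diag(chol2inv(R) %*% ZtWZ))
    gGg <- drop(crossprod(gamma, G %*% gamma))
    # penalty energy at the floating-point noise level of the quadratic form
    # (relative to the coefficient norm and penalty scale) means the
    # coefficients sit in the penalty null space
    noise_level <- function(g, e) e <= 1e-12 * max(abs(diag(G))) * (sum(g^2) + 1e-300)
    in_null <- noise_level(gamma, gGg)
    if (in_null && lambda > 1) {
      # a large lambda shrinks gamma toward the null space by construction;
      # probe at a moderate lambda before declaring a true null-space fit
      Hp <- ZtWZ + G
      gp <- solve(Hp, ZtWe)
      if (!noise_level(gp, drop(crossprod(gp, G %*% gp)))) {
        in_null <- FALSE
        lambda <- 1
        next
      }
    }
    if (in_null) {
      lambda_new <- range[2]
      capped <- TRUE
      null_space <- TRUE
    } else {
      wrss <- max(etWe - 2 * sum(gamma * ZtWe) + drop(crossprod(gamma, ZtWZ %*% gamma)), 0)
      sig2e <- wrss / max(n_eff - edf, 1)
      # guard the denominator: at a very large lambda the edf approaches the
      # null-space dimension; the guard lets the iteration move back down
      sig2b <- gGg / max(edf - order, 1e-3)
      lambda_new <- min(max(sig2e / sig2b, range[1]), range[2])
      capped <- lambda_new >= range[2]
    }
    if (abs(lambda_new - lambda) <= tol * (lambda + 1e-12)) {
      lambda <- lambda_new
      break
    }
    lambda <- lambda_new
  }
  if (null_space && warn) {
    warning("zero penalty energy (coefficients in the penalty null space): smoothing parameter capped at its upper bound",
            call. = FALSE)
  }
  # final coefficients at the returned lambda
  H <- ZtWZ + lambda * G
  R <- chol(H)
  gamma <- backsolve(R, forwardsolve(t(R), ZtWe))
  edf <- sum(diag(chol2inv(R) %*% ZtWZ))
  list(lambda = lambda, gamma = drop(gamma), edf = edf, iterations = it,
       capped = capped, null_space = null_space)
}
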