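# Model specification: per-distribution-parameter formulas with linear terms
# and pb() P-spline terms, plus fitting control settings.

#' Declare a P-spline smooth term
#'
#' Used inside model formulas, e.g. `height ~ age + pb(age)`. The linear part
#' of a covariate is written explicitly in the formula; `pb()` contributes only
#' the penalized B-spline basis.
#'
#' @param x Covariate (bare name inside a formula).
#' @param lambda Smoothing parameter: the string `"estimate"` (default, local
#'   maximum-likelihood update inside the backfitting step) or a fixed
#'   nonnegative number.
#' @param n_intervals Number of interior knot intervals.
#' @param degree Spline degree.
#' @param order Difference-penalty order.
#' @return A term descriptor (only meaningful inside a formula).
#' @export
pb <- function(x, lambda = "estimate", n_intervals = 20, degree = 3, order = 2) {
  structure(list(var = deparse(substitute(x)), lambda = lambda,
                 n_intervals = n_intervals, degree = degree, order = order),
            class = "fg_pb")
}

# split a per-parameter formula into its linear part and pb() smooth terms
parse_param_formula <- function(f, param) {
  tt <- stats::terms(f, specials = "pb")
  labels <- attr(tt, "term.labels")
  is_pb <- startsWith(labels, "pb(")
  smooths <- lapply(labels[is_pb], function(lab) {
    cl <- str2lang(lab)
    mc <- match.call(pb, cl)
    s <- list(var = deparse(mc$x),
              lambda = if (is.null(mc$lambda)) "estimate" else eval(mc$lambda),
              n_intervals = if (is.null(mc$n_intervals)) 20 else eval(mc$n_intervals),
              degree = if (is.null(mc$degree)) 3 else eval(mc$degree),
              order = if (is.null(mc$order)) 2 else eval(mc$order))
    s$q <- s$n_intervals + s$degree
    s$label <- lab
    s$id <- paste0(param, ":", lab)
    if (s$order >= s$q) stop("pb(): penalty order must be below the basis dimension", call. = FALSE)
    s
  })
  if (attr(tt, "intercept") != 1) {
    stop("every distribution parameter model must keep its intercept", call. = FALSE)
  }
  lin <- if (any(!is_pb)) {
    stats::reformulate(labels[!is_pb], intercept = TRUE)
  } else {
    ~1
  }
  list(lin = lin, smooths = smooths)
}

#' Build a model specification
#'
#' Collects the response family and one formula per distribution parameter
#' into the specification consumed by [fgamlss()] and [fgamlss_fed()]. Extra
#' formulas beyond the family's parameter count are an error; missing ones
#' default to intercept-only.
#'
#' @param formula Formula for `mu`, with the response on the left.
#' @param sigma.formula,nu.formula,tau.formula One-sided formulas for the
#'   remaining distribution parameters.
#' @param family Family name (`"NO"`, `"BCCG"`, `"BCPE"`) or an [fg_family]
#'   object.
#' @return An object of class `fg_spec`.
#' @export
fg_spec <- function(formula, sigma.formula = ~1, nu.formula = ~1, tau.formula = ~1,
                    family = "NO") {
  if (is.character(family)) family <- fg_family(family)
  stopifnot(inherits(family, "fg_family"))
  if (length(formula) != 3L) stop("the mu formula must have a response", call. = FALSE)
  response <- deparse(formula[[2L]])
  supplied <- list(mu = formula[-2L], sigma = sigma.formula,
                   nu = nu.formula, tau = tau.formula)
  is_int_only <- function(f) identical(deparse1(f), "~1")
  extra <- setdiff(c(if (!is_int_only(nu.formula)) "nu",
                     if (!is_int_only(tau.formula)) "tau"),
                   family$param_names)
  if (length(extra)) {
    stop("family ", family$name, " has no parameter(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  params <- lapply(family$param_names, function(k) {
    pf <- parse_param_formula(supplied[[k]], k)
    pf$link <- family$links[[k]]$name
    pf
  })
  names(params) <- family$param_names
  structure(list(family = family, response = response, params = params),
            class = "fg_spec")
}

# covariate names used by the linear parts and the smooths
spec_covariates <- function(spec) {
  unique(unlist(lapply(spec$params, function(p) {
    c(all.vars(p$lin), vapply(p$smooths, `[[`, "", "var"))
  })))
}

spec_smooths <- function(spec) {
  do.call(c, lapply(spec$params, `[[`, "smooths"))
}

# total number of regression coefficients (used by the disclosure guard)
spec_total_df <- function(spec, xlev) {
  sum(vapply(names(spec$params), function(k) {
    p <- spec$params[[k]]
    lin_df <- lin_ncol(p$lin, xlev)
    lin_df + sum(vapply(p$smooths, `[[`, numeric(1), "q"))
  }, numeric(1)))
}

# number of columns the linear model matrix will have, from factor levels alone
lin_ncol <- function(lin, xlev) {
  vars <- all.vars(lin)
  1L + sum(vapply(vars, function(v) {
    if (!is.null(xlev[[v]])) length(xlev[[v]]) - 1L else 1L
  }, integer(1)))
}

#' Fitting control settings
#'
#' Tolerances and iteration caps for the RS algorithm. Outer and inner
#' iterations converge on the absolute change in global deviance; backfitting
#' converges on the maximum absolute change of the predictor.
#'
#' @param outer_tol,inner_tol Absolute deviance-change tolerances.
#' @param backfit_tol Predictor-change tolerance inside backfitting.
#' @param max_outer,max_inner,max_backfit Iteration caps.
#' @param max_halvings Maximum step-halvings when a proposed update increases
#'   the penalized deviance.
#' @param lambda_range,lambda_max_iter,lambda_tol Controls for the local
#'   maximum-likelihood smoothing-parameter fixed point.
#' @param trace Print per-outer-iteration deviance.
#' @return A list of class `fg_control`.
#' @export
fg_control <- function(outer_tol = 1e-3, inner_tol = 1e-3, backfit_tol = 1e-6,
                       max_outer = 50, max_inner = 10, max_backfit = 30,
                       max_halvings = 10, lambda_range = c(1e-7, 1e7),
                       lambda_max_iter = 30, lambda_tol = 1e-3, trace = FALSE) {
  structure(list(outer_tol = outer_tol, inner_tol = inner_tol,
                 backfit_tol = backfit_tol, max_outer = max_outer,
                 max_inner = max_inner, max_backfit = max_backfit,
                 max_halvings = max_halvings, lambda_range = lambda_range,
                 lambda_max_iter = lambda_max_iter, lambda_tol = lambda_tol,
                 trace = trace), class = "fg_control")
}

#' Disclosure thresholds for federated fits
#'
#' DataSHIELD-style privacy settings applied per node before any sufficient
#' statistic is released.
#'
#' @param k_anonymity Minimum number of observations per node.
#' @param category_min Minimum count for any factor category present on a node.
#' @param df_ratio Maximum ratio of total model coefficients to node sample
#'   size.
#' @return A list of class `fg_thresholds`.
#' @export
fg_thresholds <- function(k_anonymity = 3, category_min = 3, df_ratio = 0.33) {
  structure(list(k_anonymity = k_anonymity, category_min = category_min,
                 df_ratio = df_ratio), class = "fg_thresholds")
}
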