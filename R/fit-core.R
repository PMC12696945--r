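# The RS fitting algorithm: an outer iteration over distribution parameters,
# an inner penalized-IRLS iteration per parameter, and a modified backfitting
# cycle over additive terms. The driver is written against the node/session
# abstraction, so the same arithmetic serves the pooled fit (one node holding
# all data) and the federated fit (several nodes; every per-term solve is fed
# by summed per-node cross-products). This shared path is what makes the
# federated estimates identical to pooled ones up to floating-point
# summation order.

#' Global deviance
#'
#' Minus twice the unpenalized log-likelihood, the convergence monitor of the
#' RS iterations.
#'
#' @param family An [fg_family] object.
#' @param y Response vector.
#' @param theta Named list of distribution-parameter vectors.
#' @return A scalar.
#' @export
fg_global_deviance <- function(family, y, theta) {
  -2 * sum(family$ld(y, theta))
}

#' Solve a (penalized) weighted least-squares system
#'
#' Solves `(CtWC + penalty) b = CtWz` from aggregated cross-products. The
#' system matrix is checked for rank deficiency first; an ill-conditioned
#' system is an error naming the collinear columns rather than a silent
#' near-singular solve.
#'
#' @param CtWC Aggregated weighted cross-product matrix.
#' @param CtWz Aggregated weighted response cross-product vector.
#' @param penalty Optional penalty matrix (`lambda * G`), or `NULL`.
#' @return Coefficient vector.
#' @export
fg_pwls_solve <- function(CtWC, CtWz, penalty = NULL) {
  H <- if (is.null(penalty)) CtWC else CtWC + penalty
  b <- tryCatch(solve(H, CtWz), error = function(e) NULL)
  if (is.null(b) || !all(is.finite(b))) {
    qh <- qr(H)
    cols <- colnames(H)
    if (is.null(cols)) cols <- paste0("col", seq_len(ncol(H)))
    bad <- if (qh$rank < ncol(H)) cols[qh$pivot[(qh$rank + 1L):ncol(H)]] else cols
    stop("rank-deficient or ill-conditioned system; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  drop(b)
}

# effective degrees of freedom tr[(ZtWZ + lambda G)^-1 ZtWZ]
term_edf <- function(ZtWZ, lambda, G) {
  sum(diag(solve(ZtWZ + lambda * G, ZtWZ)))
}

zero_coefs <- function(design_info) {
  lapply(design_info, function(d) {
    list(beta = stats::setNames(numeric(length(d$xnames)), d$xnames),
         gamma = lapply(d$q, numeric))
  })
}

penalty_energy <- function(coef_k, smooths, lambdas_k) {
  if (!length(smooths)) return(0)
  sum(vapply(seq_along(smooths), function(j) {
    g <- coef_k$gamma[[j]]
    G <- fg_diff_penalty(smooths[[j]]$q, smooths[[j]]$order)
    lambdas_k[j] * drop(crossprod(g, G %*% g))
  }, numeric(1)))
}

# Internal RS driver. `session` must already exist; broadcast/harmonization
# happens here. Returns the fitted-model list (before classing).
fg_rs_fit <- function(session, spec, control = fg_control(), xranges = NULL,
                      granularity = NULL, anonymize = TRUE) {
  family <- spec$family
  pnames <- family$param_names
  bc <- broadcast_spec(session, spec, xranges = xranges, granularity = granularity,
                       anonymize = anonymize)

  # design dimensions and column names are spec-determined; read client-side
  design_info <- lapply(pnames, function(k) {
    d <- session$nodes[[1L]]$design[[k]]
    list(xnames = colnames(d$X), q = vapply(d$Z, ncol, integer(1)))
  })
  names(design_info) <- pnames

  # pooled response moments -> coefficient-based initialization
  mom <- session_round(session, "init_moments", 0,
                       function(node) node_moments(node, spec))
  n_total <- mom$n
  m0 <- mom$sum / n_total
  s0 <- sqrt(max((mom$sum_sq - n_total * m0^2) / max(n_total - 1, 1), 1e-12))
  if (n_total < bc$total_df) {
    stop(sprintf("insufficient data: n = %d observations for %d coefficients",
                 as.integer(n_total), as.integer(bc$total_df)), call. = FALSE)
  }
  theta0 <- family$init(m0, s0)
  coefs <- zero_coefs(design_info)
  for (k in pnames) {
    coefs[[k]]$beta[1L] <- family$links[[k]]$linkfun(theta0[[k]])
  }
  penalties <- lapply(pnames, function(k) {
    lapply(spec$params[[k]]$smooths, function(s) fg_diff_penalty(s$q, s$order))
  })
  names(penalties) <- pnames
  lambdas <- lapply(pnames, function(k) {
    vapply(spec$params[[k]]$smooths, function(s) {
      if (identical(s$lambda, "estimate")) 10 else as.numeric(s$lambda)
    }, numeric(1))
  })
  names(lambdas) <- pnames
  estimate_lambda <- lapply(pnames, function(k) {
    vapply(spec$params[[k]]$smooths, function(s) identical(s$lambda, "estimate"), logical(1))
  })
  names(estimate_lambda) <- pnames
  edf <- lapply(pnames, function(k) {
    vapply(spec$params[[k]]$smooths, function(s) as.numeric(s$q), numeric(1))
  })
  names(edf) <- pnames

  dev <- NA_real_
  for (k in pnames) {
    st <- session_round(session, paste0("set_state:", k),
                        length(coefs[[k]]$beta) + sum(lengths(coefs[[k]]$gamma)),
                        function(node) node_set_state(node, spec, k, coefs[[k]]))
    dev <- st$dev
  }

  total_penalty <- function(cf) {
    sum(vapply(pnames, function(k) {
      penalty_energy(cf[[k]], spec$params[[k]]$smooths, lambdas[[k]])
    }, numeric(1)))
  }

  iters <- list(outer = 0L, inner = 0L, backfit = 0L, halvings = 0L)
  converged <- FALSE
  pen_trace <- numeric(0)
  step_failures <- 0L
  capped_terms <- logical(0)

  inner_iteration <- function(k) {
    smooths <- spec$params[[k]]$smooths
    J <- length(smooths)
    for (node in session$nodes) node$bf_eta <- list()
    for (it in seq_len(control$max_inner)) {
      iters$inner <<- iters$inner + 1L
      dev_old <- dev
      coef_old <- coefs[[k]]
      session_round(session, paste0("wz:", k), 0,
                    function(node) node_wz(node, spec, k))
      coef_k <- coefs[[k]]
      bcast <- length(coef_k$beta) + sum(lengths(coef_k$gamma))
      for (cycle in seq_len(control$max_backfit)) {
        iters$backfit <<- iters$backfit + 1L
        # linear part against its partial residuals
        st <- session_round(session, paste0("suffstats:", k, ":linear"), bcast,
                            function(node) node_term_stats(node, k, 0L, coef_k))
        coef_k$beta <- stats::setNames(fg_pwls_solve(st$CtWC, st$CtWe),
                                       names(coef_k$beta))
        for (j in seq_len(J)) {
          st <- session_round(session, paste0("suffstats:", k, ":", smooths[[j]]$label),
                              bcast,
                              function(node) node_term_stats(node, k, j, coef_k))
          if (estimate_lambda[[k]][j] && cycle == 1L && it == 1L) {
            # local-ML lambda update: converged variance-ratio fixed point,
            # once per parameter per outer cycle, so backfitting and the step
            # control work against a fixed penalized objective
            lm_res <- fg_lambda_ml(st$CtWC, st$CtWe, st$etWe, penalties[[k]][[j]],
                                   n_eff = st$n, order = smooths[[j]]$order,
                                   lambda = lambdas[[k]][j],
                                   max_iter = control$lambda_max_iter,
                                   tol = control$lambda_tol,
                                   range = control$lambda_range, warn = FALSE)
            capped_terms[smooths[[j]]$id] <<- lm_res$null_space
            lambdas[[k]][j] <<- lm_res$lambda
            coef_k$gamma[[j]] <- lm_res$gamma
            edf[[k]][j] <<- lm_res$edf
          } else {
            coef_k$gamma[[j]] <- fg_pwls_solve(st$CtWC, st$CtWe,
                                               lambdas[[k]][j] * penalties[[k]][[j]])
            edf[[k]][j] <<- term_edf(st$CtWC, lambdas[[k]][j], penalties[[k]][[j]])
          }
        }
        if (J == 0L) break
        delta <- session_round(session, paste0("eta_delta:", k), bcast,
                               function(node) node_eta_delta(node, k, coef_k),
                               combine = function(ps) {
                                 list(delta = max(vapply(ps, `[[`, numeric(1), "delta")))
                               })
        if (delta$delta < control$backfit_tol) break
      }
      # step control: accept only if the penalized deviance (at the current
      # smoothing parameters) does not increase; halve toward the previous
      # coefficients otherwise
      pen_old <- dev_old + total_penalty(coefs)
      halved <- 0L
      repeat {
        st <- session_round(session, paste0("set_state:", k), bcast,
                            function(node) node_set_state(node, spec, k, coef_k))
        cf_try <- coefs
        cf_try[[k]] <- coef_k
        pen_new <- st$dev + total_penalty(cf_try)
        if (pen_new <= pen_old + 1e-10 || halved >= control$max_halvings) break
        halved <- halved + 1L
        iters$halvings <<- iters$halvings + 1L
        coef_k$beta <- (coef_k$beta + coef_old$beta) / 2
        coef_k$gamma <- Map(function(a, b) (a + b) / 2, coef_k$gamma, coef_old$gamma)
      }
      if (pen_new > pen_old + 1e-10) {
        # no descent step found: keep the previous iterate
        coef_k <- coef_old
        st <- session_round(session, paste0("set_state:", k), bcast,
                            function(node) node_set_state(node, spec, k, coef_k))
        pen_new <- st$dev + total_penalty(coefs)
        step_failures <<- step_failures + 1L
      }
      coefs[[k]] <<- coef_k
      dev <<- st$dev
      pen_trace <<- c(pen_trace, pen_new)
      if (abs(dev - dev_old) < control$inner_tol) break
    }
  }

  dev_outer_prev <- Inf
  for (outer in seq_len(control$max_outer)) {
    iters$outer <- outer
    for (k in pnames) inner_iteration(k)
    if (control$trace) {
      message(sprintf("outer %d: global deviance %.6f", outer, dev))
    }
    if (abs(dev - dev_outer_prev) < control$outer_tol) {
      converged <- TRUE
      break
    }
    dev_outer_prev <- dev
  }
  if (!converged) {
    warning("RS algorithm did not converge within max_outer iterations", call. = FALSE)
  }
  if (step_failures > 0L) {
    warning(sprintf("%d inner step(s) found no descent direction and kept the previous iterate",
                    step_failures), call. = FALSE)
  }
  if (any(capped_terms)) {
    warning("zero penalty energy: smoothing parameter capped at its upper bound for term(s): ",
            paste(names(capped_terms)[capped_terms], collapse = ", "), call. = FALSE)
  }

  list(
    family = family$name,
    spec = spec,
    coefficients = coefs,
    lambda = lambdas,
    edf = edf,
    knots = bc$knots,
    xlevels = bc$xlev,
    deviance = dev,
    penalized_deviance = dev + total_penalty(coefs),
    penalized_deviance_trace = pen_trace,
    df = bc$total_df,
    n = as.integer(n_total),
    node_n = as.integer(bc$node_n),
    iterations = iters,
    converged = converged,
    comm_log = comm_log_df(session),
    control = control
  )
}

#' Fit a GAMLSS to pooled data
#'
#' Fits a generalized additive model for location, scale and shape by the RS
#' algorithm: penalized iteratively reweighted least squares per distribution
#' parameter with modified backfitting over linear and P-spline terms, and
#' local maximum-likelihood smoothing-parameter updates.
#'
#' @param formula Model formula for `mu`, e.g. `height ~ age + pb(age)`.
#' @param sigma.formula,nu.formula,tau.formula One-sided formulas for the
#'   remaining distribution parameters (defaults intercept-only).
#' @param family `"NO"`, `"BCCG"` or `"BCPE"` (or an [fg_family]).
#' @param data A data frame holding the response and covariates.
#' @param xranges Optional named list giving the covariate range
#'   (`c(min, max)`) to use for P-spline knots; defaults to the observed
#'   range.
#' @param control An [fg_control] object.
#' @return An object of class `fgamlss`. Pooled fits additionally carry the
#'   response and fitted parameter values, so [residuals()] and [fitted()]
#'   work; federated fits (see [fgamlss_fed()]) deliberately do not.
#' @examples
#' d <- data.frame(x = c(0, 1, 2), y = c(0, 1, 3))
#' m <- fgamlss(y ~ x, family = "NO", data = d)
#' coef(m)
#' @seealso [fgamlss_fed()], [predict.fgamlss()], [fg_centiles()]
#' @export
fgamlss <- function(formula, sigma.formula = ~1, nu.formula = ~1, tau.formula = ~1,
                    family = "NO", data, xranges = NULL, control = fg_control()) {
  cl <- match.call()
  spec <- fg_spec(formula, sigma.formula, nu.formula, tau.formula, family)
  # a pooled fit is a centralized analysis: no federation disclosure rules
  session <- fg_session_new(list(pooled = data),
                            thresholds = fg_thresholds(k_anonymity = 0,
                                                       category_min = 0,
                                                       df_ratio = Inf))
  fit <- fg_rs_fit(session, spec, control, xranges = xranges, anonymize = FALSE)
  fit$call <- cl
  fit$federated <- FALSE
  # pooled fits keep individual-level results (a centralized analysis may)
  node <- session$nodes[[1L]]
  fit$y <- node$y
  fit$fitted_theta <- as.data.frame(node$theta)
  structure(fit, class = "fgamlss")
}

#' Fit a GAMLSS to horizontally partitioned data
#'
#' Runs the same RS algorithm as [fgamlss()], but the individual-level data
#' stay on their nodes: each per-term solve is fed by the elementwise sum of
#' per-node sufficient statistics (weighted cross-products, scalar aggregates
#' and counts), every payload is checked against disclosure thresholds, and
#' all exchanges are recorded in a communication log. By construction the
#' estimates equal those of a pooled fit of the concatenated data up to
#' floating-point summation order.
#'
#' @inheritParams fgamlss
#' @param nodes A named list of data frames (one per node) or a character
#'   vector of CSV file paths.
#' @param thresholds An [fg_thresholds] object with the disclosure settings.
#' @param granularity Rounding step for the anonymized knot range (see
#'   [fg_anonymized_range()]); ignored when `xranges` is given.
#' @return An object of class `fgamlss` with a populated `comm_log` and no
#'   individual-level components.
#' @export
fgamlss_fed <- function(formula, sigma.formula = ~1, nu.formula = ~1, tau.formula = ~1,
                        family = "NO", nodes, thresholds = fg_thresholds(),
                        xranges = NULL, granularity = NULL, control = fg_control()) {
  cl <- match.call()
  if (is.character(nodes)) {
    paths <- nodes
    nodes <- lapply(paths, function(p) utils::read.csv(p, stringsAsFactors = FALSE))
    names(nodes) <- if (!is.null(names(paths)) && all(nzchar(names(paths)))) {
      names(paths)
    } else {
      tools::file_path_sans_ext(basename(paths))
    }
  }
  spec <- fg_spec(formula, sigma.formula, nu.formula, tau.formula, family)
  session <- fg_session_new(nodes, thresholds = thresholds)
  fit <- fg_rs_fit(session, spec, control, xranges = xranges,
                   granularity = granularity, anonymize = TRUE)
  fit$call <- cl
  fit$federated <- TRUE
  structure(fit, class = "fgamlss")
}
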