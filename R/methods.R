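# S3 methods for fitted models.

#' @export
print.fgamlss <- function(x, ...) {
  cat("Federated GAMLSS fit" , if (!x$federated) "(pooled)", "\n")
  cat("Family:", x$family, " Observations:", x$n,
      if (x$federated) sprintf(" on %d node(s) (%s)", length(x$node_n),
                               paste(x$node_n, collapse = ", ")), "\n")
  cat("Global deviance:", format(x$deviance, digits = 10),
      " Converged:", x$converged, "\n")
  for (k in names(x$coefficients)) {
    cat("\n", k, " coefficients (link = ", x$spec$params[[k]]$link, "):\n", sep = "")
    print(x$coefficients[[k]]$beta, digits = 6)
    sm <- x$spec$params[[k]]$smooths
    if (length(sm)) {
      for (j in seq_along(sm)) {
        cat(sprintf("  %s: lambda = %.4g, edf = %.2f\n",
                    sm[[j]]$label, x$lambda[[k]][j], x$edf[[k]][j]))
      }
    }
  }
  invisible(x)
}

#' @export
summary.fgamlss <- function(object, ...) {
  print(object)
  cat("\nIterations: outer", object$iterations$outer,
      "| inner", object$iterations$inner,
      "| backfit cycles", object$iterations$backfit, "\n")
  if (object$federated) {
    rounds <- if (nrow(object$comm_log)) max(object$comm_log$round) else object$comm_rounds
    cat("Communication rounds:", rounds, "\n")
  }
  cat("Note: standard errors are not provided.\n")
  invisible(object)
}

#' Extract linear coefficients
#'
#' Returns the linear-part regression coefficients, prefixed with the
#' distribution parameter they belong to (`mu.(Intercept)`, `sigma.age`,
#' ...). Spline coefficients live in `object$coefficients[[k]]$gamma`.
#'
#' @param object A fitted `fgamlss` model.
#' @param parameter Optionally restrict to one distribution parameter.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
coef.fgamlss <- function(object, parameter = NULL, ...) {
  ks <- if (is.null(parameter)) names(object$coefficients) else parameter
  out <- unlist(lapply(ks, function(k) {
    b <- object$coefficients[[k]]$beta
    stats::setNames(b, paste0(k, ".", names(b)))
  }))
  out
}

#' @export
deviance.fgamlss <- function(object, ...) object$deviance

#' @export
logLik.fgamlss <- function(object, ...) {
  structure(-object$deviance / 2, df = object$df, class = "logLik")
}

#' @export
fitted.fgamlss <- function(object, parameter = "mu", ...) {
  if (is.null(object$fitted_theta)) {
    stop("fitted values are not stored for federated fits", call. = FALSE)
  }
  object$fitted_theta[[parameter]]
}

#' Normalized quantile residuals
#'
#' z-scores of the training observations under their fitted conditional
#' distributions. Available for pooled fits only: a federated fit stores no
#' individual-level data, and per-observation residuals are exactly the kind
#' of output the disclosure model forbids.
#'
#' @param object A pooled `fgamlss` fit.
#' @param ... Unused.
#' @return Numeric vector of residuals.
#' @export
residuals.fgamlss <- function(object, ...) {
  if (object$federated || is.null(object$y)) {
    stop("residuals are unavailable for federated fits (per-observation data never leave the nodes)",
         call. = FALSE)
  }
  p <- object$spec$family$cdf(object$y, as.list(object$fitted_theta))
  stats::qnorm(pmin(pmax(p, 1e-15), 1 - 1e-15))
}

#' Simulate responses from a fitted model
#'
#' Draws new responses from the fitted conditional distribution at the given
#' covariate values via the family's inverse-CDF sampler.
#'
#' @param object A fitted `fgamlss` model.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed passed to [set.seed()].
#' @param newdata Covariate values; for pooled fits defaults to the training
#'   covariate state (the stored fitted parameters).
#' @param ... Unused.
#' @return A data frame with `nsim` columns.
#' @export
simulate.fgamlss <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  theta <- if (is.null(newdata)) {
    if (is.null(object$fitted_theta)) {
      stop("newdata is required for federated fits", call. = FALSE)
    }
    object$fitted_theta
  } else {
    predict(object, newdata)
  }
  n <- nrow(theta)
  out <- as.data.frame(lapply(seq_len(nsim), function(i) {
    object$spec$family$rfun(n, as.list(theta))
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted model as percentile curves
#'
#' Draws fitted centile curves over a grid of the given covariate. For pooled
#' fits the training observations are overplotted; federated fits draw the
#' grid curves only.
#'
#' @param x A fitted `fgamlss` model.
#' @param xvar Name of the covariate to place on the horizontal axis
#'   (defaults to the first smooth covariate).
#' @param probs Centile probabilities.
#' @param grid_length Number of grid points.
#' @param ... Passed on to [plot.fg_centiles()].
#' @return The centile table, invisibly.
#' @export
plot.fgamlss <- function(x, xvar = NULL,
                         probs = c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95),
                         grid_length = 100, ...) {
  sm <- spec_smooths(x$spec)
  if (is.null(xvar)) {
    if (!length(sm)) stop("no smooth covariate to plot against; give xvar", call. = FALSE)
    xvar <- sm[[1L]]$var
  }
  ids <- vapply(sm, `[[`, "", "var") == xvar
  if (!any(ids)) stop("no smooth term in covariate '", xvar, "'", call. = FALSE)
  s <- sm[ids][[1L]]
  kn <- x$knots[[s$id]]
  lo <- kn[s$degree + 1L]
  hi <- kn[length(kn) - s$degree]
  grid <- stats::setNames(data.frame(seq(lo, hi, length.out = grid_length)), xvar)
  ct <- fg_centiles(x, grid, probs = probs)
  plot.fg_centiles(ct, ...)
  invisible(ct)
}
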