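# Prediction of distribution parameters at new covariate values, centile
# (percentile) tables and z-scores.

# model matrices for new data, reusing stored factor levels and knots;
# extrapolation beyond the knot-supported domain is an error, never a silent
# linear extension
build_newdata_design <- function(object, k, newdata) {
  p <- object$spec$params[[k]]
  for (v in names(object$xlevels)) {
    if (!is.null(newdata[[v]])) {
      newdata[[v]] <- factor(as.character(newdata[[v]]), levels = object$xlevels[[v]])
    }
  }
  xl <- object$xlevels[intersect(names(object$xlevels), all.vars(p$lin))]
  mf <- stats::model.frame(p$lin, newdata, xlev = xl)
  X <- stats::model.matrix(p$lin, mf)
  Z <- lapply(p$smooths, function(s) {
    tryCatch(
      fg_bspline_basis(newdata[[s$var]], object$knots[[s$id]], s$degree),
      error = function(e) {
        stop("extrapolation error for term ", s$id, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
  })
  list(X = X, Z = Z)
}

#' Predict distribution parameters
#'
#' Assembles the stored coefficients with re-evaluated design matrices at new
#' covariate values and maps the predictors back to the parameter scale.
#'
#' @param object A fitted `fgamlss` model.
#' @param newdata Data frame of covariate values. For pooled fits it may be
#'   omitted, returning the training-data fitted parameters.
#' @param type `"parameter"` (natural scale, default) or `"link"` (predictor
#'   scale).
#' @param ... Unused.
#' @return A data frame with one column per distribution parameter.
#' @export
predict.fgamlss <- function(object, newdata = NULL, type = c("parameter", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$fitted_theta)) {
      stop("newdata is required for federated fits (no individual-level data are stored)",
           call. = FALSE)
    }
    if (type == "parameter") return(object$fitted_theta)
    out <- object$fitted_theta
    for (k in names(out)) out[[k]] <- object$spec$family$links[[k]]$linkfun(out[[k]])
    return(out)
  }
  fam <- object$spec$family
  out <- lapply(fam$param_names, function(k) {
    d <- build_newdata_design(object, k, newdata)
    cf <- object$coefficients[[k]]
    eta <- drop(d$X %*% cf$beta)
    for (j in seq_along(d$Z)) eta <- eta + drop(d$Z[[j]] %*% cf$gamma[[j]])
    if (type == "link") eta else fam$links[[k]]$linkinv(eta)
  })
  names(out) <- fam$param_names
  if (type == "parameter") {
    out <- fam$clip_theta(out)
  }
  as.data.frame(out)
}

#' Centile (percentile) table
#'
#' Evaluates the fitted conditional quantile function on a covariate grid.
#' Because the quantile function is strictly increasing in the probability,
#' the resulting percentile curves cannot cross.
#'
#' @param object A fitted `fgamlss` model.
#' @param newdata Data frame of grid covariate values.
#' @param probs Strictly increasing probabilities in (0, 1); default the
#'   classic 5/10/25/50/75/90/95% reference set.
#' @return A data frame of class `fg_centiles`: the grid columns, the fitted
#'   distribution parameters and one column `p<percent>` per probability.
#' @export
fg_centiles <- function(object, newdata,
                        probs = c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)) {
  stopifnot(inherits(object, "fgamlss"))
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie strictly in (0, 1)", call. = FALSE)
  if (is.unsorted(probs, strictly = TRUE)) stop("probs must be strictly increasing", call. = FALSE)
  theta <- predict(object, newdata)
  fam <- object$spec$family
  cent <- vapply(probs, function(p) fam$qfun(rep_len(p, nrow(theta)), as.list(theta)),
                 numeric(nrow(theta)))
  cent <- matrix(cent, nrow = nrow(theta))
  colnames(cent) <- paste0("p", formatC(100 * probs, format = "fg", width = 1))
  out <- cbind(newdata, theta, as.data.frame(cent))
  attr(out, "probs") <- probs
  attr(out, "xvar") <- names(newdata)[1L]
  attr(out, "response") <- object$spec$response
  class(out) <- c("fg_centiles", "data.frame")
  out
}

#' Plot percentile curves
#'
#' Line chart of the centile curves over the grid covariate. Only grid curves
#' are drawn; individual observations are never plotted from a centile table,
#' matching the federated disclosure model.
#'
#' @param x An `fg_centiles` table.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.fg_centiles <- function(x, ...) {
  probs <- attr(x, "probs")
  xvar <- attr(x, "xvar")
  cols <- paste0("p", formatC(100 * probs, format = "fg", width = 1))
  graphics::matplot(x[[xvar]], as.matrix(x[, cols, drop = FALSE]), type = "l",
                    lty = 1, col = grDevices::hcl.colors(length(probs), "Zissou 1"),
                    xlab = xvar, ylab = attr(x, "response"), ...)
  graphics::legend("topleft", legend = paste0(100 * probs, "%"), lty = 1,
                   col = grDevices::hcl.colors(length(probs), "Zissou 1"), cex = 0.7,
                   bty = "n")
  invisible(x)
}

#' Write a centile table to CSV
#'
#' Columns: grid value(s), fitted distribution parameters, one column per
#' probability. Numbers are written with 12 significant digits.
#'
#' @param x An `fg_centiles` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
fg_write_centiles <- function(x, path) {
  out <- as.data.frame(x)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(col) formatC(col, digits = 12, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' z-scores under the fitted conditional distribution
#'
#' Computes `z = qnorm(F_Y(y | theta(x)))`, the probability-integral-transform
#' z-score of each observation under its fitted conditional distribution.
#'
#' @param object A fitted `fgamlss` model.
#' @param newdata Data frame holding covariates and (unless `y` is given) the
#'   response column.
#' @param y Optional response vector overriding the column in `newdata`.
#' @return Numeric vector of z-scores.
#' @export
fg_zscore <- function(object, newdata, y = NULL) {
  if (is.null(y)) {
    y <- newdata[[object$spec$response]]
    if (is.null(y)) {
      stop("newdata must contain the response column '", object$spec$response, "'",
           call. = FALSE)
    }
  }
  theta <- predict(object, newdata)
  p <- object$spec$family$cdf(y, as.list(theta))
  stats::qnorm(pmin(pmax(p, 1e-15), 1 - 1e-15))
}
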