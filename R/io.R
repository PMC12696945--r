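# Model serialization: a fitted model round-trips through a plain JSON
# artifact (coefficients, smoothing parameters, knots, metadata) that
# reproduces predictions exactly and contains no individual-level data.

#' Save a fitted model as JSON
#'
#' Writes everything needed to reproduce predictions (formulas, family,
#' coefficients, smoothing parameters, knots, factor levels) together with
#' fit diagnostics. The artifact is deterministic: saving the same model
#' twice yields byte-identical files.
#'
#' @param object A fitted `fgamlss` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
fg_save_model <- function(object, path) {
  stopifnot(inherits(object, "fgamlss"))
  pnames <- names(object$coefficients)
  payload <- list(
    format = "fedgamlss-model",
    version = as.character(utils::packageVersion("fedgamlss")),
    family = object$family,
    response = object$spec$response,
    formula_strings = {
      fs <- lapply(pnames, function(k) {
        p <- object$spec$params[[k]]
        rhs <- paste(c(attr(stats::terms(p$lin), "term.labels"),
                       vapply(p$smooths, `[[`, "", "label")), collapse = " + ")
        if (rhs == "") rhs <- "1"
        if (k == "mu") paste(object$spec$response, "~", rhs) else paste("~", rhs)
      })
      names(fs) <- pnames
      fs
    },
    coefficients = lapply(object$coefficients, function(cf) {
      list(beta = as.list(cf$beta), gamma = cf$gamma)
    }),
    lambda = object$lambda,
    edf = object$edf,
    knots = object$knots,
    xlevels = object$xlevels,
    deviance = object$deviance,
    penalized_deviance = object$penalized_deviance,
    df = object$df,
    n = object$n,
    node_n = object$node_n,
    iterations = object$iterations,
    converged = object$converged,
    federated = object$federated,
    comm_rounds = if (nrow(object$comm_log)) max(object$comm_log$round) else 0L
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' Rebuilds an `fgamlss` object saved by [fg_save_model()]. The loaded model
#' supports prediction, centiles and z-scores; individual-level components
#' (fitted values, residuals) are not part of the artifact.
#'
#' @param path Path to a model JSON file.
#' @return An object of class `fgamlss`.
#' @export
fg_load_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!identical(m$format, "fedgamlss-model")) {
    stop("not a fedgamlss model artifact: ", path, call. = FALSE)
  }
  fs <- m$formula_strings
  spec <- fg_spec(stats::as.formula(fs$mu),
                  sigma.formula = if (!is.null(fs$sigma)) stats::as.formula(fs$sigma) else ~1,
                  nu.formula = if (!is.null(fs$nu)) stats::as.formula(fs$nu) else ~1,
                  tau.formula = if (!is.null(fs$tau)) stats::as.formula(fs$tau) else ~1,
                  family = m$family)
  pnames <- spec$family$param_names
  coefs <- lapply(pnames, function(k) {
    cf <- m$coefficients[[k]]
    list(beta = unlist(cf$beta),
         gamma = lapply(cf$gamma, as.numeric))
  })
  names(coefs) <- pnames
  lambda <- lapply(m$lambda[pnames], as.numeric)
  edf <- lapply(m$edf[pnames], as.numeric)
  xlev <- lapply(m$xlevels, as.character)
  structure(list(
    family = m$family,
    spec = spec,
    coefficients = coefs,
    lambda = lambda,
    edf = edf,
    knots = lapply(m$knots, as.numeric),
    xlevels = xlev,
    deviance = m$deviance,
    penalized_deviance = m$penalized_deviance,
    df = m$df,
    n = m$n,
    node_n = m$node_n,
    iterations = m$iterations,
    converged = m$converged,
    comm_log = data.frame(round = integer(0), direction = character(0),
                          kind = character(0), scalars = numeric(0)),
    comm_rounds = m$comm_rounds,
    federated = m$federated,
    call = quote(fg_load_model())
  ), class = "fgamlss")
}
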