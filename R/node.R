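# Node abstraction for federated fitting.
#
# A node holds a private individual-level data table and, after the model
# specification is broadcast, its local design matrices. Every object a node
# emits is forced through a plain numeric "wire" whose payload dimensions
# depend only on the model specification, never on the node's sample size,
# and is recorded in the session communication log.

fg_node_new <- function(id, data) {
  stopifnot(is.data.frame(data))
  node <- new.env(parent = emptyenv())
  node$id <- id
  node$data <- data
  node$n <- nrow(data)
  node$fail_after <- Inf # test hook: simulate node failure after this many calls
  node$calls <- 0L
  node
}

# ---- wire format ------------------------------------------------------------

# Serialize a node payload: only plain double vectors/matrices may cross.
wire_payload <- function(payload) {
  out <- lapply(payload, function(x) {
    if (!is.numeric(x)) {
      stop("wire violation: non-numeric payload element of class ", class(x)[1L],
           call. = FALSE)
    }
    storage.mode(x) <- "double"
    x
  })
  attr(out, "scalar_count") <- sum(vapply(out, length, integer(1)))
  out
}

payload_scalars <- function(payload) attr(payload, "scalar_count")

# ---- session ----------------------------------------------------------------

fg_session_new <- function(node_data, thresholds = fg_thresholds()) {
  if (!length(node_data)) stop("at least one node is required", call. = FALSE)
  if (is.null(names(node_data))) {
    names(node_data) <- paste0("node", seq_along(node_data))
  }
  # deterministic node order: sorted by id, so aggregation is reproducible
  node_data <- node_data[order(names(node_data))]
  session <- new.env(parent = emptyenv())
  session$nodes <- Map(fg_node_new, names(node_data), node_data)
  session$thresholds <- thresholds
  session$round <- 0L
  session$log <- vector("list", 256L)
  session$log_n <- 0L
  session
}

log_entry <- function(session, direction, kind, scalars) {
  session$log_n <- session$log_n + 1L
  if (session$log_n > length(session$log)) {
    length(session$log) <- 2L * length(session$log)
  }
  session$log[[session$log_n]] <- list(round = session$round, direction = direction,
                                       kind = kind, scalars = scalars)
}

comm_log_df <- function(session) {
  entries <- session$log[seq_len(session$log_n)]
  data.frame(
    round = vapply(entries, `[[`, integer(1), "round"),
    direction = vapply(entries, `[[`, character(1), "direction"),
    kind = vapply(entries, `[[`, character(1), "kind"),
    scalars = vapply(entries, `[[`, numeric(1), "scalars")
  )
}

# One client<->nodes exchange: broadcast a request, collect one wire payload
# per node, aggregate. `fn(node)` runs "on the node"; `combine` runs on the
# client (defaults to the additive aggregation).
session_round <- function(session, kind, broadcast_scalars, fn, combine = fg_aggregate) {
  session$round <- session$round + 1L
  log_entry(session, "client->nodes", kind, broadcast_scalars)
  payloads <- lapply(session$nodes, function(node) {
    node$calls <- node$calls + 1L
    if (node$calls > node$fail_after) {
      stop(sprintf("protocol error in round %d: node '%s' failed to respond",
                   session$round, node$id), call. = FALSE)
    }
    p <- withCallingHandlers(
      fn(node),
      error = function(e) {
        stop(sprintf("round %d, node '%s': %s", session$round, node$id,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    p <- wire_payload(p)
    log_entry(session, "node->client", kind, payload_scalars(p))
    p
  })
  combine(payloads)
}

#' Aggregate per-node sufficient statistics
#'
#' Elementwise sum of conformable per-node payloads (weighted cross-products,
#' vectors, scalar aggregates, counts). Addition is associative and
#' commutative up to floating point, which is the entire federation argument:
#' summed node-level cross-products equal the pooled cross-products.
#'
#' @param stats_list List with one named list of numeric arrays per node.
#' @return A single named list of the same shape containing elementwise sums.
#' @export
fg_aggregate <- function(stats_list) {
  stopifnot(length(stats_list) >= 1L)
  first <- stats_list[[1L]]
  for (other in stats_list[-1L]) {
    if (!identical(lapply(first, dim), lapply(other, dim)) ||
        !identical(lengths(first, use.names = FALSE), lengths(other, use.names = FALSE))) {
      stop("protocol error: non-conformable sufficient statistics", call. = FALSE)
    }
  }
  out <- first
  for (nm in names(first)) {
    for (other in stats_list[-1L]) out[[nm]] <- out[[nm]] + other[[nm]]
  }
  out
}

# ---- node-side computations -------------------------------------------------

# schema/metadata message used for harmonization, knots and disclosure checks
node_schema <- function(node, spec) {
  covs <- spec_covariates(spec)
  needed <- c(spec$response, covs)
  missing <- setdiff(needed, names(node$data))
  if (length(missing)) {
    stop(sprintf("harmonization error: node '%s' lacks column(s) %s",
                 node$id, paste(missing, collapse = ", ")), call. = FALSE)
  }
  fac <- covs[vapply(covs, function(v) is.factor(node$data[[v]]) || is.character(node$data[[v]]),
                     logical(1))]
  sm_vars <- unique(vapply(spec_smooths(spec), `[[`, "", "var"))
  list(
    n = node$n,
    factor_levels = lapply(stats::setNames(fac, fac), function(v) {
      tab <- table(as.character(node$data[[v]]))
      stats::setNames(as.numeric(tab), names(tab))
    }),
    smooth_ranges = lapply(stats::setNames(sm_vars, sm_vars), function(v) {
      x <- node$data[[v]]
      if (!is.numeric(x)) stop("smooth covariate '", v, "' is not numeric", call. = FALSE)
      c(min = min(x), max = max(x), n = length(x))
    })
  )
}

# build local design matrices from the broadcast spec, shared knots and levels
node_build <- function(node, spec, knots, xlev) {
  data <- node$data
  for (v in names(xlev)) {
    data[[v]] <- factor(as.character(data[[v]]), levels = xlev[[v]])
  }
  node$y <- data[[spec$response]]
  spec$family$check_y(node$y)
  node$design <- lapply(spec$params, function(p) {
    xl <- xlev[intersect(names(xlev), all.vars(p$lin))]
    mf <- stats::model.frame(p$lin, data, xlev = xl)
    X <- stats::model.matrix(p$lin, mf)
    Z <- lapply(p$smooths, function(s) {
      fg_bspline_basis(data[[s$var]], knots[[s$id]], s$degree)
    })
    list(X = X, Z = Z)
  })
  node$eta <- list()
  node$theta <- list()
  node$wz <- list()
  invisible(node)
}

# predictor of parameter k at given coefficients (node-local)
node_eta <- function(node, k, coef_k) {
  d <- node$design[[k]]
  eta <- drop(d$X %*% coef_k$beta)
  for (j in seq_along(d$Z)) eta <- eta + drop(d$Z[[j]] %*% coef_k$gamma[[j]])
  eta
}

# set the predictor/parameter state for parameter k and return the node's
# global-deviance contribution at the full current state
node_set_state <- function(node, spec, k, coef_k) {
  node$eta[[k]] <- node_eta(node, k, coef_k)
  if (length(node$eta) < spec$family$n_params) {
    # state incomplete during initialization; no deviance yet
    return(list(dev = NA_real_, n = node$n))
  }
  theta <- lapply(names(node$eta), function(kk) {
    spec$family$links[[kk]]$linkinv(node$eta[[kk]])
  })
  names(theta) <- names(node$eta)
  node$theta <- spec$family$clip_theta(theta)
  list(dev = -2 * sum(spec$family$ld(node$y, node$theta)), n = node$n)
}

node_deviance <- function(node, spec) {
  list(dev = -2 * sum(spec$family$ld(node$y, node$theta)), n = node$n)
}

# working response and weights for parameter k at the current state
node_wz <- function(node, spec, k) {
  sw <- spec$family$score_weight(k, node$y, node$theta)
  node$wz[[k]] <- list(w = sw$w, z = node$eta[[k]] + sw$u / sw$w)
  list(ok = 1)
}

# sufficient statistics for one term (0 = linear part, j >= 1 = smooth term)
# against its partial residuals at the supplied coefficients
node_term_stats <- function(node, k, term, coef_k) {
  d <- node$design[[k]]
  wz <- node$wz[[k]]
  eta <- drop(d$X %*% coef_k$beta)
  for (j in seq_along(d$Z)) eta <- eta + drop(d$Z[[j]] %*% coef_k$gamma[[j]])
  C <- if (term == 0L) d$X else d$Z[[term]]
  own <- if (term == 0L) drop(d$X %*% coef_k$beta) else drop(d$Z[[term]] %*% coef_k$gamma[[term]])
  e <- wz$z - eta + own
  Cw <- C * wz$w
  list(CtWC = crossprod(C, Cw), CtWe = drop(crossprod(Cw, e)),
       etWe = sum(wz$w * e * e), n = node$n)
}

# maximum absolute predictor change for backfitting convergence; tracks the
# previous backfitting iterate locally
node_eta_delta <- function(node, k, coef_k) {
  eta_new <- node_eta(node, k, coef_k)
  prev <- if (!is.null(node$bf_eta[[k]])) node$bf_eta[[k]] else node$eta[[k]]
  if (is.null(node$bf_eta)) node$bf_eta <- list()
  node$bf_eta[[k]] <- eta_new
  list(delta = max(abs(eta_new - prev)), n = node$n)
}

node_moments <- function(node, spec) {
  y <- node$data[[spec$response]]
  spec$family$check_y(y)
  list(n = length(y), sum = sum(y), sum_sq = sum(y^2))
}

#' Evaluate disclosure rules for one node
#'
#' A model may only be fitted on a node when the total number of regression
#' coefficients stays below `df_ratio` times the node sample size, every
#' factor category present on the node holds at least `category_min`
#' observations, and the node itself holds at least `k_anonymity`
#' observations.
#'
#' @param total_df Total number of regression coefficients of the model.
#' @param node_meta List with `n` and `factor_levels` (named category-count
#'   vectors), as produced node-side.
#' @param thresholds An [fg_thresholds] object.
#' @return Character vector of violations; empty means pass.
#' @export
fg_disclosure_guard <- function(total_df, node_meta, thresholds = fg_thresholds()) {
  violations <- character(0)
  if (node_meta$n < thresholds$k_anonymity) {
    violations <- c(violations,
                    sprintf("k-anonymity: node has %d observations, threshold %d",
                            node_meta$n, thresholds$k_anonymity))
  }
  if (total_df > thresholds$df_ratio * node_meta$n) {
    violations <- c(violations,
                    sprintf("degrees of freedom: model uses %d coefficients, limit %.1f for %d observations",
                            total_df, thresholds$df_ratio * node_meta$n, node_meta$n))
  }
  for (v in names(node_meta$factor_levels)) {
    counts <- node_meta$factor_levels[[v]]
    low <- counts[counts > 0 & counts < thresholds$category_min]
    if (length(low)) {
      violations <- c(violations,
                      sprintf("category count: '%s' level '%s' has %d observation(s), threshold %d",
                              v, names(low)[1L], as.integer(low[1L]), thresholds$category_min))
    }
  }
  violations
}

# ---- broadcast / harmonization ---------------------------------------------

# Broadcast the model spec: harmonize schemas, pool factor levels, fix shared
# knots (supplied ranges, or the anonymized range in a federated session, or
# the exact pooled range when `anonymize = FALSE`), and run the disclosure
# guard on every node. Returns knots, pooled factor levels and node metadata.
broadcast_spec <- function(session, spec, xranges = NULL, granularity = NULL,
                           anonymize = TRUE) {
  schemas <- lapply(session$nodes, function(node) node_schema(node, spec))
  # pooled factor levels, sorted, for reference-level dummy coding
  fac_names <- unique(unlist(lapply(schemas, function(s) names(s$factor_levels))))
  xlev <- lapply(stats::setNames(fac_names, fac_names), function(v) {
    sort(unique(unlist(lapply(schemas, function(s) names(s$factor_levels[[v]])))))
  })
  total_df <- spec_total_df(spec, xlev)
  for (i in seq_along(schemas)) {
    viol <- fg_disclosure_guard(total_df, schemas[[i]], session$thresholds)
    if (length(viol)) {
      stop(sprintf("disclosure error on node '%s': %s",
                   session$nodes[[i]]$id, paste(viol, collapse = "; ")), call. = FALSE)
    }
  }
  # shared knots per smooth term
  smooths <- spec_smooths(spec)
  knots <- list()
  for (s in smooths) {
    if (!is.null(xranges[[s$var]])) {
      rng <- xranges[[s$var]]
    } else {
      stats_v <- lapply(schemas, function(sc) sc$smooth_ranges[[s$var]])
      rng <- if (anonymize && length(session$nodes) > 1L) {
        fg_anonymized_range(stats_v, granularity = granularity,
                            k_anonymity = session$thresholds$k_anonymity)
      } else {
        c(min(vapply(stats_v, `[[`, numeric(1), "min")),
          max(vapply(stats_v, `[[`, numeric(1), "max")))
      }
    }
    knots[[s$id]] <- fg_default_knots(rng[1], rng[2], s$n_intervals, s$degree)
  }
  for (node in session$nodes) node_build(node, spec, knots, xlev)
  list(knots = knots, xlev = xlev, total_df = total_df,
       node_n = vapply(schemas, `[[`, numeric(1), "n"))
}
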