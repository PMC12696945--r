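# Synthetic-data generators with the statistical structure of the two
# validation use cases: age-specific growth (height) curves and a
# heteroscedastic blood-pressure regression with country-specific variances.
# Every generator stores its generating truth alongside the data so recovery
# tests can compare estimates against it.

#' Simulate study ages
#'
#' Ages are drawn uniformly between 2 and 18 years and rounded to one decimal
#' digit, reflecting how age is recorded in cohort data.
#'
#' @param n Number of ages.
#' @param seed Mandatory integer seed.
#' @return Numeric vector in `[2, 18]` on a 0.1-year grid.
#' @export
fg_sim_ages <- function(n, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  round(stats::runif(n, 2, 18), 1)
}

default_growth_truth <- function(family) {
  truth <- list(
    # smooth, monotone median height in cm with a mild pubertal acceleration
    mu = function(a) 80 + 5.2 * a - 0.05 * a^2 + 12 / (1 + exp(-1.3 * (a - 11)))
  )
  if (family == "NO") {
    truth$sigma <- function(a) 3 + 0.15 * a # absolute SD in cm
  } else {
    truth$sigma <- function(a) 0.05 * exp(-0.02 * a) # coefficient of variation
    truth$nu <- function(a) rep_len(1, length(a))
    if (family == "BCPE") truth$tau <- function(a) rep_len(2, length(a))
  }
  truth
}

split_nodes <- function(df, n_nodes, node_sizes) {
  if (is.null(node_sizes)) {
    base <- nrow(df) %/% n_nodes
    node_sizes <- rep(base, n_nodes)
    node_sizes[n_nodes] <- nrow(df) - base * (n_nodes - 1L)
  }
  stopifnot(sum(node_sizes) == nrow(df))
  idx <- rep(seq_along(node_sizes), node_sizes)
  out <- lapply(seq_along(node_sizes), function(i) df[idx == i, , drop = FALSE])
  names(out) <- sprintf("node%d", seq_along(node_sizes))
  out
}

#' Simulate growth-curve data
#'
#' Heights are sampled at uniformly drawn ages from the chosen response
#' family, with the distribution parameters following smooth functions of
#' age, and the rows are split across nodes.
#'
#' @param n Total number of observations (ignored when `node_sizes` is given).
#' @param family `"NO"`, `"BCCG"` or `"BCPE"`.
#' @param n_nodes Number of nodes for an even split.
#' @param node_sizes Optional explicit per-node sizes (supports uneven splits
#'   such as `c(500, 2000)`).
#' @param seed Mandatory integer seed.
#' @param truth Optional named list of functions of age overriding the
#'   default parameter curves (`mu`, `sigma`, and `nu`/`tau` for the Box-Cox
#'   families).
#' @return An object of class `fg_simdata`: a list with `nodes` (per-node data
#'   frames with columns `age`, `height`), `pooled`, `truth`, `family` and
#'   `seed`.
#' @export
fg_sim_growth <- function(n = 2000, family = c("BCPE", "NO", "BCCG"), n_nodes = 2,
                          node_sizes = NULL, seed, truth = NULL) {
  family <- match.arg(family)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (!is.null(node_sizes)) n <- sum(node_sizes)
  tr <- default_growth_truth(family)
  tr[names(truth)] <- truth
  fam <- fg_family(family)
  sig <- tr$sigma(seq(2, 18, by = 0.1))
  if (any(sig <= 0)) stop("invalid truth: sigma(age) must be positive everywhere", call. = FALSE)
  age <- fg_sim_ages(n, seed) # seeds the stream; height draws continue it
  theta <- list(mu = tr$mu(age), sigma = tr$sigma(age))
  if (family != "NO") theta$nu <- tr$nu(age)
  if (family == "BCPE") theta$tau <- tr$tau(age)
  height <- fam$rfun(n, theta)
  df <- data.frame(age = age, height = height)
  structure(list(nodes = split_nodes(df, n_nodes, node_sizes), pooled = df,
                 truth = tr, family = family, seed = seed, scenario = paste0("growth_", family)),
            class = "fg_simdata")
}

#' Simulate heteroscedastic blood-pressure data
#'
#' Systolic blood pressure (SBP) is generated from
#' `SBP ~ N(b10 + b11 * I(sex == "Female") + b12 * BMI, sigma^2)` with
#' `log(sigma) = b20 + b21 * I(country == "Spain")`. Each node holds one
#' country, mimicking a two-country federation with country-specific residual
#' variances.
#'
#' @param n Total number of observations, split evenly over the nodes unless
#'   `node_sizes` is given.
#' @param n_nodes Number of nodes (= countries).
#' @param node_sizes Optional explicit per-node sizes.
#' @param seed Mandatory integer seed.
#' @param beta Named generating coefficients
#'   `c(mu_intercept, mu_female, mu_bmi, sigma_intercept, sigma_spain)`.
#' @return An `fg_simdata` object; node data frames have columns `sbp`,
#'   `sex`, `bmi`, `country`. `truth$coded` stores the truth in the
#'   reference-level dummy coding the model uses (reference levels `Female`
#'   and `Germany`).
#' @export
fg_sim_sbp <- function(n = 4000, n_nodes = 2, node_sizes = NULL, seed,
                       beta = c(mu_intercept = 80, mu_female = -0.7, mu_bmi = 1.3,
                                sigma_intercept = 2.0, sigma_spain = 0.1)) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (!is.null(node_sizes)) n <- sum(node_sizes)
  set.seed(seed)
  countries <- if (n_nodes == 2L) c("Germany", "Spain") else sprintf("country%02d", seq_len(n_nodes))
  if (is.null(node_sizes)) {
    base <- n %/% n_nodes
    node_sizes <- rep(base, n_nodes)
    node_sizes[n_nodes] <- n - base * (n_nodes - 1L)
  }
  country <- rep(countries, node_sizes)
  sex <- ifelse(stats::runif(n) < 0.5, "Female", "Male")
  bmi <- stats::rlnorm(n, meanlog = log(16.4), sdlog = 0.14)
  mu <- beta[["mu_intercept"]] + beta[["mu_female"]] * (sex == "Female") +
    beta[["mu_bmi"]] * bmi
  # "spain" effect applies to every non-reference country
  sigma <- exp(beta[["sigma_intercept"]] + beta[["sigma_spain"]] * (country != countries[1L]))
  sbp <- stats::rnorm(n, mu, sigma)
  df <- data.frame(sbp = sbp, sex = sex, bmi = bmi, country = country,
                   stringsAsFactors = FALSE)
  coded <- list(
    mu = c("(Intercept)" = unname(beta[["mu_intercept"]] + beta[["mu_female"]]),
           "sexMale" = unname(-beta[["mu_female"]]),
           "bmi" = unname(beta[["mu_bmi"]])),
    sigma = stats::setNames(
      c(unname(beta[["sigma_intercept"]]), rep(unname(beta[["sigma_spain"]]), n_nodes - 1L)),
      c("(Intercept)", paste0("country", countries[-1L]))
    )
  )
  structure(list(nodes = split_nodes(df, n_nodes, node_sizes), pooled = df,
                 truth = list(beta = beta, coded = coded), family = "NO",
                 seed = seed, scenario = "sbp_hetero"),
            class = "fg_simdata")
}

#' Write simulated node data to CSV files
#'
#' One CSV per node plus a JSON truth record.
#'
#' @param sim An `fg_simdata` object.
#' @param dir Output directory (created if missing).
#' @return Character vector of the node CSV paths, invisibly.
#' @export
fg_write_simdata <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(sim$nodes), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(sim$nodes[[nm]], p, row.names = FALSE, quote = FALSE)
    p
  }, character(1))
  truth <- sim$truth
  # store function-valued truth as deparsed text
  truth <- lapply(truth, function(x) if (is.function(x)) deparse1(body(x)) else x)
  jsonlite::write_json(list(scenario = sim$scenario, family = sim$family,
                            seed = sim$seed, truth = truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
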