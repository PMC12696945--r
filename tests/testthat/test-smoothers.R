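test_that("B-spline basis matches the Cox-de Boor recursion", {
  set.seed(5)
  for (degree in 0:3) {
    kn <- fg_default_knots(0, 1, 7, degree)
    x <- runif(10, 0, 0.999) # recursion's half-open intervals exclude the right end
    B <- fg_bspline_basis(x, kn, degree)
    B_oracle <- cox_de_boor_basis(x, kn, degree)
    expect_lt(max(abs(B - B_oracle)), 1e-12)
    # partition of unity and local support
    expect_equal(rowSums(B), rep(1, length(x)), tolerance = 1e-12)
    expect_true(all(B >= 0 & B <= 1))
    expect_true(all(rowSums(B > 0) <= degree + 1))
  }
})

test_that("degree-0 basis is the interval indicator", {
  expect_equal(fg_bspline_basis(0.5, c(0, 1, 2), degree = 0),
               matrix(c(1, 0), nrow = 1))
})

test_that("basis evaluation outside the knot domain is an error", {
  kn <- fg_default_knots(2, 18, 4, 3)
  expect_error(fg_bspline_basis(c(5, 19), kn, 3), "19")
  expect_error(fg_bspline_basis(1.5, kn, 3), "domain")
})

test_that("difference penalty has the documented structure", {
  G <- fg_diff_penalty(4, 2)
  expect_equal(G, matrix(c(1, -2, 1, 0,
                           -2, 5, -4, 1,
                           1, -4, 5, -2,
                           0, 1, -2, 1), 4, 4, byrow = TRUE))
  # second differences of a line vanish
  g <- seq(3, 30, length.out = 11)
  G11 <- fg_diff_penalty(11, 2)
  expect_lt(drop(crossprod(g, G11 %*% g)), 1e-20)
  expect_equal(qr(fg_diff_penalty(23, 2))$rank, 21)
  # quadratic form equals the sum of squared order-th differences
  set.seed(2)
  for (ord in 1:3) {
    g <- rnorm(12)
    Go <- fg_diff_penalty(12, ord)
    expect_equal(drop(crossprod(g, Go %*% g)), sum(diff(g, differences = ord)^2),
                 tolerance = 1e-12)
  }
  expect_error(fg_diff_penalty(3, 3), "order")
})

test_that("default knots are equally spaced with the right counts", {
  kn <- fg_default_knots(2, 18, 20, 3)
  expect_length(kn, 27)
  expect_equal(length(kn) - 3 - 1, 23) # basis dimension
  expect_equal(fg_default_knots(2, 18, 4, 0), c(2, 6, 10, 14, 18))
  expect_length(fg_default_knots(0, 1, 1, 1), 4)
  expect_equal(diff(kn), rep(0.8, 26), tolerance = 1e-12)
  expect_error(fg_default_knots(5, 5, 10, 3), "xmin")
})

test_that("anonymized range covers and coarsens the pooled range", {
  expect_equal(fg_anonymized_range(list(c(min = 2.0, max = 17.9, n = 1258),
                                        c(min = 2.3, max = 15.0, n = 806)),
                                   granularity = 0.5),
               c(2.0, 18.0))
  expect_equal(fg_anonymized_range(list(c(min = 0, max = 10, n = 100)),
                                   granularity = 1),
               c(0, 10))
  expect_error(fg_anonymized_range(list(c(min = 0, max = 10, n = 2)), granularity = 1,
                                   k_anonymity = 3),
               "disclosure")
  # property: output always widens the pooled range to grid multiples
  set.seed(8)
  for (i in 1:25) {
    stats_i <- lapply(1:3, function(j) {
      lo <- runif(1, -5, 5); c(min = lo, max = lo + runif(1, 0.1, 20), n = 50)
    })
    g <- runif(1, 0.05, 2)
    rng <- fg_anonymized_range(stats_i, granularity = g)
    lo <- min(vapply(stats_i, `[[`, numeric(1), "min"))
    hi <- max(vapply(stats_i, `[[`, numeric(1), "max"))
    expect_lte(rng[1], lo + 1e-9)
    expect_gte(rng[2], hi - 1e-9)
    expect_lt(abs(rng[1] / g - round(rng[1] / g)), 1e-6)
    expect_lt(abs(rng[2] / g - round(rng[2] / g)), 1e-6)
  }
})

test_that("local-ML smoothing parameter tracks the REML grid oracle", {
  set.seed(99)
  n <- 500
  x <- sort(runif(n, 0, 1))
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.3)
  kn <- fg_default_knots(0, 1, 12, 3)
  Z <- fg_bspline_basis(x, kn, 3)
  q <- ncol(Z)
  G <- fg_diff_penalty(q, 2)
  ZtWZ <- crossprod(Z)
  ZtWe <- drop(crossprod(Z, y))
  etWe <- sum(y^2)
  res <- fg_lambda_ml(ZtWZ, ZtWe, etWe, G, n_eff = n, order = 2, lambda = 1)
  # independent oracle: profile (restricted) likelihood on a 50-point log grid
  m <- 2
  reml <- function(lam) {
    H <- ZtWZ + lam * G
    g <- solve(H, ZtWe)
    S <- etWe - 2 * sum(g * ZtWe) + drop(crossprod(g, ZtWZ %*% g)) +
      lam * drop(crossprod(g, G %*% g))
    -((n - m) * log(S) - (q - m) * log(lam) + determinant(H)$modulus)
  }
  grid <- 10^seq(-4, 6, length.out = 50)
  lam_star <- grid[which.max(vapply(grid, reml, numeric(1)))]
  expect_gt(res$lambda / lam_star, 0.5)
  expect_lt(res$lambda / lam_star, 2)
  expect_gte(res$edf, 2)
})

test_that("null-space coefficients cap the smoothing parameter", {
  # partial residuals that are exactly linear in the basis: gamma lands in the
  # penalty null space, lambda must be capped at its maximum with a warning
  kn <- fg_default_knots(0, 1, 8, 3)
  x <- seq(0.01, 0.99, length.out = 200)
  Z <- fg_bspline_basis(x, kn, 3)
  e <- 2 + 3 * x
  G <- fg_diff_penalty(ncol(Z), 2)
  expect_warning(
    res <- fg_lambda_ml(crossprod(Z), drop(crossprod(Z, e)), sum(e^2), G,
                        n_eff = length(x), order = 2, lambda = 1),
    "capped"
  )
  expect_equal(res$lambda, 1e7)
})
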