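test_that("global deviance matches closed forms and is additive", {
  no <- fg_family("NO")
  expect_equal(fg_global_deviance(no, 1, list(mu = 1, sigma = 1)), log(2 * pi),
               tolerance = 1e-9)
  expect_equal(fg_global_deviance(no, c(0, 1, 2), list(mu = 1, sigma = 1)),
               3 * log(2 * pi) + 2, tolerance = 1e-9)
  # additivity over a partition of the data
  set.seed(1)
  y <- rnorm(40, 5, 2)
  th <- list(mu = 5, sigma = 2)
  expect_equal(fg_global_deviance(no, y, th),
               fg_global_deviance(no, y[1:15], th) + fg_global_deviance(no, y[16:40], th))
})

test_that("penalized WLS solve matches a brute-force oracle", {
  expect_equal(fg_pwls_solve(diag(2), c(1, 2)), c(1, 2))
  set.seed(3)
  X <- matrix(rnorm(100), 20, 5)
  w <- runif(20, 0.5, 2)
  z <- rnorm(20)
  G <- fg_diff_penalty(5, 2)
  CtWC <- crossprod(X, X * w)
  CtWz <- drop(crossprod(X * w, z))
  ours <- fg_pwls_solve(CtWC, CtWz, penalty = 1 * G)
  # independent dense normal-equations solve with explicit matrices
  W <- diag(w)
  oracle <- solve(t(X) %*% W %*% X + G) %*% t(X) %*% W %*% z
  expect_lt(max(abs(ours - drop(oracle))), 1e-10)
})

test_that("an infinite penalty shrinks the smooth to its null space (a line)", {
  set.seed(4)
  x <- runif(300, 0, 1)
  z <- 1 + 2 * x + rnorm(300, 0, 0.1)
  kn <- fg_default_knots(0, 1, 8, 3)
  Z <- fg_bspline_basis(x, kn, 3)
  G <- fg_diff_penalty(ncol(Z), 2)
  gam <- fg_pwls_solve(crossprod(Z), drop(crossprod(Z, z)), penalty = 1e12 * G)
  fitted_spline <- drop(Z %*% gam)
  fitted_line <- stats::fitted(stats::lm(z ~ x))
  expect_lt(max(abs(fitted_spline - fitted_line)), 1e-4)
})

test_that("rank-deficient systems fail loudly with column names", {
  X <- cbind(a = c(1, 1, 1), b = c(2, 2, 2)) # collinear
  CtWC <- crossprod(X)
  expect_error(fg_pwls_solve(CtWC, drop(crossprod(X, c(1, 2, 3)))), "collinear")
})

test_that("a Gaussian linear model reproduces the OLS/ML closed form", {
  d <- data.frame(x = c(0, 1, 2), y = c(0, 1, 3))
  m <- fgamlss(y ~ x, family = "NO", data = d, control = fg_control(outer_tol = 1e-9))
  cf <- coef(m)
  expect_equal(unname(cf["mu.(Intercept)"]), -1 / 6, tolerance = 1e-6)
  expect_equal(unname(cf["mu.x"]), 3 / 2, tolerance = 1e-6)
  expect_equal(exp(unname(cf["sigma.(Intercept)"])), sqrt(1 / 18), tolerance = 1e-5)
})

test_that("heteroscedastic Gaussian fit matches the alternating GLS/ML oracle", {
  sim <- fg_sim_sbp(n = 1200, seed = 55)
  d <- sim$pooled
  m <- fgamlss(sbp ~ sex + bmi, sigma.formula = ~country, family = "NO", data = d,
               control = fg_control(outer_tol = 1e-9, inner_tol = 1e-9))
  # oracle: exact GLS for the mean and exact per-group variance MLE, alternated
  X <- stats::model.matrix(~ sex + bmi, d)
  grp <- d$country == "Spain"
  s2 <- c(stats::var(d$sbp), stats::var(d$sbp))
  b <- NULL
  for (i in 1:200) {
    w <- ifelse(grp, 1 / s2[2], 1 / s2[1])
    b_new <- solve(crossprod(X, X * w), crossprod(X * w, d$sbp))
    r <- d$sbp - drop(X %*% b_new)
    s2_new <- c(mean(r[!grp]^2), mean(r[grp]^2))
    if (!is.null(b) && max(abs(b_new - b)) < 1e-13 && max(abs(s2_new - s2)) < 1e-13) break
    b <- b_new; s2 <- s2_new
  }
  cf <- coef(m)
  expect_equal(unname(cf[1:3]), drop(b), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(cf["sigma.(Intercept)"]), log(sqrt(s2[1])), tolerance = 1e-6)
  expect_equal(unname(cf["sigma.countrySpain"]), log(sqrt(s2[2] / s2[1])), tolerance = 1e-6)
})

test_that("penalized deviance is non-increasing across accepted steps", {
  # without smooth terms the penalized deviance is the global deviance
  tr <- sbp_fits()$pooled$penalized_deviance_trace
  expect_gt(length(tr), 3)
  expect_true(all(diff(tr) <= 1e-8))
  # with fixed smoothing parameters the step control guarantees descent of
  # the penalized deviance (estimated lambdas change the objective itself)
  g <- fg_sim_growth(n = 600, family = "BCPE", seed = 67)
  m <- suppressWarnings(
    fgamlss(height ~ age + pb(age, lambda = 10, n_intervals = 10),
            sigma.formula = ~ age + pb(age, lambda = 10, n_intervals = 10),
            nu.formula = ~1, tau.formula = ~1, family = "BCPE",
            data = g$pooled, xranges = list(age = c(2, 18))))
  tr <- m$penalized_deviance_trace
  expect_gt(length(tr), 5)
  expect_true(all(diff(tr) <= 1e-8))
})

test_that("estimates are invariant to observation order", {
  g <- fg_sim_growth(n = 500, family = "NO", seed = 23)
  d <- g$pooled
  set.seed(77)
  d2 <- d[sample(nrow(d)), ]
  ctl <- fg_control()
  m1 <- suppressWarnings(fgamlss(height ~ age + pb(age, n_intervals = 10),
                                 sigma.formula = ~age, family = "NO", data = d,
                                 xranges = list(age = c(2, 18)), control = ctl))
  m2 <- suppressWarnings(fgamlss(height ~ age + pb(age, n_intervals = 10),
                                 sigma.formula = ~age, family = "NO", data = d2,
                                 xranges = list(age = c(2, 18)), control = ctl))
  expect_lt(max(abs(coef_vector(m1) - coef_vector(m2))), 1e-10)
})

test_that("a huge fixed lambda reduces the smooth to the linear-terms fit", {
  g <- fg_sim_growth(n = 800, family = "NO", seed = 31)
  m_pb <- suppressWarnings(
    fgamlss(height ~ age + pb(age, lambda = 1e12), sigma.formula = ~age,
            family = "NO", data = g$pooled, xranges = list(age = c(2, 18))))
  m_lin <- fgamlss(height ~ age, sigma.formula = ~age, family = "NO", data = g$pooled)
  grid <- data.frame(age = seq(3, 17, length.out = 30))
  expect_lt(max(abs(predict(m_pb, grid)$mu - predict(m_lin, grid)$mu)), 1e-3)
})

test_that("simulation truth is recovered on growth data", {
  # normal growth model: fitted mean curve within 2% of truth
  gno <- growth_no_fit()
  grid <- data.frame(age = seq(2.5, 17.5, length.out = 20))
  mu_hat <- predict(gno$fit, grid)$mu
  expect_lt(max(abs(mu_hat / gno$sim$truth$mu(grid$age) - 1)), 0.02)
  # four-parameter BCPE growth model: fitted median within 1% of the true median
  fits <- growth_bcpe_fits()
  med_hat <- fg_centiles(fits$pooled, grid, probs = 0.5)$p50
  fam <- fg_family("BCPE")
  med_true <- fam$qfun(rep(0.5, nrow(grid)), list(
    mu = fits$sim$truth$mu(grid$age), sigma = fits$sim$truth$sigma(grid$age),
    nu = fits$sim$truth$nu(grid$age), tau = fits$sim$truth$tau(grid$age)))
  expect_lt(max(abs(med_hat / med_true - 1)), 0.01)
})

test_that("misuse fails early", {
  d <- data.frame(x = 1:2, y = c(1.0, 2.0))
  expect_error(fgamlss(y ~ x, sigma.formula = ~x, family = "NO", data = d),
               "insufficient data")
  g <- fg_sim_growth(n = 200, family = "NO", seed = 2)
  expect_warning(
    fgamlss(height ~ age + pb(age, n_intervals = 8), family = "NO",
            data = g$pooled, xranges = list(age = c(2, 18)),
            control = fg_control(max_outer = 1)),
    "converge")
})
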