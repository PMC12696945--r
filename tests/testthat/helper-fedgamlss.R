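# Shared helpers: independent oracles and cached expensive fits.

# finite-difference score oracle on the predictor scale
fd_score <- function(fam, k, y, theta, h = 1e-5) {
  lk <- fam$links[[k]]
  eta <- lk$linkfun(theta[[k]])
  up <- theta; up[[k]] <- lk$linkinv(eta + h)
  dn <- theta; dn[[k]] <- lk$linkinv(eta - h)
  (fam$ld(y, up) - fam$ld(y, dn)) / (2 * h)
}

# independent Cox-de Boor recursion for a single B-spline basis function
cox_de_boor <- function(x, knots, i, degree) {
  if (degree == 0) {
    return(as.numeric(x >= knots[i] & x < knots[i + 1]))
  }
  d1 <- knots[i + degree] - knots[i]
  d2 <- knots[i + degree + 1] - knots[i + 1]
  a <- if (d1 > 0) (x - knots[i]) / d1 * cox_de_boor(x, knots, i, degree - 1) else 0
  b <- if (d2 > 0) (knots[i + degree + 1] - x) / d2 * cox_de_boor(x, knots, i + 1, degree - 1) else 0
  a + b
}

cox_de_boor_basis <- function(x, knots, degree) {
  q <- length(knots) - degree - 1
  sapply(seq_len(q), function(i) cox_de_boor(x, knots, i, degree))
}

# two-piece numeric integral of a positive-support density around its center
integrate_density <- function(fam, theta, center) {
  f <- function(y) exp(fam$ld(y, theta))
  stats::integrate(f, 0, center, rel.tol = 1e-9)$value +
    stats::integrate(f, center, Inf, rel.tol = 1e-9)$value
}

# flatten all regression coefficients (linear and spline) of a fit
coef_vector <- function(m) {
  unlist(lapply(m$coefficients, function(cf) c(cf$beta, unlist(cf$gamma))))
}

# expensive fits shared across test files (computed once per test run)
.fit_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fit_cache[[name]])) .fit_cache[[name]] <- force(expr)
  .fit_cache[[name]]
}

growth_bcpe_sim <- function() {
  cached("growth_bcpe_sim", fg_sim_growth(n = 2000, family = "BCPE", seed = 301))
}

growth_bcpe_fits <- function() {
  cached("growth_bcpe_fits", {
    g <- growth_bcpe_sim()
    fml <- list(height ~ age + pb(age), ~ age + pb(age), ~ age + pb(age), ~ age + pb(age))
    pooled <- suppressWarnings(
      fgamlss(fml[[1]], sigma.formula = fml[[2]], nu.formula = fml[[3]],
              tau.formula = fml[[4]], family = "BCPE", data = g$pooled,
              xranges = list(age = c(2, 18))))
    fed <- suppressWarnings(
      fgamlss_fed(fml[[1]], sigma.formula = fml[[2]], nu.formula = fml[[3]],
                  tau.formula = fml[[4]], family = "BCPE", nodes = g$nodes,
                  xranges = list(age = c(2, 18))))
    list(pooled = pooled, fed = fed, sim = g)
  })
}

sbp_fits <- function() {
  cached("sbp_fits", {
    sim <- fg_sim_sbp(n = 4000, seed = 1001)
    pooled <- fgamlss(sbp ~ sex + bmi, sigma.formula = ~country, family = "NO",
                      data = sim$pooled)
    fed <- fgamlss_fed(sbp ~ sex + bmi, sigma.formula = ~country, family = "NO",
                       nodes = sim$nodes)
    list(pooled = pooled, fed = fed, sim = sim)
  })
}

growth_no_fit <- function() {
  cached("growth_no_fit", {
    g <- fg_sim_growth(n = 1000, family = "NO", seed = 17)
    fit <- suppressWarnings(
      fgamlss(height ~ age + pb(age), sigma.formula = ~ age + pb(age),
              family = "NO", data = g$pooled, xranges = list(age = c(2, 18))))
    list(fit = fit, sim = g)
  })
}
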