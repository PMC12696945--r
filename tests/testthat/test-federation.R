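test_that("aggregation is an elementwise sum with protocol checks", {
  # toy: two single-observation nodes with unit design and weight
  a <- list(CtWC = matrix(1), CtWe = 3, n = 1)
  b <- list(CtWC = matrix(1), CtWe = 5, n = 1)
  agg <- fg_aggregate(list(a, b))
  expect_equal(drop(agg$CtWC), 2)
  expect_equal(agg$CtWe, 8)
  expect_equal(agg$n, 2)
  # identity, commutativity, associativity (4-way vs 2-way regrouping)
  expect_equal(fg_aggregate(list(a)), a)
  expect_equal(fg_aggregate(list(b, a)), agg)
  parts <- list(a, b, a, b)
  expect_equal(fg_aggregate(parts),
               fg_aggregate(list(fg_aggregate(parts[1:2]), fg_aggregate(parts[3:4]))))
  expect_error(fg_aggregate(list(a, list(CtWC = diag(2), CtWe = 1:2, n = 1))),
               "conformable")
})

test_that("per-node sufficient statistics sum to the pooled cross-products", {
  g <- fg_sim_growth(n = 400, family = "NO", seed = 12)
  spec <- fg_spec(height ~ age + pb(age, n_intervals = 8), sigma.formula = ~age,
                  family = "NO")
  build <- function(node_data) {
    ses <- fedgamlss:::fg_session_new(node_data, fg_thresholds())
    fedgamlss:::broadcast_spec(ses, spec, xranges = list(age = c(2, 18)))
    # put every node in the same parameter state
    di <- lapply(ses$nodes[[1]]$design, function(d) {
      list(beta = numeric(ncol(d$X)), gamma = lapply(d$Z, function(z) numeric(ncol(z))))
    })
    di$mu$beta[1] <- 120
    di$sigma$beta[1] <- log(15)
    for (node in ses$nodes) {
      for (k in c("mu", "sigma")) fedgamlss:::node_set_state(node, spec, k, di[[k]])
      fedgamlss:::node_wz(node, spec, "mu")
    }
    list(session = ses, coef = di)
  }
  pooled <- build(list(all = g$pooled))
  split2 <- build(g$nodes)
  for (term in 0:1) {
    st_pooled <- fedgamlss:::node_term_stats(pooled$session$nodes[[1]], "mu", term,
                                             pooled$coef$mu)
    st_split <- fg_aggregate(lapply(split2$session$nodes, fedgamlss:::node_term_stats,
                                    "mu", term, split2$coef$mu))
    expect_lt(max(abs(st_pooled$CtWC - st_split$CtWC)) / max(abs(st_pooled$CtWC)), 1e-12)
    expect_lt(max(abs(st_pooled$CtWe - st_split$CtWe)) / max(abs(st_pooled$CtWe)), 1e-12)
    expect_equal(st_pooled$n, st_split$n)
  }
})

test_that("disclosure guard enforces every rule", {
  meta_ok <- list(n = 1000, factor_levels = list(sex = c(Female = 500, Male = 500)))
  expect_length(fg_disclosure_guard(20, meta_ok, fg_thresholds(df_ratio = 0.33)), 0)
  expect_match(fg_disclosure_guard(400, meta_ok, fg_thresholds(df_ratio = 0.33)),
               "degrees of freedom")
  meta_sparse <- list(n = 1000, factor_levels = list(sex = c(Female = 998, Other = 2)))
  expect_match(fg_disclosure_guard(20, meta_sparse, fg_thresholds(category_min = 3)),
               "category count")
  meta_small <- list(n = 2, factor_levels = list())
  expect_match(fg_disclosure_guard(1, meta_small, fg_thresholds(k_anonymity = 3))[1],
               "k-anonymity")
  # zero-count categories (level absent from a node) are not violations
  meta_zero <- list(n = 1000, factor_levels = list(country = c(Germany = 1000, Spain = 0)))
  expect_length(fg_disclosure_guard(20, meta_zero, fg_thresholds()), 0)
})

test_that("broadcast rejects schema mismatch and sparse categories", {
  sim <- fg_sim_sbp(n = 400, seed = 9)
  nodes_bad <- sim$nodes
  nodes_bad$node2$bmi <- NULL
  expect_error(
    fgamlss_fed(sbp ~ sex + bmi, sigma.formula = ~country, family = "NO",
                nodes = nodes_bad),
    "harmonization error.*node2.*bmi")
  nodes_sparse <- sim$nodes
  nodes_sparse$node1$sex[1:2] <- "Diverse"
  nodes_sparse$node1$sex[3:200] <- "Male"
  expect_error(
    fgamlss_fed(sbp ~ sex + bmi, sigma.formula = ~country, family = "NO",
                nodes = nodes_sparse),
    "disclosure error.*category count")
  expect_error(
    fgamlss_fed(sbp ~ sex + bmi, sigma.formula = ~country, family = "NO",
                nodes = sim$nodes, thresholds = fg_thresholds(df_ratio = 0.001)),
    "disclosure error.*degrees of freedom")
})

test_that("a single-node federated fit equals the pooled fit", {
  sim <- fg_sim_sbp(n = 600, seed = 41)
  mp <- fgamlss(sbp ~ sex + bmi, sigma.formula = ~country, family = "NO",
                data = sim$pooled)
  m1 <- fgamlss_fed(sbp ~ sex + bmi, sigma.formula = ~country, family = "NO",
                    nodes = list(all = sim$pooled))
  expect_lt(max(abs(coef(mp) - coef(m1))), 1e-12)
})

test_that("even and uneven splits reproduce the pooled estimates", {
  sim <- fg_sim_sbp(n = 600, seed = 42)
  d <- sim$pooled
  mp <- fgamlss(sbp ~ sex + bmi, sigma.formula = ~country, family = "NO", data = d)
  for (sizes in list(c(300, 300), c(150, 450), c(100, 200, 300))) {
    idx <- rep(seq_along(sizes), sizes)
    nodes <- split(d, idx)
    names(nodes) <- paste0("node", seq_along(sizes))
    mf <- fgamlss_fed(sbp ~ sex + bmi, sigma.formula = ~country, family = "NO",
                      nodes = nodes)
    expect_lt(max(abs(coef(mp) - coef(mf))), 1e-10)
  }
})

test_that("payload sizes are bounded and independent of node sample size", {
  run <- function(n) {
    sim <- fg_sim_sbp(n = n, seed = 5)
    fgamlss_fed(sbp ~ sex + bmi, sigma.formula = ~country, family = "NO",
                nodes = sim$nodes)
  }
  m1 <- run(400)
  m2 <- run(1600)
  up1 <- subset(m1$comm_log, direction == "node->client")
  up2 <- subset(m2$comm_log, direction == "node->client")
  max_df <- 3 # largest term dimension (mu linear part)
  expect_true(all(up1$scalars <= max_df^2 + max_df + 3))
  # the set of payload sizes per message kind does not depend on n
  sizes1 <- tapply(up1$scalars, up1$kind, function(s) sort(unique(s)))
  sizes2 <- tapply(up2$scalars, up2$kind, function(s) sort(unique(s)))
  expect_identical(sizes1[order(names(sizes1))], sizes2[order(names(sizes2))])
})

test_that("a failing node aborts with a protocol error naming the round", {
  sim <- fg_sim_sbp(n = 400, seed = 6)
  spec <- fg_spec(sbp ~ sex + bmi, sigma.formula = ~country, family = "NO")
  ses <- fedgamlss:::fg_session_new(sim$nodes, fg_thresholds())
  ses$nodes[[2]]$fail_after <- 5
  expect_error(fedgamlss:::fg_rs_fit(ses, spec), "protocol error in round \\d+.*node2")
})

test_that("only plain numeric payloads can cross the wire", {
  expect_error(fedgamlss:::wire_payload(list(ok = 1, bad = "secret")), "wire violation")
  p <- fedgamlss:::wire_payload(list(A = diag(2), b = c(1, 2)))
  expect_equal(attr(p, "scalar_count"), 6)
})
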