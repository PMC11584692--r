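# independent brute-force PRCC oracle: residual correlation from explicit
# rank regressions
bruteForcePRCC <- function(X, y) {
  R <- as.data.frame(apply(X, 2, rank))
  names(R) <- paste0("x", seq_len(ncol(X)))
  ry <- rank(y)
  vapply(seq_len(ncol(X)), function(j) {
    others <- R[, -j, drop = FALSE]
    e1 <- if (ncol(others)) stats::resid(stats::lm(R[, j] ~ ., data = others))
          else R[, j] - mean(R[, j])
    e2 <- if (ncol(others)) stats::resid(stats::lm(ry ~ ., data = others))
          else ry - mean(ry)
    stats::cor(e1, e2)
  }, numeric(1))
}

test_that("LHS sampling is stratified, bounded and reproducible", {
  d <- lhsSample("p1", 4, 0.5, 2, seed = 3)
  s <- sort(d@multipliers[, 1])
  breaks <- seq(0.5, 2, length.out = 5)
  expect_true(all(s >= breaks[-5] & s <= breaks[-1]))
  d2 <- lhsSample("p1", 4, 0.5, 2, seed = 3)
  expect_identical(d@multipliers, d2@multipliers)
  expect_error(lhsSample("p1", 4, 2, 0.5), "low")
  # distributional check: per-column KS distance to Uniform(0.5, 2)
  d3 <- lhsSample(c("a", "b", "c"), 1000, seed = 5)
  for (j in 1:3) {
    ks <- suppressWarnings(
      stats::ks.test(d3@multipliers[, j], "punif", 0.5, 2))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("PRCC identifies perfect and absent dependence", {
  d <- lhsSample(c("a", "b", "c"), 100, seed = 9)
  y <- d@multipliers[, 1]
  res <- prcc(d, cbind(out = y))
  expect_gt(res@prcc["a", "out"], 0.99)
  expect_lt(max(abs(res@prcc[c("b", "c"), "out"])), 0.2)
  # constant output: PRCC defined as 0 with p = 1
  expect_message(res0 <- prcc(d, cbind(out = rep(1, 100))), "constant")
  expect_equal(unname(res0@prcc[, "out"]), c(0, 0, 0))
  expect_equal(unname(res0@pValues[, "out"]), c(1, 1, 1))
})

test_that("PRCC matches the brute-force rank-regression oracle", {
  set.seed(21)
  for (k in c(2, 3, 5)) {
    n <- 150
    d <- lhsSample(paste0("p", 1:k), n, seed = k)
    X <- d@multipliers
    y <- 2 * rank(X[, 1]) - rank(X[, 2]) + stats::rnorm(n, 0, 5)
    res <- prcc(d, cbind(out = y))
    oracle <- bruteForcePRCC(X, y)
    expect_equal(unname(res@prcc[, "out"]), oracle, tolerance = 1e-6)
    expect_gt(res@prcc["p1", "out"], 0)
    expect_lt(res@prcc["p2", "out"], 0)
  }
})

test_that("PRCC is invariant under monotone input transforms", {
  d <- lhsSample(c("a", "b"), 120, seed = 2)
  X <- d@multipliers
  y <- X[, 1]^2 + 0.2 * X[, 2]
  r1 <- prcc(d, cbind(out = y))
  d2 <- d
  d2@multipliers[, 1] <- exp(3 * X[, 1])  # strictly monotone transform
  r2 <- prcc(d2, cbind(out = y))
  expect_equal(r1@prcc, r2@prcc, tolerance = 1e-10)
})

test_that("null outputs keep PRCC within the 3/sqrt(n) calibration band", {
  set.seed(33)
  d <- lhsSample(paste0("p", 1:4), 400, seed = 10)
  y <- stats::rnorm(400)
  res <- prcc(d, cbind(out = y))
  expect_lt(max(abs(res@prcc[, "out"])), 3 / sqrt(400))
})

test_that("target ranking sorts by |PRCC| with significance gating", {
  res <- new("SensitivityResult", parameterIds = c("a", "b", "c"),
             outputIds = "out",
             prcc = matrix(c(0.9, -0.95, 0.1), 3, 1,
                           dimnames = list(c("a", "b", "c"), "out")),
             pValues = matrix(c(0.001, 0.001, 0.6), 3, 1,
                              dimnames = list(c("a", "b", "c"), "out")),
             pAdjusted = matrix(c(0.001, 0.001, 0.6), 3, 1,
                                dimnames = list(c("a", "b", "c"), "out")),
             nSamples = 100L)
  rt <- rankTargets(res, "out")
  expect_identical(rt$parameter, c("b", "a"))
  # all p >= alpha -> empty ranking
  res@pValues[] <- 0.5
  expect_equal(nrow(rankTargets(res, "out")), 0)
  expect_error(rankTargets(res, "nope"), "unknown output")
})

test_that("an all-ones multiplier row reproduces the unperturbed run", {
  m <- defaultModel()
  d <- lhsSample(c("kt_Succinate", "kd_ROS"), 2, seed = 1)
  d@multipliers[1, ] <- 1
  out <- evaluateDesign(m$network, m$params, d, state = m$state)
  tr <- cachedOGDR()
  expect_equal(unname(out[1, "cell_function"]),
               endpointCF(cellFunctionScore(tr)), tolerance = 1e-8)
  expect_equal(unname(out[1, "inflammation"]),
               moduleOutput(tr, "inflammation")[sum(tr@times <= 30)],
               tolerance = 1e-8)
})

test_that("design evaluation matches closed-form outputs on a toy model", {
  # decay-only species: endpoint = A0 * exp(-kd * m * t) for multiplier m
  net <- toyDecayNetwork(kd = 0.1, A0 = 1)
  d <- lhsSample("kd_A", 8, seed = 4)
  proto <- stimulusProtocol(protocolPhase("obs", 10), preEquilibration = 0)
  outs <- matrix(NA_real_, 8, 1)
  for (i in 1:8) {
    p <- scaleParameters(defaultParameters(net), d@multipliers[i, ])
    tr <- runProtocol(net, p, initialState(net), proto)
    outs[i] <- tr@amounts[nrow(tr@amounts), "A"]
  }
  expect_equal(as.numeric(outs),
               exp(-0.1 * d@multipliers[, 1] * 10), tolerance = 1e-6)
})

test_that("succinate turnover ranks among the top OGD/R sensitivities", {
  m <- defaultModel()
  ids <- c("kt_Succinate", "kd_Succinate", "kp_IKK_ROS", "kp_NFkB",
           "kt_IkB", "kd_IkB_mRNA", "kt_HIF1a", "kon_HIF1a", "koh_HIF2a",
           "kin_HIF2a", "kt_p53_HIF", "kt_Casp3", "kd_ROS", "kox_BH4",
           "kt_ZO1", "kd_ZO1_ROS", "kt_IL6", "kd_IL6", "kt_Ang2", "kp_AKT")
  d <- lhsSample(ids, 200, seed = 7)
  outs <- evaluateDesign(m$network, m$params, d, state = m$state)
  res <- prcc(d, outs)
  topInflam <- rankTargets(res, "inflammation", 10)$parameter
  topTJ <- rankTargets(res, "tight_junction", 10)$parameter
  topGrowth <- rankTargets(res, "growth", 10)$parameter
  expect_true("kt_Succinate" %in% topInflam)
  expect_true(all(c("kt_Succinate", "kd_Succinate") %in% topTJ))
  # HIF2 loading parameters dominate the growth-factor output
  expect_true(any(c("kin_HIF2a", "koh_HIF2a") %in% topGrowth))
})
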