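baselineMarkers <- function() {
  stats::setNames(rep(1, length(markerIds())), markerIds())
}

test_that("module outputs are normalized marker products", {
  base <- baselineMarkers()
  # all markers at baseline -> output identically 1
  tr <- syntheticTrajectory(base)
  expect_equal(moduleOutput(tr, "inflammation", base), rep(1, 3))
  expect_equal(moduleOutput(tr, "growth", base), rep(1, 3))
  # a single doubled factor doubles the product
  v <- base; v["IL6"] <- 2
  expect_equal(moduleOutput(syntheticTrajectory(v), "inflammation", base),
               rep(2, 3))
  # hand product 2 * 3 * 0.5 = 3
  v <- base; v["IL6"] <- 2; v["IL1b"] <- 3; v["CCL2"] <- 0.5
  expect_equal(moduleOutput(syntheticTrajectory(v), "inflammation", base),
               rep(3, 3))
  # missing marker is named
  expect_error(moduleOutput(syntheticTrajectory(base[-1]), "inflammation",
                            base), "IL6")
})

test_that("cell-function score follows the product law", {
  base <- baselineMarkers()
  sc <- cellFunctionScore(syntheticTrajectory(base), base)
  expect_equal(sc@cellFunction, rep(1, 3))
  expect_equal(sc@proliferation, rep(1, 3))
  # all six damage markers doubled: CF = 2^-6
  v <- base; v[damageMarkers()] <- 2
  sc2 <- cellFunctionScore(syntheticTrajectory(v), base)
  expect_equal(sc2@cellFunction, rep(2^-6, 3))
  # scaling one proliferation and one damage marker by c cancels exactly
  v <- base; v["Ang2"] <- 3.7; v["ROS"] <- 3.7
  sc3 <- cellFunctionScore(syntheticTrajectory(v), base)
  expect_equal(sc3@cellFunction, rep(1, 3))
  # zero baseline is a normalization error
  bad <- base; bad["ROS"] <- 0
  expect_error(cellFunctionScore(syntheticTrajectory(base), bad),
               "normalization")
})

test_that("OGD/R drives the cell-function score below baseline", {
  sc <- cellFunctionScore(cachedOGDR())
  expect_lt(endpointCF(sc), 1)
  expect_equal(sc@cellFunction[1], 1, tolerance = 1e-6)
})

test_that("phenotype grid has the printed structure and control identity", {
  m <- defaultModel()
  # zero OGD column: all log2 fold changes ~ 0
  g0 <- phenotypeGrid(m$network, m$params, ogdList = 0,
                      reoxList = c(1, 24), state = m$state)
  expect_identical(dim(g0@values), c(12L, 2L))
  expect_lt(max(abs(g0@values)), 0.02)
  # single-condition grid is 1 x 12
  g1 <- phenotypeGrid(m$network, m$params, ogdList = 6, reoxList = 24,
                      state = m$state)
  expect_identical(dim(g1@values), c(12L, 1L))
  expect_identical(g1@markers, markerIds())
  df <- gridToDataFrame(g1)
  expect_identical(names(df), c("marker", "ogd_h", "reox_h", "log2fc"))
  expect_equal(nrow(df), 12)
  expect_error(phenotypeGrid(m$network, m$params, ogdList = numeric(0)),
               "nonempty")
})

test_that("grid qualitative trends match the OGD/R phenotype map", {
  m <- defaultModel()
  g <- phenotypeGrid(m$network, m$params, ogdList = c(1, 3, 6, 24),
                     reoxList = c(1, 24), state = m$state)
  df <- gridToDataFrame(g)
  for (rx in c(1, 24)) {
    sub <- df[df$reox_h == rx, ]
    for (ck in c("IL6", "IL1b", "CCL2")) {
      v <- sub$log2fc[sub$marker == ck][order(sub$ogd_h[sub$marker == ck])]
      expect_true(all(diff(v) > -1e-6),
                  label = paste(ck, "monotone in OGD at reox", rx))
    }
    for (tj in c("ZO1", "Claudin5")) {
      v <- sub$log2fc[sub$marker == tj][order(sub$ogd_h[sub$marker == tj])]
      expect_true(all(diff(v) < 1e-6),
                  label = paste(tj, "non-increasing in OGD at reox", rx))
    }
  }
  # growth factors return toward baseline with longer reoxygenation
  for (gf in c("Ang2", "SEMA3G", "BDNF")) {
    v1 <- df$log2fc[df$marker == gf & df$ogd_h == 6 & df$reox_h == 1]
    v24 <- df$log2fc[df$marker == gf & df$ogd_h == 6 & df$reox_h == 24]
    expect_lt(abs(v24), abs(v1))
  }
  # tight junctions also non-increasing in reox duration at fixed OGD
  for (tj in c("ZO1", "Claudin5")) {
    v <- df$log2fc[df$marker == tj & df$ogd_h == 6]
    expect_lt(v[2], v[1])
  }
})
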