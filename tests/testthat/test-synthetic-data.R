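test_that("generated geographies respect their extent, grid and adjacency contracts", {
  geo <- generateGeography(nSource = 25, nTarget = 60, regionExtent = c(8, 6),
                           gridSpacing = 2, seed = 4)
  expect_equal(nrow(geo$sourceCentroids), 25)
  expect_equal(nrow(geo$targetCentroids), 60)
  expect_equal(nGridPoints(geo$grid), 5 * 4)
  for (pts in list(geo$sourceCentroids, geo$targetCentroids)) {
    expect_true(all(pts[, 1] >= 0 & pts[, 1] <= 8))
    expect_true(all(pts[, 2] >= 0 & pts[, 2] <= 6))
  }
  adj <- geo$adjacency
  expect_equal(length(adj), 60)
  for (k in seq_along(adj)) {
    expect_false(k %in% adj[[k]])
    for (l in adj[[k]]) expect_true(k %in% adj[[l]])
  }
  expect_error(generateGeography(10, 20, regionExtent = c(1, 1),
                                 gridSpacing = 2), "too small")
  # regeneration is reproducible
  geo2 <- generateGeography(nSource = 25, nTarget = 60,
                            regionExtent = c(8, 6), gridSpacing = 2, seed = 4)
  expect_identical(geo, geo2)
})

test_that("the truth runs the model forward with the stated structure", {
  geo <- generateGeography(nSource = 10, nTarget = 20, regionExtent = c(6, 6),
                           gridSpacing = 2, seed = 5)
  # degenerate configuration: no fields, no residuals, no covariate effect
  gcfg <- generatorConfig(beta = c(-0.4, 0), delta = c(-40, 0),
                          varW1 = 1e-20, varW2 = 1e-20)
  tr <- generateTruth(geo, ModelSpec(), gcfg, seed = 6)
  expect_equal(tr@rhoSource, rep(exp(-0.4), 10), tolerance = 1e-6)
  expect_equal(tr@rhoTarget, rep(exp(-0.4), 20), tolerance = 1e-6)
  # z1 matches the brute-force kernel sum
  tr2 <- generateTruth(geo, ModelSpec(), generatorConfig(), seed = 7)
  km <- kernelMatrix(geo$sourceCentroids, geo$grid, KernelSpec("normal"))
  z1 <- vapply(1:10, function(p) sum(km[p, ] * tr2@state@w1), 0)
  expect_equal(tr2@z1Source, z1, tolerance = 1e-12)
  expect_true(validObject(tr2@state))
})

test_that("observation simulation follows the three stream models", {
  geo <- generateGeography(nSource = 10, nTarget = 20, regionExtent = c(6, 6),
                           gridSpacing = 2, seed = 8)
  # noise-free covariate stream when the observation variance vanishes
  tr <- generateTruth(geo, ModelSpec(), generatorConfig(varX = 1e-20),
                      seed = 9)
  obs <- simulateObservations(tr, seed = 10)
  expect_equal(covariate(obs$target), tr@config$eta1 + tr@z2Target,
               tolerance = 1e-8)
  expect_identical(simulateObservations(tr, seed = 10)$source@count,
                   obs$source@count)
  # frames are valid and carry the truth offsets
  expect_true(validObject(obs$source))
  expect_true(validObject(obs$target))
  expect_equal(offsetPrevalence(obs$source), tr@offsetPrevSource)
  expect_equal(offsetMorbidity(obs$target), tr@offsetMorbidity)
})

test_that("prevalence counts are mean-unbiased for E times rho", {
  geo <- generateGeography(nSource = 10, nTarget = 12, regionExtent = c(6, 6),
                           gridSpacing = 2, seed = 11)
  tr <- generateTruth(geo, ModelSpec(), generatorConfig(), seed = 12)
  R <- 1000
  acc <- matrix(0, R, 10)
  for (r in 1:R)
    acc[r, ] <- counts(simulateObservations(tr, seed = 1000 + r)$source) /
      tr@offsetPrevSource
  est <- colMeans(acc)
  se <- sqrt(tr@rhoSource / tr@offsetPrevSource) / sqrt(R)
  expect_true(all(abs(est - tr@rhoSource) < 3.5 * se))
})

test_that("residual variance induces over-dispersion beyond Poisson", {
  geo <- generateGeography(nSource = 30, nTarget = 12, regionExtent = c(6, 6),
                           gridSpacing = 2, seed = 13)
  R <- 120
  logRate <- function(gcfg) {
    out <- matrix(0, R, 30)
    for (r in 1:R) {
      tr <- generateTruth(geo, ModelSpec(), gcfg, seed = 5000 + r)
      y <- counts(simulateObservations(tr, seed = 6000 + r)$source)
      out[r, ] <- log(pmax(y, 0.5) / tr@offsetPrevSource)
    }
    out
  }
  # identical except for the residual variance level
  base <- generatorConfig(varW1 = 1e-20, varW2 = 1e-20, beta = c(-0.25, 0))
  withE <- modifyList(base, list(delta = c(-2, 0)))     # V = 0.135
  noE <- modifyList(base, list(delta = c(-40, 0)))      # V ~ 0
  vWith <- mean(apply(logRate(withE), 2, var))
  vNo <- mean(apply(logRate(noE), 2, var))
  expect_gt(vWith, vNo * 2)
})

test_that("covariate and morbidity streams are conditionally independent given the truth", {
  st <- syntheticStudy(30, 800, c(14, 14), 2, seed = 14)
  xResid <- covariate(st$target) - (st$truth@config$eta1 + st$truth@z2Target)
  mResid <- counts(st$target) - st$truth@offsetMorbidity * st$truth@nu
  expect_lt(abs(cor(xResid, mResid)), 3.5 / sqrt(800))
})

test_that("the canonical fixtures have their documented dimensions", {
  st <- defaultFixture(seed = 1)
  expect_equal(nAreas(st$source), 60)
  expect_equal(nAreas(st$target), 150)
  expect_equal(nGridPoints(st$geography$grid), 25)
  expect_equal(gridSpacing(st$geography$grid), 2)
})
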