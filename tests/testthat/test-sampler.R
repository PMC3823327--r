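test_that("chain configuration arithmetic reproduces the reference run shape", {
  # two chains of 25,000 iterations with inference on the second halves
  cc <- chainConfig(nChains = 2, nIter = 25000, burnFraction = 0.5, seed = 1)
  expect_equal(retainedDraws(cc), 25000)
  expect_equal(cc$nRetainedPerChain, 12500)
  cc2 <- chainConfig(nChains = 2, nIter = 1000, thin = 4, seed = 1)
  expect_equal(cc2$nRetainedPerChain, 125)
  expect_error(chainConfig(nIter = 300, thin = 2), "at least 100")
})

test_that("initial states are valid, seed-dependent and posterior-finite", {
  toy <- toyProblem()
  s1 <- initialState(toy$source, toy$target, toy$grid, ModelSpec(), seed = 1)
  s2 <- initialState(toy$source, toy$target, toy$grid, ModelSpec(), seed = 2)
  expect_true(validObject(s1))
  expect_false(identical(s1@w1, s2@w1))
  expect_identical(s1@beta, c(0, 0))
  expect_true(is.finite(jointLogPosterior(s1, toy$source, toy$target,
                                          toy$grid, ModelSpec())))
  # determinism of the state itself
  s1b <- initialState(toy$source, toy$target, toy$grid, ModelSpec(), seed = 1)
  expect_identical(s1, s1b)
})

test_that("identical seeds give bitwise-identical retained draws", {
  st <- syntheticStudy(12, 24, c(4, 4), 2, seed = 3)
  cc <- chainConfig(nChains = 2, nIter = 300, seed = 17)
  f1 <- runMcmc(st$source, st$target, st$geography$grid, ModelSpec(), cc)
  f2 <- runMcmc(st$source, st$target, st$geography$grid, ModelSpec(), cc)
  expect_identical(f1@chains, f2@chains)
  expect_identical(f1@rhoTarget, f2@rhoTarget)
  # a different seed moves the draws
  f3 <- runMcmc(st$source, st$target, st$geography$grid, ModelSpec(),
                chainConfig(nChains = 2, nIter = 300, seed = 18))
  expect_false(identical(f1@chains, f3@chains))
})

test_that("the conjugate Poisson-Gamma subcase matches the exact posterior tail", {
  y <- 12; E <- 10; a <- 2; b <- 2
  rho <- mcmcPoissonGamma(y, E, a, b, nRetained = 10000, seed = 4)
  exact <- pgamma(1, a + y, rate = b + E, lower.tail = FALSE)
  expect_lt(abs(mean(rho > 1) - exact), 0.02)
  # posterior mean sanity at the same tolerance scale
  expect_lt(abs(mean(rho) - (a + y) / (b + E)), 0.05)
})

test_that("PSRF behaves on degenerate, well-mixed and disjoint chains", {
  # degenerate within = between = 0 is defined as exactly 1
  const <- matrix(1, 200, 1, dimnames = list(NULL, "theta"))
  expect_identical(unname(gelmanRubin(list(const, const), "theta")), 1)
  # identical non-constant chains: no between-variance, PSRF at its floor
  one <- matrix(rep(c(1, 2), 100), ncol = 1,
                dimnames = list(NULL, "theta"))
  expect_equal(unname(gelmanRubin(list(one, one), "theta")), 1,
               tolerance = 0.01)
  set.seed(5)
  mk <- function(mu) matrix(rnorm(5000, mu), ncol = 1,
                            dimnames = list(NULL, "theta"))
  expect_lt(unname(gelmanRubin(list(mk(0), mk(0)), "theta")), 1.05)
  expect_gt(unname(gelmanRubin(list(mk(0), mk(10)), "theta")), 2)
  expect_error(gelmanRubin(list(const), "theta"), "two chains")
})

test_that("post-adaptation acceptance rates are moderate for every block", {
  sh <- sharedReducedFit()
  for (ch in acceptanceRates(sh$fit)) {
    expect_true(all(ch > 0.1))
    expect_true(all(ch < 0.6))
  }
})

test_that("the posterior locates the generating coefficients on the shared fit", {
  sh <- sharedReducedFit()
  truth <- sh$study$truth@state
  m <- drawsMatrix(sh$fit, c("beta1", "beta2", "gamma2"))
  ci <- apply(m, 2, quantile, c(0.025, 0.975))
  expect_true(ci[1, "beta1"] < truth@beta[1] && truth@beta[1] < ci[2, "beta1"])
  expect_true(ci[1, "beta2"] < truth@beta[2] && truth@beta[2] < ci[2, "beta2"])
  expect_gt(mean(m[, "gamma2"]), 0)
})
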