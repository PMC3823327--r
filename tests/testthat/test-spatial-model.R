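test_that("convolution fields equal the brute-force kernel sum", {
  set.seed(1)
  kmat <- matrix(runif(12), 4, 3)
  w <- rnorm(3)
  z <- convolveField(w, kmat)
  for (p in 1:4) expect_equal(z[p], sum(kmat[p, ] * w), tolerance = 1e-14)
  expect_equal(convolveField(c(0, 0, 0), kmat), rep(0, 4))
  expect_equal(convolveField(2.5, matrix(1, 3, 1)), rep(2.5, 3))
  expect_error(convolveField(rnorm(2), kmat), "length")
})

test_that("latent covariate interpolation shares the target-side mean formula", {
  expect_equal(latentCovariate(0, rep(0, 5)), rep(0, 5))
  expect_equal(latentCovariate(1.3, rep(0, 5)), rep(1.3, 5))
  # at coincident centroids the interpolated source value equals the
  # target-side mean mu = eta1 + z2(t)
  set.seed(2)
  grid <- ProcessGrid(matrix(runif(6, 0, 4), 3, 2), spacing = 2)
  pts <- matrix(runif(8, 0, 4), 4, 2)
  w2 <- rnorm(3)
  z2 <- convolveField(w2, kernelMatrix(pts, grid, KernelSpec("normal")))
  expect_equal(latentCovariate(0.7, z2), 0.7 + z2)
})

test_that("log relative risk is the linear predictor it claims to be", {
  expect_equal(logRelativeRisk(c(0, 0), 0, 0, 0), 0)
  expect_equal(logRelativeRisk(c(0, 1), 0.5, 0, 0), 0.5)
  set.seed(3)
  beta <- rnorm(2); xv <- rnorm(6); z1 <- rnorm(6); e <- rnorm(6)
  lr <- logRelativeRisk(beta, xv, z1, e)
  for (i in 1:6)
    expect_equal(lr[i], beta[1] + beta[2] * xv[i] + z1[i] + e[i],
                 tolerance = 1e-14)
  expect_error(logRelativeRisk(beta, c(xv, 1), z1, e), "length")
  expect_error(logRelativeRisk(beta, xv, z1, replace(e, 2, NA)), "finite")
})

test_that("residual variances follow the log-linear offset regression", {
  off <- c(10, 20, 40)
  expect_equal(residualVariance(c(0, 0), off), rep(1, 3))
  expect_equal(residualVariance(c(log(4), 0), off), rep(4, 3))
  # positive slope means strictly increasing variance in the offset
  off <- sort(runif(20, 5, 500))
  V <- residualVariance(c(-1, 0.5), off)
  expect_true(all(diff(V) > 0))
  expect_true(all(V > 0))
  # explicit scale: V = exp(d1 + d2 * off / scale)
  expect_equal(residualVariance(c(-1, 0.5), off, offsetScale = 100),
               exp(-1 + 0.5 * off / 100))
  expect_error(residualVariance(c(0, 0), c(1, -2)), "positive")
})

test_that("hospitalisation risk is log-linear in natural-scale prevalence", {
  expect_equal(hospitalisationLogRisk(c(0, 0), c(1, 2)), c(0, 0))
  expect_equal(hospitalisationLogRisk(c(-1, 1), 1), 0)
  set.seed(4)
  gam <- rnorm(2); rho <- exp(rnorm(5))
  ln <- hospitalisationLogRisk(gam, rho)
  for (k in 1:5)
    expect_equal(ln[k], gam[1] + gam[2] * rho[k], tolerance = 1e-14)
  expect_error(hospitalisationLogRisk(gam, c(1, -0.5)), "positive")
})

test_that("Poisson and Gaussian stream log likelihoods match closed forms", {
  expect_equal(loglikPoisson(0L, 1), -1)
  expect_equal(loglikPoisson(2L, 2), 2 * log(2) - 2 - log(2))
  set.seed(5)
  cnt <- rpois(8, 5); mu <- runif(8, 1, 9)
  expect_equal(loglikPoisson(cnt, mu),
               sum(vapply(1:8, function(i) loglikPoisson(cnt[i], mu[i]), 0)))
  expect_error(loglikPoisson(cnt, replace(mu, 1, 0)), "positive")

  expect_equal(loglikAirQuality(1.5, 1.5, 1 / (2 * pi)), 0)
  expect_equal(loglikAirQuality(1, 0, 1), -0.5 * (log(2 * pi) + 1))
  xv <- rnorm(6); mv <- rnorm(6)
  expect_equal(loglikAirQuality(xv, mv, 0.3),
               loglikAirQuality(xv + 2, mv + 2, 0.3))
  expect_error(loglikAirQuality(xv, mv, 0), "positive")
})

test_that("the log prior sums its blocks and reaches the normal limit", {
  toy <- toyProblem()
  spec <- ModelSpec()
  st <- toy$state
  lp <- logPrior(st, toy$source, toy$target, spec)
  # block-wise oracle
  pr <- PriorSpec()
  Vs <- residualVariance(st@delta, offsetPrevalence(toy$source))
  Vt <- residualVariance(st@delta, offsetPrevalence(toy$target))
  oracle <-
    sum(dnorm(c(st@beta, st@gamma, st@delta, st@eta1), 0, sqrt(1000),
              log = TRUE)) +
    sum(dnorm(st@w1, 0, sqrt(st@varW1), log = TRUE)) +
    sum(dnorm(st@w2, 0, sqrt(st@varW2), log = TRUE)) +
    sum(dnorm(st@eSource, 0, sqrt(Vs), log = TRUE)) +
    sum(dnorm(st@eTarget, 0, sqrt(Vt), log = TRUE)) +
    sum(dgamma(1 / c(st@varW1, st@varW2, st@varX), 0.001, rate = 0.001,
               log = TRUE))
  expect_equal(lp, oracle, tolerance = 1e-10)
  # Student-t process with enormous df converges to the normal process
  specT <- ModelSpec(process = ProcessSpec("student_t", df = 1e6))
  expect_lt(abs(logPrior(st, toy$source, toy$target, specT) - lp), 1e-3)
})

test_that("the joint log posterior assembles its four components", {
  toy <- toyProblem()
  spec <- ModelSpec()
  st <- toy$state
  jlp <- jointLogPosterior(st, toy$source, toy$target, toy$grid, spec)
  Ks <- kernelMatrix(centroids(toy$source), toy$grid, spec@kernel)
  Kt <- kernelMatrix(centroids(toy$target), toy$grid, spec@kernel)
  XL <- latentCovariate(st@eta1, convolveField(st@w2, Ks))
  rhoS <- exp(logRelativeRisk(st@beta, XL, convolveField(st@w1, Ks),
                              st@eSource))
  rhoT <- exp(logRelativeRisk(st@beta, covariate(toy$target),
                              convolveField(st@w1, Kt), st@eTarget))
  nu <- exp(hospitalisationLogRisk(st@gamma, rhoT))
  muX <- st@eta1 + convolveField(st@w2, Kt)
  expect_equal(jlp,
               loglikPoisson(counts(toy$source),
                             offsetPrevalence(toy$source) * rhoS) +
               loglikPoisson(counts(toy$target),
                             offsetMorbidity(toy$target) * nu) +
               loglikAirQuality(covariate(toy$target), muX, st@varX) +
               logPrior(st, toy$source, toy$target, spec),
               tolerance = 1e-10)
})

test_that("perturbing the morbidity stream shifts the posterior by exactly its log likelihood", {
  toy <- toyProblem()
  spec <- ModelSpec()
  st <- toy$state
  target2 <- AreaFrame("target", centroids(toy$target),
                       counts(toy$target) + 1L,
                       offsetPrevalence(toy$target),
                       offsetMorbidity = offsetMorbidity(toy$target),
                       covariate = covariate(toy$target),
                       adjacency = adjacency(toy$target))
  d <- jointLogPosterior(st, toy$source, target2, toy$grid, spec) -
       jointLogPosterior(st, toy$source, toy$target, toy$grid, spec)
  Kt <- kernelMatrix(centroids(toy$target), toy$grid, spec@kernel)
  rhoT <- exp(logRelativeRisk(st@beta, covariate(toy$target),
                              convolveField(st@w1, Kt), st@eTarget))
  nu <- exp(hospitalisationLogRisk(st@gamma, rhoT))
  G <- offsetMorbidity(toy$target)
  expect_equal(d,
               loglikPoisson(counts(target2), G * nu) -
               loglikPoisson(counts(toy$target), G * nu),
               tolerance = 1e-10)
})

test_that("with beta2 = 0 and w2 = 0 the covariate stream decouples", {
  toy <- toyProblem()
  spec <- ModelSpec()
  st0 <- toy$state
  st0@beta[2] <- 0
  st0@w2[] <- 0
  permuteX <- function(frame, perm)
    AreaFrame("target", centroids(frame), counts(frame),
              offsetPrevalence(frame),
              offsetMorbidity = offsetMorbidity(frame),
              covariate = covariate(frame)[perm],
              adjacency = adjacency(frame))
  set.seed(9)
  perm <- sample(nAreas(toy$target))
  tP <- permuteX(toy$target, perm)
  # the x-permutation shifts the posterior by a constant that does not
  # depend on (beta1, w1, e): the prevalence block and the covariate block
  # are conditionally independent
  shift0 <- jointLogPosterior(st0, toy$source, tP, toy$grid, spec) -
            jointLogPosterior(st0, toy$source, toy$target, toy$grid, spec)
  for (r in 1:3) {
    st1 <- st0
    st1@beta[1] <- rnorm(1)
    st1@w1 <- rnorm(length(st0@w1), 0, 0.3)
    st1@eSource <- rnorm(length(st0@eSource), 0, 0.2)
    shift1 <- jointLogPosterior(st1, toy$source, tP, toy$grid, spec) -
              jointLogPosterior(st1, toy$source, toy$target, toy$grid, spec)
    expect_equal(shift1, shift0, tolerance = 1e-9)
  }
})

test_that("the posterior is finite on valid states and prior-dominated in beta1", {
  toy <- toyProblem()
  spec <- ModelSpec()
  jlpAt <- function(b1) {
    st <- toy$state
    st@beta[1] <- b1
    jointLogPosterior(st, toy$source, toy$target, toy$grid, spec)
  }
  # away from the data-supported region the posterior falls in both
  # directions (large positive beta1 double-exponentiates through the
  # hospitalisation link, so modest values suffice there)
  up <- vapply(c(0, 3, 6), jlpAt, 0)
  down <- vapply(c(0, -10, -100), jlpAt, 0)
  expect_true(all(is.finite(c(up, down))))
  expect_true(all(diff(up) < 0))
  expect_true(all(diff(down) < 0))
})

test_that("source and target prevalence equations share the latent field", {
  # a source centroid coincident with a target centroid, equal covariate and
  # residual, gives the same log relative risk on both frames
  set.seed(10)
  grid <- ProcessGrid(matrix(runif(8, 0, 4), 4, 2), spacing = 2)
  shared <- c(1.7, 2.2)
  srcPts <- rbind(shared, c(0.4, 3.1))
  tgtPts <- rbind(c(3.3, 0.2), shared, c(2.8, 2.9))
  spec <- ModelSpec()
  w1 <- rnorm(4); beta <- c(-0.3, 0.4)
  z1src <- convolveField(w1, kernelMatrix(srcPts, grid, spec@kernel))
  z1tgt <- convolveField(w1, kernelMatrix(tgtPts, grid, spec@kernel))
  covv <- 0.8; ee <- -0.1
  expect_equal(logRelativeRisk(beta, covv, z1src[1], ee),
               logRelativeRisk(beta, covv, z1tgt[2], ee),
               tolerance = 1e-12)
})
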