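# Shared fixtures built in code. The reduced-scale fit is expensive, so it is
# memoised and shared by the sampler, convergence and classification tests.

.fixtureCache <- new.env(parent = emptyenv())

sharedReducedFit <- function() {
  if (is.null(.fixtureCache$fit)) {
    st <- defaultFixture(seed = 11)
    fit <- runMcmc(st$source, st$target, st$geography$grid, ModelSpec(),
                   chainConfig(nChains = 2, nIter = 5000, seed = 5))
    .fixtureCache$study <- st
    .fixtureCache$fit <- fit
  }
  list(study = .fixtureCache$study, fit = .fixtureCache$fit)
}

# Small deterministic frames for oracle tests (N source, K target, J grid).
toyProblem <- function(N = 4, K = 6, J = 3, seed = 42) {
  set.seed(seed)
  grid <- ProcessGrid(cbind(runif(J, 0, 6), runif(J, 0, 6)), spacing = 2)
  srcPts <- cbind(runif(N, 0, 6), runif(N, 0, 6))
  tgtPts <- cbind(runif(K, 0, 6), runif(K, 0, 6))
  source <- AreaFrame("source", srcPts,
                      count = rpois(N, 30), offsetPrevalence = runif(N, 20, 40))
  target <- AreaFrame("target", tgtPts,
                      count = rpois(K, 3), offsetPrevalence = runif(K, 5, 10),
                      offsetMorbidity = runif(K, 3, 8),
                      covariate = rnorm(K),
                      adjacency = knnAdjacency(tgtPts, 2))
  state <- ParamState(beta = c(-0.2, 0.3), gamma = c(-1.5, 0.4),
                      delta = c(-2, 0.1), eta1 = 0.15,
                      w1 = rnorm(J, 0, 0.3), w2 = rnorm(J, 0, 0.3),
                      eSource = rnorm(N, 0, 0.2), eTarget = rnorm(K, 0, 0.2),
                      varW1 = 0.1, varW2 = 0.2, varX = 0.05)
  list(source = source, target = target, grid = grid, state = state)
}
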