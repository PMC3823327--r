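#' Symmetric k-nearest-neighbour adjacency
#'
#' Builds the locality structure for synthetic geographies: each area's k
#' nearest centroids (Euclidean), symmetrised by union so the relation is a
#' valid neighbourhood (symmetric, irreflexive).
#'
#' @param points P x 2 matrix of centroids.
#' @param k number of nearest neighbours (default 5).
#' @return list of integer neighbour-index vectors.
#' @export
knnAdjacency <- function(points, k = 5) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 2L, k >= 1L)
  k <- min(k, n - 1L)
  d2 <- as.matrix(dist(points))
  diag(d2) <- Inf
  adj <- lapply(seq_len(n), function(i) order(d2[i, ])[seq_len(k)])
  # symmetrise by union
  for (i in seq_len(n)) for (j in adj[[i]])
    if (!(i %in% adj[[j]])) adj[[j]] <- c(adj[[j]], i)
  lapply(adj, function(v) sort(as.integer(v)))
}

#' Generate a synthetic study geography
#'
#' Emulates the structure of the motivating study region: target
#' (neighbourhood) centroids from a clustered parent-offspring planar point
#' process inside a rectangular extent, source (service-area) centroids
#' jittered from a subsample of target locations (service areas sit among the
#' neighbourhoods they serve, without nesting), a regular process grid
#' covering the extent, and a symmetric k-nearest-neighbour adjacency on the
#' target centroids. The defaults reproduce the study dimensions: 189 source
#' areas, 562 target areas, and an 84-point grid at 2 km spacing (extent
#' 22 km x 12 km).
#'
#' @param nSource,nTarget numbers of source and target areas.
#' @param regionExtent numeric(2) region width and height (km).
#' @param gridSpacing process-grid spacing (km), default 2.
#' @param seed integer seed.
#' @param nParents number of cluster parents of the target point process.
#' @param clusterSd offspring dispersal standard deviation (km).
#' @param sourceJitterSd jitter applied to subsampled source centroids (km).
#' @param uniform logical; TRUE replaces the clustered process with a uniform
#'   one (degenerate-case testing).
#' @param knnK neighbours per area for the adjacency (default 5).
#' @return list with \code{sourceCentroids}, \code{targetCentroids},
#'   \code{grid} (a [ProcessGrid-class]) and \code{adjacency}.
#' @export
generateGeography <- function(nSource = 189, nTarget = 562,
                              regionExtent = c(22, 12), gridSpacing = 2,
                              seed = 1, nParents = 25, clusterSd = 1.5,
                              sourceJitterSd = 0.5, uniform = FALSE,
                              knnK = 5) {
  stopifnot(nSource >= 1, nTarget >= 2, length(regionExtent) == 2L,
            all(regionExtent > 0))
  if (any(regionExtent < gridSpacing))
    stop("region extent too small for the requested grid spacing")
  set.seed(as.integer(seed))
  rejectToExtent <- function(gen, n) {
    pts <- matrix(NA_real_, n, 2)
    filled <- 0L
    while (filled < n) {
      cand <- gen(n)
      ok <- cand[, 1] >= 0 & cand[, 1] <= regionExtent[1] &
            cand[, 2] >= 0 & cand[, 2] <= regionExtent[2]
      take <- min(n - filled, sum(ok))
      if (take > 0) {
        pts[filled + seq_len(take), ] <- cand[ok, , drop = FALSE][seq_len(take), ]
        filled <- filled + take
      }
    }
    pts
  }
  if (uniform) {
    tgt <- cbind(runif(nTarget, 0, regionExtent[1]),
                 runif(nTarget, 0, regionExtent[2]))
  } else {
    parents <- cbind(runif(nParents, 0, regionExtent[1]),
                     runif(nParents, 0, regionExtent[2]))
    tgt <- rejectToExtent(function(n) {
      pid <- sample.int(nParents, n, replace = TRUE)
      parents[pid, , drop = FALSE] +
        matrix(rnorm(2 * n, 0, clusterSd), ncol = 2)
    }, nTarget)
  }
  pick <- sample.int(nTarget, nSource, replace = nSource > nTarget)
  src <- rejectToExtent(function(n) {
    idx <- if (n == nSource) pick else sample(pick, n, replace = TRUE)
    tgt[idx, , drop = FALSE] + matrix(rnorm(2 * n, 0, sourceJitterSd),
                                      ncol = 2)
  }, nSource)
  list(sourceCentroids = src, targetCentroids = tgt,
       grid = makeGrid(regionExtent, gridSpacing),
       adjacency = knnAdjacency(tgt, knnK))
}

#' Generator configuration
#'
#' Default generating values for the synthetic study conditions. The
#' structural coefficients sit in the neighbourhood of the posterior means
#' reported for the motivating application (beta = (-0.25, 0.31), gamma =
#' (-1.8, 0.38), delta = (-3.37, 0.03)); populations average 1,500 residents
#' per target area and 5,380 per source area (log-normally scattered); the
#' region-wide prevalence rate is 4.6%. The morbidity offset rate is 10 per
#' 1,000 residents; with the hospitalisation intercept near -1.8 the realized
#' crude admission rate is then roughly 2-3 per 1,000, a realistic level for
#' asthma admissions. Grid-process variances of 0.03 give latent-field
#' standard deviations around 0.3 on the log-risk scale.
#'
#' @param beta,gamma,delta,eta1 structural coefficients.
#' @param varW1,varW2 grid-process variances.
#' @param varX covariate observation variance.
#' @param regionalRate region-wide prevalence rate in (0, 1).
#' @param morbidityRate region-wide morbidity (hospitalisation) rate.
#' @param targetPopMean,sourcePopMean mean populations.
#' @param popSdLog log-scale population scatter.
#' @return named list of generator settings.
#' @export
generatorConfig <- function(beta = c(-0.25, 0.31), gamma = c(-1.8, 0.38),
                            delta = c(-3.37, 0.03), eta1 = 0,
                            varW1 = 0.03, varW2 = 0.03, varX = 0.01,
                            regionalRate = 0.046, morbidityRate = 0.01,
                            targetPopMean = 1500, sourcePopMean = 5380,
                            popSdLog = 0.3) {
  stopifnot(length(beta) == 2L, length(gamma) == 2L, length(delta) == 2L,
            varW1 > 0, varW2 > 0, varX > 0,
            regionalRate > 0, regionalRate < 1, morbidityRate > 0)
  list(beta = beta, gamma = gamma, delta = delta, eta1 = eta1,
       varW1 = varW1, varW2 = varW2, varX = varX,
       regionalRate = regionalRate, morbidityRate = morbidityRate,
       targetPopMean = targetPopMean, sourcePopMean = sourcePopMean,
       popSdLog = popSdLog)
}

#' Generate the latent truth over a geography
#'
#' Runs the model forward: draws the grid effects from the configured
#' process, builds the convolution fields at every centroid, draws the
#' heteroscedastic residuals, and computes true relative prevalence on both
#' frames, true relative hospitalisation risk, the interpolated covariate,
#' and the offsets (populations times the regional rates).
#'
#' @param geography a [generateGeography()] list.
#' @param spec a [ModelSpec-class] (kernel and process used for generation).
#' @param genConfig a [generatorConfig()] list.
#' @param seed integer seed.
#' @return a [SyntheticTruth-class].
#' @export
generateTruth <- function(geography, spec = ModelSpec(),
                          genConfig = generatorConfig(), seed = 1) {
  stopifnot(is(spec, "ModelSpec"))
  g <- genConfig
  grid <- geography$grid
  J <- nGridPoints(grid)
  N <- nrow(geography$sourceCentroids)
  K <- nrow(geography$targetCentroids)
  set.seed(as.integer(seed))
  drawW <- function(varW) {
    if (spec@process@family == "normal") rnorm(J, 0, sqrt(varW))
    else sqrt(varW) * stats::rt(J, df = spec@process@df)
  }
  w1 <- drawW(g$varW1)
  w2 <- drawW(g$varW2)
  Ks <- kernelMatrix(geography$sourceCentroids, grid, spec@kernel)
  Kt <- kernelMatrix(geography$targetCentroids, grid, spec@kernel)
  z1s <- convolveField(w1, Ks); z1t <- convolveField(w1, Kt)
  z2s <- convolveField(w2, Ks); z2t <- convolveField(w2, Kt)

  popS <- g$sourcePopMean * exp(rnorm(N, -g$popSdLog^2 / 2, g$popSdLog))
  popT <- g$targetPopMean * exp(rnorm(K, -g$popSdLog^2 / 2, g$popSdLog))
  Es <- popS * g$regionalRate
  Et <- popT * g$regionalRate
  G <- popT * g$morbidityRate

  Vs <- residualVariance(g$delta, Es)
  Vt <- residualVariance(g$delta, Et)
  es <- rnorm(N, 0, sqrt(Vs))
  et <- rnorm(K, 0, sqrt(Vt))

  XL <- latentCovariate(g$eta1, z2s)
  xMean <- g$eta1 + z2t
  rhoS <- exp(logRelativeRisk(g$beta, XL, z1s, es))
  rhoT <- exp(logRelativeRisk(g$beta, xMean, z1t, et))
  nu <- exp(hospitalisationLogRisk(g$gamma, rhoT))

  state <- ParamState(beta = g$beta, gamma = g$gamma, delta = g$delta,
                      eta1 = g$eta1, w1 = w1, w2 = w2,
                      eSource = es, eTarget = et,
                      varW1 = g$varW1, varW2 = g$varW2, varX = g$varX)
  new("SyntheticTruth", state = state, geography = geography,
      z1Source = z1s, z1Target = z1t, z2Source = z2s, z2Target = z2t,
      latentCovariate = XL, rhoSource = rhoS, rhoTarget = rhoT, nu = nu,
      offsetPrevSource = Es, offsetPrevTarget = Et, offsetMorbidity = G,
      config = c(g, list(seed = as.integer(seed))))
}

#' Simulate observed data from a truth
#'
#' Draws the three observation streams: prevalence counts y ~ Poisson(E rho)
#' on the source frame, hospitalisation counts M ~ Poisson(G nu) on the
#' target frame, and the covariate x ~ Normal(eta1 + z2(t), varX) on the
#' target frame. Note that the target-frame relative risks rho_k already
#' include the generating residuals e_k, so marginally the counts are
#' over-dispersed relative to a pure Poisson.
#'
#' @param truth a [SyntheticTruth-class].
#' @param seed integer seed.
#' @return list with \code{source} and \code{target} [AreaFrame-class]
#'   objects ready for [runMcmc()].
#' @export
simulateObservations <- function(truth, seed = 1) {
  stopifnot(is(truth, "SyntheticTruth"))
  g <- truth@config
  geo <- truth@geography
  N <- length(truth@rhoSource); K <- length(truth@rhoTarget)
  set.seed(as.integer(seed))
  y <- rpois(N, truth@offsetPrevSource * truth@rhoSource)
  M <- rpois(K, truth@offsetMorbidity * truth@nu)
  x <- rnorm(K, g$eta1 + truth@z2Target, sqrt(g$varX))
  source <- AreaFrame("source", geo$sourceCentroids, y,
                      truth@offsetPrevSource)
  target <- AreaFrame("target", geo$targetCentroids, M,
                      truth@offsetPrevTarget,
                      offsetMorbidity = truth@offsetMorbidity,
                      covariate = x, adjacency = geo$adjacency)
  list(source = source, target = target)
}

#' Canonical synthetic fixtures
#'
#' The two reference problem sizes used throughout the package's examples,
#' tests and vignette. \code{"study"} reproduces the motivating study's
#' dimensions (189 source areas, 562 target areas, 84 grid points at 2 km
#' spacing over a 22 x 12 km region); \code{"reduced"} is a desk-scale
#' analogue (60 source areas, 150 target areas, 25 grid points at 2 km
#' spacing over an 8 x 8 km region) on which full MCMC runs take well under a
#' minute.
#'
#' @param seed master integer seed.
#' @param scale \code{"reduced"} (default) or \code{"study"}.
#' @param spec a [ModelSpec-class].
#' @param genConfig a [generatorConfig()] list.
#' @return a [syntheticStudy()] list.
#' @export
defaultFixture <- function(seed = 1, scale = c("reduced", "study"),
                           spec = ModelSpec(), genConfig = generatorConfig()) {
  scale <- match.arg(scale)
  if (scale == "study")
    syntheticStudy(189, 562, c(22, 12), 2, spec = spec,
                   genConfig = genConfig, seed = seed)
  else
    syntheticStudy(60, 150, c(8, 8), 2, spec = spec,
                   genConfig = genConfig, seed = seed)
}

#' One-call synthetic study
#'
#' Convenience wrapper chaining [generateGeography()], [generateTruth()] and
#' [simulateObservations()] with sub-seeds derived from one master seed.
#'
#' @param nSource,nTarget,regionExtent,gridSpacing passed to
#'   [generateGeography()].
#' @param spec a [ModelSpec-class].
#' @param genConfig a [generatorConfig()] list.
#' @param seed master integer seed.
#' @param ... further arguments to [generateGeography()].
#' @return list with \code{geography}, \code{truth}, \code{source},
#'   \code{target}.
#' @export
syntheticStudy <- function(nSource = 189, nTarget = 562,
                           regionExtent = c(22, 12), gridSpacing = 2,
                           spec = ModelSpec(), genConfig = generatorConfig(),
                           seed = 1, ...) {
  geo <- generateGeography(nSource, nTarget, regionExtent, gridSpacing,
                           seed = .chainSeed(seed, 1), ...)
  truth <- generateTruth(geo, spec, genConfig, seed = .chainSeed(seed, 2))
  obs <- simulateObservations(truth, seed = .chainSeed(seed, 3))
  list(geography = geo, truth = truth, source = obs$source,
       target = obs$target)
}
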