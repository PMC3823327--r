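#' @import methods
#' @importFrom stats dnorm dpois dgamma dt rnorm rpois rgamma runif quantile var sd setNames
#' @importFrom utils read.csv write.csv
NULL

#' Smoothing-kernel specification
#'
#' Describes the isotropic two-dimensional kernel used to weight grid-point
#' random effects by distance. Three families are supported, all standardised
#' so that the weight at zero distance is 1 (normalising constants are absorbed
#' by the grid-process variance, which is what identifies the model when both
#' kernel scale and process variance cannot be estimated jointly):
#' \describe{
#'   \item{normal}{\eqn{\exp(-d^2 / (2\alpha^2))} with scale \eqn{\alpha}}
#'   \item{exponential}{\eqn{\exp(-d / \eta)} with scale \eqn{\eta};
#'     more leptokurtic (peaked, fat-tailed) than the normal kernel}
#'   \item{student_t}{\eqn{(1 + d^2/(\nu \alpha^2))^{-(\nu+2)/2}} with shape
#'     (degrees of freedom) \code{kernelDf}}
#' }
#' Distances are expressed in grid-spacing units, so \code{scale = 1} is the
#' "standard" kernel whose scale equals one grid interval.
#'
#' @slot family character; one of \code{"normal"}, \code{"exponential"},
#'   \code{"student_t"}.
#' @slot scale positive numeric kernel scale in grid-spacing units.
#' @slot kernelDf positive numeric; Student-t kernel shape, ignored by the
#'   other families.
#' @seealso [kernelWeight()], [kernelMatrix()]
#' @export
setClass("KernelSpec",
  representation(family = "character", scale = "numeric", kernelDf = "numeric"))

setValidity("KernelSpec", function(object) {
  msg <- character()
  if (length(object@family) != 1L ||
      !object@family %in% c("normal", "exponential", "student_t"))
    msg <- c(msg, "family must be one of 'normal', 'exponential', 'student_t'")
  if (length(object@scale) != 1L || !is.finite(object@scale) ||
      object@scale <= 0)
    msg <- c(msg, "scale must be a single positive finite number")
  if (length(object@kernelDf) != 1L || !is.finite(object@kernelDf) ||
      object@kernelDf <= 0)
    msg <- c(msg, "kernelDf must be a single positive finite number")
  if (length(msg)) msg else TRUE
})

#' @param family kernel family.
#' @param scale kernel scale in grid-spacing units (default 1, the standard
#'   kernel).
#' @param kernelDf Student-t kernel shape (default 5; only used when
#'   \code{family = "student_t"}).
#' @rdname KernelSpec-class
#' @export
KernelSpec <- function(family = c("normal", "exponential", "student_t"),
                       scale = 1, kernelDf = 5) {
  family <- match.arg(family)
  new("KernelSpec", family = family, scale = as.numeric(scale),
      kernelDf = as.numeric(kernelDf))
}

setMethod("show", "KernelSpec", function(object) {
  extra <- if (object@family == "student_t")
    sprintf(", df = %g", object@kernelDf) else ""
  cat(sprintf("KernelSpec: %s kernel, scale = %g%s (grid-spacing units)\n",
              object@family, object@scale, extra))
})

#' Discrete process grid
#'
#' The sparse regular grid of points at which the latent-process random
#' effects live. Distances from area centroids to grid points are divided by
#' \code{spacing} before kernel evaluation, so kernels with scale 1 have scale
#' equal to one grid interval.
#'
#' @slot points numeric matrix (J x 2) of planar grid coordinates (km).
#' @slot spacing positive numeric grid spacing (km).
#' @seealso [makeGrid()], [gridCovering()]
#' @export
setClass("ProcessGrid",
  representation(points = "matrix", spacing = "numeric"))

setValidity("ProcessGrid", function(object) {
  msg <- character()
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L || nrow(p) < 1L)
    msg <- c(msg, "points must be a numeric matrix with two columns and J >= 1 rows")
  else {
    if (!all(is.finite(p))) msg <- c(msg, "grid coordinates must be finite")
    if (anyDuplicated(p)) msg <- c(msg, "grid points must be distinct")
  }
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @param points J x 2 matrix (or two-column data frame) of grid coordinates.
#' @param spacing grid spacing in the same planar units as the coordinates.
#' @rdname ProcessGrid-class
#' @export
ProcessGrid <- function(points, spacing) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  new("ProcessGrid", points = points, spacing = as.numeric(spacing))
}

setMethod("show", "ProcessGrid", function(object) {
  cat(sprintf("ProcessGrid: J = %d points at spacing %g\n",
              nrow(object@points), object@spacing))
  rng <- apply(object@points, 2, range)
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2]))
})

#' Grid-process specification
#'
#' Distribution family of the grid random effects w_j: zero-mean normal, or a
#' scaled Student-t with \code{df} degrees of freedom allowing heavier tails.
#' The fitted model variants use df = 5.
#'
#' @slot family \code{"normal"} or \code{"student_t"}.
#' @slot df positive numeric degrees of freedom (used for the t process).
#' @export
setClass("ProcessSpec",
  representation(family = "character", df = "numeric"))

setValidity("ProcessSpec", function(object) {
  msg <- character()
  if (length(object@family) != 1L ||
      !object@family %in% c("normal", "student_t"))
    msg <- c(msg, "family must be 'normal' or 'student_t'")
  if (length(object@df) != 1L || !is.finite(object@df) || object@df <= 0)
    msg <- c(msg, "df must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @param family process family.
#' @param df degrees of freedom for the Student-t process (default 5).
#' @rdname ProcessSpec-class
#' @export
ProcessSpec <- function(family = c("normal", "student_t"), df = 5) {
  family <- match.arg(family)
  new("ProcessSpec", family = family, df = as.numeric(df))
}

setMethod("show", "ProcessSpec", function(object) {
  if (object@family == "normal") cat("ProcessSpec: normal grid process\n")
  else cat(sprintf("ProcessSpec: Student-t grid process, df = %g\n", object@df))
})

#' Prior specification
#'
#' Diffuse default priors: Gamma(shape, rate) on all precisions (grid-process
#' precisions and the covariate observation precision) and N(mean, variance)
#' on every regression coefficient (intercepts, pollution effect, reflexive
#' effect, log-variance regression, risk-factor process intercept).
#'
#' @slot precisionShape,precisionRate positive Gamma hyper-parameters
#'   (default 0.001, 0.001).
#' @slot coeffMean,coeffVariance normal prior mean and variance for the
#'   regression coefficients (default 0 and 1000). \code{coeffMean} may be a
#'   single value shared by all coefficients or a length-7 vector of
#'   per-coefficient means in the order (beta1, beta2, gamma1, gamma2,
#'   delta1, delta2, eta1), which is how informative priors centred on
#'   substantive values are expressed (e.g., for prior-predictive
#'   calibration checks).
#' @export
setClass("PriorSpec",
  representation(precisionShape = "numeric", precisionRate = "numeric",
                 coeffMean = "numeric", coeffVariance = "numeric"))

setValidity("PriorSpec", function(object) {
  msg <- character()
  for (s in c("precisionShape", "precisionRate", "coeffVariance"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
        slot(object, s) <= 0)
      msg <- c(msg, paste(s, "must be a single positive number"))
  if (!length(object@coeffMean) %in% c(1L, 7L) ||
      any(!is.finite(object@coeffMean)))
    msg <- c(msg, "coeffMean must be finite, of length 1 or 7")
  if (length(msg)) msg else TRUE
})

#' @param precisionShape,precisionRate Gamma hyper-parameters for precisions.
#' @param coeffMean,coeffVariance normal prior moments for coefficients.
#' @rdname PriorSpec-class
#' @export
PriorSpec <- function(precisionShape = 0.001, precisionRate = 0.001,
                      coeffMean = 0, coeffVariance = 1000) {
  new("PriorSpec", precisionShape = as.numeric(precisionShape),
      precisionRate = as.numeric(precisionRate),
      coeffMean = as.numeric(coeffMean),
      coeffVariance = as.numeric(coeffVariance))
}

#' Full model specification
#'
#' Combines kernel family, grid-process family and priors. The four model
#' variants commonly compared are the crossings of
#' (normal | exponential kernel) x (normal | Student-t(5) process); see
#' [modelVariant()]. The ecological covariate always enters the prevalence
#' regression linearly.
#'
#' @slot kernel a [KernelSpec-class].
#' @slot process a [ProcessSpec-class].
#' @slot priors a [PriorSpec-class].
#' @slot covariateEffect character; only \code{"linear"} is implemented.
#' @export
setClass("ModelSpec",
  representation(kernel = "KernelSpec", process = "ProcessSpec",
                 priors = "PriorSpec", covariateEffect = "character"))

setValidity("ModelSpec", function(object) {
  if (!identical(object@covariateEffect, "linear"))
    "covariateEffect must be 'linear'" else TRUE
})

#' @param kernel a [KernelSpec-class].
#' @param process a [ProcessSpec-class].
#' @param priors a [PriorSpec-class].
#' @rdname ModelSpec-class
#' @export
ModelSpec <- function(kernel = KernelSpec("normal"),
                      process = ProcessSpec("normal"),
                      priors = PriorSpec()) {
  new("ModelSpec", kernel = kernel, process = process, priors = priors,
      covariateEffect = "linear")
}

#' The four standard model variants
#'
#' Variant 1: normal kernel, normal process. Variant 2: exponential kernel,
#' normal process. Variant 3: normal kernel, t(5) process. Variant 4:
#' exponential kernel, t(5) process. All use standard (scale 1) kernels and a
#' linear covariate effect.
#'
#' @param variant integer 1-4.
#' @param priors a [PriorSpec-class].
#' @return a [ModelSpec-class].
#' @export
modelVariant <- function(variant, priors = PriorSpec()) {
  stopifnot(length(variant) == 1L, variant %in% 1:4)
  kernel <- KernelSpec(if (variant %in% c(1, 3)) "normal" else "exponential")
  process <- if (variant %in% c(1, 2)) ProcessSpec("normal")
             else ProcessSpec("student_t", df = 5)
  ModelSpec(kernel = kernel, process = process, priors = priors)
}

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:\n  ")
  show(object@kernel)
  cat("  ")
  show(object@process)
  cat(sprintf("  covariate effect: %s\n", object@covariateEffect))
})

#' Areal data frame (source or target framework)
#'
#' One spatial framework: either the source areas on which prevalence counts
#' are observed (e.g., GP practice service areas) or the target areas for
#' which prevalence is interpolated (e.g., neighbourhoods). Target frames may
#' additionally carry morbidity counts with their expected values, an
#' ecological covariate, and an adjacency structure.
#'
#' @slot role \code{"source"} or \code{"target"}.
#' @slot areaId character vector of unique area identifiers.
#' @slot centroids numeric matrix (P x 2), planar km coordinates.
#' @slot count non-negative integer counts: prevalence counts y on the source
#'   frame, hospitalisation counts M on the target frame.
#' @slot offsetPrevalence positive expected prevalence counts (population
#'   times the region-wide rate).
#' @slot offsetMorbidity positive expected morbidity counts G (target only;
#'   length 0 otherwise).
#' @slot covariate ecological covariate x, e.g. a log air-quality index
#'   (target only; length 0 when absent).
#' @slot adjacency list of integer neighbour-index vectors, symmetric and
#'   irreflexive (may be empty).
#' @seealso [readAreaFrame()], [simulateObservations()]
#' @export
setClass("AreaFrame",
  representation(role = "character", areaId = "character",
                 centroids = "matrix", count = "integer",
                 offsetPrevalence = "numeric", offsetMorbidity = "numeric",
                 covariate = "numeric", adjacency = "list"))

setValidity("AreaFrame", function(object) {
  msg <- character()
  n <- nrow(object@centroids)
  if (length(object@role) != 1L || !object@role %in% c("source", "target"))
    msg <- c(msg, "role must be 'source' or 'target'")
  if (ncol(object@centroids) != 2L || !all(is.finite(object@centroids)))
    msg <- c(msg, "centroids must be a finite P x 2 matrix")
  if (length(object@areaId) != n) msg <- c(msg, "areaId length mismatch")
  if (anyDuplicated(object@areaId)) msg <- c(msg, "duplicate area ids")
  if (length(object@count) != n || any(object@count < 0L))
    msg <- c(msg, "count must be non-negative and match the number of areas")
  if (length(object@offsetPrevalence) != n ||
      any(!is.finite(object@offsetPrevalence)) ||
      any(object@offsetPrevalence <= 0))
    msg <- c(msg, "offsetPrevalence must be positive for every area")
  if (length(object@offsetMorbidity) &&
      (length(object@offsetMorbidity) != n || any(object@offsetMorbidity <= 0)))
    msg <- c(msg, "offsetMorbidity must be positive and match the number of areas")
  if (length(object@covariate)) {
    if (length(object@covariate) != n || any(!is.finite(object@covariate)))
      msg <- c(msg, "covariate must be finite and match the number of areas")
    if (object@role != "target")
      msg <- c(msg, "covariate is only carried by target frames")
  }
  if (length(object@adjacency)) {
    if (length(object@adjacency) != n)
      msg <- c(msg, "adjacency must have one entry per area")
    else {
      ok <- TRUE
      for (k in seq_len(n)) {
        nb <- object@adjacency[[k]]
        if (any(nb < 1L | nb > n) || k %in% nb) { ok <- FALSE; break }
        for (l in nb) if (!(k %in% object@adjacency[[l]])) { ok <- FALSE; break }
        if (!ok) break
      }
      if (!ok) msg <- c(msg, "adjacency must be symmetric, irreflexive and in range")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param role \code{"source"} or \code{"target"}.
#' @param centroids P x 2 matrix of planar coordinates (km).
#' @param count integer counts (prevalence y or morbidity M).
#' @param offsetPrevalence expected prevalence counts E.
#' @param offsetMorbidity expected morbidity counts G (target frames).
#' @param covariate ecological covariate x (target frames).
#' @param adjacency list of integer neighbour-index vectors.
#' @param areaId area identifiers; generated when omitted.
#' @rdname AreaFrame-class
#' @export
AreaFrame <- function(role, centroids, count, offsetPrevalence,
                      offsetMorbidity = numeric(0), covariate = numeric(0),
                      adjacency = list(), areaId = NULL) {
  centroids <- as.matrix(centroids)
  storage.mode(centroids) <- "double"
  dimnames(centroids) <- NULL
  if (is.null(areaId))
    areaId <- sprintf("%s_%03d", substr(role, 1, 1), seq_len(nrow(centroids)))
  new("AreaFrame", role = role, areaId = as.character(areaId),
      centroids = centroids, count = as.integer(count),
      offsetPrevalence = as.numeric(offsetPrevalence),
      offsetMorbidity = as.numeric(offsetMorbidity),
      covariate = as.numeric(covariate),
      adjacency = lapply(adjacency, as.integer))
}

setMethod("show", "AreaFrame", function(object) {
  cat(sprintf("AreaFrame (%s): %d areas\n", object@role,
              nrow(object@centroids)))
  cat(sprintf("  counts: total %d, offsets: mean %.1f\n",
              sum(object@count), mean(object@offsetPrevalence)))
  if (length(object@covariate))
    cat(sprintf("  covariate: mean %.3f, sd %.3f\n",
                mean(object@covariate), sd(object@covariate)))
  if (length(object@adjacency))
    cat(sprintf("  adjacency: mean %.1f neighbours\n",
                mean(lengths(object@adjacency))))
})

#' One value of all model unknowns
#'
#' A single point in parameter space: regression coefficients, the two grid
#' random-effect vectors, per-area residuals on both frames, and the three
#' variance parameters.
#'
#' @slot beta numeric(2): prevalence intercept and pollution effect.
#' @slot gamma numeric(2): hospitalisation intercept and reflexive effect
#'   (the coefficient on neighbourhood relative prevalence, natural scale).
#' @slot delta numeric(2): log-variance regression intercept and slope.
#' @slot eta1 numeric(1): risk-factor process intercept.
#' @slot w1,w2 numeric(J): grid effects of the prevalence and risk-factor
#'   processes.
#' @slot eSource,eTarget per-area over-dispersion residuals.
#' @slot varW1,varW2,varX positive variances of the two grid processes and of
#'   the covariate observation model.
#' @export
setClass("ParamState",
  representation(beta = "numeric", gamma = "numeric", delta = "numeric",
                 eta1 = "numeric", w1 = "numeric", w2 = "numeric",
                 eSource = "numeric", eTarget = "numeric",
                 varW1 = "numeric", varW2 = "numeric", varX = "numeric"))

setValidity("ParamState", function(object) {
  msg <- character()
  if (length(object@beta) != 2L) msg <- c(msg, "beta must have length 2")
  if (length(object@gamma) != 2L) msg <- c(msg, "gamma must have length 2")
  if (length(object@delta) != 2L) msg <- c(msg, "delta must have length 2")
  if (length(object@eta1) != 1L) msg <- c(msg, "eta1 must have length 1")
  if (length(object@w1) != length(object@w2))
    msg <- c(msg, "w1 and w2 must have equal length J")
  for (s in c("varW1", "varW2", "varX"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
        slot(object, s) <= 0)
      msg <- c(msg, paste(s, "must be a single positive number"))
  vals <- c(object@beta, object@gamma, object@delta, object@eta1,
            object@w1, object@w2, object@eSource, object@eTarget)
  if (any(!is.finite(vals))) msg <- c(msg, "all parameters must be finite")
  if (length(msg)) msg else TRUE
})

#' @param beta,gamma,delta,eta1,w1,w2,eSource,eTarget,varW1,varW2,varX see
#'   the class slots.
#' @rdname ParamState-class
#' @export
ParamState <- function(beta, gamma, delta, eta1, w1, w2, eSource, eTarget,
                       varW1, varW2, varX) {
  new("ParamState", beta = as.numeric(beta), gamma = as.numeric(gamma),
      delta = as.numeric(delta), eta1 = as.numeric(eta1),
      w1 = as.numeric(w1), w2 = as.numeric(w2),
      eSource = as.numeric(eSource), eTarget = as.numeric(eTarget),
      varW1 = as.numeric(varW1), varW2 = as.numeric(varW2),
      varX = as.numeric(varX))
}

setMethod("show", "ParamState", function(object) {
  cat("ParamState:\n")
  cat(sprintf("  beta = (%.3f, %.3f), gamma = (%.3f, %.3f), delta = (%.3f, %.3f), eta1 = %.3f\n",
              object@beta[1], object@beta[2], object@gamma[1], object@gamma[2],
              object@delta[1], object@delta[2], object@eta1))
  cat(sprintf("  J = %d grid effects; N = %d source, K = %d target residuals\n",
              length(object@w1), length(object@eSource), length(object@eTarget)))
  cat(sprintf("  varW1 = %.4f, varW2 = %.4f, varX = %.4f\n",
              object@varW1, object@varW2, object@varX))
})

#' Retained posterior draws
#'
#' Output of [runMcmc()]: per-chain matrices of retained parameter draws plus
#' derived per-draw fields (relative prevalence on both frames, relative
#' hospitalisation risk, the covariate mean surface, and the three
#' stream-specific deviances), the per-block acceptance rates measured after
#' adaptation, and the configuration used.
#'
#' @slot chains list of numeric matrices (retained draws x parameters), one
#'   per chain, with named columns.
#' @slot rhoSource,rhoTarget,nu,muX lists of per-chain matrices of derived
#'   fields (draws x areas).
#' @slot deviances list of per-chain matrices with columns \code{y}, \code{M},
#'   \code{x}.
#' @slot acceptance named list of post-adaptation acceptance rates per block.
#' @slot config the [chainConfig()] list used.
#' @slot spec the [ModelSpec-class] fitted.
#' @export
setClass("PosteriorDraws",
  representation(chains = "list", rhoSource = "list", rhoTarget = "list",
                 nu = "list", muX = "list", deviances = "list",
                 acceptance = "list", config = "list", spec = "ModelSpec"))

setValidity("PosteriorDraws", function(object) {
  msg <- character()
  if (length(object@chains) < 1L) msg <- c(msg, "at least one chain required")
  nd <- vapply(object@chains, nrow, 0L)
  if (length(unique(nd)) > 1L) msg <- c(msg, "chains must have equal length")
  for (s in c("rhoSource", "rhoTarget", "nu", "muX", "deviances"))
    if (length(slot(object, s)) != length(object@chains))
      msg <- c(msg, paste(s, "must have one matrix per chain"))
  if (length(msg)) msg else TRUE
})

setMethod("show", "PosteriorDraws", function(object) {
  cat(sprintf("PosteriorDraws: %d chain(s) x %d retained draws, %d parameters\n",
              length(object@chains), nrow(object@chains[[1]]),
              ncol(object@chains[[1]])))
  cat(sprintf("  frames: N = %d source, K = %d target areas\n",
              ncol(object@rhoSource[[1]]), ncol(object@rhoTarget[[1]])))
  acc <- unlist(object@acceptance)
  if (length(acc))
    cat(sprintf("  acceptance (post-adaptation): %.2f-%.2f\n",
                min(acc), max(acc)))
})

#' Generating truth of a synthetic dataset
#'
#' Everything needed to score an estimator against the data-generating
#' process: the generating [ParamState-class], the latent fields at every
#' centroid, true relative risks on both frames, the offsets, and the
#' generator configuration (regeneration from config + seed is reproducible).
#'
#' @slot state the generating [ParamState-class].
#' @slot geography list with sourceCentroids, targetCentroids, grid, adjacency.
#' @slot z1Source,z1Target,z2Source,z2Target latent convolution fields.
#' @slot latentCovariate interpolated covariate at source centroids.
#' @slot rhoSource,rhoTarget true relative prevalence.
#' @slot nu true relative hospitalisation risk.
#' @slot offsetPrevSource,offsetPrevTarget,offsetMorbidity offsets E_i, E_k, G_k.
#' @slot config the generator configuration list (includes the seed).
#' @export
setClass("SyntheticTruth",
  representation(state = "ParamState", geography = "list",
                 z1Source = "numeric", z1Target = "numeric",
                 z2Source = "numeric", z2Target = "numeric",
                 latentCovariate = "numeric",
                 rhoSource = "numeric", rhoTarget = "numeric", nu = "numeric",
                 offsetPrevSource = "numeric", offsetPrevTarget = "numeric",
                 offsetMorbidity = "numeric", config = "list"))

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: N = %d source, K = %d target, J = %d grid points\n",
              length(object@rhoSource), length(object@rhoTarget),
              nrow(object@geography$grid@points)))
  cat(sprintf("  rho (target): range %.3f-%.3f; generating beta2 = %.3f, gamma2 = %.3f\n",
              min(object@rhoTarget), max(object@rhoTarget),
              object@state@beta[2], object@state@gamma[2]))
})
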