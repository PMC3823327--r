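#' Convolution field from grid effects
#'
#' The discrete process convolution: the latent field at point p is the
#' kernel-weighted sum of the grid random effects,
#' \eqn{z(p) = \sum_j k_{pj} w_j}.
#'
#' @param w numeric(J) grid random effects.
#' @param kmat P x J kernel weight matrix from [kernelMatrix()].
#' @return numeric(P) field values.
#' @export
convolveField <- function(w, kmat) {
  kmat <- as.matrix(kmat)
  if (length(w) != ncol(kmat))
    stop("length(w) must equal ncol(kmat)")
  drop(kmat %*% w)
}

#' Interpolated (latent) covariate at source centroids
#'
#' The ecological covariate is observed only on the target frame; its value
#' at source centroids is interpolated deterministically from the current
#' risk-factor process draw as \eqn{X_{Li} = \eta_1 + z_2(s_i)}.
#'
#' @param eta1 risk-factor process intercept.
#' @param z2Source numeric(N) risk-factor convolution field at source
#'   centroids.
#' @return numeric(N) interpolated covariate values.
#' @export
latentCovariate <- function(eta1, z2Source) {
  stopifnot(length(eta1) == 1L)
  eta1 + z2Source
}

#' Log relative risk of prevalence
#'
#' The prevalence regression on either frame:
#' \eqn{\log\rho = \beta_1 + \beta_2 x + z_1 + e}, where x is the latent
#' interpolated covariate on the source frame and the observed covariate on
#' the target frame.
#'
#' @param beta numeric(2): intercept and covariate effect.
#' @param covariate numeric(P) covariate values.
#' @param z1 numeric(P) prevalence convolution field.
#' @param e numeric(P) over-dispersion residuals.
#' @return numeric(P) log relative risks.
#' @export
logRelativeRisk <- function(beta, covariate, z1, e) {
  stopifnot(length(beta) == 2L)
  n <- length(covariate)
  if (length(z1) != n || length(e) != n)
    stop("covariate, z1 and e must have equal length")
  if (any(!is.finite(c(beta, covariate, z1, e))))
    stop("non-finite inputs")
  beta[1] + beta[2] * covariate + z1 + e
}

#' Heteroscedastic residual variance
#'
#' Residual variances follow a log-linear regression on the expected counts,
#' \eqn{\log V_p = \delta_1 + \delta_2 (E_p / c)}, allowing greater residual
#' variation in smaller (or larger) populations. Offsets are divided by
#' \code{offsetScale} (by default their mean) so that \eqn{\delta_2} is on a
#' per-average-population scale and the regression stays numerically tame for
#' offsets in the hundreds.
#'
#' @param delta numeric(2): log-variance intercept and slope.
#' @param offset numeric(P) positive expected counts.
#' @param offsetScale positive scalar divisor (default \code{mean(offset)}).
#' @return numeric(P) positive variances.
#' @export
residualVariance <- function(delta, offset, offsetScale = mean(offset)) {
  stopifnot(length(delta) == 2L)
  if (any(offset <= 0)) stop("offsets must be positive")
  stopifnot(offsetScale > 0)
  exp(delta[1] + delta[2] * (offset / offsetScale))
}

#' Log relative hospitalisation risk
#'
#' The reflexive morbidity stream: hospitalisation relative risk is regressed
#' on neighbourhood relative prevalence on its natural scale,
#' \eqn{\log\nu_k = \gamma_1 + \gamma_2 \rho_k}. A positive \eqn{\gamma_2}
#' (higher prevalence, more admissions) is a substantive expectation, not an
#' imposed constraint.
#'
#' @param gamma numeric(2): intercept and reflexive effect.
#' @param rhoTarget numeric(K) positive relative prevalence.
#' @return numeric(K) log relative hospitalisation risks.
#' @export
hospitalisationLogRisk <- function(gamma, rhoTarget) {
  stopifnot(length(gamma) == 2L)
  if (any(rhoTarget <= 0) || any(!is.finite(rhoTarget)))
    stop("rhoTarget must be positive and finite")
  gamma[1] + gamma[2] * rhoTarget
}

#' Poisson log likelihood
#'
#' @param count non-negative integer counts.
#' @param mean positive Poisson means.
#' @return scalar log likelihood (includes the factorial terms).
#' @export
loglikPoisson <- function(count, mean) {
  if (length(count) != length(mean)) stop("length mismatch")
  if (any(mean <= 0) || any(!is.finite(mean)))
    stop("Poisson means must be positive and finite")
  sum(dpois(count, mean, log = TRUE))
}

#' Gaussian log likelihood of the covariate stream
#'
#' The air-quality observation model: \eqn{x_k \sim N(\mu_k, \sigma_x^2)}
#' with \eqn{\mu_k = \eta_1 + z_2(t_k)}.
#'
#' @param x numeric(K) observed covariate.
#' @param mu numeric(K) means.
#' @param varX positive observation variance.
#' @return scalar log likelihood.
#' @export
loglikAirQuality <- function(x, mu, varX) {
  if (length(x) != length(mu)) stop("length mismatch")
  if (length(varX) != 1L || !is.finite(varX) || varX <= 0)
    stop("varX must be a single positive number")
  sum(dnorm(x, mu, sqrt(varX), log = TRUE))
}

# scaled Student-t log density: y ~ t_df(0, scale^2 = varW)
.dtScaled <- function(y, df, varW, log = TRUE) {
  s <- sqrt(varW)
  out <- dt(y / s, df = df, log = TRUE) - log(s)
  if (log) out else exp(out)
}

# log density of the grid-process prior for one effect vector
.logProcessPrior <- function(w, varW, process) {
  if (process@family == "normal")
    sum(dnorm(w, 0, sqrt(varW), log = TRUE))
  else
    sum(.dtScaled(w, process@df, varW))
}

# Gamma prior log density on a precision 1/v
.logPrecisionPrior <- function(v, priors) {
  dgamma(1 / v, shape = priors@precisionShape, rate = priors@precisionRate,
         log = TRUE)
}

#' Joint log prior density
#'
#' Sum of: normal priors on the regression coefficients (beta, gamma, delta,
#' eta1); the grid-process prior (normal or scaled Student-t) for w1 and w2;
#' heteroscedastic normal priors for the residuals on both frames with
#' variances from [residualVariance()]; and Gamma priors on the three
#' precisions 1/varW1, 1/varW2, 1/varX.
#'
#' @param state a [ParamState-class].
#' @param source,target [AreaFrame-class] objects (offsets drive the residual
#'   variances).
#' @param spec a [ModelSpec-class].
#' @return scalar log prior density.
#' @export
logPrior <- function(state, source, target, spec) {
  stopifnot(is(state, "ParamState"), is(spec, "ModelSpec"))
  validObject(state)
  pr <- spec@priors
  sdC <- sqrt(pr@coeffVariance)
  coeffs <- c(state@beta, state@gamma, state@delta, state@eta1)
  mCv <- rep(pr@coeffMean, length.out = 7L)
  lp <- sum(dnorm(coeffs, mCv, sdC, log = TRUE))
  lp <- lp + .logProcessPrior(state@w1, state@varW1, spec@process)
  lp <- lp + .logProcessPrior(state@w2, state@varW2, spec@process)
  Vs <- residualVariance(state@delta, offsetPrevalence(source))
  Vt <- residualVariance(state@delta, offsetPrevalence(target))
  lp <- lp + sum(dnorm(state@eSource, 0, sqrt(Vs), log = TRUE))
  lp <- lp + sum(dnorm(state@eTarget, 0, sqrt(Vt), log = TRUE))
  lp + .logPrecisionPrior(state@varW1, pr) +
    .logPrecisionPrior(state@varW2, pr) +
    .logPrecisionPrior(state@varX, pr)
}

# Precomputed data context shared by the posterior and the sampler.
.modelContext <- function(source, target, grid, spec) {
  stopifnot(is(source, "AreaFrame"), is(target, "AreaFrame"),
            is(grid, "ProcessGrid"), is(spec, "ModelSpec"))
  if (source@role != "source" || target@role != "target")
    stop("frames must have roles 'source' and 'target'")
  if (!length(covariate(target)))
    stop("target frame must carry the ecological covariate")
  if (!length(offsetMorbidity(target)))
    stop("target frame must carry morbidity offsets")
  list(
    Ks = kernelMatrix(centroids(source), grid, spec@kernel),
    Kt = kernelMatrix(centroids(target), grid, spec@kernel),
    y = counts(source), Es = offsetPrevalence(source),
    M = counts(target), G = offsetMorbidity(target),
    x = covariate(target), Et = offsetPrevalence(target),
    sEs = offsetPrevalence(source) / mean(offsetPrevalence(source)),
    sEt = offsetPrevalence(target) / mean(offsetPrevalence(target)),
    N = nAreas(source), K = nAreas(target), J = nGridPoints(grid))
}

# All derived model quantities at one parameter state.
.derivedFields <- function(state, ctx) {
  z1s <- drop(ctx$Ks %*% state@w1)
  z1t <- drop(ctx$Kt %*% state@w1)
  z2s <- drop(ctx$Ks %*% state@w2)
  z2t <- drop(ctx$Kt %*% state@w2)
  XL <- latentCovariate(state@eta1, z2s)
  logRhoS <- logRelativeRisk(state@beta, XL, z1s, state@eSource)
  logRhoT <- logRelativeRisk(state@beta, ctx$x, z1t, state@eTarget)
  rhoS <- exp(logRhoS)
  rhoT <- exp(logRhoT)
  logNu <- hospitalisationLogRisk(state@gamma, rhoT)
  list(z1Source = z1s, z1Target = z1t, z2Source = z2s, z2Target = z2t,
       latentCovariate = XL, rhoSource = rhoS, rhoTarget = rhoT,
       nu = exp(logNu), muX = state@eta1 + z2t,
       muY = ctx$Es * rhoS, muM = ctx$G * exp(logNu))
}

#' Joint log posterior density
#'
#' Sum of the three likelihood streams and the prior: Poisson prevalence
#' counts on the source frame (whose regression uses the interpolated latent
#' covariate), Poisson hospitalisation counts on the target frame (driven by
#' relative prevalence through the reflexive regression), the Gaussian
#' covariate stream, and [logPrior()]. Latent target-frame prevalence counts
#' contribute no likelihood term: they carry no information beyond the
#' relative risks themselves.
#'
#' @param state a [ParamState-class].
#' @param source source-frame [AreaFrame-class] (prevalence counts y).
#' @param target target-frame [AreaFrame-class] (morbidity counts M,
#'   covariate x, morbidity offsets G).
#' @param grid a [ProcessGrid-class].
#' @param spec a [ModelSpec-class].
#' @return scalar log posterior density (unnormalised).
#' @export
jointLogPosterior <- function(state, source, target, grid, spec) {
  ctx <- .modelContext(source, target, grid, spec)
  der <- .derivedFields(state, ctx)
  loglikPoisson(ctx$y, der$muY) +
    loglikPoisson(ctx$M, der$muM) +
    loglikAirQuality(ctx$x, der$muX, state@varX) +
    logPrior(state, source, target, spec)
}
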