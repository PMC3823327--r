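#' MCMC chain configuration
#'
#' Settings for [runMcmc()]. Per-chain seeds are derived from \code{seed} by a
#' fixed splitting rule (\code{(seed * 1009 + chain * 7919) mod (2^31 - 1)}),
#' so runs are reproducible across platforms up to floating-point conformance.
#' Retained draws per chain are \code{floor((1 - burnFraction) * nIter /
#' thin)} and must be at least 100 for the convergence diagnostics to be
#' meaningful.
#'
#' @param nChains number of chains (>= 2 for convergence diagnostics; 1 is
#'   allowed for exploratory runs).
#' @param nIter total iterations per chain.
#' @param burnFraction fraction of iterations discarded as burn-in
#'   (default 0.5, i.e. inference on second halves of the chains).
#' @param thin thinning interval (default 1).
#' @param seed master integer seed.
#' @param adaptIters iterations over which proposal scales adapt
#'   (default: the burn-in length; adaptation never extends past burn-in).
#' @param targetAccept target acceptance rate for the adaptive random-walk
#'   updates (default 0.35, between the scalar and multivariate optima).
#' @return a named list of validated settings.
#' @export
chainConfig <- function(nChains = 2, nIter = 5000, burnFraction = 0.5,
                        thin = 1, seed = 1, adaptIters = NULL,
                        targetAccept = 0.35) {
  stopifnot(nChains >= 1, nIter >= 2, burnFraction > 0, burnFraction < 1,
            thin >= 1, targetAccept > 0, targetAccept < 1)
  nBurn <- floor(burnFraction * nIter)
  if (is.null(adaptIters)) adaptIters <- nBurn
  adaptIters <- min(adaptIters, nBurn)
  kept <- floor((nIter - nBurn) / thin)
  if (kept < 100)
    stop("configuration retains ", kept,
         " draws per chain; at least 100 are required")
  list(nChains = as.integer(nChains), nIter = as.integer(nIter),
       burnFraction = burnFraction, thin = as.integer(thin),
       seed = as.integer(seed), adaptIters = as.integer(adaptIters),
       targetAccept = targetAccept, nBurn = as.integer(nBurn),
       nRetainedPerChain = as.integer(kept))
}

#' Total retained draws implied by a configuration
#'
#' @param config a [chainConfig()] list.
#' @return integer: retained draws summed over chains.
#' @export
retainedDraws <- function(config) {
  config$nChains * config$nRetainedPerChain
}

.chainSeed <- function(seed, chain) {
  as.integer((as.numeric(seed) * 1009 + chain * 7919) %% (2^31 - 1))
}

#' Deterministic over-dispersed initial state
#'
#' Coefficients start at zero, grid effects and residuals are drawn from
#' N(0, 0.01) under the given seed, and all variances start at 1. The joint
#' posterior is finite at any such state.
#'
#' @param source,target [AreaFrame-class] frames.
#' @param grid a [ProcessGrid-class].
#' @param spec a [ModelSpec-class].
#' @param seed integer seed.
#' @return a valid [ParamState-class].
#' @export
initialState <- function(source, target, grid, spec, seed) {
  N <- nAreas(source); K <- nAreas(target); J <- nGridPoints(grid)
  set.seed(as.integer(seed))
  ParamState(beta = c(0, 0), gamma = c(0, 0), delta = c(0, 0), eta1 = 0,
             w1 = rnorm(J, 0, 0.1), w2 = rnorm(J, 0, 0.1),
             eSource = rnorm(N, 0, 0.1), eTarget = rnorm(K, 0, 0.1),
             varW1 = 1, varW2 = 1, varX = 1)
}

# One adaptive Metropolis-within-Gibbs chain.
#
# The hot loop never evaluates dpois/dnorm: Metropolis log-ratios use the
# closed-form differences in which factorial and normalising constants
# cancel. For a Poisson stream with log-mean offset + lr,
#   delta loglik = sum(count * d(lr)) - sum(mu' - mu),
# and for the Gaussian covariate stream with mean mux,
#   delta loglik = (sum(r * dmu) - sum(dmu^2)/2) / varX,  r = x - mux.
# Caches: lrs/lrt (log relative risks), muY/muM (fitted means), rt, lnu,
# mux. Grid effects and residual vectors are updated site-wise (residuals in
# one vectorised sweep of conditionally independent sites).
.runChain <- function(ctx, spec, config, chainSeed) {
  N <- ctx$N; K <- ctx$K; J <- ctx$J
  pr <- spec@priors
  tProcess <- spec@process@family == "student_t"
  df <- spec@process@df
  a0 <- pr@precisionShape; b0 <- pr@precisionRate
  vC <- pr@coeffVariance
  mCv <- rep(pr@coeffMean, length.out = 7L)  # beta1..eta1 order
  Ks <- ctx$Ks; Kt <- ctx$Kt
  y <- ctx$y; Es <- ctx$Es; M <- ctx$M; G <- ctx$G; x <- ctx$x
  sEs <- ctx$sEs; sEt <- ctx$sEt
  sumY <- sum(y); sumM <- sum(M)
  yKs <- drop(crossprod(Ks, y))       # sum_i y_i Ks[i,j], per grid site
  Kt2 <- colSums(Kt^2)
  sumSEs <- sum(sEs); sumSEt <- sum(sEt)
  rowSs <- rowSums(Ks); rowSt <- rowSums(Kt)
  Rbar <- mean(c(rowSs, rowSt))       # typical kernel row sum (level moves)

  # initial state
  set.seed(chainSeed)
  b1 <- 0; b2 <- 0; g1 <- 0; g2 <- 0; d1 <- 0; d2 <- 0; eta1 <- 0
  w1 <- rnorm(J, 0, 0.1); w2 <- rnorm(J, 0, 0.1)
  es <- rnorm(N, 0, 0.1); et <- rnorm(K, 0, 0.1)
  varW1 <- 1; varW2 <- 1; varX <- 1

  # caches (z1s/z1t/z2s/z2t maintained for the non-centered scale moves)
  z1s <- drop(Ks %*% w1); z1t <- drop(Kt %*% w1)
  z2s <- drop(Ks %*% w2); z2t <- drop(Kt %*% w2)
  XL <- eta1 + z2s
  lrs <- b1 + b2 * XL + z1s + es; muY <- Es * exp(lrs)
  lrt <- b1 + b2 * x + z1t + et; rt <- exp(lrt)
  lnu <- g1 + g2 * rt; muM <- G * exp(lnu)
  mux <- eta1 + z2t
  sMuY <- sum(muY); sMuM <- sum(muM); sMrt <- sum(M * rt)
  iVs <- exp(-(d1 + d2 * sEs)); iVt <- exp(-(d1 + d2 * sEt))

  pieces <- c(y = sum(dpois(y, muY, log = TRUE)),
              M = sum(dpois(M, muM, log = TRUE)),
              x = sum(dnorm(x, mux, sqrt(varX), log = TRUE)))
  if (any(!is.finite(pieces)))
    stop("non-finite log posterior at the initial state (stream: ",
         paste(names(pieces)[!is.finite(pieces)], collapse = ", "), ")")

  scalarNames <- c("beta1", "beta2", "gamma1", "gamma2",
                   "delta1", "delta2", "eta1",
                   "deltaNC1", "deltaNC2", "varW1NC", "varW2NC",
                   "levelW1", "levelW2", "betaRidge", "gammaRidge")
  if (tProcess) scalarNames <- c(scalarNames, "logVarW1", "logVarW2")
  lsS <- setNames(rep(log(0.1), length(scalarNames)), scalarNames)
  lsW1 <- rep(log(0.3), J); lsW2 <- rep(log(0.3), J)
  lsEs <- rep(log(0.3), N); lsEt <- rep(log(0.3), K)
  tgt <- config$targetAccept
  accSum <- setNames(numeric(length(scalarNames) + 4),
                     c(scalarNames, "w1", "w2", "eSource", "eTarget"))
  accN <- 0L

  nIter <- config$nIter; nBurn <- config$nBurn
  adaptIters <- config$adaptIters; thin <- config$thin
  kept <- config$nRetainedPerChain
  parNames <- c("beta1", "beta2", "gamma1", "gamma2",
                "delta1", "delta2", "eta1", "varW1", "varW2", "varX",
                sprintf("w1[%d]", seq_len(J)), sprintf("w2[%d]", seq_len(J)),
                sprintf("eSource[%d]", seq_len(N)),
                sprintf("eTarget[%d]", seq_len(K)))
  params <- matrix(NA_real_, kept, length(parNames),
                   dimnames = list(NULL, parNames))
  rhoSrc <- matrix(NA_real_, kept, N)
  rhoTgt <- matrix(NA_real_, kept, K)
  nuMat <- matrix(NA_real_, kept, K)
  muxMat <- matrix(NA_real_, kept, K)
  devMat <- matrix(NA_real_, kept, 3, dimnames = list(NULL, c("y", "M", "x")))
  keptRow <- 0L

  set.seed(.chainSeed(chainSeed, 1L))

  coefPriorDiff <- function(cur, d, m)
    ((cur - m)^2 - (cur + d - m)^2) / (2 * vC)
  wPriorDiff <- function(wNew, wOld, varW) {
    if (tProcess) .dtScaled(wNew, df, varW) - .dtScaled(wOld, df, varW)
    else (wOld^2 - wNew^2) / (2 * varW)
  }

  for (it in seq_len(nIter)) {
    adapting <- it <= adaptIters
    gain <- if (adapting) it^-0.6 else 0
    tracking <- it > nBurn

    ## -- beta1 (streams y, M) -----------------------------------------
    d <- rnorm(1) * exp(lsS[["beta1"]])
    ed <- exp(d)
    rt2 <- rt * ed; lnu2 <- g1 + g2 * rt2; muM2 <- G * exp(lnu2)
    sMuM2 <- sum(muM2)
    la <- d * sumY - (ed - 1) * sMuY +
      g2 * (ed - 1) * sMrt - (sMuM2 - sMuM) + coefPriorDiff(b1, d, mCv[1])
    apr <- min(1, exp(la))
    if (runif(1) < apr) {
      b1 <- b1 + d; lrs <- lrs + d; muY <- muY * ed; sMuY <- sMuY * ed
      lrt <- lrt + d; rt <- rt2; lnu <- lnu2; muM <- muM2
      sMuM <- sMuM2; sMrt <- sMrt * ed
    }
    if (adapting) lsS[["beta1"]] <- lsS[["beta1"]] + gain * (apr - tgt)
    if (tracking) accSum[["beta1"]] <- accSum[["beta1"]] + apr

    ## -- beta2 (streams y, M) -----------------------------------------
    d <- rnorm(1) * exp(lsS[["beta2"]])
    lrs2 <- lrs + d * XL; muY2 <- Es * exp(lrs2); sMuY2 <- sum(muY2)
    lrt2 <- lrt + d * x; rt2 <- exp(lrt2)
    lnu2 <- g1 + g2 * rt2; muM2 <- G * exp(lnu2); sMuM2 <- sum(muM2)
    sMrt2 <- sum(M * rt2)
    la <- d * sum(y * XL) - (sMuY2 - sMuY) +
      g2 * (sMrt2 - sMrt) - (sMuM2 - sMuM) + coefPriorDiff(b2, d, mCv[2])
    apr <- min(1, exp(la))
    if (runif(1) < apr) {
      b2 <- b2 + d; lrs <- lrs2; muY <- muY2; sMuY <- sMuY2
      lrt <- lrt2; rt <- rt2; lnu <- lnu2; muM <- muM2
      sMuM <- sMuM2; sMrt <- sMrt2
    }
    if (adapting) lsS[["beta2"]] <- lsS[["beta2"]] + gain * (apr - tgt)
    if (tracking) accSum[["beta2"]] <- accSum[["beta2"]] + apr

    ## -- gamma1 (stream M; closed form) -------------------------------
    d <- rnorm(1) * exp(lsS[["gamma1"]])
    la <- d * sumM - (exp(d) - 1) * sMuM + coefPriorDiff(g1, d, mCv[3])
    apr <- min(1, exp(la))
    if (runif(1) < apr) {
      g1 <- g1 + d; lnu <- lnu + d; muM <- muM * exp(d); sMuM <- sum(muM)
    }
    if (adapting) lsS[["gamma1"]] <- lsS[["gamma1"]] + gain * (apr - tgt)
    if (tracking) accSum[["gamma1"]] <- accSum[["gamma1"]] + apr

    ## -- gamma2 (stream M) --------------------------------------------
    d <- rnorm(1) * exp(lsS[["gamma2"]])
    lnu2 <- lnu + d * rt; muM2 <- G * exp(lnu2); sMuM2 <- sum(muM2)
    la <- d * sMrt - (sMuM2 - sMuM) + coefPriorDiff(g2, d, mCv[4])
    apr <- min(1, exp(la))
    if (runif(1) < apr) {
      g2 <- g2 + d; lnu <- lnu2; muM <- muM2; sMuM <- sMuM2
    }
    if (adapting) lsS[["gamma2"]] <- lsS[["gamma2"]] + gain * (apr - tgt)
    if (tracking) accSum[["gamma2"]] <- accSum[["gamma2"]] + apr

    ## -- ridge moves for near-collinear coefficient pairs -------------
    # (beta1, beta2) and (gamma1, gamma2) sit on narrow likelihood ridges
    # (the covariate and the relative risks have nearly constant means), so
    # slide along the ridge: raise the slope, lower the intercept by the
    # slope change times the mean regressor.
    d <- rnorm(1) * exp(lsS[["betaRidge"]])
    xref <- (sum(XL) + sum(x)) / (N + K)
    dls <- d * (XL - xref); dlt <- d * (x - xref)
    lrs2 <- lrs + dls; muY2 <- Es * exp(lrs2); sMuY2 <- sum(muY2)
    lrt2 <- lrt + dlt; rt2 <- exp(lrt2)
    lnu2 <- g1 + g2 * rt2; muM2 <- G * exp(lnu2); sMuM2 <- sum(muM2)
    la <- sum(y * dls) - (sMuY2 - sMuY) +
      sum(M * (lnu2 - lnu)) - (sMuM2 - sMuM) +
      coefPriorDiff(b1, -d * xref, mCv[1]) + coefPriorDiff(b2, d, mCv[2])
    apr <- min(1, exp(la))
    if (runif(1) < apr) {
      b1 <- b1 - d * xref; b2 <- b2 + d
      lrs <- lrs2; muY <- muY2; sMuY <- sMuY2
      lrt <- lrt2; rt <- rt2; lnu <- lnu2; muM <- muM2
      sMuM <- sMuM2; sMrt <- sum(M * rt)
    }
    if (adapting) lsS[["betaRidge"]] <- lsS[["betaRidge"]] + gain * (apr - tgt)
    if (tracking) accSum[["betaRidge"]] <- accSum[["betaRidge"]] + apr

    d <- rnorm(1) * exp(lsS[["gammaRidge"]])
    rref <- mean(rt)
    lnu2 <- lnu + d * (rt - rref)
    muM2 <- G * exp(lnu2); sMuM2 <- sum(muM2)
    la <- sum(M * (lnu2 - lnu)) - (sMuM2 - sMuM) +
      coefPriorDiff(g1, -d * rref, mCv[3]) + coefPriorDiff(g2, d, mCv[4])
    apr <- min(1, exp(la))
    if (runif(1) < apr) {
      g1 <- g1 - d * rref; g2 <- g2 + d
      lnu <- lnu2; muM <- muM2; sMuM <- sMuM2
    }
    if (adapting) lsS[["gammaRidge"]] <- lsS[["gammaRidge"]] + gain * (apr - tgt)
    if (tracking) accSum[["gammaRidge"]] <- accSum[["gammaRidge"]] + apr

    ## -- delta1, delta2 (residual priors only) ------------------------
    sEs2 <- sum(es^2 * iVs) + sum(et^2 * iVt)   # quadratic form, current
    for (di in 1:2) {
      nm <- c("delta1", "delta2")[di]
      d <- rnorm(1) * exp(lsS[[nm]])
      if (di == 1) {
        iVs2 <- iVs * exp(-d); iVt2 <- iVt * exp(-d)
        dLogDet <- (N + K) * d
        cur <- d1
      } else {
        iVs2 <- iVs * exp(-d * sEs); iVt2 <- iVt * exp(-d * sEt)
        dLogDet <- d * (sumSEs + sumSEt)
        cur <- d2
      }
      q2 <- sum(es^2 * iVs2) + sum(et^2 * iVt2)
      la <- -0.5 * (dLogDet + q2 - sEs2) + coefPriorDiff(cur, d, mCv[4 + di])
      apr <- min(1, exp(la))
      if (runif(1) < apr) {
        if (di == 1) d1 <- d1 + d else d2 <- d2 + d
        iVs <- iVs2; iVt <- iVt2; sEs2 <- q2
      }
      if (adapting) lsS[[nm]] <- lsS[[nm]] + gain * (apr - tgt)
      if (tracking) accSum[[nm]] <- accSum[[nm]] + apr
    }

    ## -- eta1 (stream y through X_L; stream x) ------------------------
    d <- rnorm(1) * exp(lsS[["eta1"]])
    edb <- exp(b2 * d)
    rx <- x - mux
    la <- (b2 * d) * sumY - (edb - 1) * sMuY +
      (d * sum(rx) - K * d^2 / 2) / varX + coefPriorDiff(eta1, d, mCv[7])
    apr <- min(1, exp(la))
    if (runif(1) < apr) {
      eta1 <- eta1 + d; XL <- XL + d
      lrs <- lrs + b2 * d; muY <- muY * edb; sMuY <- sMuY * edb
      mux <- mux + d
    }
    if (adapting) lsS[["eta1"]] <- lsS[["eta1"]] + gain * (apr - tgt)
    if (tracking) accSum[["eta1"]] <- accSum[["eta1"]] + apr

    ## -- w1 sites (streams y, M) --------------------------------------
    aprW <- 0
    for (j in seq_len(J)) {
      dw <- rnorm(1) * exp(lsW1[j])
      lrs2 <- lrs + Ks[, j] * dw; muY2 <- Es * exp(lrs2); sMuY2 <- sum(muY2)
      lrt2 <- lrt + Kt[, j] * dw; rt2 <- exp(lrt2)
      lnu2 <- g1 + g2 * rt2; muM2 <- G * exp(lnu2); sMuM2 <- sum(muM2)
      sMrt2 <- sum(M * rt2)
      la <- dw * yKs[j] - (sMuY2 - sMuY) +
        g2 * (sMrt2 - sMrt) - (sMuM2 - sMuM) +
        wPriorDiff(w1[j] + dw, w1[j], varW1)
      apr <- min(1, exp(la))
      if (runif(1) < apr) {
        w1[j] <- w1[j] + dw
        z1s <- z1s + Ks[, j] * dw; z1t <- z1t + Kt[, j] * dw
        lrs <- lrs2; muY <- muY2; sMuY <- sMuY2
        lrt <- lrt2; rt <- rt2; lnu <- lnu2; muM <- muM2
        sMuM <- sMuM2; sMrt <- sMrt2
      }
      if (adapting) lsW1[j] <- lsW1[j] + gain * (apr - tgt)
      aprW <- aprW + apr
    }
    if (tracking) accSum[["w1"]] <- accSum[["w1"]] + aprW / J

    ## -- w2 sites (stream y through X_L; stream x) --------------------
    aprW <- 0
    rx <- x - mux
    rxKt <- drop(crossprod(Kt, rx))
    for (j in seq_len(J)) {
      dw <- rnorm(1) * exp(lsW2[j])
      lrs2 <- lrs + (b2 * dw) * Ks[, j]
      muY2 <- Es * exp(lrs2); sMuY2 <- sum(muY2)
      la <- (b2 * dw) * yKs[j] - (sMuY2 - sMuY) +
        (dw * rxKt[j] - dw^2 * Kt2[j] / 2) / varX +
        wPriorDiff(w2[j] + dw, w2[j], varW2)
      apr <- min(1, exp(la))
      if (runif(1) < apr) {
        w2[j] <- w2[j] + dw
        z2s <- z2s + Ks[, j] * dw; z2t <- z2t + Kt[, j] * dw
        XL <- XL + Ks[, j] * dw
        lrs <- lrs2; muY <- muY2; sMuY <- sMuY2
        mux <- mux + Kt[, j] * dw
        rx <- x - mux
        rxKt <- drop(crossprod(Kt, rx))
      }
      if (adapting) lsW2[j] <- lsW2[j] + gain * (apr - tgt)
      aprW <- aprW + apr
    }
    if (tracking) accSum[["w2"]] <- accSum[["w2"]] + aprW / J

    ## -- source residuals (independent sites, vectorised) -------------
    de <- rnorm(N) * exp(lsEs)
    prop <- es + de
    muY2 <- muY * exp(de)
    la <- y * de - (muY2 - muY) + (es^2 - prop^2) * iVs / 2
    apr <- pmin(1, exp(la))
    acc <- runif(N) < apr
    if (any(acc)) {
      es[acc] <- prop[acc]; lrs[acc] <- lrs[acc] + de[acc]
      muY[acc] <- muY2[acc]; sMuY <- sum(muY)
    }
    if (adapting) lsEs <- lsEs + gain * (apr - tgt)
    if (tracking) accSum[["eSource"]] <- accSum[["eSource"]] + mean(apr)

    ## -- target residuals (independent sites, vectorised) -------------
    de <- rnorm(K) * exp(lsEt)
    prop <- et + de
    rt2 <- rt * exp(de)
    lnu2 <- g1 + g2 * rt2; muM2 <- G * exp(lnu2)
    la <- M * (lnu2 - lnu) - (muM2 - muM) + (et^2 - prop^2) * iVt / 2
    apr <- pmin(1, exp(la))
    acc <- runif(K) < apr
    if (any(acc)) {
      et[acc] <- prop[acc]; lrt[acc] <- lrt[acc] + de[acc]
      rt[acc] <- rt2[acc]; lnu[acc] <- lnu2[acc]; muM[acc] <- muM2[acc]
      sMuM <- sum(muM); sMrt <- sum(M * rt)
    }
    if (adapting) lsEt <- lsEt + gain * (apr - tgt)
    if (tracking) accSum[["eTarget"]] <- accSum[["eTarget"]] + mean(apr)

    ## -- grid-process variances ---------------------------------------
    if (!tProcess) {
      varW1 <- 1 / rgamma(1, a0 + J / 2, rate = b0 + sum(w1^2) / 2)
      varW2 <- 1 / rgamma(1, a0 + J / 2, rate = b0 + sum(w2^2) / 2)
    } else {
      for (vi in 1:2) {
        nm <- c("logVarW1", "logVarW2")[vi]
        v <- if (vi == 1) varW1 else varW2
        w <- if (vi == 1) w1 else w2
        d <- rnorm(1) * exp(lsS[[nm]])
        v2 <- v * exp(d)
        la <- sum(.dtScaled(w, df, v2)) - sum(.dtScaled(w, df, v)) +
          dgamma(1 / v2, a0, rate = b0, log = TRUE) -
          dgamma(1 / v, a0, rate = b0, log = TRUE) - d
        apr <- min(1, exp(la))
        if (runif(1) < apr) {
          if (vi == 1) varW1 <- v2 else varW2 <- v2
        }
        if (adapting) lsS[[nm]] <- lsS[[nm]] + gain * (apr - tgt)
        if (tracking) accSum[[nm]] <- accSum[[nm]] + apr
      }
    }

    ## -- non-centered scale moves -------------------------------------
    # Centered updates of delta and the process variances mix slowly when
    # the residuals or grid effects are weakly identified (the variance then
    # tracks the current draws instead of the data). Interweaving with
    # non-centered moves -- rescaling the effects jointly with their
    # variance while holding the standardised effects fixed -- restores
    # direct likelihood feedback on the scale parameters.
    for (di in 1:2) {
      nm <- c("deltaNC1", "deltaNC2")[di]
      d <- rnorm(1) * exp(lsS[[nm]])
      if (di == 1) { fs <- exp(d / 2); ft <- fs; cur <- d1 }
      else { fs <- exp(d * sEs / 2); ft <- exp(d * sEt / 2); cur <- d2 }
      dls <- es * (fs - 1); dlt <- et * (ft - 1)
      lrs2 <- lrs + dls; muY2 <- Es * exp(lrs2); sMuY2 <- sum(muY2)
      lrt2 <- lrt + dlt; rt2 <- exp(lrt2)
      lnu2 <- g1 + g2 * rt2; muM2 <- G * exp(lnu2); sMuM2 <- sum(muM2)
      la <- sum(y * dls) - (sMuY2 - sMuY) +
        sum(M * (lnu2 - lnu)) - (sMuM2 - sMuM) + coefPriorDiff(cur, d, mCv[4 + di])
      apr <- min(1, exp(la))
      if (runif(1) < apr) {
        if (di == 1) {
          d1 <- d1 + d; iVs <- iVs * exp(-d); iVt <- iVt * exp(-d)
        } else {
          d2 <- d2 + d
          iVs <- iVs * exp(-d * sEs); iVt <- iVt * exp(-d * sEt)
        }
        es <- es * fs; et <- et * ft
        lrs <- lrs2; muY <- muY2; sMuY <- sMuY2
        lrt <- lrt2; rt <- rt2; lnu <- lnu2; muM <- muM2
        sMuM <- sMuM2; sMrt <- sum(M * rt)
      }
      if (adapting) lsS[[nm]] <- lsS[[nm]] + gain * (apr - tgt)
      if (tracking) accSum[[nm]] <- accSum[[nm]] + apr
    }

    # varW1: rescale w1 (hence z1 on both frames) with the variance
    d <- rnorm(1) * exp(lsS[["varW1NC"]])
    f <- exp(d / 2); v2 <- varW1 * exp(d)
    dls <- (f - 1) * z1s; dlt <- (f - 1) * z1t
    lrs2 <- lrs + dls; muY2 <- Es * exp(lrs2); sMuY2 <- sum(muY2)
    lrt2 <- lrt + dlt; rt2 <- exp(lrt2)
    lnu2 <- g1 + g2 * rt2; muM2 <- G * exp(lnu2); sMuM2 <- sum(muM2)
    la <- sum(y * dls) - (sMuY2 - sMuY) +
      sum(M * (lnu2 - lnu)) - (sMuM2 - sMuM) +
      dgamma(1 / v2, a0, rate = b0, log = TRUE) -
      dgamma(1 / varW1, a0, rate = b0, log = TRUE) - d
    apr <- min(1, exp(la))
    if (runif(1) < apr) {
      varW1 <- v2; w1 <- w1 * f; z1s <- z1s * f; z1t <- z1t * f
      lrs <- lrs2; muY <- muY2; sMuY <- sMuY2
      lrt <- lrt2; rt <- rt2; lnu <- lnu2; muM <- muM2
      sMuM <- sMuM2; sMrt <- sum(M * rt)
    }
    if (adapting) lsS[["varW1NC"]] <- lsS[["varW1NC"]] + gain * (apr - tgt)
    if (tracking) accSum[["varW1NC"]] <- accSum[["varW1NC"]] + apr

    # varW2: rescale w2 (hence z2, X_L, mu_x) with the variance
    d <- rnorm(1) * exp(lsS[["varW2NC"]])
    f <- exp(d / 2); v2 <- varW2 * exp(d)
    dls <- b2 * (f - 1) * z2s
    lrs2 <- lrs + dls; muY2 <- Es * exp(lrs2); sMuY2 <- sum(muY2)
    dmu <- (f - 1) * z2t
    rx <- x - mux
    la <- sum(y * dls) - (sMuY2 - sMuY) +
      (sum(rx * dmu) - sum(dmu^2) / 2) / varX +
      dgamma(1 / v2, a0, rate = b0, log = TRUE) -
      dgamma(1 / varW2, a0, rate = b0, log = TRUE) - d
    apr <- min(1, exp(la))
    if (runif(1) < apr) {
      varW2 <- v2; w2 <- w2 * f; z2s <- z2s * f; z2t <- z2t * f
      XL <- eta1 + z2s; mux <- eta1 + z2t
      lrs <- lrs2; muY <- muY2; sMuY <- sMuY2
    }
    if (adapting) lsS[["varW2NC"]] <- lsS[["varW2NC"]] + gain * (apr - tgt)
    if (tracking) accSum[["varW2NC"]] <- accSum[["varW2NC"]] + apr

    ## -- level moves (intercepts vs grid-field means) ------------------
    # The intercepts are confounded with the mean level of their convolution
    # field (a constant shift of w moves every z by about the kernel row
    # sum). Joint proposals shifting the intercept and counter-shifting the
    # field keep the likelihood nearly unchanged and decorrelate the pair.
    wSum <- if (tProcess) function(w, v) sum(.dtScaled(w, df, v))
            else function(w, v) -sum(w^2) / (2 * v)
    d <- rnorm(1) * exp(lsS[["levelW1"]])
    sh <- d / Rbar
    dls <- d - sh * rowSs; dlt <- d - sh * rowSt
    lrs2 <- lrs + dls; muY2 <- Es * exp(lrs2); sMuY2 <- sum(muY2)
    lrt2 <- lrt + dlt; rt2 <- exp(lrt2)
    lnu2 <- g1 + g2 * rt2; muM2 <- G * exp(lnu2); sMuM2 <- sum(muM2)
    la <- sum(y * dls) - (sMuY2 - sMuY) +
      sum(M * (lnu2 - lnu)) - (sMuM2 - sMuM) +
      wSum(w1 - sh, varW1) - wSum(w1, varW1) + coefPriorDiff(b1, d, mCv[1])
    apr <- min(1, exp(la))
    if (runif(1) < apr) {
      b1 <- b1 + d; w1 <- w1 - sh
      z1s <- z1s - sh * rowSs; z1t <- z1t - sh * rowSt
      lrs <- lrs2; muY <- muY2; sMuY <- sMuY2
      lrt <- lrt2; rt <- rt2; lnu <- lnu2; muM <- muM2
      sMuM <- sMuM2; sMrt <- sum(M * rt)
    }
    if (adapting) lsS[["levelW1"]] <- lsS[["levelW1"]] + gain * (apr - tgt)
    if (tracking) accSum[["levelW1"]] <- accSum[["levelW1"]] + apr

    d <- rnorm(1) * exp(lsS[["levelW2"]])
    sh <- d / Rbar
    dXL <- d - sh * rowSs; dmu <- d - sh * rowSt
    dls <- b2 * dXL
    lrs2 <- lrs + dls; muY2 <- Es * exp(lrs2); sMuY2 <- sum(muY2)
    rx <- x - mux
    la <- sum(y * dls) - (sMuY2 - sMuY) +
      (sum(rx * dmu) - sum(dmu^2) / 2) / varX +
      wSum(w2 - sh, varW2) - wSum(w2, varW2) + coefPriorDiff(eta1, d, mCv[7])
    apr <- min(1, exp(la))
    if (runif(1) < apr) {
      eta1 <- eta1 + d; w2 <- w2 - sh
      z2s <- z2s - sh * rowSs; z2t <- z2t - sh * rowSt
      XL <- eta1 + z2s; mux <- eta1 + z2t
      lrs <- lrs2; muY <- muY2; sMuY <- sMuY2
    }
    if (adapting) lsS[["levelW2"]] <- lsS[["levelW2"]] + gain * (apr - tgt)
    if (tracking) accSum[["levelW2"]] <- accSum[["levelW2"]] + apr

    ## -- covariate observation variance (conjugate) -------------------
    ssrX <- sum((x - mux)^2)
    varX <- 1 / rgamma(1, a0 + K / 2, rate = b0 + ssrX / 2)

    if (tracking) accN <- accN + 1L

    ## -- retention ----------------------------------------------------
    if (it > nBurn && (it - nBurn) %% thin == 0L && keptRow < kept) {
      keptRow <- keptRow + 1L
      rs <- muY / Es
      params[keptRow, ] <- c(b1, b2, g1, g2, d1, d2, eta1,
                             varW1, varW2, varX, w1, w2, es, et)
      rhoSrc[keptRow, ] <- rs
      rhoTgt[keptRow, ] <- rt
      nuMat[keptRow, ] <- exp(lnu)
      muxMat[keptRow, ] <- mux
      devMat[keptRow, ] <- c(poissonDeviance(y, muY),
                             poissonDeviance(M, muM),
                             K * log(2 * pi * varX) + ssrX / varX)
    }
  }

  accRates <- accSum / max(accN, 1L)
  if (any(accRates[!grepl("logVar", names(accRates))] == 0))
    warning("zero post-adaptation acceptance in block(s): ",
            paste(names(accRates)[accRates == 0], collapse = ", "))
  list(params = params, rhoSource = rhoSrc, rhoTarget = rhoTgt,
       nu = nuMat, muX = muxMat, deviances = devMat, acceptance = accRates)
}

#' Fit the model by adaptive Metropolis-within-Gibbs
#'
#' Samples the joint posterior of all unknowns. Scalar coefficients and the
#' grid effects (one site at a time) use adaptive random-walk Metropolis
#' steps; the per-area residuals are conditionally independent given the rest
#' and are updated in one vectorised sweep of single-site Metropolis moves;
#' the grid-process precisions (under a normal process) and the covariate
#' observation precision have conjugate Gamma full conditionals and are
#' updated by Gibbs steps. Proposal scales adapt by a diminishing
#' Robbins-Monro recursion on the log scale during burn-in and are frozen
#' afterwards, so retained draws satisfy detailed balance. Identical data,
#' spec, config and seed give identical draws.
#'
#' @param source,target [AreaFrame-class] frames (the target frame must carry
#'   morbidity counts and offsets and the ecological covariate).
#' @param grid a [ProcessGrid-class].
#' @param spec a [ModelSpec-class].
#' @param config a [chainConfig()] list.
#' @return a [PosteriorDraws-class].
#' @examples
#' \donttest{
#' geo <- generateGeography(nSource = 20, nTarget = 40,
#'                          regionExtent = c(10, 8), seed = 1)
#' truth <- generateTruth(geo, ModelSpec(), seed = 2)
#' obs <- simulateObservations(truth, seed = 3)
#' fit <- runMcmc(obs$source, obs$target, geo$grid, ModelSpec(),
#'                chainConfig(nChains = 2, nIter = 400, seed = 4))
#' }
#' @export
runMcmc <- function(source, target, grid, spec, config = chainConfig()) {
  ctx <- .modelContext(source, target, grid, spec)
  out <- lapply(seq_len(config$nChains), function(ch)
    .runChain(ctx, spec, config, .chainSeed(config$seed, ch)))
  new("PosteriorDraws",
      chains = lapply(out, `[[`, "params"),
      rhoSource = lapply(out, `[[`, "rhoSource"),
      rhoTarget = lapply(out, `[[`, "rhoTarget"),
      nu = lapply(out, `[[`, "nu"),
      muX = lapply(out, `[[`, "muX"),
      deviances = lapply(out, `[[`, "deviances"),
      acceptance = lapply(out, `[[`, "acceptance"),
      config = config, spec = spec)
}

#' Brooks-Gelman-Rubin potential scale reduction factors
#'
#' The classic multi-chain PSRF: with m chains of length n, within-chain
#' variance W and between-chain variance B (n times the variance of the chain
#' means), the pooled variance estimate is (n-1)/n W + B/n and the PSRF is the
#' square root of its ratio to W. Values near 1 indicate the chains have
#' mixed; 1.1 is the conventional cutoff used by the pipeline's convergence
#' verdict. Degenerate chains with zero within- and between-variance are
#' reported as exactly 1.
#'
#' @param draws a [PosteriorDraws-class] with at least two chains, or a list
#'   of per-chain numeric matrices with common named columns.
#' @param params character vector of parameter names (default: the structural
#'   coefficients beta, gamma, delta, eta1).
#' @return named numeric vector of PSRFs.
#' @export
gelmanRubin <- function(draws, params = NULL) {
  chains <- if (is(draws, "PosteriorDraws")) draws@chains else draws
  if (length(chains) < 2L)
    stop("at least two chains are required for the PSRF")
  if (is.null(params)) {
    default <- c("beta1", "beta2", "gamma1", "gamma2",
                 "delta1", "delta2", "eta1")
    params <- intersect(default, colnames(chains[[1]]))
    if (!length(params)) params <- colnames(chains[[1]])
  }
  n <- nrow(chains[[1]])
  vapply(params, function(p) {
    cols <- lapply(chains, function(ch) ch[, p])
    W <- mean(vapply(cols, var, 0))
    B <- n * var(vapply(cols, mean, 0))
    if (W == 0) return(if (B == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
}

#' Poisson-Gamma conjugate subcase sampler
#'
#' A single-area check of the Metropolis machinery: y ~ Poisson(E rho) with a
#' Gamma(shape, rate) prior on rho has the closed-form posterior
#' Gamma(shape + y, rate + E). This function samples log(rho) with the same
#' adaptive random-walk used by [runMcmc()] so the sampled exceedance
#' probability Pr(rho > 1) can be compared against
#' \code{pgamma(1, shape + y, rate + E, lower.tail = FALSE)}.
#'
#' @param y observed count.
#' @param E expected count (offset).
#' @param shape,rate Gamma prior parameters.
#' @param nRetained retained draws (after burn-in).
#' @param nBurn burn-in iterations.
#' @param seed integer seed.
#' @return numeric vector of retained rho draws.
#' @export
mcmcPoissonGamma <- function(y, E, shape = 1, rate = 1,
                             nRetained = 10000, nBurn = 1000, seed = 1) {
  stopifnot(y >= 0, E > 0, shape > 0, rate > 0)
  set.seed(as.integer(seed))
  # posterior of theta = log(rho): (shape + y) theta - (rate + E) exp(theta)
  a <- shape + y; b <- rate + E
  theta <- log(a / b)
  ls <- log(0.5)
  lp <- a * theta - b * exp(theta)
  out <- numeric(nRetained)
  total <- nBurn + nRetained
  for (it in seq_len(total)) {
    d <- rnorm(1) * exp(ls)
    lp2 <- a * (theta + d) - b * exp(theta + d)
    apr <- min(1, exp(lp2 - lp))
    if (runif(1) < apr) { theta <- theta + d; lp <- lp2 }
    if (it <= nBurn) ls <- ls + it^-0.6 * (apr - 0.35)
    else out[it - nBurn] <- exp(theta)
  }
  out
}
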