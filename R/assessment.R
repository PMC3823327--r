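#' Saturated Poisson deviance
#'
#' \eqn{2 \sum_p [y_p \log(y_p/\mu_p) - (y_p - \mu_p)]} with the convention
#' \eqn{0 \log 0 = 0}. Zero at a perfect fit, free of factorial constants;
#' the standard form reported by Gibbs-sampling software of the
#' disease-mapping tradition.
#'
#' @param count non-negative integer counts.
#' @param mean positive fitted means.
#' @return scalar deviance.
#' @export
poissonDeviance <- function(count, mean) {
  if (length(count) != length(mean)) stop("length mismatch")
  if (any(mean <= 0) || any(!is.finite(mean)))
    stop("fitted means must be positive and finite")
  lr <- ifelse(count > 0, count * log(count / mean), 0)
  2 * sum(lr - (count - mean))
}

#' Gaussian deviance of the covariate stream
#'
#' Minus twice [loglikAirQuality()].
#'
#' @inheritParams loglikAirQuality
#' @return scalar deviance.
#' @export
gaussianDeviance <- function(x, mu, varX) {
  -2 * loglikAirQuality(x, mu, varX)
}

#' Deviance information criterion from deviance draws
#'
#' DIC = D-bar + pD where D-bar is the posterior mean deviance and pD =
#' D-bar - D(plug-in) is the effective number of parameters. pD can be
#' negative (e.g., under strong posterior asymmetry); it is reported as
#' computed, never clamped. The identity DIC = D(plug-in) + 2 pD holds by
#' construction.
#'
#' @param devianceDraws numeric vector of per-draw deviances (>= 100 draws).
#' @param plugInDeviance deviance at the plug-in (posterior mean fitted
#'   means).
#' @return named numeric vector with elements \code{DIC}, \code{pD},
#'   \code{Dbar}, \code{Dhat}.
#' @export
dic <- function(devianceDraws, plugInDeviance) {
  if (!length(devianceDraws)) stop("empty deviance draws")
  Dbar <- mean(devianceDraws)
  pD <- Dbar - plugInDeviance
  c(DIC = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = plugInDeviance)
}

#' Stream-specific DIC report for a fitted model
#'
#' Computes, for each of the three data streams (prevalence counts y,
#' hospitalisation counts M, covariate x), the posterior mean deviance, the
#' plug-in deviance and the DIC. The plug-in point is the posterior mean of
#' the stream's fitted means (mean over draws of E rho, G nu, and mu_x; and
#' the posterior mean of varX for the Gaussian stream), which avoids the
#' log-scale asymmetry of evaluating at parameter-wise posterior means.
#'
#' @param draws a [PosteriorDraws-class].
#' @param source,target the [AreaFrame-class] frames the model was fitted to.
#' @param label optional model label recorded in the output.
#' @return data.frame with one row per stream: \code{model}, \code{stream},
#'   \code{Dbar}, \code{Dhat}, \code{pD}, \code{DIC}.
#' @export
dicReport <- function(draws, source, target, label = "model") {
  stopifnot(is(draws, "PosteriorDraws"))
  dev <- fieldDraws(draws, "deviances")
  if (nrow(dev) < 100) stop("at least 100 retained draws are required")
  y <- counts(source); Es <- offsetPrevalence(source)
  M <- counts(target); G <- offsetMorbidity(target)
  x <- covariate(target)

  muYbar <- Es * colMeans(fieldDraws(draws, "rhoSource"))
  muMbar <- G * colMeans(fieldDraws(draws, "nu"))
  muXbar <- colMeans(fieldDraws(draws, "muX"))
  varXbar <- mean(drawsMatrix(draws, "varX"))

  rows <- rbind(
    dic(dev[, "y"], poissonDeviance(y, muYbar)),
    dic(dev[, "M"], poissonDeviance(M, muMbar)),
    dic(dev[, "x"], gaussianDeviance(x, muXbar, varXbar)))
  data.frame(model = label, stream = c("y", "M", "x"),
             Dbar = rows[, "Dbar"], Dhat = rows[, "Dhat"],
             pD = rows[, "pD"], DIC = rows[, "DIC"],
             row.names = NULL)
}
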