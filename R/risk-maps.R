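# pooled draws x K matrix from either a PosteriorDraws or a matrix
.rhoDrawMatrix <- function(rhoDraws, field = "rhoTarget") {
  m <- if (is(rhoDraws, "PosteriorDraws")) fieldDraws(rhoDraws, field)
       else as.matrix(rhoDraws)
  if (nrow(m) < 1L) stop("empty draws")
  m
}

#' Posterior exceedance probabilities
#'
#' For each target area, the fraction of retained draws with relative
#' prevalence above 1 — the posterior probability Pr(rho_k > 1 | y, M, x)
#' that the area's prevalence risk is above the regional average.
#'
#' @param rhoDraws a [PosteriorDraws-class] or a draws x K matrix of relative
#'   prevalence draws (at least 100 draws).
#' @return numeric(K) probabilities in \[0, 1\].
#' @export
exceedanceProbability <- function(rhoDraws) {
  m <- .rhoDrawMatrix(rhoDraws)
  if (nrow(m) < 100) stop("at least 100 draws are required")
  colMeans(m > 1)
}

#' Classify localised hotspots
#'
#' An area is flagged as a localised high-risk hotspot when its exceedance
#' probability strictly exceeds the threshold (conventionally 0.8 or 0.9);
#' the inequality is strict, so a probability exactly at the threshold is not
#' flagged.
#'
#' @param p numeric vector of exceedance probabilities.
#' @param threshold numeric in \[0, 1\], default 0.8.
#' @return logical vector of hotspot flags.
#' @export
classifyHotspots <- function(p, threshold = 0.8) {
  if (length(threshold) != 1L || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  p > threshold
}

#' Posterior cluster-centre probabilities
#'
#' For each area k with neighbours A_k (sizes L_k), the posterior mean of
#' \eqn{J_k \cdot (1/L_k) \sum_{l \in A_k} J_l} where \eqn{J_k = I(\rho_k >
#' 1)}: the exceedance indicator of the area weighted by the fraction of its
#' neighbours that also exceed. C_k is bounded above by the exceedance
#' probability and grows as more adjacent areas share the excess risk, which
#' is why its classification threshold (0.25) sits below the hotspot one:
#' with the area itself exceeding and at least one of up to four neighbours
#' exceeding, C_k >= 0.25 is attainable. Isolated areas (no neighbours) are
#' given C_k = 0 with a warning.
#'
#' @inheritParams exceedanceProbability
#' @param adjacency list of integer neighbour-index vectors covering all
#'   areas (symmetric, irreflexive), e.g. from [adjacency()].
#' @param allNeighbours logical; if TRUE, use the stricter variant requiring
#'   every neighbour to exceed (the minimum instead of the fraction).
#' @return numeric(K) cluster-centre probabilities.
#' @export
clusterCentreProbability <- function(rhoDraws, adjacency,
                                     allNeighbours = FALSE) {
  m <- .rhoDrawMatrix(rhoDraws)
  K <- ncol(m)
  if (length(adjacency) != K)
    stop("adjacency must supply a neighbour set for every area")
  Jmat <- m > 1
  Lk <- lengths(adjacency)
  if (any(Lk == 0))
    warning("isolated area(s) with no neighbours scored 0: ",
            paste(which(Lk == 0), collapse = ", "))
  vapply(seq_len(K), function(k) {
    if (Lk[k] == 0) return(0)
    nb <- Jmat[, adjacency[[k]], drop = FALSE]
    frac <- if (allNeighbours) apply(nb, 1, min) else rowMeans(nb)
    mean(Jmat[, k] * frac)
  }, 0)
}

#' Classify cluster centres
#'
#' Flags areas whose cluster-centre probability strictly exceeds the
#' threshold (default 0.25).
#'
#' @param C numeric vector of cluster-centre probabilities.
#' @param threshold numeric in \[0, 1\], default 0.25.
#' @return logical vector of cluster flags.
#' @export
classifyClusters <- function(C, threshold = 0.25) {
  classifyHotspots(C, threshold)
}

#' Cross-tabulate two classifications
#'
#' 2 x 2 table of counts of areas classified (or not) by two model variants
#' (or two thresholds), used to assess co-location of hotspot or
#' cluster-centre classifications across model specifications.
#'
#' @param flagsA,flagsB logical vectors of equal length.
#' @return 2 x 2 integer matrix with dimnames \code{A = c("no", "yes")},
#'   \code{B = c("no", "yes")}; entries sum to the number of areas.
#' @export
crosstabClassifications <- function(flagsA, flagsB) {
  if (length(flagsA) != length(flagsB)) stop("length mismatch")
  tab <- matrix(c(sum(!flagsA & !flagsB), sum(!flagsA & flagsB),
                  sum(flagsA & !flagsB), sum(flagsA & flagsB)),
                nrow = 2, byrow = TRUE,
                dimnames = list(A = c("no", "yes"), B = c("no", "yes")))
  storage.mode(tab) <- "integer"
  tab
}

#' Prevalence percentages and their distributional summary
#'
#' Converts relative prevalence draws to percentage prevalence rates via the
#' region-wide rate (\eqn{100 \cdot rate \cdot \rho_k} per draw), returns the
#' per-area posterior means, and summarises their distribution across areas
#' (mean, median, moment skewness, and the 1st/5th/95th/99th percentiles).
#'
#' @inheritParams exceedanceProbability
#' @param regionalRate region-wide prevalence rate in (0, 1), e.g. 0.046.
#' @return list with \code{areaMeans} (numeric(K) posterior-mean percentages)
#'   and \code{summary} (named numeric vector of distributional
#'   characteristics across areas).
#' @export
prevalencePercent <- function(rhoDraws, regionalRate) {
  if (length(regionalRate) != 1L || regionalRate <= 0 || regionalRate >= 1)
    stop("regionalRate must lie strictly between 0 and 1")
  m <- .rhoDrawMatrix(rhoDraws)
  areaMeans <- 100 * regionalRate * colMeans(m)
  mu <- mean(areaMeans)
  s <- sd(areaMeans)
  skew <- if (s > 0) mean((areaMeans - mu)^3) / s^3 else 0
  qs <- quantile(areaMeans, c(0.01, 0.05, 0.5, 0.95, 0.99), names = FALSE)
  list(areaMeans = areaMeans,
       summary = c(mean = mu, median = qs[3], skewness = skew,
                   p1 = qs[1], p5 = qs[2], p95 = qs[4], p99 = qs[5]))
}

#' Per-area posterior risk summary
#'
#' Assembles the full classification table for the target frame: exceedance
#' probability, cluster-centre probability, hotspot and cluster flags at the
#' given thresholds, and posterior-mean prevalence percentage.
#'
#' @param draws a [PosteriorDraws-class].
#' @param target the target [AreaFrame-class] (supplies area ids and
#'   adjacency).
#' @param regionalRate region-wide prevalence rate in (0, 1).
#' @param hotspotThreshold exceedance-probability threshold (default 0.8).
#' @param clusterThreshold cluster-centre threshold (default 0.25).
#' @return data.frame keyed by \code{area_id} with columns
#'   \code{exceedance_prob}, \code{cluster_prob}, \code{hotspot},
#'   \code{cluster}, \code{prevalence_pct}.
#' @export
riskSummary <- function(draws, target, regionalRate = 0.046,
                        hotspotThreshold = 0.8, clusterThreshold = 0.25) {
  stopifnot(is(draws, "PosteriorDraws"), is(target, "AreaFrame"))
  if (!length(adjacency(target)))
    stop("target frame carries no adjacency; cluster probabilities need one")
  rho <- fieldDraws(draws, "rhoTarget")
  p <- exceedanceProbability(rho)
  C <- clusterCentreProbability(rho, adjacency(target))
  prev <- prevalencePercent(rho, regionalRate)
  data.frame(area_id = areaIds(target),
             exceedance_prob = p,
             cluster_prob = C,
             hotspot = classifyHotspots(p, hotspotThreshold),
             cluster = classifyClusters(C, clusterThreshold),
             prevalence_pct = prev$areaMeans,
             row.names = NULL)
}
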