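test_that("exceedance probabilities count draws above 1", {
  m <- matrix(rep(c(0.9, 1.1, 1.2, 0.8), 30), ncol = 1)
  expect_equal(exceedanceProbability(m)[1], 0.5)
  expect_equal(exceedanceProbability(matrix(1.5, 100, 2)), c(1, 1))
  # sort-based oracle: p = 1 - ECDF(1)
  set.seed(1)
  mm <- matrix(exp(rnorm(600, 0, 0.5)), 200, 3)
  p <- exceedanceProbability(mm)
  for (k in 1:3) {
    srt <- sort(mm[, k])
    expect_equal(p[k], (length(srt) - findInterval(1, srt)) / length(srt))
  }
  expect_error(exceedanceProbability(matrix(1, 10, 2)), "100")
})

test_that("hotspot classification is strict and nests across thresholds", {
  expect_true(classifyHotspots(0.85, 0.8))
  expect_false(classifyHotspots(0.8, 0.8))   # strict inequality
  expect_error(classifyHotspots(0.5, 1.2), "threshold")
  expect_error(classifyHotspots(1.4, 0.8))
  set.seed(2)
  p <- runif(50)
  h9 <- classifyHotspots(p, 0.9)
  h8 <- classifyHotspots(p, 0.8)
  expect_true(all(h8[h9]))            # 0.9-set nested in 0.8-set
  expect_lte(sum(h9), sum(h8))
})

test_that("cluster-centre probabilities match a brute-force oracle and are bounded", {
  set.seed(3)
  K <- 8; R <- 120
  pts <- matrix(runif(2 * K, 0, 5), K, 2)
  adj <- knnAdjacency(pts, 3)
  m <- matrix(exp(rnorm(R * K, 0, 0.4)), R, K)
  C <- clusterCentreProbability(m, adj)
  # brute force over draws and neighbours
  for (k in 1:K) {
    acc <- 0
    for (r in 1:R) {
      Jk <- as.numeric(m[r, k] > 1)
      Jl <- vapply(adj[[k]], function(l) as.numeric(m[r, l] > 1), 0)
      acc <- acc + Jk * mean(Jl)
    }
    expect_equal(C[k], acc / R, tolerance = 1e-12)
  }
  p <- exceedanceProbability(m)
  expect_true(all(C <= p + 1e-12))
  expect_true(all(C >= 0))
  # single draw, area exceeding, 2 of 4 neighbours exceeding -> 0.5
  m1 <- matrix(c(2, 2, 2, 0.5, 0.5), 1, 5)
  adj1 <- list(2:5, c(1L, 3L), c(1L, 2L), c(1L, 5L), c(1L, 4L))
  expect_equal(clusterCentreProbability(m1, adj1)[1], 0.5)
  # never exceeding itself -> 0; everyone always exceeding -> 1
  m0 <- m; m0[, 1] <- 0.5
  expect_equal(clusterCentreProbability(m0, adj)[1], 0)
  expect_equal(clusterCentreProbability(matrix(2, R, K), adj), rep(1, K))
  expect_error(clusterCentreProbability(m, adj[1:3]), "every area")
})

test_that("cluster classification is strict and monotone in the threshold", {
  expect_true(classifyClusters(0.3))
  expect_false(classifyClusters(0.25))
  set.seed(4)
  C <- runif(40, 0, 0.6)
  counts <- vapply(c(0.1, 0.25, 0.4), function(t) sum(classifyClusters(C, t)),
                   0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("cross-tabulations have consistent cells and marginals", {
  set.seed(5)
  a <- runif(60) > 0.7
  b <- a | (runif(60) > 0.8)   # a nested in b
  tab <- crosstabClassifications(a, b)
  expect_equal(sum(tab), 60)
  expect_equal(tab["yes", "no"], 0L)           # nesting empties one cell
  expect_equal(unname(rowSums(tab)), c(sum(!a), sum(a)))
  expect_equal(unname(colSums(tab)), c(sum(!b), sum(b)))
  self <- crosstabClassifications(a, a)
  expect_equal(self["yes", "no"] + self["no", "yes"], 0L)
  comp <- crosstabClassifications(a, !a)
  expect_equal(unname(diag(comp)), c(0L, 0L))
  expect_error(crosstabClassifications(a, b[-1]), "length")
})

test_that("prevalence percentages scale the regional rate by relative risk", {
  m <- matrix(1, 150, 4)
  pv <- prevalencePercent(m, 0.046)
  expect_equal(pv$areaMeans, rep(4.6, 4))
  set.seed(6)
  mm <- matrix(exp(rnorm(150 * 30, 0, 0.3)), 150, 30)
  pv1 <- prevalencePercent(mm, 0.02)
  pv2 <- prevalencePercent(mm, 0.04)
  expect_equal(2 * pv1$areaMeans, pv2$areaMeans, tolerance = 1e-12)
  expect_equal(unname(2 * pv1$summary[c("mean", "median", "p1", "p99")]),
               unname(pv2$summary[c("mean", "median", "p1", "p99")]),
               tolerance = 1e-12)
  # quantile oracle
  expect_equal(unname(pv1$summary["p95"]),
               unname(quantile(pv1$areaMeans, 0.95)), tolerance = 1e-12)
  expect_error(prevalencePercent(mm, 1.2), "between 0 and 1")
})

test_that("classification outputs are invariant to draw order", {
  set.seed(7)
  K <- 10
  pts <- matrix(runif(2 * K, 0, 5), K, 2)
  adj <- knnAdjacency(pts, 3)
  m <- matrix(exp(rnorm(200 * K, 0, 0.4)), 200, K)
  perm <- sample(nrow(m))
  expect_equal(exceedanceProbability(m), exceedanceProbability(m[perm, ]))
  expect_equal(clusterCentreProbability(m, adj),
               clusterCentreProbability(m[perm, ], adj))
})

test_that("the risk summary table is coherent on a fitted model", {
  sh <- sharedReducedFit()
  rs <- riskSummary(sh$fit, sh$study$target, regionalRate = 0.046)
  expect_equal(nrow(rs), nAreas(sh$study$target))
  expect_true(all(rs$cluster_prob <= rs$exceedance_prob + 1e-12))
  expect_true(all(rs$exceedance_prob >= 0 & rs$exceedance_prob <= 1))
  expect_identical(rs$hotspot, rs$exceedance_prob > 0.8)
  expect_identical(rs$cluster, rs$cluster_prob > 0.25)
  expect_true(all(rs$prevalence_pct > 0))
})
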