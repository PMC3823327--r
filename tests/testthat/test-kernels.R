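test_that("all kernel families are standardised to weight 1 at zero distance", {
  for (fam in c("normal", "exponential", "student_t"))
    expect_identical(kernelWeight(0, KernelSpec(fam)), 1)
})

test_that("kernel weights match their closed forms and reject bad distances", {
  expect_equal(kernelWeight(1, KernelSpec("normal")), exp(-0.5),
               tolerance = 1e-12)
  expect_equal(kernelWeight(2, KernelSpec("exponential", scale = 0.5)),
               exp(-4), tolerance = 1e-12)
  expect_equal(kernelWeight(1, KernelSpec("student_t", kernelDf = 5)),
               (1 + 1 / 5)^(-3.5), tolerance = 1e-12)
  expect_error(kernelWeight(-0.1, KernelSpec("normal")), "non-negative")
  expect_error(kernelWeight(NaN, KernelSpec("normal")), "finite")
  expect_error(KernelSpec("normal", scale = -1), "positive")
})

test_that("weights decrease strictly with distance for every family", {
  d <- seq(0, 6, by = 0.25)
  for (fam in c("normal", "exponential", "student_t")) {
    w <- kernelWeight(d, KernelSpec(fam))
    expect_true(all(diff(w) < 0))
    expect_true(all(w > 0 & w <= 1))
  }
})

test_that("the exponential kernel is heavier-tailed than the normal at equal scale", {
  expect_gt(kernelWeight(3, KernelSpec("exponential")),
            kernelWeight(3, KernelSpec("normal")))
})

test_that("standardised distances agree with a brute-force double loop", {
  set.seed(7)
  pts <- matrix(runif(6, 0, 10), 3, 2)
  grid <- ProcessGrid(matrix(runif(4, 0, 10), 2, 2), spacing = 2)
  d <- standardisedDistances(pts, grid)
  for (p in 1:3) for (j in 1:2)
    expect_equal(d[p, j],
                 sqrt(sum((pts[p, ] - gridPoints(grid)[j, ])^2)) / 2,
                 tolerance = 1e-12)
  # displacement equal to one grid spacing standardises to exactly 1
  g1 <- ProcessGrid(matrix(c(0, 0), 1, 2), spacing = 2)
  expect_equal(drop(standardisedDistances(matrix(c(2, 0), 1, 2), g1)), 1)
  expect_equal(drop(standardisedDistances(matrix(c(0, 0), 1, 2), g1)), 0)
  expect_error(standardisedDistances(matrix(numeric(0), 0, 2), g1), "empty")
})

test_that("kernel matrix composes weight and distance and respects symmetry", {
  set.seed(8)
  pts <- matrix(runif(10, 0, 8), 5, 2)
  grid <- ProcessGrid(matrix(runif(8, 0, 8), 4, 2), spacing = 2)
  spec <- KernelSpec("exponential")
  km <- kernelMatrix(pts, grid, spec)
  expect_equal(km,
               matrix(kernelWeight(as.vector(standardisedDistances(pts, grid)),
                                   spec), 5, 4))
  expect_true(all(km > 0 & km <= 1))
  # coincident single point / single grid point
  expect_equal(kernelMatrix(matrix(c(1, 1), 1, 2),
                            ProcessGrid(matrix(c(1, 1), 1, 2), 1), spec),
               matrix(1, 1, 1))
  # mirror geometry: two points and two grid points reflected about x = 0
  mirrorPts <- rbind(c(-1, 0), c(1, 0))
  mirrorGrid <- ProcessGrid(rbind(c(-2, 0), c(2, 0)), spacing = 1)
  kmm <- kernelMatrix(mirrorPts, mirrorGrid, spec)
  expect_equal(kmm[1, 2], kmm[2, 1])
  expect_equal(kmm[1, 1], kmm[2, 2])
  # permutation equivariance under grid reordering
  perm <- c(3, 1, 4, 2)
  gridP <- ProcessGrid(gridPoints(grid)[perm, ], spacing = 2)
  expect_equal(kernelMatrix(pts, gridP, spec), km[, perm])
})

test_that("regular grids cover extents and bounding boxes at the set spacing", {
  g <- makeGrid(c(22, 12), 2)
  expect_equal(nGridPoints(g), 84)
  expect_equal(gridSpacing(g), 2)
  pts <- matrix(runif(40, 1, 9), 20, 2)
  gc <- gridCovering(pts, 2)
  expect_true(all(apply(gridPoints(gc), 2, min) <= apply(pts, 2, min)))
  expect_true(all(apply(gridPoints(gc), 2, max) >= apply(pts, 2, max)))
  expect_error(makeGrid(c(-1, 2), 2))
})

test_that("grid tables round-trip through delimited text", {
  g <- makeGrid(c(6, 4), 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(grid_id = seq_len(nGridPoints(g)),
                       easting = gridPoints(g)[, 1],
                       northing = gridPoints(g)[, 2]),
            path, row.names = FALSE)
  g2 <- readGrid(path, spacing = 2)
  expect_equal(gridPoints(g2), gridPoints(g))
})
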