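#' Kernel weight at a standardised distance
#'
#' Evaluates the standardised smoothing kernel at non-negative distances
#' (already expressed in grid-spacing units; see [standardisedDistances()]).
#' All families satisfy weight(0) = 1 and decrease strictly with distance:
#' \describe{
#'   \item{normal}{\eqn{\exp(-d^2/(2\alpha^2))}}
#'   \item{exponential}{\eqn{\exp(-d/\eta)}}
#'   \item{student_t}{\eqn{(1 + d^2/(\nu\alpha^2))^{-(\nu+2)/2}}}
#' }
#' At equal scale the exponential kernel is more leptokurtic than the normal:
#' heavier-tailed at large d, so distant grid effects retain more influence.
#'
#' @param d numeric vector of non-negative standardised distances.
#' @param spec a [KernelSpec-class].
#' @return numeric vector of weights in (0, 1].
#' @examples
#' kernelWeight(0:3, KernelSpec("normal"))
#' kernelWeight(0:3, KernelSpec("exponential"))
#' @export
kernelWeight <- function(d, spec) {
  stopifnot(is(spec, "KernelSpec"))
  validObject(spec)
  if (length(d) == 0L) stop("empty distance vector")
  if (any(!is.finite(d))) stop("distances must be finite")
  if (any(d < 0)) stop("distances must be non-negative")
  switch(spec@family,
    normal = exp(-d^2 / (2 * spec@scale^2)),
    exponential = exp(-d / spec@scale),
    student_t = (1 + d^2 / (spec@kernelDf * spec@scale^2))^
      (-(spec@kernelDf + 2) / 2))
}

#' Standardised centroid-to-grid distances
#'
#' Euclidean distances from each point to each grid point, divided by the
#' grid spacing. With this standardisation, a kernel of scale 1 (the
#' "standard" kernel) has scale equal to one grid interval. Coordinates are
#' assumed planar (km); no projection is attempted.
#'
#' @param points P x 2 numeric matrix of planar coordinates.
#' @param grid a [ProcessGrid-class].
#' @return P x J matrix of non-negative standardised distances.
#' @export
standardisedDistances <- function(points, grid) {
  stopifnot(is(grid, "ProcessGrid"))
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty point set")
  if (ncol(points) != 2L) stop("points must have two columns")
  if (any(!is.finite(points))) stop("point coordinates must be finite")
  u <- grid@points
  dx <- outer(points[, 1], u[, 1], "-")
  dy <- outer(points[, 2], u[, 2], "-")
  sqrt(dx^2 + dy^2) / grid@spacing
}

#' Kernel weight matrix linking points to grid points
#'
#' Elementwise kernel evaluation of the standardised distance matrix: entry
#' (p, j) weights grid effect j in the convolution field at point p.
#'
#' @inheritParams standardisedDistances
#' @param spec a [KernelSpec-class].
#' @return P x J matrix with entries in (0, 1].
#' @seealso [convolveField()]
#' @export
kernelMatrix <- function(points, grid, spec) {
  d <- standardisedDistances(points, grid)
  w <- kernelWeight(as.vector(d), spec)
  matrix(w, nrow = nrow(d), ncol = ncol(d))
}

#' Construct a regular grid over a rectangle
#'
#' Grid points at \code{spacing} intervals covering \code{[0, extent[1]] x
#' [0, extent[2]]} (inclusive of both ends when the extent is a multiple of
#' the spacing). An extent of c(22, 12) at spacing 2 gives a 12 x 7 = 84-point
#' grid.
#'
#' @param extent numeric(2): width and height of the region (km).
#' @param spacing grid spacing (km), default 2.
#' @param origin numeric(2) lower-left corner, default c(0, 0).
#' @return a [ProcessGrid-class].
#' @export
makeGrid <- function(extent, spacing = 2, origin = c(0, 0)) {
  stopifnot(length(extent) == 2L, all(extent > 0), spacing > 0)
  xs <- seq(origin[1], origin[1] + extent[1] + 1e-9, by = spacing)
  ys <- seq(origin[2], origin[2] + extent[2] + 1e-9, by = spacing)
  if (length(xs) < 1L || length(ys) < 1L)
    stop("extent too small for the requested grid spacing")
  ProcessGrid(as.matrix(expand.grid(x = xs, y = ys)), spacing)
}

#' Construct a regular grid covering a set of centroids
#'
#' A lattice at the requested spacing covering the bounding box of all
#' supplied centroids, used when no explicit grid table is given.
#'
#' @param points P x 2 matrix (or several matrices row-bound together) of
#'   centroid coordinates.
#' @param spacing grid spacing (km), default 2.
#' @return a [ProcessGrid-class].
#' @export
gridCovering <- function(points, spacing = 2) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 1L, ncol(points) == 2L, spacing > 0)
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  extent <- spacing * ceiling((hi - lo) / spacing + 1e-9)
  makeGrid(extent = extent, spacing = spacing, origin = lo)
}

#' Read a grid from a coordinate table
#'
#' Expects a headed delimited file with columns \code{grid_id},
#' \code{easting}, \code{northing}.
#'
#' @param path file path.
#' @param spacing grid spacing (km) used for distance standardisation.
#' @return a [ProcessGrid-class].
#' @export
readGrid <- function(path, spacing) {
  tab <- read.csv(path, comment.char = "#")
  need <- c("grid_id", "easting", "northing")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("grid table missing column(s): ", paste(missing, collapse = ", "))
  ProcessGrid(cbind(tab$easting, tab$northing), spacing)
}
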