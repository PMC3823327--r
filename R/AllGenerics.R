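#' @name accessors
#' @title Accessors for areal frames, grids and posterior draws
#' @description Small accessor generics used across the package in place of
#'   direct slot access.
#' @param object an object of the documented classes.
#' @param ... passed on to methods.
NULL

#' @rdname accessors
#' @export
setGeneric("nAreas", function(object) standardGeneric("nAreas"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("offsetPrevalence", function(object) standardGeneric("offsetPrevalence"))
#' @rdname accessors
#' @export
setGeneric("offsetMorbidity", function(object) standardGeneric("offsetMorbidity"))
#' @rdname accessors
#' @export
setGeneric("covariate", function(object) standardGeneric("covariate"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("areaIds", function(object) standardGeneric("areaIds"))
#' @rdname accessors
#' @export
setGeneric("gridPoints", function(object) standardGeneric("gridPoints"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("nGridPoints", function(object) standardGeneric("nGridPoints"))
#' @rdname accessors
#' @export
setGeneric("nChains", function(object) standardGeneric("nChains"))
#' @rdname accessors
#' @export
setGeneric("nRetained", function(object) standardGeneric("nRetained"))
#' @rdname accessors
#' @export
setGeneric("acceptanceRates", function(object) standardGeneric("acceptanceRates"))

#' @rdname accessors
#' @export
setMethod("nAreas", "AreaFrame", function(object) nrow(object@centroids))
#' @rdname accessors
#' @export
setMethod("centroids", "AreaFrame", function(object) object@centroids)
#' @rdname accessors
#' @export
setMethod("counts", "AreaFrame", function(object, ...) object@count)
#' @rdname accessors
#' @export
setMethod("offsetPrevalence", "AreaFrame", function(object) object@offsetPrevalence)
#' @rdname accessors
#' @export
setMethod("offsetMorbidity", "AreaFrame", function(object) object@offsetMorbidity)
#' @rdname accessors
#' @export
setMethod("covariate", "AreaFrame", function(object) object@covariate)
#' @rdname accessors
#' @export
setMethod("adjacency", "AreaFrame", function(object) object@adjacency)
#' @rdname accessors
#' @export
setMethod("areaIds", "AreaFrame", function(object) object@areaId)

#' @rdname accessors
#' @export
setMethod("gridPoints", "ProcessGrid", function(object) object@points)
#' @rdname accessors
#' @export
setMethod("gridSpacing", "ProcessGrid", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("nGridPoints", "ProcessGrid", function(object) nrow(object@points))

#' @rdname accessors
#' @export
setMethod("nChains", "PosteriorDraws", function(object) length(object@chains))
#' @rdname accessors
#' @export
setMethod("nRetained", "PosteriorDraws", function(object) nrow(object@chains[[1]]))
#' @rdname accessors
#' @export
setMethod("acceptanceRates", "PosteriorDraws", function(object) object@acceptance)

#' Extract pooled parameter draws
#'
#' Returns retained draws of selected scalar parameters, pooled across chains
#' (rows stacked chain by chain).
#'
#' @param draws a [PosteriorDraws-class].
#' @param params character vector of parameter names (default: all).
#' @return numeric matrix, pooled draws x parameters.
#' @export
drawsMatrix <- function(draws, params = NULL) {
  stopifnot(is(draws, "PosteriorDraws"))
  m <- do.call(rbind, draws@chains)
  if (!is.null(params)) {
    missing <- setdiff(params, colnames(m))
    if (length(missing))
      stop("unknown parameter(s): ", paste(missing, collapse = ", "))
    m <- m[, params, drop = FALSE]
  }
  m
}

#' Extract pooled derived-field draws
#'
#' Per-draw derived fields pooled across chains: relative prevalence on either
#' frame, relative hospitalisation risk, the covariate mean surface, or the
#' per-stream deviances.
#'
#' @param draws a [PosteriorDraws-class].
#' @param field one of \code{"rhoTarget"}, \code{"rhoSource"}, \code{"nu"},
#'   \code{"muX"}, \code{"deviances"}.
#' @return numeric matrix, pooled draws x areas (or x 3 streams).
#' @export
fieldDraws <- function(draws, field = c("rhoTarget", "rhoSource", "nu",
                                        "muX", "deviances")) {
  stopifnot(is(draws, "PosteriorDraws"))
  field <- match.arg(field)
  do.call(rbind, slot(draws, field))
}
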