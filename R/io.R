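#' Read an areal frame from a delimited table
#'
#' Expects a headed comma-separated file with columns \code{area_id},
#' \code{easting}, \code{northing}, \code{count}, \code{offset_prevalence}
#' and, for target frames, optionally \code{offset_morbidity} and
#' \code{covariate}. Lines starting with \code{#} are treated as comments.
#' Row order is preserved; duplicate ids and non-positive offsets are
#' rejected naming the offending row.
#'
#' @param path path to the area table.
#' @param role \code{"source"} or \code{"target"}.
#' @param adjacencyPath optional path to an edge-list file with columns
#'   \code{area_id_a}, \code{area_id_b}; validated symmetric.
#' @return an [AreaFrame-class].
#' @export
readAreaFrame <- function(path, role = c("source", "target"),
                          adjacencyPath = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.csv(path, comment.char = "#")
  need <- c("area_id", "easting", "northing", "count", "offset_prevalence")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  dup <- which(duplicated(tab$area_id))
  if (length(dup))
    stop("duplicate area_id at row ", dup[1], ": ", tab$area_id[dup[1]])
  bad <- which(!is.finite(tab$offset_prevalence) | tab$offset_prevalence <= 0)
  if (length(bad))
    stop("non-positive offset_prevalence at row ", bad[1],
         " (area ", tab$area_id[bad[1]], ")")
  adjacency <- if (!is.null(adjacencyPath))
    readAdjacency(adjacencyPath, tab$area_id) else list()
  AreaFrame(role, cbind(tab$easting, tab$northing), tab$count,
            tab$offset_prevalence,
            offsetMorbidity = if ("offset_morbidity" %in% names(tab))
              tab$offset_morbidity else numeric(0),
            covariate = if ("covariate" %in% names(tab))
              tab$covariate else numeric(0),
            adjacency = adjacency, areaId = as.character(tab$area_id))
}

#' Read an adjacency edge list
#'
#' @param path edge-list file with headed columns \code{area_id_a},
#'   \code{area_id_b}.
#' @param areaIds character vector of area ids defining index order.
#' @return list of integer neighbour-index vectors (symmetrised; an edge
#'   listed once implies its mirror).
#' @export
readAdjacency <- function(path, areaIds) {
  if (!file.exists(path)) stop("no such file: ", path)
  ed <- read.csv(path, comment.char = "#")
  need <- c("area_id_a", "area_id_b")
  if (!all(need %in% names(ed)))
    stop("adjacency file must have columns area_id_a, area_id_b")
  a <- match(as.character(ed$area_id_a), areaIds)
  b <- match(as.character(ed$area_id_b), areaIds)
  if (anyNA(a) || anyNA(b))
    stop("adjacency references unknown area id(s)")
  if (any(a == b)) stop("self-loop in adjacency file")
  adj <- vector("list", length(areaIds))
  for (i in seq_along(a)) {
    adj[[a[i]]] <- c(adj[[a[i]]], b[i])
    adj[[b[i]]] <- c(adj[[b[i]]], a[i])
  }
  lapply(adj, function(v) sort(unique(as.integer(v))))
}

#' Write an areal frame (and optionally its adjacency) to delimited text
#'
#' Inverse of [readAreaFrame()]: a round-trip write/read reproduces the
#' frame. An optional header comment (e.g., recording a generating seed) is
#' written before the column row.
#'
#' @param frame an [AreaFrame-class].
#' @param path output path for the area table.
#' @param adjacencyPath optional output path for the edge list (each
#'   undirected edge written once).
#' @param comment optional header comment line (without the leading
#'   \code{#}).
#' @return invisibly, \code{path}.
#' @export
writeAreaFrame <- function(frame, path, adjacencyPath = NULL,
                           comment = NULL) {
  stopifnot(is(frame, "AreaFrame"))
  tab <- data.frame(area_id = areaIds(frame),
                    easting = centroids(frame)[, 1],
                    northing = centroids(frame)[, 2],
                    count = counts(frame),
                    offset_prevalence = offsetPrevalence(frame))
  if (length(offsetMorbidity(frame)))
    tab$offset_morbidity <- offsetMorbidity(frame)
  if (length(covariate(frame)))
    tab$covariate <- covariate(frame)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  write.csv(tab, con, row.names = FALSE, quote = FALSE)
  if (!is.null(adjacencyPath) && length(adjacency(frame))) {
    ids <- areaIds(frame)
    edges <- do.call(rbind, lapply(seq_along(adjacency(frame)), function(k) {
      nb <- adjacency(frame)[[k]]
      nb <- nb[nb > k]
      if (length(nb)) data.frame(area_id_a = ids[k], area_id_b = ids[nb])
      else NULL
    }))
    write.csv(edges, adjacencyPath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Persist posterior draws
#'
#' Writes the scalar-parameter draws in two re-loadable plain-text forms: a
#' long table (chain, iteration, parameter, value) and one wide
#' comma-separated matrix per chain. Derived fields and deviances are written
#' as wide per-chain tables as well.
#'
#' @param draws a [PosteriorDraws-class].
#' @param dir output directory (created if needed).
#' @param parameters which scalar parameters to include in the long table
#'   (default: the structural coefficients and variances).
#' @return invisibly, \code{dir}.
#' @export
writeDraws <- function(draws, dir,
                       parameters = c("beta1", "beta2", "gamma1", "gamma2",
                                      "delta1", "delta2", "eta1",
                                      "varW1", "varW2", "varX")) {
  stopifnot(is(draws, "PosteriorDraws"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- do.call(rbind, lapply(seq_along(draws@chains), function(ch) {
    m <- draws@chains[[ch]][, parameters, drop = FALSE]
    data.frame(chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
  write.csv(long, file.path(dir, "draws_long.csv"), row.names = FALSE,
            quote = FALSE)
  for (ch in seq_along(draws@chains)) {
    write.csv(as.data.frame(draws@chains[[ch]]),
              file.path(dir, sprintf("draws_wide_chain%d.csv", ch)),
              row.names = FALSE, quote = FALSE)
    write.csv(as.data.frame(draws@deviances[[ch]]),
              file.path(dir, sprintf("deviances_chain%d.csv", ch)),
              row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Re-load persisted scalar draws
#'
#' Reads the wide per-chain matrices written by [writeDraws()] back into a
#' list of chain matrices (suitable for [gelmanRubin()]).
#'
#' @param dir directory written by [writeDraws()].
#' @return list of per-chain numeric matrices with named columns.
#' @export
readDraws <- function(dir) {
  files <- sort(list.files(dir, "^draws_wide_chain[0-9]+\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no wide draw files under ", dir)
  lapply(files, function(f) {
    m <- as.matrix(read.csv(f, check.names = FALSE))
    storage.mode(m) <- "double"
    m
  })
}

#' Run configuration
#'
#' A flat configuration for [runPipeline()]. Defaults reproduce the standard
#' variant-1 settings: normal kernel, normal process, diffuse priors, 2 km
#' grid spacing, classification thresholds 0.8 and 0.25.
#'
#' @param sourcePath,targetPath,adjacencyPath input table paths (NULL to
#'   simulate instead).
#' @param variant model variant 1-4 (see [modelVariant()]).
#' @param gridSpacing process-grid spacing (km).
#' @param nChains,nIter,burnFraction,thin,seed chain settings.
#' @param hotspotThreshold,clusterThreshold classification thresholds.
#' @param regionalRate region-wide prevalence rate.
#' @param outDir output directory.
#' @param simulate list of overrides for [syntheticStudy()] when no input
#'   paths are given (e.g., \code{list(nSource = 60, nTarget = 150)}).
#' @return named list (class checked structurally by [runPipeline()]).
#' @export
runConfig <- function(sourcePath = NULL, targetPath = NULL,
                      adjacencyPath = NULL, variant = 1, gridSpacing = 2,
                      nChains = 2, nIter = 5000, burnFraction = 0.5,
                      thin = 1, seed = 1, hotspotThreshold = 0.8,
                      clusterThreshold = 0.25, regionalRate = 0.046,
                      outDir = "prevconv_run", simulate = list()) {
  list(sourcePath = sourcePath, targetPath = targetPath,
       adjacencyPath = adjacencyPath, variant = as.integer(variant),
       gridSpacing = gridSpacing, nChains = nChains, nIter = nIter,
       burnFraction = burnFraction, thin = thin, seed = as.integer(seed),
       hotspotThreshold = hotspotThreshold,
       clusterThreshold = clusterThreshold, regionalRate = regionalRate,
       outDir = outDir, simulate = simulate)
}

#' Read / write a run configuration
#'
#' Flat key: value YAML. Unknown keys are rejected; missing keys take the
#' [runConfig()] defaults, so serialise-then-parse round-trips to an
#' equivalent configuration.
#'
#' @param path configuration file path.
#' @return [readRunConfig()]: a [runConfig()] list.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(runConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(runConfig, vals)
}

#' @param config a [runConfig()] list.
#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}

#' Run the full pipeline: load or simulate, fit, assess, classify
#'
#' Orchestrates one model run and writes its artifacts under
#' \code{config$outDir}: the posterior draws (long and wide), the DIC table
#' (\code{dic.csv}), the per-area risk summary (\code{risk_summary.csv}), a
#' convergence report (\code{convergence.txt}) and a run log
#' (\code{run.log}) recording the configuration hash, seeds, acceptance
#' rates and the PSRF verdict (cutoff 1.1). Deterministic given the seed.
#'
#' @param config a [runConfig()] list.
#' @return invisibly, a list with \code{draws}, \code{dic}, \code{risk},
#'   \code{psrf}, \code{converged}, \code{outDir}.
#' @export
runPipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  spec <- modelVariant(config$variant)

  dat <- stage("data", {
    if (!is.null(config$sourcePath)) {
      source <- readAreaFrame(config$sourcePath, "source")
      target <- readAreaFrame(config$targetPath, "target",
                              adjacencyPath = config$adjacencyPath)
      grid <- gridCovering(rbind(centroids(source), centroids(target)),
                           config$gridSpacing)
      if (!length(adjacency(target)))
        target <- initialize(target,
                             adjacency = knnAdjacency(centroids(target)))
      list(source = source, target = target, grid = grid)
    } else {
      args <- c(list(spec = spec, seed = config$seed,
                     gridSpacing = config$gridSpacing), config$simulate)
      st <- do.call(syntheticStudy, args)
      writeAreaFrame(st$source, file.path(outDir, "source.csv"),
                     comment = paste("generated with seed", config$seed))
      writeAreaFrame(st$target, file.path(outDir, "target.csv"),
                     adjacencyPath = file.path(outDir, "adjacency.csv"),
                     comment = paste("generated with seed", config$seed))
      list(source = st$source, target = st$target, grid = st$geography$grid,
           truth = st$truth)
    }
  })

  cc <- chainConfig(nChains = config$nChains, nIter = config$nIter,
                    burnFraction = config$burnFraction, thin = config$thin,
                    seed = config$seed)
  draws <- stage("fit", runMcmc(dat$source, dat$target, dat$grid, spec, cc))
  stage("persist", writeDraws(draws, file.path(outDir, "draws")))

  dicTab <- stage("assess", dicReport(draws, dat$source, dat$target,
                                      label = paste0("variant", config$variant)))
  write.csv(dicTab, file.path(outDir, "dic.csv"), row.names = FALSE,
            quote = FALSE)

  psrf <- stage("assess", gelmanRubin(draws))
  converged <- all(psrf < 1.1)
  writeLines(c(sprintf("PSRF (Brooks-Gelman-Rubin), cutoff 1.1:"),
               sprintf("  %-8s %.4f", names(psrf), psrf),
               sprintf("verdict: %s",
                       if (converged) "converged" else "NOT converged")),
             file.path(outDir, "convergence.txt"))

  risk <- stage("classify",
                riskSummary(draws, dat$target,
                            regionalRate = config$regionalRate,
                            hotspotThreshold = config$hotspotThreshold,
                            clusterThreshold = config$clusterThreshold))
  write.csv(risk, file.path(outDir, "risk_summary.csv"), row.names = FALSE,
            quote = FALSE)

  acc <- acceptanceRates(draws)[[1]]
  cfgHash <- sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 1e9
  writeLines(c(sprintf("prevconv run, variant %d", config$variant),
               sprintf("config hash: %d", cfgHash),
               sprintf("master seed: %d; chain seeds: %s", config$seed,
                       paste(vapply(seq_len(config$nChains), function(ch)
                         .chainSeed(config$seed, ch), 0L), collapse = ", ")),
               sprintf("retained draws: %d", retainedDraws(cc)),
               "post-adaptation acceptance rates (chain 1):",
               sprintf("  %-10s %.3f", names(acc), acc),
               sprintf("PSRF verdict: %s",
                       if (converged) "converged" else "NOT converged")),
             file.path(outDir, "run.log"))

  invisible(list(draws = draws, dic = dicTab, risk = risk, psrf = psrf,
                 converged = converged, outDir = outDir))
}

#' Compare fitted model runs
#'
#' Side-by-side DIC table (one row per variant and stream) plus pairwise
#' cross-tabulations of hotspot and cluster flags of each run against the
#' first, from artifact directories written by [runPipeline()]. All runs must
#' share the same target frame (checked by area ids).
#'
#' @param runDirs character vector of two or more run output directories.
#' @return list with \code{dic} (stacked data.frame) and \code{crosstabs}
#'   (named list of 2 x 2 matrices \code{<run>_vs_<first>} for hotspots and
#'   clusters).
#' @export
compareModels <- function(runDirs) {
  stopifnot(length(runDirs) >= 2L)
  dics <- lapply(runDirs, function(d)
    read.csv(file.path(d, "dic.csv")))
  risks <- lapply(runDirs, function(d)
    read.csv(file.path(d, "risk_summary.csv")))
  ids <- lapply(risks, `[[`, "area_id")
  for (i in seq_along(ids)[-1])
    if (!identical(ids[[i]], ids[[1]]))
      stop("runs do not share the same target frame: ", runDirs[i])
  labels <- basename(runDirs)
  crosstabs <- list()
  for (i in seq_along(runDirs)[-1]) {
    crosstabs[[paste0(labels[i], "_vs_", labels[1], "_hotspot")]] <-
      crosstabClassifications(risks[[i]]$hotspot, risks[[1]]$hotspot)
    crosstabs[[paste0(labels[i], "_vs_", labels[1], "_cluster")]] <-
      crosstabClassifications(risks[[i]]$cluster, risks[[1]]$cluster)
  }
  list(dic = do.call(rbind, dics), crosstabs = crosstabs)
}
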