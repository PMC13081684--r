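# End-to-end replica pipeline: generate (or load) -> detect -> classify ->
# measure -> compare. Deterministic under a fixed config + seed; the
# effective configuration is echoed into every output bundle.

#' Pipeline configuration with module-level defaults
#'
#' Every tunable defaults to the corresponding module default: binding
#' criterion 4 Angstrom / 5 ns, contact cutoff 4.5 Angstrom, time-averaged
#' MSD with an origin-free fit over 2--20 percent of the duration,
#' equilibration fraction 0.25, average-linkage clustering.
#'
#' @param replicas data.frame with columns \code{mode} ("top"/"side") and
#'   \code{plantedD} (Angstrom^2/ns), one row per synthetic replica; or a
#'   character vector of trajectory-table paths (with \code{topologyPath}
#'   pointing to a structure file).
#' @param nFrames,approachFrames,jitterSigma,dt synthetic generator
#'   settings (\code{\link{makeBindingTrajectory}}).
#' @param bindingCutoff,bindingPersistence binding criterion.
#' @param contactCutoff contact propensity cutoff (Angstrom).
#' @param msdMode,fitWindowFraction MSD estimator and relative fit window.
#' @param maxLagFraction largest MSD lag as a fraction of duration.
#' @param equilibriumFraction equilibration cut for distributions.
#' @param linkage clustering linkage method.
#' @param seed root seed.
#' @param topologyPath structure file defining the topology when
#'   \code{replicas} are table paths.
#' @return a list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(replicas = data.frame(
                             mode = rep(c("top", "side"), each = 10L),
                             plantedD = rep(c(22, 13.4), each = 10L)),
                           nFrames = 200L, approachFrames = 50L,
                           jitterSigma = 1, dt = 1,
                           bindingCutoff = 4, bindingPersistence = 5,
                           contactCutoff = 4.5,
                           msdMode = "time_averaged",
                           fitWindowFraction = c(0.02, 0.20),
                           maxLagFraction = 0.25,
                           equilibriumFraction = 0.25,
                           linkage = "average", seed = 1L,
                           topologyPath = NULL) {
  cfg <- list(replicas = replicas, nFrames = nFrames,
              approachFrames = approachFrames, jitterSigma = jitterSigma,
              dt = dt, bindingCutoff = bindingCutoff,
              bindingPersistence = bindingPersistence,
              contactCutoff = contactCutoff, msdMode = msdMode,
              fitWindowFraction = fitWindowFraction,
              maxLagFraction = maxLagFraction,
              equilibriumFraction = equilibriumFraction,
              linkage = linkage, seed = seed, topologyPath = topologyPath)
  class(cfg) <- "PipelineConfig"
  cfg
}

.loadReplicas <- function(cfg) {
  if (is.data.frame(cfg$replicas)) {
    if (nrow(cfg$replicas) == 0L) stop("usage error: no replicas configured")
    trajs <- lapply(seq_len(nrow(cfg$replicas)), function(i)
      makeBindingTrajectory(mode = cfg$replicas$mode[i],
                            nFrames = cfg$nFrames,
                            approachFrames = cfg$approachFrames,
                            plantedD = cfg$replicas$plantedD[i],
                            jitterSigma = cfg$jitterSigma, dt = cfg$dt,
                            seed = spawnSeed(cfg$seed, 100L + i)))
    names(trajs) <- sprintf("%s_%02d", cfg$replicas$mode,
                            seq_len(nrow(cfg$replicas)))
  } else {
    if (length(cfg$replicas) == 0L) stop("usage error: no replicas configured")
    if (is.null(cfg$topologyPath))
      stop("usage error: topologyPath required to read trajectory tables")
    top <- topology(readStructure(cfg$topologyPath))
    trajs <- lapply(cfg$replicas, readTrajectoryTable, topology = top)
    names(trajs) <- basename(cfg$replicas)
  }
  trajs
}

#' Run the full replica pipeline
#'
#' Per replica: binding event, post-binding fingerprint, median orientation
#' angle, unwrapped in-plane COM path and a fitted diffusion coefficient.
#' Across replicas: binding-mode assignment by fingerprint clustering,
#' per-mode diffusivity summary, and per-mode mean contact propensities.
#' When \code{outputDir} is given, results are written as JSON/TSV with the
#' effective configuration echoed into the bundle.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outputDir optional output directory.
#' @return result list (invisibly when writing): \code{events},
#'   \code{assignment}, \code{diffusion} (per-replica estimates),
#'   \code{diffusivitySummary}, \code{propensity} (per-mode mean tables),
#'   \code{config}.
#' @export
runReplicaPipeline <- function(config = pipelineConfig(), outputDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  trajs <- .loadReplicas(config)
  cls <- classifyBindingModes(trajs, cutoff = config$bindingCutoff,
                              persistence = config$bindingPersistence,
                              linkage = config$linkage)
  boundIds <- cls$assignment@replicaIds
  labels <- stats::setNames(cls$assignment@labels, boundIds)

  ests <- lapply(boundIds, function(id) {
    ev <- cls$events[[id]]
    frames <- seq(ev@firstBoundFrame, nFrames(trajs[[id]]))
    xy <- comTrajectoryXY(trajs[[id]])[frames, , drop = FALSE]
    xy <- unwrapXY(xy, trajs[[id]]@box[frames, 1:2, drop = FALSE])
    fitDiffusion(msdCurve(xy, dt = config$dt, mode = config$msdMode,
                          maxLagFraction = config$maxLagFraction))
  })
  names(ests) <- boundIds
  dsum <- summarizeDiffusivity(ests, labels[boundIds])

  props <- lapply(split(boundIds, labels[boundIds]), function(ids) {
    tabs <- lapply(ids, function(id)
      contactPropensity(trajs[[id]], cls$events[[id]],
                        cutoff = config$contactCutoff)@propensity)
    Reduce(`+`, tabs) / length(tabs)
  })

  result <- list(events = cls$events, assignment = cls$assignment,
                 orientations = cls$orientations, diffusion = ests,
                 diffusivitySummary = dsum, propensity = props,
                 unbound = cls$unbound, config = config)
  if (!is.null(outputDir)) .writePipelineBundle(result, outputDir)
  if (is.null(outputDir)) result else invisible(result)
}

.writePipelineBundle <- function(result, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  a <- result$assignment
  json <- list(
    config = result$config[setdiff(names(result$config), "replicas")],
    replicas = lapply(a@replicaIds, function(id) list(
      id = id, label = a@labels[a@replicaIds == id],
      firstBoundFrame = result$events[[id]]@firstBoundFrame,
      medianOrientation = unname(result$orientations[id]),
      D = result$diffusion[[id]]@D,
      log10D = result$diffusion[[id]]@log10D)),
    modeOrientation = as.list(a@modeOrientation),
    diffusivitySummary = result$diffusivitySummary,
    unbound = result$unbound)
  jsonlite::write_json(json, file.path(outputDir, "pipeline.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  fp <- data.table::as.data.table(a@fingerprints, keep.rownames = "replica")
  data.table::fwrite(fp, file.path(outputDir, "fingerprints.tsv"), sep = "\t")
  for (mode in names(result$propensity))
    writeProfileTable(
      data.frame(residue = as.integer(rownames(result$propensity[[mode]])),
                 result$propensity[[mode]]),
      file.path(outputDir, paste0("propensity_", mode, ".tsv")))
  det <- attr(result$diffusivitySummary, "detail")
  data.table::fwrite(det, file.path(outputDir, "diffusion_long.tsv"),
                     sep = "\t")
  invisible(outputDir)
}
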