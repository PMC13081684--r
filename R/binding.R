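# Binding-event detection and top/side mode classification.

#' Detect the membrane-binding event of one replica
#'
#' The protein is bound from the first frame at which its minimum
#' protein-lipid distance drops below \code{cutoff} and stays below it
#' continuously for at least \code{persistence} nanoseconds. A single-frame
#' dip that leaves again does not qualify. Defaults are a heavy-atom
#' contact cutoff of 4 Angstrom with 5 ns persistence.
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param cutoff contact distance (Angstrom), > 0.
#' @param persistence minimum continuous time below cutoff (ns); must be
#'   shorter than the trajectory.
#' @return a \linkS4class{BindingEvent}.
#' @export
detectBinding <- function(traj, cutoff = 4, persistence = 5) {
  if (cutoff <= 0) stop("validation error: cutoff must be > 0")
  times <- traj@times
  duration <- times[length(times)] - times[1]
  if (persistence >= duration)
    stop("persistence must be shorter than the trajectory duration")
  # a system with no lipids at all cannot bind: report "never bound"
  if (!any(atoms(traj)$group == "lipid"))
    return(new("BindingEvent", bound = FALSE,
               firstBoundFrame = NA_integer_,
               cutoff = cutoff, persistence = persistence))
  below <- minProteinLipidDistance(traj) < cutoff
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    if (times[ends[k]] - times[starts[k]] >= persistence)
      return(new("BindingEvent", bound = TRUE,
                 firstBoundFrame = starts[k],
                 cutoff = cutoff, persistence = persistence))
  }
  new("BindingEvent", bound = FALSE, firstBoundFrame = NA_integer_,
      cutoff = cutoff, persistence = persistence)
}

#' Post-binding residue fingerprint of a replica
#'
#' Mean minimal residue-membrane distance (any lipid class) over the frames
#' from the binding event to the end of the trajectory. Frames before the
#' event never enter the fingerprint.
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param event the replica's \linkS4class{BindingEvent}.
#' @return named numeric vector (Angstrom), one entry per protein residue.
#' @export
bindingFingerprint <- function(traj, event) {
  stopifnot(is(event, "BindingEvent"))
  if (!event@bound)
    stop("state error: cannot fingerprint an unbound replica")
  frames <- seq(event@firstBoundFrame, nFrames(traj))
  fp <- residueMinDistances(traj, lipidClass = "any", frames = frames)
  attr(fp, "perFrame") <- NULL
  fp
}

#' Cluster replica fingerprints into binding modes
#'
#' Agglomerative hierarchical clustering on Euclidean distances between the
#' per-replica fingerprints, cut into \code{k} clusters. Average linkage is
#' the default (robust to unequal cluster sizes); ward.D2, complete and
#' single are available. The full merge tree is kept so other cuts can be
#' inspected.
#'
#' @param fingerprints matrix replicas x residues (rownames = replica ids),
#'   or a list of fingerprint vectors.
#' @param k number of clusters (default 2, the two recurrent modes).
#' @param linkage \code{hclust} method.
#' @return a \linkS4class{ModeAssignment} with numeric cluster labels
#'   ("1".."k"); pass through \code{\link{assignModeNames}} to name them.
#' @export
clusterFingerprints <- function(fingerprints, k = 2L,
                                linkage = c("average", "ward.D2",
                                            "complete", "single")) {
  linkage <- match.arg(linkage)
  if (is.list(fingerprints)) fingerprints <- do.call(rbind, fingerprints)
  fingerprints <- as.matrix(fingerprints)
  if (is.null(rownames(fingerprints)))
    rownames(fingerprints) <- paste0("replica", seq_len(nrow(fingerprints)))
  if (nrow(fingerprints) < k)
    stop("clustering error: fewer fingerprints (", nrow(fingerprints),
         ") than clusters (", k, ")")
  hc <- stats::hclust(stats::dist(fingerprints), method = linkage)
  labels <- as.character(stats::cutree(hc, k = k))
  new("ModeAssignment", replicaIds = rownames(fingerprints),
      fingerprints = fingerprints, linkage = hc, labels = labels,
      modeOrientation = numeric())
}

#' Name two fingerprint clusters "top" and "side"
#'
#' The cluster whose replicas have the smaller median post-binding
#' orientation angle (principal axis closer to the membrane normal) is
#' named \code{top}; the other \code{side}. Exact ties are broken by the
#' mean fingerprint: the cluster in deeper contact (smaller mean minimal
#' distance) becomes \code{side}, with a warning.
#'
#' @param assignment a \linkS4class{ModeAssignment} with exactly 2 clusters.
#' @param orientations named numeric vector: median post-binding
#'   orientation angle (degrees) per replica.
#' @return the assignment with labels renamed and \code{modeOrientation}
#'   filled; if the assignment does not have exactly two clusters it is
#'   returned unchanged with a message.
#' @export
assignModeNames <- function(assignment, orientations) {
  stopifnot(is(assignment, "ModeAssignment"))
  labs <- assignment@labels
  uniq <- unique(labs)
  if (length(uniq) != 2L) {
    message("mode naming skipped: needs exactly 2 clusters, found ",
            length(uniq))
    return(assignment)
  }
  ori <- orientations[assignment@replicaIds]
  med <- vapply(uniq, function(u) stats::median(ori[labs == u]), numeric(1))
  if (med[1] == med[2]) {
    warning("orientation medians tie; breaking by mean fingerprint depth")
    depth <- vapply(uniq, function(u)
      mean(assignment@fingerprints[labs == u, , drop = FALSE]), numeric(1))
    topCluster <- uniq[which.max(depth)]  # deeper contact -> side
  } else {
    topCluster <- uniq[which.min(med)]
  }
  newLabs <- ifelse(labs == topCluster, "top", "side")
  assignment@labels <- newLabs
  assignment@modeOrientation <- c(
    top = stats::median(ori[newLabs == "top"]),
    side = stats::median(ori[newLabs == "side"]))
  assignment
}

#' Detect, fingerprint and classify a set of replicas
#'
#' Convenience wrapper running \code{\link{detectBinding}},
#' \code{\link{bindingFingerprint}}, post-binding orientation medians,
#' \code{\link{clusterFingerprints}} and \code{\link{assignModeNames}}
#' across replicas. Only replicas that bind are clustered.
#'
#' @param trajs named list of \linkS4class{TrajectoryEnsemble} replicas.
#' @param cutoff,persistence binding criterion
#'   (\code{\link{detectBinding}}).
#' @param k,linkage clustering options
#'   (\code{\link{clusterFingerprints}}).
#' @return list with \code{assignment} (\linkS4class{ModeAssignment}),
#'   \code{events}, \code{orientations} (median post-binding angle per
#'   replica) and \code{unbound} (ids of replicas that never bound).
#' @export
classifyBindingModes <- function(trajs, cutoff = 4, persistence = 5,
                                 k = 2L, linkage = "average") {
  if (is.null(names(trajs)))
    names(trajs) <- paste0("replica", seq_along(trajs))
  events <- lapply(trajs, detectBinding, cutoff = cutoff,
                   persistence = persistence)
  bound <- vapply(events, function(e) e@bound, logical(1))
  if (sum(bound) < k)
    stop("clustering error: only ", sum(bound), " replicas bound; need >= ", k)
  fps <- t(vapply(names(trajs)[bound], function(id)
    bindingFingerprint(trajs[[id]], events[[id]]),
    numeric(length(proteinResidues(trajs[[1]])))))
  ori <- vapply(names(trajs)[bound], function(id) {
    oa <- orientationAngle(trajs[[id]])
    stats::median(oa$angle[seq(events[[id]]@firstBoundFrame, nrow(oa))])
  }, numeric(1))
  assignment <- clusterFingerprints(fps, k = k, linkage = linkage)
  if (k == 2L) assignment <- assignModeNames(assignment, ori)
  list(assignment = assignment, events = events, orientations = ori,
       unbound = names(trajs)[!bound])
}
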