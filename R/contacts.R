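# Lipid-class-stratified residue contact propensities.

#' Residue x lipid-class contact propensities after binding
#'
#' A residue is "in contact" with lipid class c in a frame iff the minimum
#' PBC-aware distance from any of its atoms to any atom of a class-c lipid
#' is below \code{cutoff}. The propensity is the fraction of analyzed
#' frames in contact; by default the window runs from the binding event to
#' the end of the trajectory (set \code{fullTrajectory = TRUE} to use all
#' frames). A class absent from the membrane yields a zero column with a
#' warning, not an error.
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param event the replica's \linkS4class{BindingEvent}; required unless
#'   \code{fullTrajectory = TRUE}.
#' @param cutoff contact cutoff (Angstrom); default 4.5 (heavy-atom
#'   contact).
#' @param classes lipid classes to stratify by.
#' @param fullTrajectory analyze every frame instead of the post-binding
#'   window.
#' @return a \linkS4class{ContactPropensityTable}.
#' @export
contactPropensity <- function(traj, event = NULL, cutoff = 4.5,
                              classes = c("POPC", "POPS", "POPI"),
                              fullTrajectory = FALSE) {
  if (cutoff <= 0) stop("validation error: cutoff must be > 0")
  if (fullTrajectory) {
    frames <- seq_len(nFrames(traj))
  } else {
    stopifnot(is(event, "BindingEvent"))
    if (!event@bound)
      stop("state error: cannot compute post-binding propensities for an unbound replica")
    frames <- seq(event@firstBoundFrame, nFrames(traj))
  }
  present <- unique(atoms(traj)$lipidClass[atoms(traj)$group == "lipid"])
  res <- proteinResidues(traj)
  prop <- matrix(0, length(res), length(classes),
                 dimnames = list(res, classes))
  for (cl in classes) {
    if (cl != "any" && !(cl %in% present)) {
      warning("lipid class ", cl, " absent from the membrane; propensity 0")
      next
    }
    m <- .residueMinDistMatrix(traj, lipidClass = cl, frames = frames)
    prop[, cl] <- colMeans(m < cutoff)
  }
  new("ContactPropensityTable", propensity = prop, cutoff = cutoff,
      frameWindow = as.integer(range(frames)))
}

#' Differential contact propensity between two conditions
#'
#' Elementwise difference \code{a - b} of two propensity tables (for
#' example variant minus wild type), plus per-class mean differences. A
#' uniformly positive class mean signals globally increased membrane
#' avidity; opposite signs across classes signal a shift in lipid
#' preference.
#'
#' @param a,b \linkS4class{ContactPropensityTable} objects over the same
#'   residues, classes and cutoff.
#' @return list with \code{delta} (matrix residues x classes, in [-1, 1])
#'   and \code{classMean} (named numeric).
#' @export
differentialPropensity <- function(a, b) {
  stopifnot(is(a, "ContactPropensityTable"), is(b, "ContactPropensityTable"))
  if (!identical(dimnames(a@propensity), dimnames(b@propensity)))
    stop("alignment error: propensity tables cover different residues or classes")
  if (!isTRUE(all.equal(a@cutoff, b@cutoff)))
    stop("alignment error: propensity tables use different cutoffs")
  delta <- a@propensity - b@propensity
  list(delta = delta, classMean = colMeans(delta))
}
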