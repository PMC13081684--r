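# Accessors and show methods for the core containers.

#' @rdname TrajectoryEnsemble-class
#' @param object,x a \linkS4class{TrajectoryEnsemble}.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname TrajectoryEnsemble-class
#' @export
setMethod("nFrames", "TrajectoryEnsemble", function(x) dim(x@coords)[1])

#' @rdname TrajectoryEnsemble-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname TrajectoryEnsemble-class
#' @export
setMethod("nAtoms", "TrajectoryEnsemble", function(x) dim(x@coords)[2])
#' @rdname SystemTopology-class
#' @export
setMethod("nAtoms", "SystemTopology", function(x) nrow(x@atoms))

#' Coordinates of one frame as an n x 3 matrix
#' @param x a \linkS4class{TrajectoryEnsemble}.
#' @param i frame index.
#' @return numeric matrix \code{n_atoms x 3} (Angstrom).
#' @export
frameCoords <- function(x, i) {
  stopifnot(is(x, "TrajectoryEnsemble"), i >= 1, i <= nFrames(x))
  matrix(x@coords[i, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' @rdname TrajectoryEnsemble-class
#' @export
frameTimes <- function(x) x@times

#' @rdname TrajectoryEnsemble-class
#' @export
boxLengths <- function(x) x@box

#' @rdname TrajectoryEnsemble-class
#' @export
topology <- function(x) x@topology

#' @rdname SystemTopology-class
#' @param x a \linkS4class{SystemTopology}.
#' @export
atoms <- function(x) {
  if (is(x, "TrajectoryEnsemble")) x <- x@topology
  x@atoms
}

#' Protein residue numbers of a topology (sorted)
#' @param x a \linkS4class{SystemTopology} or \linkS4class{TrajectoryEnsemble}.
#' @export
proteinResidues <- function(x) {
  a <- atoms(x)
  sort(unique(a$residueSeq[a$group == "protein"]))
}

#' @rdname ModeAssignment-class
#' @param x a \linkS4class{ModeAssignment}.
#' @export
modeLabels <- function(x) {
  stopifnot(is(x, "ModeAssignment"))
  stats::setNames(x@labels, x@replicaIds)
}

#' @rdname DiffusionEstimate-class
#' @param x a \linkS4class{DiffusionEstimate}.
#' @export
diffusionCoefficient <- function(x) {
  stopifnot(is(x, "DiffusionEstimate"))
  x@D
}

setMethod("show", "SystemTopology", function(object) {
  a <- object@atoms
  cat("SystemTopology:", nrow(a), "atoms,",
      length(unique(a$residueSeq)), "residues\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(a$group)),
                                 table(a$group)), collapse = ", "), "\n")
  lip <- a[a$group == "lipid", ]
  if (nrow(lip))
    cat("  lipid classes:",
        paste(sprintf("%s=%d", names(table(lip$lipidClass)),
                      table(lip$lipidClass)), collapse = ", "), "\n")
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat("TrajectoryEnsemble:", nFrames(object), "frames x",
      nAtoms(object), "atoms\n")
  cat(sprintf("  time: %.3f .. %.3f ns; box[1]: %.1f x %.1f x %.1f A\n",
              object@times[1], object@times[length(object@times)],
              object@box[1, 1], object@box[1, 2], object@box[1, 3]))
})

setMethod("show", "BindingEvent", function(object) {
  if (object@bound)
    cat(sprintf("BindingEvent: bound at frame %d (cutoff %.2f A, persistence %.2f ns)\n",
                object@firstBoundFrame, object@cutoff, object@persistence))
  else
    cat(sprintf("BindingEvent: never bound (cutoff %.2f A, persistence %.2f ns)\n",
                object@cutoff, object@persistence))
})

setMethod("show", "ModeAssignment", function(object) {
  cat("ModeAssignment:", length(object@replicaIds), "replicas\n")
  print(table(object@labels))
  if (length(object@modeOrientation))
    cat("  median orientation (deg):",
        paste(sprintf("%s=%.1f", names(object@modeOrientation),
                      object@modeOrientation), collapse = ", "), "\n")
})

setMethod("show", "DiffusionEstimate", function(object) {
  cat(sprintf("DiffusionEstimate: D = %.4g +/- %.2g A^2/ns (window %.3g-%.3g ns, R^2 = %.4f)\n",
              object@D, object@stderr, object@fitWindow[1],
              object@fitWindow[2], object@rSquared))
})

setMethod("show", "VariantRecord", function(object) {
  cat(sprintf("VariantRecord: %s%d%s [%s]\n", object@wtAA, object@position,
              object@mutAA, object@severity))
})

setMethod("show", "ContactPropensityTable", function(object) {
  cat("ContactPropensityTable:", nrow(object@propensity), "residues x",
      ncol(object@propensity), "lipid classes",
      sprintf("(cutoff %.2f A, frames %d-%d)\n", object@cutoff,
              object@frameWindow[1], object@frameWindow[2]))
  cat("  per-class mean propensity:",
      paste(sprintf("%s=%.3f", colnames(object@propensity),
                    colMeans(object@propensity)), collapse = ", "), "\n")
})
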