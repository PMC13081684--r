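#' @import methods
NULL

LIPID_CLASSES <- c("POPC", "POPS", "POPI")
ATOM_GROUPS <- c("protein", "lipid", "solvent", "ion")
VARIANT_SEVERITIES <- c("benign", "likely_benign", "pathogenic",
                        "likely_pathogenic", "VUS", "conflicting", "unknown")

#' System topology: the per-atom table defining all selections
#'
#' A \code{SystemTopology} holds one row per atom with its name, author
#' residue numbering (e.g. 253--413 for the SynGAP C2 construct), mass,
#' coarse group (protein / lipid / solvent / ion) and, for lipids, the lipid
#' class (POPC, POPS or POPI). Internal atom indices are 1-based; residue
#' numbering is kept exactly as authored so that loop and variant positions
#' can be referred to directly.
#'
#' @slot atoms \code{data.frame} with columns \code{atomIndex},
#'   \code{atomName}, \code{residueSeq}, \code{residueName}, \code{mass},
#'   \code{group}, \code{lipidClass}.
#' @slot residueIndex named list mapping \code{residueSeq} (as character)
#'   to integer atom indices.
#' @export
setClass("SystemTopology",
         representation(atoms = "data.frame", residueIndex = "list"))

setValidity("SystemTopology", function(object) {
  a <- object@atoms
  need <- c("atomIndex", "atomName", "residueSeq", "residueName",
            "mass", "group", "lipidClass")
  if (!all(need %in% names(a)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("empty atom table")
  if (!identical(as.integer(a$atomIndex), seq_len(nrow(a))))
    return("atomIndex must be 1..n, unique and contiguous")
  if (any(!is.finite(a$mass)) || any(a$mass <= 0))
    return("all masses must be finite and > 0")
  if (!all(a$group %in% ATOM_GROUPS))
    return("unknown atom group")
  isLip <- a$group == "lipid"
  if (any(isLip & !(a$lipidClass %in% LIPID_CLASSES)))
    return("lipid atoms must carry a lipid class (POPC/POPS/POPI)")
  if (any(!isLip & a$lipidClass != "none"))
    return("non-lipid atoms must have lipidClass 'none'")
  pres <- sort(unique(a$residueSeq[a$group == "protein"]))
  if (length(pres) > 1L && !identical(pres, seq(min(pres), max(pres))))
    return("protein residue numbering must be contiguous")
  TRUE
})

#' Trajectory ensemble: frames x atoms x 3 coordinates with box and times
#'
#' Coordinates are in Angstrom, times in nanoseconds, and each frame carries
#' orthorhombic box edge lengths (Lx, Ly, Lz) in Angstrom. This is the
#' substrate of every analysis in the package.
#'
#' @slot coords numeric array \code{frames x atoms x 3} (Angstrom).
#' @slot box numeric matrix \code{frames x 3} of box edge lengths (Angstrom).
#' @slot times numeric vector of frame timestamps (ns), strictly increasing.
#' @slot topology the \linkS4class{SystemTopology} the coordinates refer to.
#' @export
setClass("TrajectoryEnsemble",
         representation(coords = "array", box = "matrix",
                        times = "numeric", topology = "SystemTopology"))

setValidity("TrajectoryEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    return("coords must be a frames x atoms x 3 array")
  if (d[2] != nrow(object@topology@atoms))
    return("atom count of coords does not match topology")
  if (length(object@times) != d[1])
    return("times length must equal number of frames")
  if (d[1] > 1L && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (!identical(dim(object@box), c(d[1], 3L)))
    return("box must be a frames x 3 matrix")
  if (any(!is.finite(object@box)) || any(object@box <= 0))
    return("all box lengths must be finite and > 0")
  TRUE
})

#' Region mask: a named set of protein residues
#'
#' @slot name label of the mask (e.g. \code{"full"}, \code{"no_termini"}).
#' @slot residues integer vector of included \code{residueSeq} values.
#' @export
setClass("RegionMask",
         representation(name = "character", residues = "integer"))

setValidity("RegionMask", function(object) {
  if (length(object@name) != 1L) return("name must be a single string")
  if (length(object@residues) == 0L) return("mask must contain residues")
  if (anyDuplicated(object@residues)) return("duplicated residues in mask")
  TRUE
})

#' Missense variant record
#'
#' @slot wtAA one-letter wild-type amino acid.
#' @slot position author residue number within the construct range.
#' @slot mutAA one-letter mutant amino acid.
#' @slot severity clinical severity label.
#' @export
setClass("VariantRecord",
         representation(wtAA = "character", position = "integer",
                        mutAA = "character", severity = "character"))

#' Binding event detected in one replica
#'
#' @slot bound logical; did the protein bind under the criterion?
#' @slot firstBoundFrame integer frame index (NA when unbound).
#' @slot cutoff contact distance cutoff (Angstrom).
#' @slot persistence minimum time below cutoff (ns).
#' @export
setClass("BindingEvent",
         representation(bound = "logical", firstBoundFrame = "integer",
                        cutoff = "numeric", persistence = "numeric"))

setValidity("BindingEvent", function(object) {
  if (!object@bound && !is.na(object@firstBoundFrame))
    return("unbound event must not carry a binding frame")
  TRUE
})

#' Binding-mode assignment across replicas
#'
#' Holds the per-replica mean minimal-distance fingerprints, the hierarchical
#' clustering merge tree, cluster labels and the per-cluster median
#' orientation angle used to name the clusters top/side.
#'
#' @slot replicaIds character replica identifiers.
#' @slot fingerprints matrix replicas x residues of mean minimal distances
#'   (Angstrom); column names are residue numbers.
#' @slot linkage the \code{hclust} merge tree.
#' @slot labels character cluster label per replica ("top"/"side" once
#'   named, otherwise "1","2",...).
#' @slot modeOrientation named numeric: median post-binding orientation
#'   angle (degrees) per cluster label.
#' @export
setClass("ModeAssignment",
         representation(replicaIds = "character", fingerprints = "matrix",
                        linkage = "ANY", labels = "character",
                        modeOrientation = "numeric"))

setValidity("ModeAssignment", function(object) {
  if (length(object@labels) != length(object@replicaIds))
    return("every replica must be labeled")
  if (nrow(object@fingerprints) != length(object@replicaIds))
    return("fingerprint rows must match replicas")
  TRUE
})

#' Mean-squared-displacement curve
#'
#' @slot lags time lags (ns), starting at 0.
#' @slot msd MSD values (Angstrom^2); \code{msd[lag 0] == 0}.
#' @slot nPairs number of displacement pairs averaged at each lag.
#' @slot mode \code{"ensemble_origin"} (average over trajectories from t=0)
#'   or \code{"time_averaged"} (additionally over all time origins).
#' @slot duration trajectory duration (ns), used for relative fit windows.
#' @export
setClass("MSDCurve",
         representation(lags = "numeric", msd = "numeric",
                        nPairs = "numeric", mode = "character",
                        duration = "numeric"))

setValidity("MSDCurve", function(object) {
  if (length(object@lags) != length(object@msd))
    return("lags and msd must have equal length")
  if (any(object@msd < 0)) return("msd must be non-negative")
  if (object@lags[1] != 0 || object@msd[1] != 0)
    return("curve must start at lag 0 with msd 0")
  TRUE
})

#' Fitted 2D lateral diffusion coefficient
#'
#' @slot D diffusion coefficient (Angstrom^2/ns), slope/4 of the MSD fit.
#' @slot stderr standard error of D from the linear fit.
#' @slot fitWindow lag window (ns) used for the fit.
#' @slot rSquared coefficient of determination of the fit.
#' @slot log10D base-10 log of D (NA when D <= 0).
#' @export
setClass("DiffusionEstimate",
         representation(D = "numeric", stderr = "numeric",
                        fitWindow = "numeric", rSquared = "numeric",
                        log10D = "numeric"))

setValidity("DiffusionEstimate", function(object) {
  if (object@D < 0) return("D must be >= 0 (negative fits are clipped)")
  if (length(object@fitWindow) != 2L || object@fitWindow[1] >= object@fitWindow[2])
    return("fitWindow must be (lagMin, lagMax) with lagMin < lagMax")
  TRUE
})

#' Principal-component basis of a conformational ensemble
#'
#' Eigen decomposition of the covariance matrix of superposed
#' representative-atom coordinates (one atom per residue).
#'
#' @slot meanCoords matrix n x 3, the converged mean structure (Angstrom).
#' @slot vectors 3n x 3n orthonormal eigenvector matrix (columns are modes).
#' @slot values eigenvalues (Angstrom^2), non-negative, descending.
#' @slot residues residue numbers of the selection, in order.
#' @export
setClass("PCABasis",
         representation(meanCoords = "matrix", vectors = "matrix",
                        values = "numeric", residues = "integer"))

setValidity("PCABasis", function(object) {
  if (any(object@values < -1e-8)) return("eigenvalues must be non-negative")
  if (is.unsorted(rev(object@values))) return("eigenvalues must be descending")
  TRUE
})

#' Residue x lipid-class contact propensity table
#'
#' @slot propensity matrix residues x classes with per-frame contact
#'   fractions in [0, 1]; rownames are residue numbers.
#' @slot cutoff contact cutoff (Angstrom).
#' @slot frameWindow integer (first, last) analyzed frame.
#' @export
setClass("ContactPropensityTable",
         representation(propensity = "matrix", cutoff = "numeric",
                        frameWindow = "integer"))

setValidity("ContactPropensityTable", function(object) {
  p <- object@propensity
  if (any(p < 0 | p > 1)) return("propensities must lie in [0, 1]")
  TRUE
})
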