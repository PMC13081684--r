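# Membrane-frame geometric primitives.
#
# Conventions: the bilayer lies in the xy plane; periodic boundaries are
# applied in x and y via the minimum-image convention. PBC in z is ignored
# for protein-membrane distances (membrane-centered convention): the
# membrane is the z reference, so images above/below are never the nearest
# physical contact in these systems.

.minImage <- function(d, L) d - L * round(d / L)

.massCOM <- function(xyz, mass) colSums(xyz * mass) / sum(mass)

#' Mass-weighted bilayer midplane (z) per frame
#'
#' @param traj a \linkS4class{TrajectoryEnsemble} containing lipid atoms.
#' @return numeric vector of midplane z (Angstrom), one per frame.
#' @export
bilayerMidplane <- function(traj) {
  stopifnot(is(traj, "TrajectoryEnsemble"))
  li <- lipidAtomIndices(traj@topology)
  m <- atoms(traj)$mass[li]
  vapply(seq_len(nFrames(traj)), function(f)
    sum(traj@coords[f, li, 3] * m) / sum(m), numeric(1))
}

#' Protein COM distance from the bilayer midplane
#'
#' Per frame, the absolute difference between the mass-weighted z of the
#' protein heavy atoms and the bilayer midplane.
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param mask optional \linkS4class{RegionMask}.
#' @return data.frame(time, value) with attribute
#'   \code{definition = "com_to_midplane"}.
#' @export
comMembraneDistance <- function(traj, mask = NULL) {
  pi_ <- proteinAtomIndices(traj@topology, mask)
  m <- atoms(traj)$mass[pi_]
  mid <- bilayerMidplane(traj)
  zc <- vapply(seq_len(nFrames(traj)), function(f)
    sum(traj@coords[f, pi_, 3] * m) / sum(m), numeric(1))
  structure(data.frame(time = traj@times, value = abs(zc - mid)),
            definition = "com_to_midplane")
}

#' In-plane (xy) protein center-of-mass trajectory
#'
#' The raw, possibly wrapped, COM path in the membrane plane; feed through
#' \code{\link{unwrapXY}} before computing MSDs.
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param mask optional \linkS4class{RegionMask}.
#' @return nFrames x 2 matrix (Angstrom).
#' @export
comTrajectoryXY <- function(traj, mask = NULL) {
  pi_ <- proteinAtomIndices(traj@topology, mask)
  m <- atoms(traj)$mass[pi_]
  t(vapply(seq_len(nFrames(traj)), function(f)
    .massCOM(matrix(traj@coords[f, pi_, 1:2], ncol = 2L), m), numeric(2)))
}

#' Orientation angle of the protein principal axis vs the membrane normal
#'
#' Per frame, the angle between z (the membrane normal) and the eigenvector
#' of the protein's mass-weighted gyration tensor with the largest
#' eigenvalue, folded into [0, 90] degrees (the axis sign is meaningless).
#' Frames whose top two gyration eigenvalues coincide within a relative gap
#' of 1e-6 have no well-defined principal axis; their angle is still
#' reported but a degeneracy warning is emitted and the frames are flagged
#' in the \code{degenerate} attribute.
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param mask optional \linkS4class{RegionMask}.
#' @return data.frame(time, angle) with attribute \code{degenerate}.
#' @export
orientationAngle <- function(traj, mask = NULL) {
  pi_ <- proteinAtomIndices(traj@topology, mask)
  if (length(pi_) < 3L) stop("need >= 3 protein atoms for a principal axis")
  m <- atoms(traj)$mass[pi_]
  nf <- nFrames(traj)
  ang <- numeric(nf); degen <- logical(nf)
  for (f in seq_len(nf)) {
    xyz <- matrix(traj@coords[f, pi_, ], ncol = 3L)
    cen <- sweep(xyz, 2L, .massCOM(xyz, m))
    gyr <- crossprod(cen * sqrt(m)) / sum(m)
    e <- eigen(gyr, symmetric = TRUE)
    degen[f] <- (e$values[1] - e$values[2]) < 1e-6 * max(e$values[1], .Machine$double.eps)
    v <- e$vectors[, 1]
    ang[f] <- acos(min(1, abs(v[3]))) * 180 / pi
  }
  if (any(degen))
    warning("degenerate gyration tensor in ", sum(degen),
            " frame(s); principal axis ill-defined there")
  structure(data.frame(time = traj@times, angle = ang), degenerate = degen)
}

# Per-frame, per-residue minimum protein-lipid distance matrix.
# Returns frames x residues matrix; PBC minimum image in x/y only.
.residueMinDistMatrix <- function(traj, lipidClass = "any", frames = NULL) {
  top <- traj@topology
  pi_ <- proteinAtomIndices(top)
  li <- lipidAtomIndices(top, lipidClass)
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  if (!length(frames)) stop("empty frame window")
  resOf <- atoms(top)$residueSeq[pi_]
  resLevels <- sort(unique(resOf))
  grp <- split(seq_along(pi_), factor(resOf, levels = resLevels))
  out <- matrix(NA_real_, length(frames), length(resLevels),
                dimnames = list(NULL, resLevels))
  for (i in seq_along(frames)) {
    f <- frames[i]
    L <- traj@box[f, ]
    dx <- .minImage(outer(traj@coords[f, pi_, 1], traj@coords[f, li, 1], "-"), L[1])
    dy <- .minImage(outer(traj@coords[f, pi_, 2], traj@coords[f, li, 2], "-"), L[2])
    dz <- outer(traj@coords[f, pi_, 3], traj@coords[f, li, 3], "-")
    d2 <- dx * dx + dy * dy + dz * dz
    atomMin <- d2[cbind(seq_along(pi_), max.col(-d2, ties.method = "first"))]
    out[i, ] <- sqrt(vapply(grp, function(g) min(atomMin[g]), numeric(1)))
  }
  out
}

#' Mean minimal residue-membrane distances over a frame window
#'
#' For each protein residue, the per-frame minimum over all (residue atom x
#' selected lipid atom) PBC-aware distances, averaged over the window. This
#' is the per-residue membrane-proximity fingerprint used for binding-mode
#' classification.
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param lipidClass \code{"any"} or one of POPC/POPS/POPI.
#' @param frames integer frame indices (default: all frames).
#' @return named numeric vector (Angstrom), names are residue numbers; the
#'   per-frame matrix is attached as attribute \code{perFrame}.
#' @export
residueMinDistances <- function(traj, lipidClass = "any", frames = NULL) {
  m <- .residueMinDistMatrix(traj, lipidClass, frames)
  structure(colMeans(m), names = colnames(m), perFrame = m)
}

#' Minimum protein-lipid distance per frame
#'
#' The global contact distance used by the binding detector.
#'
#' @inheritParams residueMinDistances
#' @return numeric vector, one value per frame.
#' @export
minProteinLipidDistance <- function(traj, lipidClass = "any") {
  m <- .residueMinDistMatrix(traj, lipidClass)
  apply(m, 1L, min)
}

#' Unwrap a periodic 2D trajectory
#'
#' Accumulates minimum-image frame-to-frame displacements, removing box
#' wrapping exactly whenever the true displacement per frame is below half
#' the box edge on each axis (a violation of that precondition is
#' undetectable from the wrapped data).
#'
#' @param xy nFrames x 2 matrix of wrapped positions (Angstrom).
#' @param box per-frame box edges: nFrames x 2 matrix, or length-2 (or
#'   length-1 square) vector.
#' @return nFrames x 2 matrix of continuous positions.
#' @export
unwrapXY <- function(xy, box) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (is.null(dim(box))) {
    if (length(box) == 1L) box <- c(box, box)
    box <- matrix(box[1:2], n, 2L, byrow = TRUE)
  }
  if (n < 2L) return(xy)
  d <- diff(xy)
  d[, 1] <- .minImage(d[, 1], box[-1, 1])
  d[, 2] <- .minImage(d[, 2], box[-1, 2])
  cs <- apply(d, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
  out <- rbind(xy[1, , drop = FALSE], sweep(cs, 2L, xy[1, ], "+"))
  dimnames(out) <- dimnames(xy)
  out
}

#' @rdname unwrapXY
#' @param xy nFrames x 2 matrix of continuous positions.
#' @export
wrapXY <- function(xy, box) {
  xy <- as.matrix(xy)
  if (is.null(dim(box))) {
    if (length(box) == 1L) box <- c(box, box)
    box <- matrix(box[1:2], nrow(xy), 2L, byrow = TRUE)
  }
  xy %% box
}
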