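# Conformational ensemble statistics: superposition, RMSD, radius of
# gyration, RMSF, covariance PCA, basin projection and overlap.
#
# Defaults follow the standard per-residue reduction: one representative
# atom per residue (the C-alpha, or the residue bead in synthetic systems),
# mass-weighted least-squares superposition with a proper rotation
# (reflections excluded).

# Optimal weighted rigid superposition (Kabsch, via SVD).
# Returns list(R, t, rmsd): x %*% R + t best matches `ref` under weights w.
.kabsch <- function(x, ref, w = NULL) {
  n <- nrow(x)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  cx <- colSums(x * w); cr <- colSums(ref * w)
  xc <- sweep(x, 2L, cx); rc <- sweep(ref, 2L, cr)
  H <- crossprod(xc * w, rc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- xc %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - rc)^2)))
  list(R = R, t = cr - cx %*% R, rmsd = rmsd,
       coords = sweep(fitted, 2L, cr, "+"))
}

#' Optimal least-squares superposition of two frames
#'
#' Rotates and translates \code{mobile} onto \code{reference}, minimizing
#' the mass-weighted squared deviation; the rotation is proper (no
#' reflection). Requires at least 3 non-collinear atoms.
#'
#' @param mobile,reference n x 3 coordinate matrices over the same atoms.
#' @param weights per-atom weights (e.g. masses); uniform by default.
#' @return list with \code{coords} (superposed mobile), \code{rmsd}
#'   (Angstrom), \code{rotation} and \code{translation}.
#' @export
superposeFrames <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("alignment error: coordinate sets differ in size")
  if (nrow(mobile) < 3L) stop("need >= 3 atoms to superpose")
  k <- .kabsch(mobile, reference, weights)
  list(coords = k$coords, rmsd = k$rmsd, rotation = k$R, translation = k$t)
}

# representative-atom coordinate stack: frames x nres x 3 + residues + masses
.repCoords <- function(traj, mask = NULL) {
  idx <- repAtomIndices(traj@topology, mask)
  res <- attr(idx, "residues")
  list(coords = traj@coords[, idx, , drop = FALSE],
       residues = res, mass = atoms(traj)$mass[idx])
}

#' Per-frame RMSD to a reference after superposition
#'
#' Each frame is optimally superposed on the reference over the selection,
#' then the mass-weighted RMSD is computed over the same selection. The
#' values after the equilibration cut (default: first 25 percent of frames
#' discarded) form the equilibrium distribution attached as attribute
#' \code{equilibrium}.
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param reference frame index into \code{traj} (default 1) or an
#'   n x 3 matrix over the selection's residues.
#' @param mask optional \linkS4class{RegionMask}.
#' @param equilibriumFraction fraction of initial frames excluded from the
#'   equilibrium distribution.
#' @return data.frame(time, rmsd) with attribute \code{equilibrium}.
#' @export
rmsdSeries <- function(traj, reference = 1L, mask = NULL,
                       equilibriumFraction = 0.25) {
  rc <- .repCoords(traj, mask)
  nf <- dim(rc$coords)[1]
  ref <- if (is.matrix(reference)) reference
         else matrix(rc$coords[reference, , ], ncol = 3L)
  if (nrow(ref) != dim(rc$coords)[2])
    stop("alignment error: reference size does not match selection")
  vals <- vapply(seq_len(nf), function(f)
    .kabsch(matrix(rc$coords[f, , ], ncol = 3L), ref, rc$mass)$rmsd,
    numeric(1))
  eqStart <- min(nf, floor(equilibriumFraction * nf) + 1L)
  structure(data.frame(time = traj@times, rmsd = vals),
            equilibrium = vals[eqStart:nf])
}

#' Per-frame radius of gyration
#'
#' Mass-weighted root-mean-square distance of the selected atoms from their
#' center of mass.
#'
#' @inheritParams rmsdSeries
#' @return data.frame(time, rg) with attribute \code{equilibrium}.
#' @export
gyrationSeries <- function(traj, mask = NULL, equilibriumFraction = 0.25) {
  rc <- .repCoords(traj, mask)
  if (dim(rc$coords)[2] < 2L) stop("need >= 2 selected atoms")
  w <- rc$mass / sum(rc$mass)
  nf <- dim(rc$coords)[1]
  vals <- vapply(seq_len(nf), function(f) {
    xyz <- matrix(rc$coords[f, , ], ncol = 3L)
    cen <- sweep(xyz, 2L, colSums(xyz * w))
    sqrt(sum(w * rowSums(cen^2)))
  }, numeric(1))
  eqStart <- min(nf, floor(equilibriumFraction * nf) + 1L)
  structure(data.frame(time = traj@times, rg = vals),
            equilibrium = vals[eqStart:nf])
}

# Iterative mean-structure superposition: superpose all frames on the
# current mean, recompute the mean, repeat to convergence.
.convergedMeanFit <- function(coordsArr, mass, maxIter = 100L, tol = 1e-6) {
  nf <- dim(coordsArr)[1]; n <- dim(coordsArr)[2]
  fitted <- coordsArr
  ref <- matrix(coordsArr[1L, , ], ncol = 3L)
  for (it in seq_len(maxIter)) {
    for (f in seq_len(nf))
      fitted[f, , ] <- .kabsch(matrix(coordsArr[f, , ], ncol = 3L),
                               ref, mass)$coords
    newRef <- apply(fitted, c(2L, 3L), mean)
    shift <- sqrt(mean((newRef - ref)^2))
    ref <- newRef
    if (shift < tol) return(list(fitted = fitted, mean = ref, iter = it))
  }
  stop("convergence error: mean-structure superposition did not converge in ",
       maxIter, " iterations")
}

#' Per-residue root-mean-square fluctuations
#'
#' Frames are superposed on their converged mean structure (iterated
#' mean-and-superpose), then RMSF_i is the root mean over frames of the
#' squared displacement of residue i's representative atom from its mean
#' position. For an isotropic Gaussian ensemble with per-coordinate scale
#' sigma the expected RMSF is sigma * sqrt(3).
#'
#' @param traj a \linkS4class{TrajectoryEnsemble} with >= 2 frames.
#' @param mask optional \linkS4class{RegionMask}.
#' @param maxIter,tol convergence control for the mean-structure iteration.
#' @return data.frame(residue, rmsf) (Angstrom).
#' @export
rmsfProfile <- function(traj, mask = NULL, maxIter = 100L, tol = 1e-6) {
  if (nFrames(traj) < 2L) stop("need >= 2 frames for fluctuations")
  rc <- .repCoords(traj, mask)
  fit <- .convergedMeanFit(rc$coords, rc$mass, maxIter, tol)
  nf <- dim(fit$fitted)[1]
  dev2 <- matrix(0, nf, dim(fit$fitted)[2])
  for (f in seq_len(nf))
    dev2[f, ] <- rowSums((matrix(fit$fitted[f, , ], ncol = 3L) - fit$mean)^2)
  data.frame(residue = rc$residues, rmsf = sqrt(colMeans(dev2)))
}

#' RMSF difference profile (variant minus wild type)
#'
#' @param variant,wt RMSF profiles over the same residues
#'   (\code{\link{rmsfProfile}} output).
#' @return data.frame(residue, delta) (Angstrom).
#' @export
deltaRmsf <- function(variant, wt) {
  if (!identical(variant$residue, wt$residue))
    stop("alignment error: RMSF profiles cover different residues")
  data.frame(residue = variant$residue, delta = variant$rmsf - wt$rmsf)
}

#' Covariance PCA of a conformational ensemble
#'
#' Frames are superposed on their converged mean; the covariance matrix of
#' the flattened representative-atom coordinates (3 x n residues) is
#' eigendecomposed. Eigenvalues are the modes' spectral weights; their sum
#' equals the total positional variance of the superposed ensemble. Fewer
#' frames than coordinates yields a rank-deficient covariance (allowed;
#' trailing eigenvalues are zero) with a warning.
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param mask optional \linkS4class{RegionMask}.
#' @return a \linkS4class{PCABasis}.
#' @export
covariancePca <- function(traj, mask = NULL) {
  rc <- .repCoords(traj, mask)
  if (any(is.na(rc$coords))) stop("validation error: NaN coordinates")
  nf <- dim(rc$coords)[1]; n <- dim(rc$coords)[2]
  if (nf < 3L * n)
    warning("fewer frames (", nf, ") than coordinates (", 3L * n,
            "); covariance is rank-deficient")
  fit <- .convergedMeanFit(rc$coords, rc$mass)
  X <- matrix(NA_real_, nf, 3L * n)
  for (f in seq_len(nf)) X[f, ] <- as.vector(t(matrix(fit$fitted[f, , ], ncol = 3L)))
  C <- stats::cov(X)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  new("PCABasis", meanCoords = fit$mean, vectors = e$vectors,
      values = vals, residues = rc$residues)
}

#' Spectral weights of the leading principal components
#'
#' @param basis a \linkS4class{PCABasis}.
#' @param n number of modes to report (default 10).
#' @return data.frame(mode, eigenvalue, weight) where weight is the
#'   eigenvalue fraction of the total variance.
#' @export
spectralWeights <- function(basis, n = 10L) {
  stopifnot(is(basis, "PCABasis"))
  n <- min(n, length(basis@values))
  data.frame(mode = seq_len(n), eigenvalue = basis@values[seq_len(n)],
             weight = basis@values[seq_len(n)] / sum(basis@values))
}

#' Project a trajectory onto a reference PC plane
#'
#' Each frame is superposed on the basis mean structure (mapping residues
#' by position, so variants project onto the wild-type basis), centered,
#' and dotted with the first two principal components. Cross-condition
#' comparisons must always use the reference basis, never a re-fitted one.
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param basis the reference \linkS4class{PCABasis}.
#' @param mask optional \linkS4class{RegionMask}; must select the basis
#'   residues.
#' @param label source label stored on the cloud (e.g. "WT", "A301T").
#' @return data.frame(time, pc1, pc2) with attribute \code{label}.
#' @export
projectOntoReference <- function(traj, basis, mask = NULL, label = "") {
  stopifnot(is(basis, "PCABasis"))
  rc <- .repCoords(traj, mask)
  if (length(rc$residues) != length(basis@residues))
    stop("alignment error: selection does not map onto the basis residues")
  nf <- dim(rc$coords)[1]
  mu <- as.vector(t(basis@meanCoords))
  p <- matrix(NA_real_, nf, 2L)
  for (f in seq_len(nf)) {
    fitted <- .kabsch(matrix(rc$coords[f, , ], ncol = 3L),
                      basis@meanCoords, rc$mass)$coords
    x <- as.vector(t(fitted)) - mu
    p[f, ] <- c(sum(x * basis@vectors[, 1]), sum(x * basis@vectors[, 2]))
  }
  structure(data.frame(time = traj@times, pc1 = p[, 1], pc2 = p[, 2]),
            label = label)
}

# convex-polygon containment with tolerance; vertices ordered (chull)
.inConvexHull <- function(pts, hull, tol) {
  nh <- nrow(hull)
  inside <- rep(TRUE, nrow(pts))
  # orientation of the hull polygon
  area2 <- sum(hull[, 1] * hull[c(2:nh, 1), 2] - hull[c(2:nh, 1), 1] * hull[, 2])
  s <- sign(area2)
  for (i in seq_len(nh)) {
    a <- hull[i, ]; b <- hull[if (i == nh) 1L else i + 1L, ]
    cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & (s * cross >= -tol)
  }
  inside
}

#' Fraction of a projection cloud inside a reference basin
#'
#' Default metric: fraction of frames falling inside the convex hull of the
#' reference cloud (parameter-free and deterministic). Alternative:
#' \code{method = "kde"} uses the 95 percent highest-density contour of a
#' 2D kernel density estimate of the reference cloud. The metric used is
#' recorded as attribute \code{method}.
#'
#' @param cloud,referenceCloud data.frames with \code{pc1}, \code{pc2}
#'   columns (\code{\link{projectOntoReference}} output).
#' @param method \code{"hull"} or \code{"kde"}.
#' @param kdeLevel probability mass enclosed by the KDE contour.
#' @return fraction in [0, 1].
#' @export
basinOverlap <- function(cloud, referenceCloud, method = c("hull", "kde"),
                         kdeLevel = 0.95) {
  method <- match.arg(method)
  P <- as.matrix(cloud[, c("pc1", "pc2")])
  R <- as.matrix(referenceCloud[, c("pc1", "pc2")])
  if (!nrow(P) || !nrow(R)) stop("clouds must be non-empty")
  if (method == "hull") {
    if (nrow(unique(R)) < 3L)
      stop("reference cloud needs >= 3 distinct points for a convex hull")
    hull <- R[grDevices::chull(R), , drop = FALSE]
    tol <- 1e-9 * max(1, max(abs(R)))
    frac <- mean(.inConvexHull(P, hull, tol))
  } else {
    scale <- pmax(apply(R, 2L, stats::sd), 1e-12)
    kd <- MASS::kde2d(R[, 1], R[, 2], n = 101,
                      lims = c(range(R[, 1]) + c(-2, 2) * scale[1],
                               range(R[, 2]) + c(-2, 2) * scale[2]))
    # density threshold enclosing kdeLevel of the probability mass
    z <- sort(as.vector(kd$z), decreasing = TRUE)
    cellArea <- diff(kd$x[1:2]) * diff(kd$y[1:2])
    cum <- cumsum(z) * cellArea
    thr <- z[which(cum >= kdeLevel * max(cum))[1]]
    ix <- findInterval(P[, 1], kd$x, all.inside = TRUE)
    iy <- findInterval(P[, 2], kd$y, all.inside = TRUE)
    frac <- mean(kd$z[cbind(ix, iy)] >= thr)
  }
  structure(frac, method = method)
}

#' Pearson correlation between two covariance matrices
#'
#' Correlation over corresponding upper-triangle elements (diagonal
#' included), the scatter-plot comparison of residue-motion covariances
#' between two conditions.
#'
#' @param a,b square covariance matrices of equal dimension.
#' @return Pearson correlation coefficient.
#' @export
covarianceCorrelation <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop("alignment error: covariance matrices differ in dimension")
  ut <- upper.tri(a, diag = TRUE)
  stats::cor(a[ut], b[ut])
}
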