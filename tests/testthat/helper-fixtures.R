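# In-code fixtures shared across test files.

# Minimal hand-built trajectory: coords is an n x 3 matrix (one frame) or a
# frames x atoms x 3 array; residueName decides protein vs lipid grouping.
toyTrajectory <- function(coords, residueSeq, residueName,
                          atomName = NULL, mass = NULL,
                          box = c(100, 100, 100), times = NULL) {
  if (is.matrix(coords)) {
    arr <- array(NA_real_, c(1L, nrow(coords), 3L))
    arr[1, , ] <- coords
    coords <- arr
  }
  n <- dim(coords)[2]
  if (is.null(atomName))
    atomName <- ifelse(toupper(residueName) %in% names(defaultLipidClassMap()),
                       "P", "CA")
  if (is.null(mass)) mass <- rep(12, n)
  top <- systemTopology(atomName = atomName, residueSeq = residueSeq,
                        residueName = residueName, mass = mass)
  nf <- dim(coords)[1]
  if (is.null(times)) times <- seq_len(nf) - 1
  new("TrajectoryEnsemble", coords = coords,
      box = matrix(box, nf, 3L, byrow = TRUE), times = times, topology = top)
}

# Subset a trajectory to the atoms of the given residues (used for the
# mask-then-compute vs compute-on-masked-input property).
subsetTrajectory <- function(traj, residues) {
  a <- atoms(traj)
  idx <- which(a$residueSeq %in% residues)
  top <- systemTopology(atomName = a$atomName[idx],
                        residueSeq = a$residueSeq[idx],
                        residueName = a$residueName[idx],
                        mass = a$mass[idx])
  new("TrajectoryEnsemble",
      coords = traj@coords[, idx, , drop = FALSE],
      box = traj@box, times = traj@times, topology = top)
}

# Brute-force all-pairs per-residue minimal distance oracle (PBC in xy).
oracleResidueMinDist <- function(traj, lipidClass = "any", frames = NULL) {
  a <- atoms(traj)
  pidx <- which(a$group == "protein" & a$mass > 2)
  lidx <- which(a$group == "lipid")
  if (lipidClass != "any") lidx <- lidx[a$lipidClass[lidx] == lipidClass]
  if (is.null(frames)) frames <- seq_len(nFrames(traj))
  res <- sort(unique(a$residueSeq[pidx]))
  out <- matrix(NA_real_, length(frames), length(res),
                dimnames = list(NULL, res))
  mic <- function(d, L) d - L * round(d / L)
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    L <- traj@box[f, ]
    for (ri in seq_along(res)) {
      best <- Inf
      for (p in pidx[a$residueSeq[pidx] == res[ri]]) {
        for (l in lidx) {
          dx <- mic(traj@coords[f, p, 1] - traj@coords[f, l, 1], L[1])
          dy <- mic(traj@coords[f, p, 2] - traj@coords[f, l, 2], L[2])
          dz <- traj@coords[f, p, 3] - traj@coords[f, l, 3]
          best <- min(best, sqrt(dx^2 + dy^2 + dz^2))
        }
      }
      out[fi, ri] <- best
    }
  }
  out
}

# Brute-force MSD oracle: explicit double loop over origins and lags.
oracleMSD <- function(xyList, mode) {
  if (!is.list(xyList)) xyList <- list(xyList)
  n <- nrow(xyList[[1]])
  vapply(0:(n - 1L), function(k) {
    tot <- 0; cnt <- 0L
    for (traj in xyList) {
      origins <- if (mode == "time_averaged") seq_len(n - k) else 1L
      for (o in origins) {
        d <- traj[o + k, ] - traj[o, ]
        tot <- tot + sum(d^2)
        cnt <- cnt + 1L
      }
    }
    tot / cnt
  }, numeric(1))
}

rotationMatrix <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}
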