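# The package's tabular interchange formats.
#
# Trajectory table (TSV): one row per frame with columns
#   time, Lx, Ly, Lz, x_1, y_1, z_1, ..., x_n, y_n, z_n
# (times in ns, lengths in Angstrom). Written at full double precision so
# write -> read round-trips bit-faithfully.

#' Write a trajectory to the tabular interchange format
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param path output TSV path.
#' @export
writeTrajectoryTable <- function(traj, path) {
  stopifnot(is(traj, "TrajectoryEnsemble"))
  nf <- nFrames(traj); na <- nAtoms(traj)
  flat <- matrix(NA_real_, nf, 3L * na)
  for (k in 1:3) flat[, seq(k, 3L * na, by = 3L)] <- traj@coords[, , k]
  dt <- data.table::as.data.table(cbind(traj@times, traj@box, flat))
  names(dt) <- c("time", "Lx", "Ly", "Lz",
                 paste0(rep(c("x_", "y_", "z_"), na),
                        rep(seq_len(na), each = 3L)))
  # serialize at 17 significant digits so doubles round-trip bit-faithfully
  for (j in names(dt))
    data.table::set(dt, j = j, value = sprintf("%.17g", dt[[j]]))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a trajectory table written by \code{\link{writeTrajectoryTable}}
#'
#' @param path TSV path.
#' @param topology the \linkS4class{SystemTopology} the coordinates belong
#'   to; the column count must equal \code{3 * nAtoms + 4}.
#' @return a \linkS4class{TrajectoryEnsemble}.
#' @export
readTrajectoryTable <- function(path, topology) {
  stopifnot(is(topology, "SystemTopology"))
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (nrow(dt) == 0L) stop("no frames in trajectory table '", path, "'")
  na <- nAtoms(topology)
  if (ncol(dt) != 3L * na + 4L)
    stop("parse error: expected ", 3L * na + 4L, " columns for ", na,
         " atoms, found ", ncol(dt))
  bad <- which(!stats::complete.cases(dt))
  if (length(bad)) stop("parse error: incomplete row ", bad[1])
  m <- as.matrix(dt)
  dimnames(m) <- NULL
  nf <- nrow(m)
  coords <- array(NA_real_, c(nf, na, 3L))
  for (k in 1:3) coords[, , k] <- m[, 4L + seq(k, 3L * na, by = 3L), drop = FALSE]
  new("TrajectoryEnsemble", coords = coords,
      box = m[, 2:4, drop = FALSE], times = as.numeric(m[, 1]),
      topology = topology)
}

#' Write a per-residue profile as TSV
#'
#' Columns: \code{residue} then one column per value vector, full double
#' precision. NaN values are serialized literally with a warning.
#'
#' @param profile data.frame whose first column is \code{residue}, or a
#'   named numeric vector indexed by residue number.
#' @param path output TSV path.
#' @export
writeProfileTable <- function(profile, path) {
  if (is.numeric(profile) && !is.null(names(profile)))
    profile <- data.frame(residue = as.integer(names(profile)),
                          value = unname(profile))
  stopifnot(is.data.frame(profile))
  if (names(profile)[1] != "residue")
    stop("profile must be indexed by a leading 'residue' column")
  if (any(vapply(profile, function(x) any(is.nan(x)), logical(1))))
    warning("profile contains NaN values; serialized literally")
  dt <- data.table::as.data.table(profile)
  for (j in names(dt))
    if (is.double(dt[[j]]))
      data.table::set(dt, j = j, value = sprintf("%.17g", dt[[j]]))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Serialize a time series (distance or orientation) to TSV
#'
#' @param series data.frame with a \code{time} column, as returned by
#'   \code{\link{comMembraneDistance}} or \code{\link{orientationAngle}}.
#' @param path output TSV path.
#' @export
writeSeriesTable <- function(series, path) {
  stopifnot(is.data.frame(series), "time" %in% names(series))
  data.table::fwrite(data.table::as.data.table(series), path, sep = "\t")
  invisible(path)
}
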