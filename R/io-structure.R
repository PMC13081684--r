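# Structure readers/writers: multi-model PDB (via bio3d) and GRO.
# Units: coordinates in Angstrom everywhere; GRO nm are converted on read.

.parseCryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(NULL)
  f <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                    substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                    substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
  if (any(is.na(f[1:3]))) stop("parse error: malformed CRYST1 record")
  angles <- f[4:6]
  if (any(!is.na(angles) & abs(angles - 90) > 1e-3))
    stop("unsupported format: triclinic box (only orthorhombic cells are handled)")
  f[1:3]
}

#' Read a structure file into a TrajectoryEnsemble
#'
#' Multi-model PDB files (one frame per MODEL, box from CRYST1) are parsed
#' through \code{bio3d::read.pdb}; GRO files (single frame, nm converted to
#' Angstrom, box from the final box line) are parsed directly. Lipid
#' classes, solvent and ions are inferred from residue names via
#' \code{lipidClassMap}.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"gro"}.
#' @param lipidClassMap residue-name to lipid-class table
#'   (\code{\link{defaultLipidClassMap}}).
#' @param box optional length-3 box override (Angstrom) when the file
#'   carries none.
#' @param dt frame spacing (ns) assigned to PDB models.
#' @return a \linkS4class{TrajectoryEnsemble}.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "gro"),
                          lipidClassMap = defaultLipidClassMap(),
                          box = NULL, dt = 1) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") .readPDBMulti(path, lipidClassMap, box, dt)
  else .readGRO(path, lipidClassMap, box)
}

.readPDBMulti <- function(path, lipidClassMap, box, dt) {
  lines <- readLines(path)
  fileBox <- .parseCryst1(lines)
  if (is.null(fileBox)) {
    if (is.null(box))
      stop("no CRYST1 box in '", path, "' and no box override supplied")
    fileBox <- as.numeric(box)
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("parse error reading PDB: ",
                                           conditionMessage(e)))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  na <- nrow(pdb$atom)
  if (ncol(xyz) != 3L * na)
    stop("structural error: atom count differs between models")
  top <- systemTopology(atomName = trimws(pdb$atom$elety),
                        residueSeq = pdb$atom$resno,
                        residueName = trimws(pdb$atom$resid),
                        element = pdb$atom$elesy,
                        lipidClassMap = lipidClassMap)
  coords <- array(NA_real_, c(nf, na, 3L))
  for (k in 1:3) coords[, , k] <- xyz[, seq(k, 3L * na, by = 3L), drop = FALSE]
  new("TrajectoryEnsemble", coords = coords,
      box = matrix(fileBox, nf, 3L, byrow = TRUE),
      times = seq(0, by = dt, length.out = nf), topology = top)
}

.readGRO <- function(path, lipidClassMap, box) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("parse error: GRO file too short")
  na <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(na)) stop("parse error: bad atom count on GRO line 2")
  if (length(lines) < 3L + na) stop("parse error: truncated GRO file")
  al <- lines[3:(2 + na)]
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resnm <- trimws(substr(al, 6, 10))
  atnm <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("parse error: malformed GRO atom record at line ", 2L + bad[1])
  boxLine <- suppressWarnings(as.numeric(strsplit(trimws(lines[3L + na]),
                                                  "[[:space:]]+")[[1]]))
  if (!length(boxLine) || any(is.na(boxLine))) {
    if (is.null(box)) stop("no box line in '", path, "' and no box override supplied")
    fileBox <- as.numeric(box)
  } else if (length(boxLine) == 3L) {
    fileBox <- boxLine * 10  # nm -> Angstrom
  } else {
    if (any(abs(boxLine[-(1:3)]) > 1e-9))
      stop("unsupported format: triclinic GRO box")
    fileBox <- boxLine[1:3] * 10
  }
  top <- systemTopology(atomName = atnm, residueSeq = resno,
                        residueName = resnm, lipidClassMap = lipidClassMap)
  coords <- array(NA_real_, c(1L, na, 3L))
  coords[1, , 1] <- x * 10; coords[1, , 2] <- y * 10; coords[1, , 3] <- z * 10
  new("TrajectoryEnsemble", coords = coords,
      box = matrix(fileBox, 1L, 3L), times = 0, topology = top)
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL block per frame, CRYST1 from the first frame's box. Protein
#' atoms go to chain A, lipids to chain L. Coordinates are written at PDB
#' precision (0.001 Angstrom).
#'
#' @param traj a \linkS4class{TrajectoryEnsemble}.
#' @param path output file.
#' @export
writeMultiModelPDB <- function(traj, path) {
  stopifnot(is(traj, "TrajectoryEnsemble"))
  a <- atoms(traj)
  chain <- ifelse(a$group == "protein", "A",
                  ifelse(a$group == "lipid", "L", "S"))
  elem <- toupper(substr(gsub("^[0-9]+", "", a$atomName), 1, 1))
  con <- file(path, "w")
  on.exit(close(con))
  b <- traj@box[1, ]
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                     b[1], b[2], b[3]), con)
  serial <- (seq_len(nrow(a)) - 1L) %% 99999L + 1L
  resno <- a$residueSeq %% 10000L
  for (f in seq_len(nFrames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frameCoords(traj, f)
    # name cols 13-16, resName 18-21 (4-char lipid names), chain 22,
    # resSeq 23-26, x/y/z 31-54, element 77-78
    writeLines(sprintf("ATOM  %5d %-4s %-4s%s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       serial, substr(a$atomName, 1, 4),
                       substr(a$residueName, 1, 4), chain, resno,
                       xyz[, 1], xyz[, 2], xyz[, 3], elem), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
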