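# Topology construction, lipid-class mapping, region masks, variant parsing.

#' Default mapping from residue names to lipid classes
#'
#' Both phosphoinositide species of the standard bilayer composition,
#' PI(2,5)P and PI(2,4)P, map to the single class \code{POPI}: contact
#' analyses stratify by the three classes POPC, POPS and POPI only. The
#' mapping is user-editable: pass a modified copy to the readers.
#'
#' @return named character vector: residue name -> lipid class.
#' @export
defaultLipidClassMap <- function() {
  c(POPC = "POPC", POPS = "POPS", POPI = "POPI",
    PI25 = "POPI", PI24 = "POPI", POP2 = "POPI", POP5 = "POPI")
}

SOLVENT_RESNAMES <- c("SOL", "TIP3", "HOH", "WAT", "TIP4")
ION_RESNAMES <- c("NA", "CL", "SOD", "CLA", "K", "POT", "MG", "CA2")

# Standard atomic masses for the elements that occur in protein/lipid
# systems; unknown elements fall back to carbon with a warning upstream.
ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, NA. = 22.990, CL = 35.45,
                    K = 39.098, MG = 24.305, CA = 40.078, FE = 55.845)

.massFromElement <- function(elesy, atomName) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  # fall back to the first alphabetic character of the atom name
  el[miss] <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                  gsub("^[0-9]+", "", atomName[miss])), 1, 1))
  el[el == "NA"] <- "NA."
  m <- ELEMENT_MASSES[el]
  unknown <- is.na(m)
  if (any(unknown)) {
    warning(sum(unknown), " atoms with unrecognized element; assigning carbon mass")
    m[unknown] <- ELEMENT_MASSES[["C"]]
  }
  unname(m)
}

.classifyResidue <- function(residueName, lipidClassMap) {
  rn <- toupper(trimws(residueName))
  group <- rep("protein", length(rn))
  lipidClass <- rep("none", length(rn))
  isLip <- rn %in% names(lipidClassMap)
  group[isLip] <- "lipid"
  lipidClass[isLip] <- unname(lipidClassMap[rn[isLip]])
  group[rn %in% SOLVENT_RESNAMES] <- "solvent"
  group[rn %in% ION_RESNAMES] <- "ion"
  list(group = group, lipidClass = lipidClass)
}

#' Build a SystemTopology from per-atom vectors
#'
#' @param atomName character atom names.
#' @param residueSeq integer author residue numbers.
#' @param residueName character residue names; lipid classes and
#'   solvent/ion groups are inferred from these via \code{lipidClassMap}.
#' @param mass atomic masses (amu); if \code{NULL}, inferred from
#'   \code{element} / atom names.
#' @param element optional element symbols used for mass inference.
#' @param lipidClassMap residue-name to lipid-class mapping table.
#' @return a \linkS4class{SystemTopology}.
#' @export
systemTopology <- function(atomName, residueSeq, residueName, mass = NULL,
                           element = NULL,
                           lipidClassMap = defaultLipidClassMap()) {
  n <- length(atomName)
  stopifnot(length(residueSeq) == n, length(residueName) == n)
  if (is.null(mass)) {
    if (is.null(element)) element <- rep("", n)
    mass <- .massFromElement(element, atomName)
  }
  cls <- .classifyResidue(residueName, lipidClassMap)
  atomsDf <- data.frame(atomIndex = seq_len(n),
                        atomName = as.character(atomName),
                        residueSeq = as.integer(residueSeq),
                        residueName = as.character(residueName),
                        mass = as.numeric(mass),
                        group = cls$group,
                        lipidClass = cls$lipidClass,
                        stringsAsFactors = FALSE)
  # residues are identified by (group, residueSeq); split on the raw
  # residueSeq because protein and lipid numbering never overlap here
  ridx <- split(seq_len(n), atomsDf$residueSeq)
  new("SystemTopology", atoms = atomsDf, residueIndex = ridx)
}

#' Atom index selections
#'
#' \code{proteinAtomIndices} selects protein atoms, optionally restricted to
#' a \linkS4class{RegionMask} and to heavy atoms (hydrogens excluded, the
#' default for center-of-mass and distance work). \code{lipidAtomIndices}
#' selects lipid atoms of one class or of any class.
#' \code{repAtomIndices} returns one representative atom per protein residue
#' (the C-alpha where present, else the residue's first atom), the reduction
#' used by RMSF and PCA.
#'
#' @param top a \linkS4class{SystemTopology} (or trajectory).
#' @param mask optional \linkS4class{RegionMask}.
#' @param heavyOnly drop hydrogens (mass < 2 amu)?
#' @return integer atom indices.
#' @export
proteinAtomIndices <- function(top, mask = NULL, heavyOnly = TRUE) {
  a <- atoms(top)
  keep <- a$group == "protein"
  if (heavyOnly) keep <- keep & a$mass > 2
  if (!is.null(mask)) {
    stopifnot(is(mask, "RegionMask"))
    keep <- keep & a$residueSeq %in% mask@residues
  }
  idx <- which(keep)
  if (!length(idx)) stop("selection error: no protein atoms selected")
  idx
}

#' @rdname proteinAtomIndices
#' @param lipidClass \code{"any"}, \code{"POPC"}, \code{"POPS"} or \code{"POPI"}.
#' @export
lipidAtomIndices <- function(top, lipidClass = "any") {
  a <- atoms(top)
  keep <- a$group == "lipid"
  if (!identical(lipidClass, "any")) {
    lipidClass <- match.arg(lipidClass, LIPID_CLASSES)
    keep <- keep & a$lipidClass == lipidClass
  }
  idx <- which(keep)
  if (!length(idx))
    stop("selection error: no lipid atoms of class '", lipidClass, "'")
  idx
}

#' @rdname proteinAtomIndices
#' @export
repAtomIndices <- function(top, mask = NULL) {
  a <- atoms(top)
  keep <- a$group == "protein"
  if (!is.null(mask)) keep <- keep & a$residueSeq %in% mask@residues
  a <- a[keep, , drop = FALSE]
  if (!nrow(a)) stop("selection error: no protein atoms selected")
  pick <- function(d) if (any(d$atomName == "CA")) d$atomIndex[d$atomName == "CA"][1] else d$atomIndex[1]
  idx <- vapply(split(a, a$residueSeq), pick, integer(1))
  res <- as.integer(names(idx))
  ord <- order(res)
  structure(unname(idx[ord]), residues = res[ord])
}

#' Create a region mask
#'
#' @param name mask label.
#' @param residues integer residue numbers to include.
#' @param top optional topology; when given, residues are validated as a
#'   subset of its protein residues.
#' @return a \linkS4class{RegionMask}.
#' @export
regionMask <- function(name, residues, top = NULL) {
  residues <- sort(unique(as.integer(residues)))
  if (!is.null(top)) {
    pres <- proteinResidues(top)
    if (!all(residues %in% pres))
      stop("mask residues outside the topology's protein residues: ",
           paste(setdiff(residues, pres), collapse = ", "))
  }
  new("RegionMask", name = name, residues = residues)
}

#' The three canonical region masks of the C2 construct
#'
#' Full domain; domain excluding the N- and C-terminal residues (253--260
#' and 405--413); and additionally excluding the large flexible loop
#' (residues 370--395). Masks are intersected with the residues actually
#' present in the topology.
#'
#' @param top a \linkS4class{SystemTopology} or trajectory.
#' @param termini residue numbers treated as termini.
#' @param loop residue numbers of the large loop.
#' @return named list of three \linkS4class{RegionMask} objects:
#'   \code{full}, \code{no_termini}, \code{no_termini_loop}.
#' @export
canonicalMasks <- function(top, termini = c(253:260, 405:413),
                           loop = 370:395) {
  pres <- proteinResidues(top)
  list(full = regionMask("full", pres),
       no_termini = regionMask("no_termini", setdiff(pres, termini)),
       no_termini_loop = regionMask("no_termini_loop",
                                    setdiff(pres, c(termini, loop))))
}

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Parse a missense variant string such as "A301T"
#'
#' @param spec substitution string \code{<wt><position><mut>} in one-letter
#'   amino-acid code.
#' @param severity clinical severity label.
#' @param range allowed position range (the C2 construct spans 253--413).
#' @return a \linkS4class{VariantRecord}.
#' @export
parseVariant <- function(spec, severity = "unknown", range = c(253L, 413L)) {
  severity <- match.arg(severity, VARIANT_SEVERITIES)
  m <- regmatches(spec, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", spec))[[1]]
  if (length(m) != 4L)
    stop("parse error: variant must match <AA><position><AA>, got '", spec, "'")
  wt <- toupper(m[2]); mut <- toupper(m[4]); pos <- as.integer(m[3])
  if (!(wt %in% AA1) || !(mut %in% AA1))
    stop("parse error: unknown amino-acid letter in '", spec, "'")
  if (wt == mut)
    stop("validation error: wild-type and mutant amino acids are identical")
  if (pos < range[1] || pos > range[2])
    stop("domain-range error: position ", pos, " outside [",
         range[1], ", ", range[2], "]")
  new("VariantRecord", wtAA = wt, position = pos, mutAA = mut,
      severity = severity)
}
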