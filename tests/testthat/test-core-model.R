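# Domain types, structure/table I/O, masks and variant parsing.

test_that("multi-model PDB reading counts frames and atoms and keeps geometry", {
  pdb <- tempfile(fileext = ".pdb")
  mk <- function(z) sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    1:5, 301:305, c(0, 3, 6, 9, 12), 0, z)
  writeLines(c("CRYST1   40.000   40.000   40.000  90.00  90.00  90.00 P 1",
               unlist(lapply(c(0, 1, 2), function(z)
                 c(sprintf("MODEL  %6d", z + 1), mk(rep(z, 5)), "ENDMDL"))),
               "END"), pdb)
  tr <- readStructure(pdb)
  expect_equal(nFrames(tr), 3L)
  expect_equal(nAtoms(tr), 5L)
  expect_equal(tr@box[1, ], c(40, 40, 40))
  # 2-atom geometry: distance between first two atoms is 3 A
  xyz <- frameCoords(tr, 1)
  expect_equal(sqrt(sum((xyz[1, ] - xyz[2, ])^2)), 3)
})

test_that("a GRO file without protein is read fine; selection fails downstream", {
  gro <- tempfile(fileext = ".gro")
  writeLines(c("lipid-only box",
               "    2",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "POPC", "P", 1L,
                       1.0, 1.0, 1.75),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 2L, "POPS", "P", 2L,
                       2.0, 2.0, -1.75),
               "   4.00000   4.00000   8.00000"), gro)
  tr <- readStructure(gro)
  expect_equal(nAtoms(tr), 2L)
  expect_equal(tr@box[1, ], c(40, 40, 80))           # nm converted to A
  expect_equal(unname(frameCoords(tr, 1)[1, 3]), 17.5)
  expect_equal(atoms(tr)$lipidClass, c("POPC", "POPS"))
  expect_error(proteinAtomIndices(topology(tr)), "selection error")
})

test_that("PDB write/read round-trip is coordinate-faithful to PDB precision", {
  set.seed(11)
  tr <- makeBindingTrajectory("top", nFrames = 4L, approachFrames = 1L,
                              plantedD = 5, seed = 3)
  pdb <- tempfile(fileext = ".pdb")
  writeMultiModelPDB(tr, pdb)
  back <- readStructure(pdb)
  expect_equal(nFrames(back), 4L)
  expect_equal(nAtoms(back), nAtoms(tr))
  expect_equal(back@coords, tr@coords, tolerance = 1e-3)
  expect_lt(max(abs(back@coords - tr@coords)), 5.1e-4)  # 0.001 A rounding
  expect_equal(atoms(back)$group, atoms(tr)$group)
  expect_equal(atoms(back)$lipidClass, atoms(tr)$lipidClass)
})

test_that("trajectory table round-trips bit-faithfully and validates input", {
  tr <- makeGaussianEnsemble(matrix(rnorm(30), 10), sigma = 0.7,
                             nFrames = 10L, seed = 5)
  tsv <- tempfile(fileext = ".tsv")
  writeTrajectoryTable(tr, tsv)
  back <- readTrajectoryTable(tsv, topology(tr))
  expect_identical(back@coords, tr@coords)
  expect_identical(back@times, tr@times)
  expect_identical(back@box, tr@box)

  empty <- tempfile(fileext = ".tsv")
  writeLines(readLines(tsv)[1], empty)                 # header only
  expect_error(readTrajectoryTable(empty, topology(tr)), "no frames")

  # non-monotone times violate the ensemble invariant
  lines <- readLines(tsv)
  swapped <- lines[c(1, 3, 2, 4:length(lines))]
  bad <- tempfile(fileext = ".tsv")
  writeLines(swapped, bad)
  expect_error(readTrajectoryTable(bad, topology(tr)), "increasing")

  # wrong column count for the topology
  wrongTop <- systemTopology(rep("CA", 4), 1:4, rep("ALA", 4),
                             mass = rep(12, 4))
  expect_error(readTrajectoryTable(tsv, wrongTop), "columns")
})

test_that("variant parsing accepts the studied variants and enforces the domain range", {
  v <- parseVariant("A301T", severity = "VUS")
  expect_s4_class(v, "VariantRecord")
  expect_equal(v@wtAA, "A"); expect_equal(v@position, 301L)
  expect_equal(v@mutAA, "T"); expect_equal(v@severity, "VUS")
  g <- parseVariant("G344S")
  expect_equal(c(g@wtAA, g@mutAA), c("G", "S"))
  expect_equal(g@position, 344L)
  # every variant studied alongside the WT parses cleanly
  for (s in c("A271D", "C282R", "L323P", "A301T", "R335H", "G344S"))
    expect_s4_class(parseVariant(s), "VariantRecord")
  expect_error(parseVariant("A200T"), "domain-range")
  expect_error(parseVariant("A500T"), "domain-range")
  expect_error(parseVariant("A301A"), "identical")
  expect_error(parseVariant("B301T"), "unknown amino-acid")
  expect_error(parseVariant("301T"), "parse error")
})

test_that("profile tables serialize one row per residue, NaN with a warning", {
  prof <- data.frame(residue = 253:413, rmsf = runif(161))
  tsv <- tempfile(fileext = ".tsv")
  writeProfileTable(prof, tsv)
  expect_equal(length(readLines(tsv)), 162L)           # header + 161 rows
  back <- read.delim(tsv)
  expect_identical(back$rmsf, prof$rmsf)               # full precision

  writeProfileTable(prof[0, ], tsv)
  expect_equal(length(readLines(tsv)), 1L)             # header-only

  prof$rmsf[5] <- NaN
  expect_warning(writeProfileTable(prof, tsv), "NaN")
})

test_that("canonical region masks exclude termini and the large loop", {
  tr <- makeBindingTrajectory("top", nFrames = 60L, approachFrames = 10L,
                              seed = 1)
  masks <- canonicalMasks(topology(tr))
  expect_equal(length(masks$full@residues), 161L)
  expect_equal(length(masks$no_termini@residues), 161L - 8L - 9L)
  expect_equal(length(masks$no_termini_loop@residues), 144L - 26L)
  expect_false(any(c(253:260, 405:413) %in% masks$no_termini@residues))
  expect_false(any(370:395 %in% masks$no_termini_loop@residues))
  expect_error(regionMask("bad", 999, topology(tr)), "outside")
})

test_that("topology invariants reject bad masses and inconsistent lipid classes", {
  expect_error(systemTopology("CA", 1L, "ALA", mass = -1), "mass")
  top <- systemTopology(c("CA", "P"), 1:2, c("ALA", "POPC"),
                        mass = c(12, 95))
  expect_equal(atoms(top)$group, c("protein", "lipid"))
  expect_equal(atoms(top)$lipidClass, c("none", "POPC"))
  # POPI species collapse to class POPI
  top2 <- systemTopology(c("P", "P"), 1:2, c("PI25", "PI24"), mass = c(95, 95))
  expect_equal(atoms(top2)$lipidClass, c("POPI", "POPI"))
})
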