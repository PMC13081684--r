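# Synthetic ground-truth generators.
#
# These emulate the statistical structure the analyses assume: free or
# bounded 2D Brownian motion with a planted diffusivity, a coarse two-leaflet
# bilayer of single-bead pseudo-lipids with the standard 90/17/3/3
# (POPC/POPS/PI(2,5)P/PI(2,4)P) per-leaflet composition, scripted
# approach-and-binding trajectories of a bead-per-residue pseudo-protein in
# a planted top or side orientation, and Gaussian conformational ensembles
# with per-residue fluctuation amplitudes.

#' Deterministic child-seed spawning
#'
#' One root seed drives every generator; per-trajectory child generators are
#' seeded as \code{(seed * 48271 + index * 104729) mod (2^31 - 1)}, so
#' changing the number of trajectories never reshuffles earlier ones.
#'
#' @param seed root seed (integer).
#' @param index child index (0, 1, 2, ...).
#' @return integer child seed in [1, 2^31 - 2].
#' @export
spawnSeed <- function(seed, index) {
  m <- 2147483647
  as.integer((((as.numeric(seed) %% m) * 48271) %% m +
                (as.numeric(index) * 104729) %% m) %% m + 1) %% m
}

#' Generate 2D Brownian trajectories with a planted diffusion coefficient
#'
#' Increments are i.i.d. Gaussian per axis with variance \code{2 * D * dt},
#' the discrete realization of free lateral diffusion at coefficient D.
#' Optionally the positions are wrapped into a periodic square box
#' (\code{boxXY}) or confined to a reflecting disc
#' (\code{confinementRadius}); the two boundary models are mutually
#' exclusive. Both wrapped and unwrapped coordinates are returned.
#'
#' @param D planted diffusion coefficient (Angstrom^2/ns), >= 0.
#' @param nSteps number of positions per trajectory (>= 2).
#' @param dt time step (ns), > 0.
#' @param nTraj number of independent trajectories.
#' @param boxXY optional periodic box edge (Angstrom).
#' @param confinementRadius optional reflecting-disc radius (Angstrom).
#' @param seed root seed.
#' @return list with \code{times} (ns), \code{unwrapped} and \code{wrapped}:
#'   lists of \code{nSteps x 2} matrices, and the parameters under
#'   \code{params}.
#' @export
makeBrownian2D <- function(D, nSteps, dt, nTraj = 1L, boxXY = NULL,
                           confinementRadius = NULL, seed = 1L) {
  if (D < 0) stop("D must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  if (nSteps < 2) stop("nSteps must be >= 2")
  if (!is.null(boxXY) && !is.null(confinementRadius))
    stop("configuration error: choose either a periodic box or a reflecting disc, not both")
  sd1 <- sqrt(2 * D * dt)
  unwrapped <- vector("list", nTraj)
  wrapped <- vector("list", nTraj)
  for (j in seq_len(nTraj)) {
    set.seed(spawnSeed(seed, j - 1L))
    steps <- matrix(stats::rnorm(2L * (nSteps - 1L), sd = sd1),
                    ncol = 2L)
    if (is.null(confinementRadius)) {
      pos <- rbind(c(0, 0), apply(steps, 2L, cumsum))
    } else {
      pos <- matrix(0, nSteps, 2L)
      for (i in 2:nSteps) {
        p <- pos[i - 1L, ] + steps[i - 1L, ]
        r <- sqrt(sum(p^2))
        if (r > confinementRadius) p <- p * (2 * confinementRadius - r) / r
        pos[i, ] <- p
      }
    }
    unwrapped[[j]] <- pos
    wrapped[[j]] <- if (is.null(boxXY)) pos else pos %% boxXY
  }
  list(times = (seq_len(nSteps) - 1L) * dt, unwrapped = unwrapped,
       wrapped = wrapped,
       params = list(D = D, nSteps = nSteps, dt = dt, nTraj = nTraj,
                     boxXY = boxXY, confinementRadius = confinementRadius,
                     seed = seed))
}

DEFAULT_LEAFLET_COUNTS <- c(POPC = 90L, POPS = 17L, POPI25P = 3L, POPI24P = 3L)

# residue names carried by the pseudo-lipids; POPI species collapse to
# class POPI through the default lipid-class map
.LIPID_RESNAME <- c(POPC = "POPC", POPS = "POPS", POPI25P = "PI25",
                    POPI24P = "PI24")

#' Build a coarse bilayer fixture of single-bead pseudo-lipids
#'
#' Two leaflets of headgroup beads on a jittered square lattice centered on
#' z = +/- leafletSpacing/2. Per-leaflet class counts default to the
#' standard composition 90 POPC / 17 POPS / 3 PI(2,5)P / 3 PI(2,4)P.
#' Classes are assigned to lattice sites in a seeded random order; when
#' \code{popiPatchCenter} is given, the phosphoinositide species are instead
#' placed on the sites nearest that xy point, creating a POPI-enriched
#' patch.
#'
#' @param counts named integer vector of per-leaflet lipid counts.
#' @param leafletSpacing distance between leaflet planes (Angstrom).
#' @param gridSpacing lateral lattice constant (Angstrom).
#' @param jitterSigma Gaussian positional jitter of the beads (Angstrom).
#' @param boxXY optional lateral box edge; must fit all beads on the
#'   lattice, otherwise a layout error is raised. Default: smallest square
#'   lattice that holds the counts.
#' @param boxZ box height (Angstrom).
#' @param popiPatchCenter optional xy center of a POPI patch.
#' @param seed root seed.
#' @return single-frame \linkS4class{TrajectoryEnsemble} of lipid beads.
#' @export
makeMembraneFixture <- function(counts = DEFAULT_LEAFLET_COUNTS,
                                leafletSpacing = 35, gridSpacing = 8,
                                jitterSigma = 0.5, boxXY = NULL, boxZ = 150,
                                popiPatchCenter = NULL, seed = 1L) {
  counts <- counts[counts > 0]
  if (any(counts < 0)) stop("lipid counts must be >= 0")
  nPerLeaflet <- sum(counts)
  side <- ceiling(sqrt(max(nPerLeaflet, 1L)))
  if (is.null(boxXY)) {
    boxXY <- side * gridSpacing
  } else {
    side <- floor(boxXY / gridSpacing)
    if (side * side < nPerLeaflet)
      stop("layout error: lateral grid (", side, "x", side,
           " sites) too small for ", nPerLeaflet, " lipids per leaflet")
  }
  if (nPerLeaflet == 0L) {
    # empty membrane: keep a single far-away dummy? No -- topologies must be
    # non-empty, so an empty membrane is represented by zero lipid atoms and
    # is only meaningful combined with a protein; return NULL marker.
    return(NULL)
  }
  sites <- as.matrix(expand.grid(x = (seq_len(side) - 0.5) * gridSpacing,
                                 y = (seq_len(side) - 0.5) * gridSpacing))
  species <- rep(names(counts), counts)
  coordsList <- list(); resnmList <- list()
  set.seed(spawnSeed(seed, 0L))
  for (leaf in 1:2) {
    z0 <- if (leaf == 1) leafletSpacing / 2 else -leafletSpacing / 2
    pick <- sample.int(nrow(sites), nPerLeaflet)
    sxy <- sites[pick, , drop = FALSE]
    ord <- sample.int(nPerLeaflet)  # which species sits on which site
    assigned <- character(nPerLeaflet)
    if (is.null(popiPatchCenter)) {
      assigned <- species[ord]
    } else {
      isPI <- grepl("^POPI", species)
      d2 <- (sxy[, 1] - popiPatchCenter[1])^2 + (sxy[, 2] - popiPatchCenter[2])^2
      nearest <- order(d2)
      assigned[nearest[seq_len(sum(isPI))]] <- sample(species[isPI])
      assigned[nearest[-seq_len(sum(isPI))]] <- sample(species[!isPI])
    }
    jit <- matrix(stats::rnorm(3L * nPerLeaflet, sd = jitterSigma), ncol = 3L)
    coordsList[[leaf]] <- cbind(sxy[, 1] + jit[, 1], sxy[, 2] + jit[, 2],
                                z0 + jit[, 3])
    resnmList[[leaf]] <- .LIPID_RESNAME[assigned]
  }
  xyz <- do.call(rbind, coordsList)
  resnm <- unname(do.call(c, resnmList))
  n <- nrow(xyz)
  top <- systemTopology(atomName = rep("P", n),
                        residueSeq = 1000L + seq_len(n),
                        residueName = resnm,
                        mass = rep(94.97, n))  # PO4 headgroup bead
  coords <- array(NA_real_, c(1L, n, 3L)); coords[1, , ] <- xyz
  new("TrajectoryEnsemble", coords = coords,
      box = matrix(c(boxXY, boxXY, boxZ), 1L, 3L), times = 0, topology = top)
}

#' Bead-per-residue pseudo-protein body
#'
#' An elongated rigid body (length ~40 Angstrom) standing in for the C2
#' domain: one bead per residue 253--413 arranged around a long axis. Two
#' designated residue sets realize the planted binding interfaces: the
#' \code{topContact} residues form a tip at the low-axis end (the
#' beta-sandwich tip loops of the top mode), and the \code{sideContact}
#' residues form a protruding lateral band (the side-mode face). The exact
#' residue lists are fixture configuration, not biology claims.
#'
#' @param residues residue numbers (default 253:413).
#' @param topContact residues placed at the body tip.
#' @param sideContact residues placed on the protruding lateral band.
#' @param bodyLength axis length (Angstrom).
#' @param radius body radius (Angstrom).
#' @param bandRadius radius of the side band (must exceed \code{radius} so
#'   the band is the closest face when lying sideways).
#' @return n x 3 matrix of body-frame coordinates (axis along +z, tip at
#'   z = 0), with attributes \code{residues}, \code{topContact},
#'   \code{sideContact}.
#' @export
buildPseudoProtein <- function(residues = 253:413, topContact = 368:380,
                               sideContact = 296:322, bodyLength = 40,
                               radius = 6, bandRadius = 7.5) {
  stopifnot(all(topContact %in% residues), all(sideContact %in% residues),
            bandRadius > radius)
  n <- length(residues)
  isTip <- residues %in% topContact
  isBand <- residues %in% sideContact
  a <- numeric(n)
  a[isTip] <- seq(0, 1.5, length.out = sum(isTip))
  a[!isTip] <- seq(6, bodyLength, length.out = sum(!isTip))
  phi <- 2 * pi * ((seq_len(n) * 0.381966) %% 1)
  # keep the downward face (phi = -pi/2 when lying sideways) clear of
  # ordinary beads so the band is unambiguously closest in side mode
  down <- -pi / 2
  d <- atan2(sin(phi - down), cos(phi - down))
  shift <- abs(d) < 0.5
  phi[shift] <- phi[shift] + sign(d[shift] + 1e-9) * (1 - abs(d[shift]))
  phi[isBand] <- down + seq(-0.25, 0.25, length.out = sum(isBand))
  r <- ifelse(isBand, bandRadius, radius)
  xyz <- cbind(r * cos(phi), r * sin(phi), a)
  structure(xyz, residues = as.integer(residues),
            topContact = as.integer(topContact),
            sideContact = as.integer(sideContact))
}

#' Scripted approach-and-binding trajectory with planted ground truth
#'
#' The pseudo-protein starts with a minimum membrane distance of
#' \code{startGap} (>= 12 Angstrom, the unbound initial condition), descends
#' linearly during \code{approachFrames}, then remains bound at
#' \code{boundGap} in the planted orientation: \code{"top"} puts the body
#' axis normal to the membrane with the tip-contact residues closest,
#' \code{"side"} lays the axis in the membrane plane with the lateral band
#' closest. Throughout, the in-plane center of mass performs 2D Brownian
#' motion with diffusivity \code{plantedD} (wrapped into the lateral box;
#' the molecule is kept whole), and every protein bead receives isotropic
#' Gaussian jitter of scale \code{jitterSigma} per frame. The membrane beads
#' are static.
#'
#' @param mode planted binding mode: \code{"top"}, \code{"side"} or
#'   \code{"none"} (hovering, never binds; requires
#'   \code{approachFrames = 0}).
#' @param nFrames total frames (must exceed \code{approachFrames}).
#' @param approachFrames frames spent descending (>= 1 for binding modes).
#' @param plantedD planted lateral diffusivity (Angstrom^2/ns).
#' @param jitterSigma per-coordinate bead jitter (Angstrom).
#' @param boundGap bound minimum vertical gap to the upper leaflet plane
#'   (Angstrom).
#' @param startGap initial minimum gap (Angstrom, >= 12).
#' @param dt frame spacing (ns).
#' @param seed root seed.
#' @param membrane optional pre-built membrane fixture
#'   (\code{\link{makeMembraneFixture}} output); built with
#'   \code{spawnSeed(seed, 0)} otherwise.
#' @param body optional pseudo-protein body
#'   (\code{\link{buildPseudoProtein}} output).
#' @return a \linkS4class{TrajectoryEnsemble} (protein + lipid beads) with
#'   attribute \code{groundTruth}: list(mode, plantedD, bindingFrame,
#'   contactSet).
#' @export
makeBindingTrajectory <- function(mode = c("top", "side", "none"),
                                  nFrames = 200L, approachFrames = 50L,
                                  plantedD = 22, jitterSigma = 1,
                                  boundGap = 1.5, startGap = 15, dt = 1,
                                  seed = 1L, membrane = NULL, body = NULL) {
  mode <- match.arg(mode)
  if (mode == "none" && approachFrames >= 1L)
    stop("configuration error: mode 'none' cannot script an approach; set approachFrames = 0")
  if (mode != "none" && (approachFrames < 1L || nFrames <= approachFrames))
    stop("need nFrames > approachFrames >= 1")
  if (startGap < 12)
    stop("startGap must be >= 12 Angstrom (unbound initial condition)")
  if (is.null(membrane))
    membrane <- makeMembraneFixture(seed = spawnSeed(seed, 0L))
  if (is.null(membrane)) stop("empty membrane fixture")
  if (is.null(body)) body <- buildPseudoProtein()
  residues <- attr(body, "residues")
  np <- nrow(body); box <- membrane@box[1, ]

  # orient the rigid body: rows of `oriented` are world offsets from the
  # body anchor before centering
  oriented <- switch(mode,
    top = body,                                   # axis +z, tip (z=0) lowest
    side = cbind(body[, 3], body[, 1], body[, 2]),# axis -> x, band face down
    none = body)
  center <- colMeans(oriented)
  offsets <- sweep(oriented, 2L, center)

  lipXYZ <- frameCoords(membrane, 1L)
  leafletTop <- max(lipXYZ[, 3])
  zmin <- min(offsets[, 3])
  zBound <- leafletTop + boundGap - zmin   # COM height when bound
  zStart <- leafletTop + startGap - zmin

  # in-plane COM path: one Brownian trajectory at the planted diffusivity
  bm <- makeBrownian2D(D = plantedD, nSteps = nFrames, dt = dt,
                       nTraj = 1L, seed = spawnSeed(seed, 1L))
  comXY <- sweep(bm$unwrapped[[1]], 2L, c(box[1] / 2, box[2] / 2), "+")
  comXY <- comXY %% box[1:2][col(comXY)]  # wrapped COM, molecule kept whole

  zCom <- rep(zBound, nFrames)
  if (mode == "none") {
    zCom[] <- zStart
  } else if (approachFrames >= 1L) {
    # square-root descent: fast initial drop, slow final approach, so the
    # contact cutoff is crossed close to the scripted binding frame
    f <- seq_len(approachFrames) - 1L
    zCom[seq_len(approachFrames)] <-
      zBound + (zStart - zBound) * sqrt(1 - f / approachFrames)
  }

  set.seed(spawnSeed(seed, 2L))
  na <- np + nAtoms(membrane)
  coords <- array(NA_real_, c(nFrames, na, 3L))
  for (f in seq_len(nFrames)) {
    prot <- offsets
    prot[, 1] <- prot[, 1] + comXY[f, 1]
    prot[, 2] <- prot[, 2] + comXY[f, 2]
    prot[, 3] <- prot[, 3] + zCom[f]
    prot <- prot + matrix(stats::rnorm(3L * np, sd = jitterSigma), ncol = 3L)
    coords[f, seq_len(np), ] <- prot
    coords[f, np + seq_len(nAtoms(membrane)), ] <- lipXYZ
  }

  protTop <- systemTopology(atomName = rep("CA", np),
                            residueSeq = residues,
                            residueName = rep("ALA", np),
                            mass = rep(110, np))  # mean residue mass
  topAll <- systemTopology(
    atomName = c(protTop@atoms$atomName, membrane@topology@atoms$atomName),
    residueSeq = c(protTop@atoms$residueSeq, membrane@topology@atoms$residueSeq),
    residueName = c(protTop@atoms$residueName, membrane@topology@atoms$residueName),
    mass = c(protTop@atoms$mass, membrane@topology@atoms$mass))

  traj <- new("TrajectoryEnsemble", coords = coords,
              box = matrix(box, nFrames, 3L, byrow = TRUE),
              times = (seq_len(nFrames) - 1L) * dt, topology = topAll)
  attr(traj, "groundTruth") <- list(
    mode = mode, plantedD = plantedD,
    bindingFrame = if (mode == "none") NA_integer_ else approachFrames + 1L,
    contactSet = switch(mode, top = attr(body, "topContact"),
                        side = attr(body, "sideContact"), none = integer()))
  traj
}

#' Gaussian conformational ensemble around a reference structure
#'
#' Every frame is the reference plus isotropic Gaussian displacements with
#' per-coordinate standard deviation sigma_i for residue i. No rigid-body
#' motion is added, so the planted per-residue RMSF is sigma_i * sqrt(3).
#'
#' @param reference n x 3 coordinate matrix (one bead/atom per residue) or a
#'   single-frame \linkS4class{TrajectoryEnsemble}.
#' @param sigma per-residue displacement scale (Angstrom); length 1 or
#'   n residues.
#' @param nFrames frames to generate.
#' @param seed root seed.
#' @param dt frame spacing (ns).
#' @param residues residue numbers when \code{reference} is a bare matrix.
#' @return a \linkS4class{TrajectoryEnsemble} of protein beads.
#' @export
makeGaussianEnsemble <- function(reference, sigma, nFrames, seed = 1L,
                                 dt = 1, residues = NULL) {
  if (is(reference, "TrajectoryEnsemble")) {
    idx <- repAtomIndices(reference@topology)
    residues <- attr(idx, "residues")
    ref <- frameCoords(reference, 1L)[idx, , drop = FALSE]
    box <- reference@box[1, ]
  } else {
    ref <- as.matrix(reference)
    if (is.null(residues)) residues <- seq_len(nrow(ref)) + 252L
    box <- c(500, 500, 500)
  }
  n <- nrow(ref)
  if (length(sigma) == 1L) sigma <- rep(sigma, n)
  if (length(sigma) != n)
    stop("validation error: sigma length (", length(sigma),
         ") does not match residue count (", n, ")")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  set.seed(spawnSeed(seed, 0L))
  coords <- array(NA_real_, c(nFrames, n, 3L))
  for (f in seq_len(nFrames)) {
    disp <- matrix(stats::rnorm(3L * n), ncol = 3L) * sigma
    coords[f, , ] <- ref + disp
  }
  top <- systemTopology(atomName = rep("CA", n),
                        residueSeq = residues,
                        residueName = rep("ALA", n),
                        mass = rep(110, n))
  new("TrajectoryEnsemble", coords = coords,
      box = matrix(box, nFrames, 3L, byrow = TRUE),
      times = (seq_len(nFrames) - 1L) * dt, topology = top)
}
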