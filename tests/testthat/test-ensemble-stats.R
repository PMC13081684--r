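# Conformational statistics: superposition, RMSD, Rg, RMSF, PCA,
# projections, basin overlap, covariance correlation.

test_that("superposition removes rigid-body motion exactly", {
  set.seed(3)
  x <- matrix(rnorm(30), 10)
  self <- superposeFrames(x, x)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  R <- rotationMatrix(0.4, -1.1, 2.2)
  moved <- x %*% t(R) + matrix(c(5, -3, 8), 10, 3, byrow = TRUE)
  fit <- superposeFrames(moved, x)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$coords, x, tolerance = 1e-8)
  # proper rotation: a mirrored copy cannot be superposed to zero
  mirrored <- x %*% diag(c(-1, 1, 1))
  expect_gt(superposeFrames(mirrored, x)$rmsd, 0.1)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("superposition RMSD matches a rotation-search oracle on 4-atom toys", {
  set.seed(13)
  for (rep in 1:2) {
    a <- matrix(rnorm(12, sd = 2), 4)
    b <- matrix(rnorm(12, sd = 2), 4)
    got <- superposeFrames(a, b)$rmsd
    # oracle: center both, then minimize over rotations parameterized by
    # Euler angles with multi-start Nelder-Mead (independent of the SVD path)
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    obj <- function(ang) {
      R <- rotationMatrix(ang[1], ang[2], ang[3])
      sqrt(mean(rowSums((ac %*% t(R) - bc)^2)))
    }
    best <- Inf
    for (s in 1:12) {
      st <- runif(3, -pi, pi)
      o <- optim(st, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
      best <- min(best, o$value)
    }
    expect_equal(got, best, tolerance = 1e-3)
    expect_lte(got, best + 1e-6)   # Kabsch is the true minimum
  }
})

test_that("RMSD series are zero for frozen ensembles and stationary for Gaussian ones", {
  frozen <- makeGaussianEnsemble(matrix(rnorm(60), 20), 0, nFrames = 8,
                                 seed = 1)
  expect_true(all(rmsdSeries(frozen)$rmsd < 1e-10))
  ens <- makeGaussianEnsemble(matrix(rnorm(90, sd = 6), 30), 0.5,
                              nFrames = 400, seed = 6)
  r <- rmsdSeries(ens)$rmsd
  expect_equal(mean(r[2:200]), mean(r[201:400]), tolerance = 0.05)
})

test_that("masking out a perturbed loop shrinks the RMSD spread", {
  ref <- buildPseudoProtein()
  sig <- rep(0.2, 161)
  sig[attr(ref, "residues") %in% 370:395] <- 1.5
  ens <- makeGaussianEnsemble(ref[, 1:3], sig, nFrames = 250, seed = 17,
                              residues = attr(ref, "residues"))
  masks <- canonicalMasks(topology(ens))
  full <- attr(rmsdSeries(ens, mask = masks$full), "equilibrium")
  noLoop <- attr(rmsdSeries(ens, mask = masks$no_termini_loop), "equilibrium")
  expect_lt(sd(noLoop), sd(full) / 2)
  expect_lt(mean(noLoop), mean(full))
})

test_that("radius of gyration matches closed forms and scales homogeneously", {
  two <- toyTrajectory(rbind(c(0, 0, 0), c(2, 0, 0)), 1:2, rep("ALA", 2),
                       mass = c(12, 12))
  expect_equal(gyrationSeries(two)$rg, 1)
  set.seed(8)
  pts <- matrix(rnorm(15, sd = 3), 5)
  m <- c(12, 14, 16, 12, 32)
  toy <- toyTrajectory(pts, 1:5, rep("ALA", 5), mass = m)
  com <- colSums(pts * m) / sum(m)
  oracle <- sqrt(sum(m * rowSums(sweep(pts, 2, com)^2)) / sum(m))
  expect_equal(gyrationSeries(toy)$rg, oracle, tolerance = 1e-12)
  dbl <- toyTrajectory(pts * 2, 1:5, rep("ALA", 5), mass = m)
  expect_equal(gyrationSeries(dbl)$rg, 2 * oracle, tolerance = 1e-12)
})

test_that("RMSF recovers planted fluctuation amplitudes and bands", {
  frozen <- makeGaussianEnsemble(matrix(rnorm(45), 15), 0, nFrames = 6,
                                 seed = 2)
  expect_true(all(rmsfProfile(frozen)$rmsf < 1e-10))
  ref <- buildPseudoProtein()
  sig <- rep(0.3, 161)
  sig[attr(ref, "residues") %in% 370:395] <- 1.2
  ens <- makeGaussianEnsemble(ref[, 1:3], sig, nFrames = 600, seed = 23,
                              residues = attr(ref, "residues"))
  prof <- rmsfProfile(ens)
  expect_true(prof$residue[which.max(prof$rmsf)] %in% 370:395)
  inBand <- prof$residue %in% 370:395
  expect_gt(min(prof$rmsf[inBand]), max(prof$rmsf[!inBand]))
  # delta-RMSF signs follow planted rigidification/flexibilization
  sigVar <- sig; sigVar[attr(ref, "residues") %in% 300:320] <- 0.05
  var <- rmsfProfile(makeGaussianEnsemble(ref[, 1:3], sigVar, nFrames = 600,
                                          seed = 24,
                                          residues = attr(ref, "residues")))
  d <- deltaRmsf(var, prof)
  expect_true(all(d$delta[d$residue %in% 300:320] < 0))
  expect_equal(deltaRmsf(prof, prof)$delta, rep(0, 161))
})

test_that("ensemble statistics are invariant under per-frame rigid-body motion", {
  ens <- makeGaussianEnsemble(matrix(rnorm(60, sd = 5), 20), 0.4,
                              nFrames = 120, seed = 31)
  moved <- ens
  set.seed(99)
  for (f in seq_len(nFrames(ens))) {
    R <- rotationMatrix(runif(1, -pi, pi), runif(1, -pi, pi),
                        runif(1, -pi, pi))
    shift <- matrix(rnorm(3, sd = 20), 20, 3, byrow = TRUE)
    moved@coords[f, , ] <- frameCoords(ens, f) %*% t(R) + shift
  }
  expect_equal(rmsfProfile(moved)$rmsf, rmsfProfile(ens)$rmsf,
               tolerance = 1e-6)
  expect_equal(rmsdSeries(moved)$rmsd, rmsdSeries(ens)$rmsd,
               tolerance = 1e-6)
  expect_equal(covariancePca(moved)@values, covariancePca(ens)@values,
               tolerance = 1e-6)
})

test_that("region masking commutes with computation", {
  ens <- makeGaussianEnsemble(matrix(rnorm(90, sd = 4), 30), 0.5,
                              nFrames = 60, seed = 37)
  keep <- proteinResidues(ens)[5:25]
  mask <- regionMask("sub", keep)
  a <- rmsfProfile(ens, mask = mask)
  b <- rmsfProfile(subsetTrajectory(ens, keep))
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(gyrationSeries(ens, mask = mask)$rg,
               gyrationSeries(subsetTrajectory(ens, keep))$rg,
               tolerance = 1e-12)
})

test_that("PCA spectra reflect planted covariance structure", {
  set.seed(43)
  n <- 12L
  ref <- matrix(rnorm(3 * n, sd = 5), n)
  # rigid-body modes at the reference (3 translations + 3 rotations), in
  # n x 3 form; planted collective vectors are orthogonalized against them
  # because superposition removes exactly these components
  cen <- sweep(ref, 2, colMeans(ref))
  rigid <- cbind(as.vector(matrix(rep(c(1, 0, 0), each = n), n)),
                 as.vector(matrix(rep(c(0, 1, 0), each = n), n)),
                 as.vector(matrix(rep(c(0, 0, 1), each = n), n)),
                 as.vector(cbind(0, -cen[, 3], cen[, 2])),
                 as.vector(cbind(cen[, 3], 0, -cen[, 1])),
                 as.vector(cbind(-cen[, 2], cen[, 1], 0)))
  Q <- qr.Q(qr(rigid))
  deflate <- function(x) {
    x <- x - Q %*% crossprod(Q, x)
    x / sqrt(sum(x^2))
  }
  v <- deflate(rnorm(3 * n))
  w <- deflate(rnorm(3 * n)); w <- w - sum(w * v) * v
  w <- w / sqrt(sum(w^2))
  nf <- 400
  amp1 <- rnorm(nf, sd = 2); amp2 <- rnorm(nf, sd = 1)
  coords1 <- array(NA_real_, c(nf, n, 3))
  coords2 <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf)) {
    coords1[f, , ] <- ref + matrix(amp1[f] * v, n) +
      matrix(rnorm(3 * n, sd = 0.01), n)
    coords2[f, , ] <- ref + matrix(amp1[f] * v + amp2[f] * w, n)
  }
  # variance along a single collective vector -> PC1 weight ~ 1
  tr <- toyTrajectory(coords1, 1:n, rep("ALA", n))
  basis <- covariancePca(tr)
  expect_gt(spectralWeights(basis, 1)$weight, 0.95)
  # two planted modes with a 4:1 variance ratio
  tr2 <- toyTrajectory(coords2, 1:n, rep("ALA", n))
  basis2 <- covariancePca(tr2)
  ratio <- basis2@values[1] / basis2@values[2]
  expect_equal(ratio, 4, tolerance = 0.2)
})

test_that("isotropic ensembles have a flat spectrum above the rigid-body modes", {
  ens <- makeGaussianEnsemble(matrix(rnorm(30, sd = 6), 10), 0.5,
                              nFrames = 5000, seed = 47)
  vals <- covariancePca(ens)@values
  p <- length(vals)
  soft <- vals[(p - 5):p]                  # 6 rigid-body modes removed
  stiff <- vals[1:(p - 6)]
  expect_lt(max(soft), 0.15 * mean(stiff))
  expect_lt((max(stiff) - min(stiff)) / mean(stiff), 0.5)
})

test_that("projections obey the PCA identities", {
  ens <- makeGaussianEnsemble(matrix(rnorm(45, sd = 5), 15), 0.6,
                              nFrames = 500, seed = 53)
  basis <- covariancePca(ens)
  cloud <- projectOntoReference(ens, basis)
  expect_equal(var(cloud$pc1), basis@values[1], tolerance = 1e-4)
  expect_equal(var(cloud$pc2), basis@values[2], tolerance = 1e-4)
  expect_equal(mean(cloud$pc1), 0, tolerance = 1e-4)
  # the mean structure projects to the origin
  meanTr <- toyTrajectory(basis@meanCoords, proteinResidues(ens),
                          rep("ALA", 15))
  pt <- projectOntoReference(meanTr, basis)
  expect_equal(c(pt$pc1, pt$pc2), c(0, 0), tolerance = 1e-6)
  # displacing every frame along PC1 moves the centroid to (delta, 0)
  delta <- 3
  shifted <- ens
  d1 <- matrix(basis@vectors[, 1], ncol = 3, byrow = TRUE)
  for (f in seq_len(nFrames(ens)))
    shifted@coords[f, , ] <- frameCoords(ens, f) + delta * d1
  cloud2 <- projectOntoReference(shifted, basis)
  expect_equal(mean(cloud2$pc1) - mean(cloud$pc1), delta, tolerance = 0.05)
})

test_that("basin overlap is 1 on itself, 0 far away, ~0.5 half-in", {
  set.seed(59)
  ref <- data.frame(pc1 = runif(2000, -1, 1), pc2 = runif(2000, -1, 1))
  expect_equal(as.numeric(basinOverlap(ref, ref)), 1)
  far <- data.frame(pc1 = ref$pc1 + 100, pc2 = ref$pc2)
  expect_equal(as.numeric(basinOverlap(far, ref)), 0)
  half <- data.frame(pc1 = runif(2000, 0, 2), pc2 = runif(2000, -1, 1))
  expect_equal(as.numeric(basinOverlap(half, ref)), 0.5, tolerance = 0.07)
  expect_error(basinOverlap(ref, ref[1:2, ]), ">= 3")
  # KDE metric agrees qualitatively
  expect_gt(as.numeric(basinOverlap(ref, ref, method = "kde")), 0.9)
  expect_equal(as.numeric(basinOverlap(far, ref, method = "kde")), 0)
})

test_that("covariance correlation compares matrices elementwise", {
  set.seed(61)
  a <- crossprod(matrix(rnorm(100), 20))
  expect_equal(covarianceCorrelation(a, a), 1)
  expect_equal(covarianceCorrelation(a, -a), -1)
  # independent symmetric matrices decorrelate
  s1 <- matrix(rnorm(2500), 50); s1 <- (s1 + t(s1)) / 2
  s2 <- matrix(rnorm(2500), 50); s2 <- (s2 + t(s2)) / 2
  expect_lt(abs(covarianceCorrelation(s1, s2)), 0.1)
  expect_error(covarianceCorrelation(a, s1), "alignment error")
})
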