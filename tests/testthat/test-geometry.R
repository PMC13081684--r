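# Membrane-frame geometry: midplane, COM distance, orientation angle,
# PBC-aware minimal distances, unwrapping.

test_that("bilayer midplane is the mass-weighted lipid z", {
  sym <- toyTrajectory(rbind(c(0, 0, 20), c(5, 5, -20)), 1:2,
                       c("POPC", "POPC"), mass = c(95, 95))
  expect_equal(bilayerMidplane(sym), 0)
  one <- toyTrajectory(rbind(c(0, 0, 17.5)), 1L, "POPC", mass = 95)
  expect_equal(bilayerMidplane(one), 17.5)
  mem <- makeMembraneFixture(jitterSigma = 0, seed = 2)
  expect_equal(bilayerMidplane(mem), 0, tolerance = 1e-12)
  noLip <- toyTrajectory(rbind(c(0, 0, 0)), 1L, "ALA")
  expect_error(bilayerMidplane(noLip), "selection error")
})

test_that("COM-midplane distance is zero at the midplane and translation invariant", {
  tr <- toyTrajectory(rbind(c(0, 0, 20), c(0, 0, -20), c(3, 3, 0)),
                      c(1L, 2L, 10L), c("POPC", "POPC", "ALA"),
                      mass = c(95, 95, 12))
  expect_equal(comMembraneDistance(tr)$value, 0)
  shifted <- tr
  shifted@coords[, , 3] <- shifted@coords[, , 3] + 5
  expect_equal(comMembraneDistance(shifted)$value,
               comMembraneDistance(tr)$value)
})

test_that("binding trajectories start beyond 12 A and plateau after the approach", {
  tr <- makeBindingTrajectory("top", nFrames = 90, approachFrames = 30,
                              plantedD = 5, seed = 12)
  d <- comMembraneDistance(tr)$value
  expect_gt(d[1], 12)
  post <- d[35:90]
  expect_lt(max(post) - min(post), 3)                 # plateau (jitter only)
  expect_lt(mean(post), d[1])
})

test_that("orientation angle matches hand geometries and is z-rotation invariant", {
  line <- function(dir) {
    pts <- outer(c(1, 2.1, 3.3, 4.6), dir)            # unequal spacing
    toyTrajectory(pts, 1:4, rep("ALA", 4))
  }
  expect_equal(orientationAngle(line(c(0, 0, 1)))$angle, 0, tolerance = 1e-8)
  expect_equal(orientationAngle(line(c(1, 0, 0)))$angle, 90, tolerance = 1e-8)
  expect_equal(orientationAngle(line(c(1, 0, 1) / sqrt(2)))$angle, 45,
               tolerance = 1e-6)
  # rotating about z preserves the angle to the membrane normal
  set.seed(77)
  pts <- matrix(rnorm(30), 10) * c(3, 1, 2)
  base <- toyTrajectory(pts, 1:10, rep("ALA", 10))
  th <- runif(1, 0, 2 * pi)
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- toyTrajectory(pts %*% t(Rz), 1:10, rep("ALA", 10))
  expect_equal(orientationAngle(rot)$angle, orientationAngle(base)$angle,
               tolerance = 1e-8)
  # a perfectly isotropic arrangement has no principal axis
  iso <- toyTrajectory(rbind(diag(3), -diag(3)), 1:6, rep("ALA", 6))
  expect_warning(orientationAngle(iso), "degenerate")
})

test_that("residue minimal distances honor the minimum-image convention", {
  tr <- toyTrajectory(rbind(c(1, 5, 0), c(39, 5, 0)), c(10L, 100L),
                      c("ALA", "POPC"), mass = c(12, 95),
                      box = c(40, 40, 40))
  expect_equal(unname(residueMinDistances(tr)["10"]), 2)
  # direct adjacency without wrapping
  tr2 <- toyTrajectory(rbind(c(0, 0, 4), c(0, 0, 0), c(20, 20, 0)),
                       c(10L, 100L, 101L), c("ALA", "POPC", "POPC"),
                       mass = c(12, 95, 95), box = c(60, 60, 60))
  expect_equal(unname(residueMinDistances(tr2)["10"]), 4)
})

test_that("minimal distances equal the all-pairs brute-force oracle exactly", {
  set.seed(5)
  nprot <- 24L; nlip <- 30L
  coords <- array(runif((nprot + nlip) * 3 * 3, 0, 50), c(3, nprot + nlip, 3))
  tr <- toyTrajectory(coords,
                      residueSeq = c(rep(301:308, each = 3), 1000L + 1:nlip),
                      residueName = c(rep("ALA", nprot),
                                      sample(c("POPC", "POPS", "PI25"), nlip,
                                             TRUE)),
                      mass = c(rep(12, nprot), rep(95, nlip)),
                      box = c(50, 50, 50))
  got <- attr(residueMinDistances(tr), "perFrame")
  expect_equal(got, oracleResidueMinDist(tr), tolerance = 1e-12)
  for (cl in c("POPC", "POPS", "POPI"))
    expect_equal(attr(residueMinDistances(tr, cl), "perFrame"),
                 oracleResidueMinDist(tr, cl), tolerance = 1e-12)
  # invariance under whole-box shifts of every atom
  sh <- tr
  sh@coords[, , 1] <- sh@coords[, , 1] + 50
  expect_equal(residueMinDistances(sh), residueMinDistances(tr),
               tolerance = 1e-9)
})

test_that("unwrapping inverts wrapping and accumulates crossings", {
  # no crossings: identity
  xy <- cbind(seq(1, 5, length.out = 20), seq(2, 8, length.out = 20))
  expect_equal(unwrapXY(xy, c(40, 40)), xy)
  # steady drift across the boundary: strictly increasing after unwrap
  drift <- cbind((0:59) * 1.0 %% 40, rep(5, 60))
  drift[, 1] <- drift[, 1] %% 40
  uw <- unwrapXY(drift, c(40, 40))
  expect_true(all(diff(uw[, 1]) > 0))
  expect_equal(uw[, 1], 0:59)
  # Brownian round trip: wrap(unwrap(wrapped)) == wrapped
  bm <- makeBrownian2D(D = 4, nSteps = 400, dt = 1, nTraj = 1, boxXY = 30,
                       seed = 14)
  w <- bm$wrapped[[1]]
  expect_equal(wrapXY(unwrapXY(w, 30), 30), w, tolerance = 1e-9)
  # unwrap recovers the true path when steps are below half the box
  expect_equal(unwrapXY(w, 30), bm$unwrapped[[1]], tolerance = 1e-9)
})
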