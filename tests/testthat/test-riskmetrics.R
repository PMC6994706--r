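# Vascular distance maps, the 128-node risk score and the remaining
# per-trajectory safety metrics.

test_that("vessel distance maps are exact and zero on vessels", {
  d <- c(24, 24, 24)
  g <- VoxelGrid(d, affine = diag(4))
  mask <- array(FALSE, d); mask[10, 10, 10] <- TRUE
  dm <- vesselDistanceMap(mask, g)
  expect_equal(dm[10, 10, 10], 0)
  expect_equal(dm[15, 10, 10], 5)  # five 1 mm steps along an axis

  set.seed(5)
  sparse <- array(runif(prod(d)) < 0.01, d)
  sparse[3, 20, 7] <- TRUE
  expect_equal(vesselDistanceMap(sparse, g), bfDistanceTransform(sparse),
               tolerance = 1e-9)

  expect_error(vesselDistanceMap(array(FALSE, d), g), "empty")
})

test_that("node sampling is uniform, inclusive and collinear", {
  tr <- Trajectory(c(0, 0, 0), c(100, 0, 0))
  expect_equal(sampleNodes(tr, 2L), rbind(c(0, 0, 0), c(100, 0, 0)),
               ignore_attr = TRUE)
  n128 <- sampleNodes(tr, 128L)
  expect_equal(unique(round(diff(n128[, 1]), 9)), 100 / 127)
  tr2 <- Trajectory(c(1, 2, 3), c(31, -18, 27))
  nodes <- sampleNodes(tr2, 64L)
  d <- trajDirection(tr2)
  off <- sweep(nodes, 2, entryPoint(tr2))
  proj <- (off %*% d) %*% t(d)
  expect_lt(max(abs(off - proj)), 1e-9)
  expect_error(sampleNodes(tr, 1L), ">= 2")
})

test_that("risk score follows the piecewise calibration arithmetic", {
  d <- c(40, 40, 40)
  g <- VoxelGrid(d, affine = diag(4))
  mask <- array(FALSE, d)
  mask[, 20, 20] <- TRUE  # straight vessel along x at y=19,z=19 (0-based)
  dm <- vesselDistanceMap(mask, g)

  traj <- function(dy) Trajectory(c(2, 19 + dy, 19), c(37, 19 + dy, 19))
  # all nodes at >= 10 mm: zero risk
  expect_equal(riskScore(traj(15), dm, g), 0)
  # closest node at 5 mm: (10 - 5)/7, and certified < 1
  expect_equal(riskScore(traj(5), dm, g), 5 / 7, tolerance = 1e-9)
  expect_lt(riskScore(traj(5), dm, g), 1)
  # parallel at 1 mm clearance: 1 + 2/3, matching a per-node brute force
  s <- riskScore(traj(1), dm, g)
  expect_equal(s, 1 + 2 / 3, tolerance = 1e-9)
  nodes <- sampleNodes(traj(1), 128L)
  dn <- apply(nodes, 1, function(p) {
    co <- callosoplan:::maskWorldCoords(mask, g)
    min(sqrt(colSums((t(co) - p)^2)))
  })
  rn <- ifelse(dn >= 10, 0, ifelse(dn >= 3, (10 - dn) / 7,
                                   1 + (3 - dn) / 3))
  expect_equal(s, max(rn), tolerance = 1e-6)
})

test_that("mean aggregation and custom models are honoured", {
  d <- c(24, 24, 24); g <- VoxelGrid(d, affine = diag(4))
  mask <- array(FALSE, d); mask[12, 12, 12] <- TRUE
  dm <- vesselDistanceMap(mask, g)
  tr <- Trajectory(c(2, 11, 11), c(21, 11, 11))
  mMax <- RiskModel(aggregation = "max")
  mMean <- RiskModel(aggregation = "mean")
  expect_gte(riskScore(tr, dm, g, mMax), riskScore(tr, dm, g, mMean))
  expect_error(RiskModel(dSafe = 11), "dSafe")
  expect_error(RiskModel(aggregation = "median"), "max.*mean|aggregation")
})

test_that("minimum vessel distance is the node minimum and zero on contact", {
  d <- c(24, 24, 24); g <- VoxelGrid(d, affine = diag(4))
  mask <- array(FALSE, d); mask[12, 12, 12] <- TRUE
  dm <- vesselDistanceMap(mask, g)
  through <- Trajectory(c(2, 11, 11), c(21, 11, 11))  # passes the vessel
  # nodes land within half a node spacing of the vessel voxel centre
  expect_lt(minVesselDistance(through, dm, g), 0.1)
  nodes <- sampleNodes(through, 128L)
  dn <- callosoplan:::interpWorld(dm, g, nodes)
  expect_true(all(minVesselDistance(through, dm, g) <= dn + 1e-12))

  outside <- Trajectory(c(-100, 0, 0), c(100, 0, 0))
  expect_error(riskScore(outside, dm, g), "outside")
})

test_that("risk is anti-monotone in vessel removal", {
  set.seed(9)
  d <- c(20, 20, 20); g <- VoxelGrid(d, affine = diag(4))
  big <- array(runif(prod(d)) < 0.05, d); big[10, 10, 10] <- TRUE
  small <- big & array(runif(prod(d)) < 0.5, d); small[10, 10, 10] <- TRUE
  dmBig <- vesselDistanceMap(big, g)
  dmSmall <- vesselDistanceMap(small, g)
  for (i in 1:20) {
    tr <- Trajectory(runif(3, 1, 8), runif(3, 11, 18))
    expect_gte(riskScore(tr, dmBig, g), riskScore(tr, dmSmall, g))
    expect_lte(minVesselDistance(tr, dmBig, g),
               minVesselDistance(tr, dmSmall, g))
  }
})

test_that("intracerebral length measures from first brain entry", {
  sw <- slabWorld(n = 80, ylim = c(-20, 20))  # 40 mm slab in y
  tr <- Trajectory(c(0, 35, 0), c(0, -15, 0))  # enters at y=20, 35 deep
  L <- intracerebralLength(tr, sw$mask, sw$grid)
  expect_equal(L, 35, tolerance = 1)
  # shrinking the mask cannot increase the length
  sw2 <- slabWorld(n = 80, ylim = c(-20, 10))
  expect_lte(intracerebralLength(tr, sw2$mask & sw$mask, sw$grid), L + 1e-9)
  # target outside the brain is a contract violation
  expect_error(intracerebralLength(Trajectory(c(0, 35, 0), c(0, 25, 0)),
                                   sw$mask, sw$grid), "outside")
})

test_that("drilling angle recovers analytic incidence on a planar slab", {
  sw <- slabWorld(n = 64, zlim = c(-30, 0))  # flat surface at z = 0
  entry <- c(0, 0, 0.5)
  orth <- Trajectory(entry, entry + 30 * c(0, 0, -1))
  expect_lt(drillingAngle(orth, sw$mask, sw$grid), 2)
  d45 <- c(0, sin(pi / 4), -cos(pi / 4))
  tr45 <- Trajectory(entry, entry + 30 * d45)
  expect_equal(drillingAngle(tr45, sw$mask, sw$grid), 45, tolerance = 3)
  flipped <- Trajectory(entry, entry - 30 * d45)
  expect_equal(drillingAngle(tr45, sw$mask, sw$grid),
               drillingAngle(flipped, sw$mask, sw$grid), tolerance = 1e-9)
  expect_error(drillingAngle(Trajectory(c(0, 0, 20), c(0, 0, -10)),
                             sw$mask, sw$grid), "surface")
})

test_that("callosal fraction of a catheter crossing a flat boundary", {
  sw <- slabWorld(n = 64, zlim = c(-30, 0))
  inside <- Trajectory(c(0, 0, -25), c(0, 0, -5))
  expect_equal(ccFraction(inside, sw$mask, sw$grid), 1)
  outside <- Trajectory(c(0, 0, 25), c(0, 0, 5))
  expect_equal(ccFraction(outside, sw$mask, sw$grid), 0)
  half <- Trajectory(c(0, 0, 10), c(0, 0, -10))
  expect_equal(ccFraction(half, sw$mask, sw$grid), 0.5, tolerance = 0.05)
  expect_error(ccFraction(half, sw$mask, sw$grid, extentMm = 0), "> 0")
})

test_that("trajectoryMetrics agrees with the individual metric functions", {
  vol <- fixVolume()
  g <- vol@grid
  dm <- vesselDistanceMap(fixVesselMask(), g)
  brain <- brainCompositeMask(vol)
  cc <- roleMask(vol, "corpus_callosum")
  head <- headMask(vol)
  sel <- selectedTrajectories(fixPlan())[[1]]
  m <- trajectoryMetrics(sel, dm, brain, cc, head, g)
  expect_equal(m@riskScore, riskScore(sel, dm, g))
  expect_equal(m@minVesselDistance, minVesselDistance(sel, dm, g))
  icl <- intracerebralLength(sel, brain, g)
  expect_equal(m@intracerebralLength, icl)
  expect_equal(m@ccFraction, ccFraction(sel, cc, g, extentMm = icl))
  expect_equal(m@drillingAngle, drillingAngle(sel, head, g))
})
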