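# Pull-back counting and simulated ablation cavities.

test_that("callosal segment length on an orthogonal slab crossing", {
  sw <- slabWorld(n = 64, zlim = c(-10, 10))  # 20 mm slab
  tr <- Trajectory(c(0, 0, 25), c(0, 0, -15))
  seg <- ccSegment(tr, sw$mask, sw$grid)
  expect_equal(seg$length, 20, tolerance = 1)
  expect_true(bfPointsInMask(sw$mask, affine(sw$grid),
                             matrix(seg$proximal, 1)))
  expect_true(bfPointsInMask(sw$mask, affine(sw$grid),
                             matrix(seg$distal, 1)))
  miss <- Trajectory(c(0, 0, 25), c(0, 30, 25))
  expect_error(ccSegment(miss, sw$mask, sw$grid), "intersect")
})

test_that("pull-back counting is the stated ceiling rule", {
  expect_equal(nPullbacks(21), 3L)
  expect_equal(nPullbacks(22), 4L)
  expect_equal(nPullbacks(0), 1L)   # single ablation at the target
  expect_equal(nPullbacks(6.9), 1L)
  expect_equal(nPullbacks(35, spacingMm = 5), 7L)
  expect_error(nPullbacks(-1), ">= 0")
})

test_that("ablation parameters enforce confluence and the 5-15 mm range", {
  expect_error(AblationParams(diameter = 15, spacing = 16), "confluence")
  expect_error(AblationParams(diameter = 4), "5, 15")
  expect_error(AblationParams(diameter = 20), "5, 15")
  expect_s4_class(AblationParams(diameter = 5, spacing = 5),
                  "AblationParams")
})

test_that("a ~20 mm crossing with 7 mm pull-backs gives 3 confluent spheres", {
  sw <- slabWorld(n = 64, zlim = c(-10, 10))  # 20 voxel columns of slab
  tr <- Trajectory(c(0, 0, 28), c(0, 0, -12))
  cav <- simulateCavity(tr, sw$mask, sw$grid,
                        AblationParams(diameter = 15, spacing = 7))
  expect_equal(cav@nPullbacks, 3L)
  expect_equal(nrow(cav@centres), 3)
  expect_equal(sort(round(diff(cav@centres[, 3]), 6)), c(7, 7))
  expect_equal(callosoplan:::nComponents26(cav@mask), 1L)
})

test_that("unclipped cavities match analytic sphere and capsule volumes", {
  sw <- slabWorld(n = 64, zlim = c(-3, 3))  # thin slab: one pull-back
  tr <- Trajectory(c(0, 0, 25), c(0, 0, 0))
  one <- simulateCavity(tr, sw$mask, sw$grid,
                        AblationParams(diameter = 15, clipToCC = FALSE))
  expect_equal(one@nPullbacks, 1L)
  sphere <- 4 / 3 * pi * 7.5^3
  expect_lt(abs(sum(one@mask) - sphere) / sphere, 0.15)

  sw2 <- slabWorld(n = 64, zlim = c(-10, 10))
  three <- simulateCavity(Trajectory(c(0, 0, 28), c(0, 0, -12)), sw2$mask,
                          sw2$grid, AblationParams(clipToCC = FALSE))
  span <- 14  # two 7 mm pull-back steps between the extreme centres
  capsule <- pi * 7.5^2 * span + 4 / 3 * pi * 7.5^3
  expect_lt(abs(sum(three@mask) - capsule) / capsule, 0.15)
  # volume is monotone in diameter
  smaller <- simulateCavity(Trajectory(c(0, 0, 28), c(0, 0, -12)), sw2$mask,
                            sw2$grid,
                            AblationParams(diameter = 10, clipToCC = FALSE))
  expect_lt(sum(smaller@mask), sum(three@mask))
})

test_that("combined cavities obey the union bound and additivity", {
  sw <- slabWorld(n = 64, zlim = c(-10, 10))
  t1 <- Trajectory(c(-15, 0, 25), c(-15, 0, -5))
  t2 <- Trajectory(c(15, 0, 25), c(15, 0, -5))
  comb <- combinedCavity(list(a = t1, b = t2), sw$mask, sw$grid,
                         AblationParams(diameter = 10))
  vols <- vapply(comb$cavities, function(cv) sum(cv@mask), 1)
  expect_equal(sum(comb$mask), sum(vols))  # disjoint cavities add exactly
  overlapping <- combinedCavity(
    list(a = t1, b = Trajectory(c(-12, 0, 25), c(-12, 0, -5))),
    sw$mask, sw$grid, AblationParams(diameter = 10))
  expect_lt(sum(overlapping$mask),
            sum(vapply(overlapping$cavities, function(cv) sum(cv@mask), 1)))
})

test_that("the planned cavities blanket the anterior two-thirds callosum", {
  vol <- fixVolume()
  cc <- roleMask(vol, "corpus_callosum")
  comb <- fixCavity()
  split <- splitAnteriorTwoThirds(cc, vol@grid)
  coverage <- sum(comb$mask & split$anterior) / sum(split$anterior)
  expect_gte(coverage, 0.9)
  for (cv in comb$cavities) {
    expect_gte(cv@nPullbacks, 1L)
    expect_equal(callosoplan:::nComponents26(cv@mask), 1L)
  }
})
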