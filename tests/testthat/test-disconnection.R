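# Streamline filtering, callosal partition and residual connectivity.

test_that("the anterior/splenium split partitions the callosum exactly", {
  sw <- slabWorld(n = 48, ylim = c(-15, 15), zlim = c(-3, 3),
                  xlim = c(-5, 5))  # 30 mm AP extent
  split <- splitAnteriorTwoThirds(sw$mask, sw$grid, fraction = 2 / 3)
  expect_equal(sum(split$anterior & split$splenium), 0)
  expect_identical(split$anterior | split$splenium, sw$mask)
  co <- callosoplan:::maskWorldCoords(split$anterior, sw$grid)
  expect_equal(max(co[, 2]) - min(co[, 2]), 20, tolerance = 1)
  # the anterior part contains the anterior-most voxel
  coAll <- callosoplan:::maskWorldCoords(sw$mask, sw$grid)
  expect_equal(max(co[, 2]), max(coAll[, 2]))

  # fraction -> 1 limit: the splenium shrinks to the posterior-most sheet
  nearOne <- splitAnteriorTwoThirds(sw$mask, sw$grid, fraction = 0.99)
  expect_lt(sum(nearOne$splenium), sum(split$splenium))
  coNear <- callosoplan:::maskWorldCoords(nearOne$splenium, sw$grid)
  coAll2 <- callosoplan:::maskWorldCoords(sw$mask, sw$grid)
  expect_equal(unique(coNear[, 2]), min(coAll2[, 2]))
  expect_error(splitAnteriorTwoThirds(sw$mask, sw$grid, fraction = 1), "0, 1")
  expect_error(splitAnteriorTwoThirds(array(FALSE, dim(sw$mask)), sw$grid),
               "empty")
})

test_that("streamline filtering matches brute-force point membership", {
  g <- VoxelGrid(c(32, 32, 32))
  mask <- array(FALSE, dim = c(32, 32, 32))
  mask[14:18, 14:18, 14:18] <- TRUE  # block around the origin
  set.seed(31)
  sl <- lapply(1:10, function(i) {
    from <- runif(3, -14, -6); to <- runif(3, 6, 14)
    rbind(from, (from + to) / 2 + rnorm(3, sd = 4), to)
  })
  set <- StreamlineSet(sl)
  filt <- filterStreamlines(set, mask, g, step = 0.5)
  hitOracle <- bfFilterStreamlines(set, mask, affine(g), step = 0.5)
  expect_equal(length(streamlines(filt$removed)), sum(hitOracle))
  expect_identical(streamlines(filt$survivors), sl[!hitOracle])

  # empty exclusion: everything survives, verbatim
  none <- filterStreamlines(set, array(FALSE, c(32, 32, 32)), g)
  expect_identical(streamlines(none$survivors), sl)
})

test_that("whole-brain exclusion removes every phantom streamline", {
  vol <- fixVolume()
  sub <- StreamlineSet(streamlines(fixStreams())[1:200])
  filt <- filterStreamlines(sub, brainCompositeMask(vol), vol@grid)
  expect_length(filt$survivors, 0)
})

test_that("filtering is monotone in the exclusion mask and step-stable", {
  vol <- fixVolume()
  g <- vol@grid
  sub <- StreamlineSet(streamlines(fixStreams())[1:300])
  small <- fixCavity()$mask
  big <- dilateMask(small, g, 2)
  fS <- filterStreamlines(sub, small, g)
  fB <- filterStreamlines(sub, big, g)
  expect_lte(length(fB$survivors), length(fS$survivors))

  hitAt <- function(step) vapply(streamlines(sub), function(s) {
    pts <- callosoplan:::.resample_polyline_cpp(s, step)
    any(callosoplan:::pointsInMask(small, g, pts))
  }, TRUE)
  disagree <- mean(hitAt(0.5) != hitAt(0.1))
  expect_lte(disagree, 0.01)
})

test_that("residual connectivity volumes follow voxel counting", {
  sw <- slabWorld(n = 48, ylim = c(-15, 15), zlim = c(-3, 3), xlim = c(-5, 5))
  split <- splitAnteriorTwoThirds(sw$mask, sw$grid)
  empty <- residualConnectivity(StreamlineSet(), sw$mask, split$anterior,
                                sw$grid, nInput = 10)
  expect_equal(empty@residualVolume, 0)
  expect_false(empty@residualInAnteriorTwoThirds)
  expect_equal(empty@anteriorVolume + empty@spleniumVolume, empty@ccVolume)

  crossing <- StreamlineSet(list(rbind(c(-20, 10, 0), c(20, 10, 0))))
  rep <- residualConnectivity(crossing, sw$mask, split$anterior, sw$grid,
                              nInput = 1)
  expect_gt(rep@residualVolume, 0)
  expect_true(rep@residualInAnteriorTwoThirds)
  # residual mask confined to the callosum
  expect_true(all(sw$mask[rep@residualMask]))
})

test_that("ablating the whole anterior two-thirds spares only the splenium", {
  vol <- fixVolume()
  cc <- roleMask(vol, "corpus_callosum")
  split <- splitAnteriorTwoThirds(cc, vol@grid)
  sub <- StreamlineSet(streamlines(fixStreams())[1:800])
  rep <- assessPlan(NULL, sub, cc, vol@grid,
                    cavityMask = dilateMask(split$anterior, vol@grid, 1))
  expect_equal(rep@residualAnteriorVolume, 0)
  expect_gt(rep@residualVolume, 0)  # splenium crossings survive
  expect_false(rep@residualInAnteriorTwoThirds)
})

test_that("paramedian inclusion planes keep only true crossers", {
  sl <- list(rbind(c(-20, 0, 0), c(20, 0, 1)),   # crosses both planes
             rbind(c(-20, 0, 0), c(-2, 0, 1)),   # stays left
             rbind(c(2, 0, 0), c(20, 0, 1)))     # stays right
  kept <- filterByInclusionPlanes(StreamlineSet(sl), xLeft = -10, xRight = 10)
  expect_length(kept, 1)
})
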