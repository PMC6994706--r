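# The digital head phantom: structure, determinism, vessel placement and
# synthetic streamlines.

test_that("default phantom resolves every planner role, non-empty", {
  vol <- fixVolume()
  for (role in names(labelTable(vol)))
    expect_gt(sum(roleMask(vol, role)), 0)
})

test_that("phantom generation is deterministic for a fixed config", {
  cfg <- phantomConfig()
  a <- makeHeadPhantom(cfg)
  b <- makeHeadPhantom(cfg)
  expect_identical(labelArray(a$volume), labelArray(b$volume))
  expect_identical(a$vessels@centrelines, b$vessels@centrelines)
})

test_that("callosal voxel volume matches the analytic arch-slab volume", {
  cfg <- phantomConfig()
  vol <- fixVolume()
  arch <- phantomArch(cfg, 4096L)
  arcLen <- sum(sqrt(rowSums(diff(arch$yz)^2)))
  a <- cfg@arch
  analytic <- arcLen * (2 * a[["radius"]]) * (2 * a[["halfWidth"]])
  vox <- sum(roleMask(vol, "corpus_callosum"))
  expect_lt(abs(vox - analytic) / analytic, 0.10)
})

test_that("pericallosal arteries hug the dorsal callosal surface", {
  ph <- fixPhantom()
  vol <- fixVolume()
  dcc <- distanceTransform(roleMask(vol, "corpus_callosum"), vol@grid)
  for (nm in c("pericallosal_left", "pericallosal_right")) {
    pts <- ph$vessels@centrelines[[nm]]
    d <- callosoplan:::interpWorld(dcc, vol@grid, pts)
    expect_lt(max(d), 3)      # everywhere within 3 mm of the surface
    expect_gt(min(d), 0.25)   # but outside it
    expect_equal(unique(abs(pts[, 1])), 2)
  }
})

test_that("phantom config geometry violations name the offending structure", {
  expect_error(makeHeadPhantom(phantomConfig(dim = 64L)), "scalp")
  expect_error(makeHeadPhantom(phantomConfig(arch = c(apSemi = 40))),
               "corpus_callosum")
  expect_error(phantomConfig(fractions = c(0.5, 0.3, 0.7)), "increasing")
  expect_error(phantomConfig(arch = c(radius = -1)), "> 0")
})

test_that("dominance flag mirrors all laterality roles", {
  cfgR <- phantomConfig(dominance = "right")
  phR <- makeHeadPhantom(cfgR)
  mL <- roleMask(phR$volume, "left_superior_frontal")
  mR <- roleMask(phR$volume, "right_superior_frontal")
  # with right dominance the non-dominant superior frontal patch sits left
  coL <- callosoplan:::maskWorldCoords(mL, phR$volume@grid)
  coR <- callosoplan:::maskWorldCoords(mR, phR$volume@grid)
  expect_lt(mean(coL[, 1]), 0)
  expect_gt(mean(coR[, 1]), 0)
})

test_that("interhemispheric streamlines cross the callosum left to right", {
  vol <- fixVolume()
  cc <- roleMask(vol, "corpus_callosum")
  set <- makeInterhemisphericStreamlines(vol, n = 300L, seed = 3L)
  expect_length(set, 300)
  crosses <- vapply(streamlines(set), function(s) {
    any(callosoplan:::pointsInMask(cc, vol@grid,
                                   callosoplan:::.resample_polyline_cpp(s, 0.5)))
  }, TRUE)
  expect_true(all(crosses))
  starts <- vapply(streamlines(set), function(s) s[1, 1], 1)
  ends <- vapply(streamlines(set), function(s) s[nrow(s), 1], 1)
  expect_true(all(starts < 0))
  expect_true(all(ends > 0))
})

test_that("streamline generation is seed-deterministic and handles n = 0", {
  vol <- fixVolume()
  a <- makeInterhemisphericStreamlines(vol, n = 25L, seed = 99L)
  b <- makeInterhemisphericStreamlines(vol, n = 25L, seed = 99L)
  expect_identical(streamlines(a), streamlines(b))
  expect_length(makeInterhemisphericStreamlines(vol, n = 0L), 0)
  expect_error(makeInterhemisphericStreamlines(vol, n = -1L), ">= 0")
})

test_that("streamline crossings cover the arch from rostrum to splenium", {
  cfg <- phantomConfig()
  vol <- fixVolume()
  arch <- phantomArch(cfg, 1024L)
  set <- fixStreams()
  mids <- t(vapply(streamlines(set), function(s) s[(nrow(s) + 1) %/% 2, ],
                   numeric(3)))
  tv <- vapply(seq_len(nrow(mids)), function(i)
    arch$t[which.min((arch$yz[, 1] - mids[i, 2])^2 +
                       (arch$yz[, 2] - mids[i, 3])^2)], 1)
  counts <- table(cut(tv, seq(0, 1, 0.1)))
  expect_true(all(counts > 0))
})
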