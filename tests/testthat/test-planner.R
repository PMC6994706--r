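# Constraint table, candidate enumeration, ranking and plan selection.

test_that("the default constraint table carries the five canonical rows", {
  specs <- defaultTrajectorySpecs()
  expect_length(specs, 5)
  df <- data.frame(entry = vapply(specs, function(s) s@entryRole, ""),
                   target = vapply(specs, function(s) s@targetRole, ""),
                   len = vapply(specs, function(s) s@maxLength, 1),
                   ang = vapply(specs, function(s) s@maxAngle, 1))
  expect_equal(df$entry, c("right_superior_frontal", "right_superior_parietal",
                           "right_angular", "left_superior_frontal",
                           "left_middle_frontal"))
  expect_equal(df$target, c("anterior", "middle", "middle", "posterior",
                            "posterior"))
  expect_equal(df$len, c(60, 110, 110, 90, 90))
  expect_equal(df$ang, c(15, 35, 35, 35, 35))

  flipped <- defaultTrajectorySpecs(dominance = "right")
  expect_equal(vapply(flipped, function(s) s@entryRole, "")[c(1, 4)],
               c("left_superior_frontal", "right_superior_frontal"))
})

test_that("enumerated candidates satisfy every hard constraint (oracle)", {
  plan <- fixPlan()
  vol <- fixVolume()
  g <- vol@grid
  vent <- roleMask(vol, "ventricles")
  head <- headMask(vol)
  for (i in seq_along(plan@specs)) {
    cand <- plan@candidates[[i]]
    expect_gt(nrow(cand), 0)
    spec <- plan@specs[[i]]
    # lengths: recompute from coordinates
    len <- sqrt((cand$targetX - cand$entryX)^2 +
                  (cand$targetY - cand$entryY)^2 +
                  (cand$targetZ - cand$entryZ)^2)
    expect_equal(len, cand$length, tolerance = 1e-9)
    expect_true(all(len <= spec@maxLength + 1e-9))
    expect_true(all(cand$angle <= spec@maxAngle + 1e-9))
    # independent re-evaluation of angle and ventricle transgression on a
    # subsample
    take <- seq(1, nrow(cand), length.out = min(25, nrow(cand)))
    for (j in unique(round(take))) {
      tr <- Trajectory(c(cand$entryX[j], cand$entryY[j], cand$entryZ[j]),
                       c(cand$targetX[j], cand$targetY[j], cand$targetZ[j]))
      expect_equal(drillingAngle(tr, head, g), cand$angle[j],
                   tolerance = 1e-6)
      steps <- sampleNodes(tr, max(2L, ceiling(trajLength(tr) / 0.5) + 1L))
      expect_false(any(bfPointsInMask(vent, affine(g), steps)))
    }
  }
})

test_that("an infeasible length bound rejects every pair, with diagnostics", {
  vol <- fixVolume()
  ctx <- callosoplan:::planContext(vol, fixVesselMask())
  tg <- generateTargets(vol)
  er <- extractEntryRegions(vol)
  tiny <- TrajectorySpec("right_superior_frontal", "anterior", 1, 15)
  cand <- enumerateCandidates(tiny, er, tg, ctx)
  expect_equal(nrow(cand), 0)
  diag <- attr(cand, "diagnostics")
  expect_equal(diag[["rejLength"]], diag[["pairs"]])
})

test_that("ranking matches a brute-force weighted sort on random tables", {
  set.seed(21)
  df <- data.frame(entryX = runif(50), entryY = runif(50), entryZ = runif(50),
                   targetX = runif(50), targetY = runif(50),
                   targetZ = runif(50), length = runif(50, 20, 100),
                   angle = runif(50, 0, 35), riskScore = runif(50, 0, 2),
                   minVesselDistance = runif(50, 0, 8),
                   intracerebralLength = runif(50, 20, 90),
                   ccFraction = runif(50))
  w <- ObjectiveWeights()
  got <- rankCandidates(df, w)
  want <- bfRankCandidates(df, w@weights)
  expect_equal(got$entryX, want$entryX)
  expect_equal(got$riskScore, want$riskScore)

  # single-factor dominance: only risk differs
  two <- df[1:2, ]
  two[, ] <- two[1, ]
  two$riskScore <- c(1.5, 0.5)
  expect_equal(rankCandidates(two, w)$riskScore, c(0.5, 1.5))
  # all weight on length
  wl <- ObjectiveWeights(risk = 0, minDistance = 0, length = 1, angle = 0,
                         ccFraction = 0)
  two$riskScore <- 1
  two$intracerebralLength <- c(80, 30)
  expect_equal(rankCandidates(two, wl)$intracerebralLength, c(30, 80))
})

test_that("the plan returns five best candidates and a selected triple", {
  plan <- fixPlan()
  expect_true(all(plan@feasible))
  expect_equal(nrow(bestCandidates(plan)), 5)
  sel <- selectedPlan(plan)
  expect_equal(nrow(sel), 3)
  expect_setequal(sel$role, c("anterior", "middle", "posterior"))
  # selection rule: pooled re-ranking of the paired specs
  for (role in c("middle", "posterior")) {
    idx <- which(vapply(plan@specs, function(s) s@targetRole, "") == role)
    pool <- do.call(rbind, plan@candidates[idx])
    pool$objective <- NULL
    best <- rankCandidates(pool, plan@weights)[1, ]
    expect_equal(sel[sel$role == role, "riskScore"], best$riskScore)
    expect_equal(sel[sel$role == role, "entryX"], best$entryX)
  }
})

test_that("planning is deterministic and stored metrics are reproducible", {
  plan <- fixPlan()
  plan2 <- planCallosotomy(fixVolume(), fixVesselMask())
  expect_equal(selectedPlan(plan), selectedPlan(plan2))
  expect_equal(bestCandidates(plan), bestCandidates(plan2))

  vol <- fixVolume()
  g <- vol@grid
  dm <- vesselDistanceMap(fixVesselMask(), g)
  brain <- brainCompositeMask(vol)
  cc <- roleMask(vol, "corpus_callosum")
  hm <- headMask(vol)
  sel <- selectedPlan(plan)
  for (i in seq_len(nrow(sel))) {
    tr <- Trajectory(c(sel$entryX[i], sel$entryY[i], sel$entryZ[i]),
                     c(sel$targetX[i], sel$targetY[i], sel$targetZ[i]))
    m <- trajectoryMetrics(tr, dm, brain, cc, hm, g)
    expect_equal(m@riskScore, sel$riskScore[i], tolerance = 1e-9)
    expect_equal(m@minVesselDistance, sel$minVesselDistance[i],
                 tolerance = 1e-9)
    expect_equal(m@intracerebralLength, sel$intracerebralLength[i],
                 tolerance = 1e-9)
    expect_equal(m@ccFraction, sel$ccFraction[i], tolerance = 1e-9)
    expect_equal(m@drillingAngle, sel$angle[i], tolerance = 1e-9)
  }
})

test_that("sealing the non-dominant frontal approach starves spec 1 only", {
  vol <- fixVolume()
  # hard-avoidance shell over the whole right-superior-frontal cone
  g <- vol@grid
  d <- dim(vol)
  co <- voxelToWorld(g, arrayInd(seq_len(prod(d)), d) - 1)
  r <- sqrt(rowSums(co^2))
  u <- c(0.15, 0.90, 0.41); u <- u / sqrt(sum(u^2))
  cosang <- (co %*% u) / pmax(r, 1e-9)
  shell <- array(r >= 30 & r <= 34 & cosang >= cos(35 * pi / 180), d)
  plan <- planCallosotomy(vol, fixVesselMask(), avoidMask = shell)
  expect_false(plan@feasible[1])
  expect_true(all(plan@feasible[2:5]))
  expect_gt(plan@diagnostics[[1]][["rejAvoid"]], 0)
  expect_setequal(selectedPlan(plan)$role, c("middle", "posterior"))
})

test_that("the selected plan clears vessels better than a midline plan", {
  vol <- fixVolume()
  g <- vol@grid
  dm <- vesselDistanceMap(fixVesselMask(), g)
  tg <- generateTargets(vol)
  sel <- selectedPlan(fixPlan())
  midlineMin <- sapply(rownames(tg@points), function(r) {
    tgt <- tg@points[r, ]; tgt[1] <- 0
    entry <- c(0, tgt[2], sqrt(44.5^2 - tgt[2]^2))  # sagittal, from above
    minVesselDistance(Trajectory(entry, tgt), dm, g)
  })
  expect_gte(min(sel$minVesselDistance), min(midlineMin))
})
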