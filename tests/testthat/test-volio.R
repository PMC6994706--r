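# Coordinate conventions and file round trips.

test_that("world/voxel conversion applies the affine and its inverse", {
  g <- VoxelGrid(c(16, 16, 16), affine = diag(4))
  expect_equal(worldToVoxel(g, c(3, 4, 5)), c(3, 4, 5))
  expect_equal(voxelToWorld(g, c(3, 4, 5)), c(3, 4, 5))

  # 2 mm isotropic, origin (-10,-10,-10): world 0 -> index 5 (hand computed)
  A <- diag(c(2, 2, 2, 1)); A[1:3, 4] <- -10
  g2 <- VoxelGrid(c(16, 16, 16), affine = A)
  expect_equal(worldToVoxel(g2, c(0, 0, 0)), c(5, 5, 5))
  expect_equal(spacing(g2), c(2, 2, 2))

  # a rotated anisotropic affine still round-trips to 1e-9
  th <- 0.3
  R <- diag(4)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  A3 <- R %*% diag(c(1, 2, 3, 1)); A3[1:3, 4] <- c(5, -7, 2)
  g3 <- VoxelGrid(c(10, 10, 10), affine = A3)
  pts <- matrix(runif(30, 0, 9), ncol = 3)
  expect_equal(worldToVoxel(g3, voxelToWorld(g3, pts)), pts,
               tolerance = 1e-9)
})

test_that("VoxelGrid validity rejects degenerate affines", {
  A <- diag(4); A[1, 1] <- 0
  expect_error(VoxelGrid(c(8, 8, 8), affine = A), "invertible|spacing")
  expect_error(VoxelGrid(c(8, 8, 0)), "positive")
})

test_that("NIfTI label volumes round-trip losslessly, plain and gzipped", {
  labels <- array(sample.int(5L, 6 * 7 * 8, replace = TRUE) - 1L, c(6, 7, 8))
  A <- diag(c(2, 2, 2, 1)); A[1:3, 4] <- c(-6, -7, -8)
  vol <- LabelVolume(labels, VoxelGrid(c(6, 7, 8), affine = A),
                     table = c(roi = 1L))
  for (ext in c(".nii", ".nii.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    writeLabelVolume(vol, path)
    back <- readLabelVolume(path, c(roi = 1L))
    expect_identical(labelArray(back), labels)
    # srow is float32; these values are exactly representable
    expect_equal(affine(back), A)
    expect_equal(spacing(back), c(2, 2, 2))
  }
})

test_that("label-volume reader validates inputs loudly", {
  expect_error(readLabelVolume(tempfile(fileext = ".nii")), "not found")
  path <- withr::local_tempfile(fileext = ".nii")
  callosoplan:::writeNifti(array(0.5, c(4, 4, 4)), diag(4), path,
                           datatype = "float32")
  expect_error(readLabelVolume(path), "non-integer")
  labels <- array(0L, c(4, 4, 4)); labels[2, 2, 2] <- 3L
  writeLabelVolume(LabelVolume(labels), path2 <- withr::local_tempfile(
    fileext = ".nii"))
  expect_error(readLabelVolume(path2, c(corpus_callosum = 9L)),
               "corpus_callosum")
})

test_that("phantom parcellation survives a write/read cycle on disk", {
  vol <- fixVolume()
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeLabelVolume(vol, path)
  back <- readLabelVolume(path, labelTable(vol))
  expect_identical(labelArray(back), labelArray(vol))
  expect_equal(spacing(back), c(1, 1, 1))
  expect_equal(affine(back), affine(vol))
})

test_that("TCK streamline files round-trip below 1e-4 mm", {
  set.seed(11)
  sl <- lapply(1:10, function(i) matrix(runif(15, -40, 40), ncol = 3))
  set <- StreamlineSet(sl, provenance = "test")
  path <- withr::local_tempfile(fileext = ".tck")
  writeStreamlines(set, path)
  back <- readStreamlines(path)
  expect_length(back, 10)
  dev <- max(mapply(function(a, b) max(abs(a - b)), streamlines(set),
                    streamlines(back)))
  expect_lt(dev, 1e-4)

  # empty set round trip
  writeStreamlines(StreamlineSet(), path)
  expect_length(readStreamlines(path), 0)
})

test_that("text streamline fallback round-trips and rejects malformed input", {
  sl <- list(matrix(c(0, 0, 0, 1, 2, 3), ncol = 3, byrow = TRUE))
  path <- withr::local_tempfile(fileext = ".txt")
  writeStreamlines(StreamlineSet(sl), path)
  back <- readStreamlines(path)
  expect_equal(streamlines(back)[[1]], sl[[1]], ignore_attr = TRUE)

  bad <- withr::local_tempfile(fileext = ".tck")
  writeLines("not a tck", bad)
  expect_error(readStreamlines(bad), "malformed")
})

test_that("a 5000-streamline phantom tractogram keeps its count on disk", {
  path <- withr::local_tempfile(fileext = ".tck")
  writeStreamlines(fixStreams(), path)
  expect_length(readStreamlines(path), 5000)
})

test_that("label schemas round-trip through JSON", {
  sch <- c(corpus_callosum = 5L, brain = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  writeLabelSchema(sch, path)
  expect_identical(readLabelSchema(path), sch)
})
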