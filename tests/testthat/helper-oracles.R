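# Brute-force oracles, deliberately independent of the package's compiled
# kernels: plain-R exhaustive computations on small grids.

# O(N^2) nearest-feature Euclidean distance, spacing-aware
bfDistanceTransform <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  feat <- which(mask, arr.ind = TRUE)
  out <- array(Inf, d)
  if (!nrow(feat)) return(out)
  fw <- sweep(feat - 1, 2, spacing, "*")
  idx <- arrayInd(seq_len(prod(d)), d)
  iw <- sweep(idx - 1, 2, spacing, "*")
  for (v in seq_len(nrow(iw))) {
    dd <- sqrt(colSums((t(fw) - iw[v, ])^2))
    out[v] <- min(dd)
  }
  out
}

# lattice-enumeration dilation: voxel set iff within radius of a TRUE voxel
bfDilate <- function(mask, spacing, radius) {
  d <- bfDistanceTransform(mask, spacing)
  array(d <= radius + 1e-9, dim(mask))
}

# nearest-voxel membership of world points, 0-based voxel convention
bfPointsInMask <- function(mask, affine, pts) {
  inv <- solve(affine)
  v <- round(sweep(pts %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")) + 1
  d <- dim(mask)
  apply(v, 1, function(ijk) {
    if (any(ijk < 1) || any(ijk > d)) return(FALSE)
    mask[ijk[1], ijk[2], ijk[3]]
  })
}

# brute-force streamline filtering: resample in plain R, test every point
bfFilterStreamlines <- function(set, mask, affine, step) {
  hit <- vapply(streamlines(set), function(s) {
    pts <- s[1, , drop = FALSE]
    for (i in seq_len(nrow(s) - 1)) {
      L <- sqrt(sum((s[i + 1, ] - s[i, ])^2))
      k <- max(1, ceiling(L / step))
      f <- seq_len(k) / k
      pts <- rbind(pts, outer(1 - f, s[i, ]) + outer(f, s[i + 1, ]))
    }
    any(bfPointsInMask(mask, affine, pts))
  }, TRUE)
  hit
}

# brute-force weighted-objective ranking of a candidate metric table
bfRankCandidates <- function(df, w) {
  nrm <- function(x) if (diff(range(x)) < 1e-12) rep(0, length(x))
                     else (x - min(x)) / diff(range(x))
  obj <- w[["risk"]] * nrm(df$riskScore) -
    w[["minDistance"]] * nrm(df$minVesselDistance) +
    w[["length"]] * nrm(df$intracerebralLength) +
    w[["angle"]] * nrm(df$angle) -
    w[["ccFraction"]] * nrm(df$ccFraction)
  df[order(obj, df$riskScore, df$intracerebralLength, df$entryX, df$entryY,
           df$entryZ, df$targetX, df$targetY, df$targetZ), , drop = FALSE]
}

# slab-world fixture: a rectangular mask inside a centred 1 mm grid
slabWorld <- function(n = 48L, xlim = c(-50, 50), ylim = c(-50, 50),
                      zlim = c(-50, 50)) {
  grid <- VoxelGrid(rep(n, 3))
  co <- arrayInd(seq_len(n^3), rep(n, 3)) - 1
  w <- voxelToWorld(grid, co)
  mask <- array(w[, 1] >= xlim[1] & w[, 1] <= xlim[2] &
                  w[, 2] >= ylim[1] & w[, 2] <= ylim[2] &
                  w[, 3] >= zlim[1] & w[, 3] <= zlim[2], rep(n, 3))
  list(grid = grid, mask = mask)
}
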