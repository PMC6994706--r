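# Per-trajectory safety metrics.
#
# The vascular risk score samples the trajectory at 128 equally placed nodes
# and looks each node up in the Euclidean distance map of the vessel
# segmentation (trilinearly interpolated, so sub-voxel trajectories behave
# smoothly). The per-node risk is piecewise linear in the vessel distance d:
#
#   r = 0                          d >= dRisk (10 mm)
#   r = (dRisk - d)/(dRisk - dSafe)    dSafe <= d < dRisk   (0, 1]
#   r = 1 + (dSafe - d)/dSafe          d < dSafe (3 mm)     (1, 2]
#
# and the trajectory score is the maximum over nodes (default), which makes
# the calibration exact: score < 1 if and only if every node is more than
# 3 mm from vasculature.

#' Euclidean distance map to the nearest vessel
#'
#' @param vesselMask binary vessel segmentation: a [LabelVolume] or a
#'   logical array plus `grid`.
#' @param grid required when `vesselMask` is a bare array.
#' @return a numeric 3D array of mm distances (zero exactly on vessel
#'   voxels).
#' @export
vesselDistanceMap <- function(vesselMask, grid = NULL) {
  if (is(vesselMask, "LabelVolume")) {
    grid <- vesselMask@grid
    vesselMask <- vesselMask@labels != 0L
  }
  if (!any(vesselMask))
    stop("vessel mask is empty: the risk score is undefined without vessels",
         call. = FALSE)
  distanceTransform(vesselMask, grid)
}

#' Sample nodes equally placed along a trajectory
#'
#' @param traj a [Trajectory].
#' @param nNodes number of nodes (>= 2); entry and target inclusive.
#' @return nNodes x 3 matrix of world-mm points.
#' @export
sampleNodes <- function(traj, nNodes = 128L) {
  if (nNodes < 2L) stop("nNodes must be >= 2", call. = FALSE)
  f <- seq(0, 1, length.out = nNodes)
  cbind(traj@entry[1] + f * (traj@target[1] - traj@entry[1]),
        traj@entry[2] + f * (traj@target[2] - traj@entry[2]),
        traj@entry[3] + f * (traj@target[3] - traj@entry[3]))
}

# node distances, with the out-of-grid guard shared by the risk metrics
.nodeDistances <- function(traj, dmap, grid, model) {
  nodes <- sampleNodes(traj, model@nNodes)
  if (!all(pointsInGrid(grid, nodes)))
    stop("trajectory node lies outside the planning grid; clip first",
         call. = FALSE)
  interpWorld(dmap, grid, nodes)
}

# vectorised piecewise-linear node risk
nodeRisk <- function(d, model = RiskModel()) {
  r <- numeric(length(d))
  mid <- d >= model@dSafe & d < model@dRisk
  near <- d < model@dSafe
  r[mid] <- (model@dRisk - d[mid]) / (model@dRisk - model@dSafe)
  r[near] <- 1 + (model@dSafe - d[near]) / model@dSafe
  r
}

#' Vascular risk score of a trajectory
#'
#' @param traj a [Trajectory].
#' @param dmap distance map from [vesselDistanceMap()].
#' @param grid the [VoxelGrid] of `dmap`.
#' @param model a [RiskModel].
#' @return dimensionless score; < 1 certifies that every sampled node is
#'   more than `dSafe` (3 mm) from vasculature (max aggregation).
#' @export
riskScore <- function(traj, dmap, grid, model = RiskModel()) {
  r <- nodeRisk(.nodeDistances(traj, dmap, grid, model), model)
  if (model@aggregation == "max") max(r) else mean(r)
}

#' Minimum distance to vasculature along a trajectory
#'
#' Minimum of the trilinearly interpolated distance map over the sampled
#' nodes.
#'
#' @inheritParams riskScore
#' @return distance in mm.
#' @export
minVesselDistance <- function(traj, dmap, grid, model = RiskModel()) {
  min(.nodeDistances(traj, dmap, grid, model))
}

#' Intracerebral length of a trajectory
#'
#' Length of the segment from the first brain-mask entry to the target, by
#' dense sampling at `step` mm.
#'
#' @param traj a [Trajectory].
#' @param brainMask logical 3D array (use [brainCompositeMask()] for a
#'   parcellation).
#' @param grid the [VoxelGrid].
#' @param step sampling step, mm (<= 0.5 recommended).
#' @return length in mm.
#' @export
intracerebralLength <- function(traj, brainMask, grid, step = 0.5) {
  g <- .gridOf(grid)
  runs <- .segment_mask_runs_cpp(matrix(traj@entry, 1), matrix(traj@target, 1),
                                 as.logical(brainMask), g@dim, solve(g@affine),
                                 step)
  if (runs[1, "lastIn"] != runs[1, "nSamples"] - 1)
    stop("target lies outside the brain mask", call. = FALSE)
  L <- trajLength(traj)
  unname(L * (1 - runs[1, "firstIn"] / (runs[1, "nSamples"] - 1)))
}

#' Drilling angle from the skull-surface orthogonal
#'
#' The outward surface normal at the entry is estimated from the gradient of
#' a Gaussian-smoothed signed distance to the head/skull mask (2 mm kernel;
#' stable on voxelised surfaces). 0 degrees is orthogonal drilling. The
#' result is unsigned and invariant to flipping the trajectory direction.
#'
#' @param traj a [Trajectory] whose entry lies on (within 2 voxels of) the
#'   mask's outer surface.
#' @param skullMask logical 3D array of the head (scalp + skull + brain);
#'   its outer boundary is the drilling surface.
#' @param grid the [VoxelGrid].
#' @param sigmaMm smoothing kernel, mm.
#' @return angle in degrees, in `[0, 90]`.
#' @export
drillingAngle <- function(traj, skullMask, grid, sigmaMm = 2) {
  g <- .gridOf(grid)
  sdf <- signedDistanceField(skullMask, g, sigmaMm)
  raw <- sdf$raw
  if (abs(interpWorld(raw, g, traj@entry)) > 2 * max(spacing(g)))
    stop("trajectory entry is farther than 2 voxels from the surface",
         call. = FALSE)
  n <- surfaceNormals(sdf$smooth, g, matrix(traj@entry, 1))[1, ]
  d <- trajDirection(traj)
  acos(min(1, abs(sum(d * n)))) * 180 / pi
}

# signed distance (positive outside) and its smoothed version
signedDistanceField <- function(mask, grid, sigmaMm = 2) {
  g <- .gridOf(grid)
  inside <- distanceTransform(!mask, g)
  outside <- distanceTransform(mask, g)
  raw <- outside - inside
  smooth <- .gauss_smooth3_cpp(as.numeric(raw), g@dim, sigmaMm / spacing(g))
  list(raw = raw, smooth = array(smooth, g@dim))
}

# outward unit normals at world points, by central differences of the field
surfaceNormals <- function(field, grid, pointsMm, h = 1) {
  g <- .gridOf(grid)
  n <- nrow(pointsMm)
  grad <- matrix(0, n, 3)
  for (ax in 1:3) {
    off <- matrix(0, n, 3); off[, ax] <- h
    grad[, ax] <- (interpWorld(field, g, pointsMm + off) -
                     interpWorld(field, g, pointsMm - off)) / (2 * h)
  }
  grad / pmax(sqrt(rowSums(grad^2)), 1e-12)
}

#' Proportion of the catheter within the corpus callosum
#'
#' Fraction of `step`-mm samples of the distal `extentMm` of the catheter
#' (measured back from the target along the trajectory) lying inside the
#' callosal mask. `extentMm` defaults to the full trajectory length; the
#' planner passes the intracerebral length.
#'
#' @param traj a [Trajectory].
#' @param ccMask logical 3D array.
#' @param grid the [VoxelGrid].
#' @param extentMm catheter extent, mm (> 0).
#' @param step sampling step, mm.
#' @return fraction in `[0, 1]`.
#' @export
ccFraction <- function(traj, ccMask, grid, extentMm = trajLength(traj),
                       step = 0.5) {
  if (extentMm <= 0) stop("catheter extent must be > 0", call. = FALSE)
  g <- .gridOf(grid)
  extentMm <- min(extentMm, trajLength(traj))
  start <- traj@target - trajDirection(traj) * extentMm
  runs <- .segment_mask_runs_cpp(matrix(start, 1), matrix(traj@target, 1),
                                 as.logical(ccMask), g@dim, solve(g@affine),
                                 step)
  unname(runs[1, "nIn"] / runs[1, "nSamples"])
}

#' All five safety metrics of one trajectory
#'
#' @param traj a [Trajectory].
#' @param dmap vessel distance map.
#' @param brainMask,ccMask,headMask logical arrays on `grid`.
#' @param grid the [VoxelGrid].
#' @param model a [RiskModel].
#' @return a [TrajectoryMetrics] object.
#' @export
trajectoryMetrics <- function(traj, dmap, brainMask, ccMask, headMask, grid,
                              model = RiskModel()) {
  d <- .nodeDistances(traj, dmap, grid, model)
  r <- nodeRisk(d, model)
  icl <- intracerebralLength(traj, brainMask, grid)
  new("TrajectoryMetrics",
      intracerebralLength = icl,
      drillingAngle = drillingAngle(traj, headMask, grid),
      riskScore = if (model@aggregation == "max") max(r) else mean(r),
      minVesselDistance = min(d),
      ccFraction = ccFraction(traj, ccMask, grid, extentMm = icl))
}
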