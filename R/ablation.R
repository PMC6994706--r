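# Simulated pull-back laser ablation cavities.
#
# The number of pull-backs is the length of the catheter within the corpus
# callosum divided by the pull-back spacing (7 mm), rounded up with a
# minimum of one so the whole callosal segment is covered. Ablation centres
# are anchored at the distal (target) end of the callosal segment and step
# proximally -- the catheter is pulled *back*. Each ablation is a sphere of
# the configured diameter; with spacing <= diameter the union is confluent
# and converges to a capped cylinder, matching the cylindrical-cavity
# description of clinical laser systems while staying rotation-invariant on
# the voxel lattice.

#' Callosal segment of a trajectory
#'
#' The longest contiguous in-callosum interval of the entry-to-target
#' segment, found by dense sampling.
#'
#' @param traj a [Trajectory].
#' @param ccMask logical corpus-callosum mask.
#' @param grid the [VoxelGrid].
#' @param step sampling step, mm.
#' @return list with `proximal`, `distal` (world-mm points, both inside the
#'   mask) and `length` (mm).
#' @export
ccSegment <- function(traj, ccMask, grid, step = 0.5) {
  g <- .gridOf(grid)
  runs <- .segment_mask_runs_cpp(matrix(traj@entry, 1),
                                 matrix(traj@target, 1),
                                 as.logical(ccMask), g@dim, solve(g@affine),
                                 step)
  if (runs[1, "firstIn"] < 0)
    stop("trajectory does not intersect the corpus callosum", call. = FALSE)
  ns <- runs[1, "nSamples"]
  L <- trajLength(traj)
  f0 <- runs[1, "runStart"] / (ns - 1)
  f1 <- runs[1, "runEnd"] / (ns - 1)
  d <- trajDirection(traj)
  list(proximal = unname(traj@entry + f0 * L * d),
       distal = unname(traj@entry + f1 * L * d),
       length = unname((f1 - f0) * L))
}

#' Number of catheter pull-backs for a callosal segment
#'
#' `ceiling(segmentLength / spacing)`, with a minimum of one (a single
#' ablation at the target), so the cavity always covers the whole segment.
#'
#' @param segmentLengthMm callosal segment length, mm (>= 0).
#' @param spacingMm pull-back spacing, mm (default 7).
#' @return integer count.
#' @export
nPullbacks <- function(segmentLengthMm, spacingMm = 7) {
  if (segmentLengthMm < 0)
    stop("segment length must be >= 0", call. = FALSE)
  max(1L, as.integer(ceiling(segmentLengthMm / spacingMm - 1e-9)))
}

#' Simulate the ablation cavity of one catheter
#'
#' Spheres of the configured diameter are rasterised at the pull-back
#' centres; with `clipToCC` the cavity is intersected with the callosal mask
#' dilated by 2 mm (thermal margin), modelling a surgeon limiting the
#' ablation to the callosum.
#'
#' @param traj a [Trajectory] intersecting the corpus callosum.
#' @param ccMask logical corpus-callosum mask.
#' @param grid the [VoxelGrid].
#' @param params an [AblationParams].
#' @return an [AblationCavity].
#' @export
simulateCavity <- function(traj, ccMask, grid, params = AblationParams()) {
  validObject(params)
  g <- .gridOf(grid)
  seg <- ccSegment(traj, ccMask, g)
  n <- nPullbacks(seg$length, params@spacing)
  d <- trajDirection(traj)
  centres <- t(vapply(seq_len(n) - 1L,
                      function(k) seg$distal - k * params@spacing * d,
                      numeric(3)))
  spheres <- lapply(seq_len(n), function(i) centres[i, , drop = FALSE])
  mask <- .capsule_mask_cpp(spheres, rep(params@diameter / 2, n), g@dim,
                            g@affine, solve(g@affine))
  if (params@clipToCC)
    mask <- mask & dilateMask(ccMask, g, 2)
  new("AblationCavity", mask = array(mask, g@dim), centres = centres,
      nPullbacks = as.integer(n), grid = g)
}

#' Combined cavity of a selected plan
#'
#' Voxelwise union of the per-trajectory cavities of the selected triple.
#'
#' @param plan a [PlanSet] with a selected triple (or a list of
#'   [Trajectory]).
#' @param ccMask logical corpus-callosum mask.
#' @param grid the [VoxelGrid].
#' @param params an [AblationParams].
#' @return list with `mask` (union) and `cavities` (per-trajectory
#'   [AblationCavity] list).
#' @export
combinedCavity <- function(plan, ccMask, grid, params = AblationParams()) {
  trajs <- if (is(plan, "PlanSet")) {
    if (!nrow(plan@selected)) stop("plan has no selected triple",
                                   call. = FALSE)
    selectedTrajectories(plan)
  } else plan
  cavities <- lapply(trajs, simulateCavity, ccMask = ccMask, grid = grid,
                     params = params)
  mask <- Reduce(`|`, lapply(cavities, function(cv) cv@mask))
  list(mask = mask, cavities = cavities)
}
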