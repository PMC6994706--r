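# Tractography-based disconnection assessment: streamline filtering through
# ablation exclusion masks and residual-connectivity volumetry.
#
# A streamline is excluded when any point of its resampled polyline falls
# inside the exclusion mask (polyline resampling rather than voxel
# traversal: simple, and convergent as the step shrinks). Residual
# connectivity is the set of callosal voxels still traversed by surviving
# streamlines; volumes are voxel counts, reported in cm^3. The callosum is
# partitioned into the anterior two-thirds (the intended ablation extent)
# and the spared splenium by a coronal plane at a configurable fraction of
# its anterior-posterior extent.

#' Split the corpus callosum into anterior two-thirds and splenium
#'
#' The split is a coronal plane at `fraction` of the callosal AP (world y)
#' extent; the anterior part contains the anterior-most voxel and the two
#' masks partition the callosum exactly.
#'
#' @param ccMask non-empty logical corpus-callosum mask.
#' @param grid the [VoxelGrid].
#' @param fraction anterior share of the AP extent, in (0, 1); default 2/3.
#' @return list with `anterior` and `splenium` logical masks.
#' @export
splitAnteriorTwoThirds <- function(ccMask, grid, fraction = 2 / 3) {
  if (!any(ccMask)) stop("corpus-callosum mask is empty", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)", call. = FALSE)
  g <- .gridOf(grid)
  co <- maskWorldCoords(ccMask, g)
  y <- co[, 2]
  cut <- max(y) - fraction * (max(y) - min(y))
  anterior <- array(FALSE, dim(ccMask))
  anterior[which(ccMask)] <- y >= cut - 1e-9
  list(anterior = anterior, splenium = ccMask & !anterior)
}

#' Filter streamlines through an exclusion mask
#'
#' A streamline is removed iff any point of its polyline, resampled at
#' `step` mm, falls inside the exclusion mask; survivors are preserved
#' verbatim.
#'
#' @param set a [StreamlineSet].
#' @param exclusionMask logical 3D array (e.g. the combined ablation
#'   cavity).
#' @param grid the [VoxelGrid].
#' @param step resampling step, mm.
#' @return list of [StreamlineSet]s: `survivors` and `removed`.
#' @export
filterStreamlines <- function(set, exclusionMask, grid, step = 0.5) {
  g <- .gridOf(grid)
  inv <- solve(g@affine)
  mask <- as.logical(exclusionMask)
  hit <- vapply(set@streamlines, function(s) {
    pts <- .resample_polyline_cpp(s, step)
    any(pointsInMask(array(mask, g@dim), g, pts))
  }, TRUE)
  list(survivors = StreamlineSet(set@streamlines[!hit],
                                 provenance = set@provenance),
       removed = StreamlineSet(set@streamlines[hit],
                               provenance = set@provenance))
}

#' Residual interhemispheric connectivity of surviving streamlines
#'
#' The residual mask is the set of callosal voxels visited by at least
#' `minVisits` surviving streamlines (resampled at `step` mm); volumes are
#' voxel counts times the voxel volume, in cm^3.
#'
#' @param survivors a [StreamlineSet].
#' @param ccMask logical corpus-callosum mask.
#' @param anteriorMask anterior-two-thirds mask (from
#'   [splitAnteriorTwoThirds()]).
#' @param grid the [VoxelGrid].
#' @param nInput total streamlines before filtering (defaults to survivor
#'   count, for standalone use).
#' @param step resampling step, mm.
#' @param minVisits visitation threshold for binarising residual
#'   connectivity (default 1).
#' @return a [DisconnectionReport].
#' @export
residualConnectivity <- function(survivors, ccMask, anteriorMask, grid,
                                 nInput = length(survivors), step = 0.5,
                                 minVisits = 1L) {
  g <- .gridOf(grid)
  inv <- solve(g@affine)
  visits <- integer(prod(g@dim))
  for (s in survivors@streamlines) {
    idx <- .polyline_voxels_cpp(s, g@dim, inv, step)
    visits[idx] <- visits[idx] + 1L
  }
  residual <- array(visits >= minVisits, g@dim) & ccMask
  spleniumMask <- ccMask & !anteriorMask
  resAnt <- residual & anteriorMask
  vox <- prod(spacing(g)) / 1000
  apFrac <- NA_real_
  if (any(resAnt)) {
    yCC <- maskWorldCoords(ccMask, g)[, 2]
    yRes <- maskWorldCoords(resAnt, g)[, 2]
    # 0 = anterior-most extreme of the callosum
    apFrac <- (max(yCC) - max(yRes)) / (max(yCC) - min(yCC))
  }
  new("DisconnectionReport",
      nInput = as.integer(nInput), nSurviving = length(survivors),
      residualMask = residual,
      residualVolume = sum(residual) * vox,
      residualAnteriorVolume = sum(resAnt) * vox,
      residualInAnteriorTwoThirds = any(resAnt),
      ccVolume = sum(ccMask) * vox,
      anteriorVolume = sum(ccMask & anteriorMask) * vox,
      spleniumVolume = sum(spleniumMask) * vox,
      anteriorPositionFraction = apFrac,
      grid = g)
}

#' Assess a plan end to end
#'
#' Filters the streamlines through the combined ablation cavity of the
#' selected plan and reports residual connectivity, including the AP
#' position of any residual anterior connectivity (0 = anterior-most, the
#' failure mode where cortical vasculature blocks the frontal trajectory
#' from reaching the rostrum).
#'
#' @param plan a [PlanSet] (or list of [Trajectory]).
#' @param streamlines a [StreamlineSet].
#' @param ccMask logical corpus-callosum mask.
#' @param grid the [VoxelGrid].
#' @param params an [AblationParams].
#' @param fraction anterior split fraction.
#' @param cavityMask optionally a precomputed exclusion mask (skips cavity
#'   simulation).
#' @return a [DisconnectionReport].
#' @export
assessPlan <- function(plan, streamlines, ccMask, grid,
                       params = AblationParams(), fraction = 2 / 3,
                       cavityMask = NULL) {
  g <- .gridOf(grid)
  if (is.null(cavityMask))
    cavityMask <- combinedCavity(plan, ccMask, g, params)$mask
  split <- splitAnteriorTwoThirds(ccMask, g, fraction)
  filt <- filterStreamlines(streamlines, cavityMask, g)
  residualConnectivity(filt$survivors, ccMask, split$anterior, g,
                       nInput = length(streamlines))
}

#' Keep streamlines crossing two paramedian planes
#'
#' Emulates the seed/inclusion-plane selection of interhemispheric
#' tractography: a streamline is kept iff it has points on both sides
#' beyond `xLeft` and `xRight` (world x, mm).
#'
#' @param set a [StreamlineSet].
#' @param xLeft,xRight plane positions, mm (left < 0 < right).
#' @return a [StreamlineSet].
#' @export
filterByInclusionPlanes <- function(set, xLeft = -10, xRight = 10) {
  keep <- vapply(set@streamlines, function(s)
    any(s[, 1] <= xLeft) && any(s[, 1] >= xRight), TRUE)
  StreamlineSet(set@streamlines[keep], provenance = set@provenance)
}
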