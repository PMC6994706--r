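# Constrained candidate search and trajectory selection.
#
# The search is exhaustive over stride-subsampled (entry-surface point x
# target-region voxel) pairs, which keeps the planner deterministic and
# oracle-checkable. Hard constraints per spec row: skull-to-target length,
# drilling angle, and ventricle transgression (ventricle avoidance is hard
# by default, as in stereotactic practice). Vessel avoidance is soft,
# entering through the risk-score and minimum-distance terms of the
# objective, so sub-3 mm approaches remain admissible where nothing better
# exists.

#' The five default entry/target constraint rows
#'
#' One row per candidate trajectory family: non-dominant superior frontal to
#' the anterior target (60 mm, 15 deg), non-dominant superior parietal
#' lobule and angular gyrus to the middle target (110 mm, 35 deg), dominant
#' superior and middle frontal to the posterior target (90 mm, 35 deg).
#' With the default left dominance the non-dominant side is the right.
#'
#' @param dominance `"left"` (default) or `"right"`; entry laterality
#'   follows the flag.
#' @return list of five [TrajectorySpec] objects.
#' @export
defaultTrajectorySpecs <- function(dominance = "left") {
  rows <- list(
    TrajectorySpec("right_superior_frontal", "anterior", 60, 15),
    TrajectorySpec("right_superior_parietal", "middle", 110, 35),
    TrajectorySpec("right_angular", "middle", 110, 35),
    TrajectorySpec("left_superior_frontal", "posterior", 90, 35),
    TrajectorySpec("left_middle_frontal", "posterior", 90, 35))
  if (dominance == "right")
    rows <- lapply(rows, function(s) {
      s@entryRole <- if (startsWith(s@entryRole, "right_"))
        sub("^right_", "left_", s@entryRole)
      else sub("^left_", "right_", s@entryRole)
      s
    })
  rows
}

# voxels of a mask whose 6-neighbourhood leaves the mask (or the grid)
maskSurface6 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  shift <- function(m, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    src <- seq_len(d[ax]) - by
    pad <- src < 1 | src > d[ax]
    src[pad] <- 1
    idx[[ax]] <- src
    res <- do.call(`[`, c(list(m), idx))
    # out-of-grid neighbours count as background
    idx2 <- rep(list(quote(expr = )), 3)
    idx2[[ax]] <- which(pad)
    if (any(pad)) res <- do.call(`[<-`, c(list(res), idx2, list(FALSE)))
    res
  }
  for (ax in 1:3) for (by in c(-1, 1))
    out <- out | (mask & !shift(mask, ax, by))
  out
}

# everything the per-spec search needs, computed once per plan
planContext <- function(parcellation, vesselMask, model = RiskModel()) {
  grid <- parcellation@grid
  head <- headMask(parcellation)
  surf <- maskSurface6(head)
  sfeat <- distanceTransform(surf, grid, feature = TRUE)$feature
  sdf <- signedDistanceField(head, grid, sigmaMm = 2)
  list(grid = grid,
       head = head,
       brain = brainCompositeMask(parcellation),
       cc = roleMask(parcellation, "corpus_callosum"),
       ventricles = roleMask(parcellation, "ventricles"),
       dmap = vesselDistanceMap(vesselMask, grid),
       surfaceFeature = sfeat,
       sdfSmooth = sdf$smooth,
       model = model)
}

#' Enumerate constraint-satisfying candidate trajectories for one spec row
#'
#' Entry points are the scalp-surface projections (nearest outer-surface
#' voxel) of the entry-gyrus voxels, stride-subsampled; target points are
#' stride-subsampled target-region voxel centres, always including the
#' region's snapped centroid. Candidates violating the length or drilling
#' angle bound, or transgressing the ventricles (or `avoidMask`), are
#' discarded.
#'
#' @param spec a [TrajectorySpec].
#' @param entries an [EntryRegions].
#' @param targets a [TargetRegions].
#' @param context a plan context (internal; built by [planCallosotomy()]).
#' @param strides named integer vector `c(entry = , target = )`.
#' @param avoidMask optional additional hard-avoidance mask.
#' @return `data.frame` of candidates (entry/target world mm, `length`,
#'   `angle`), with a `diagnostics` attribute of per-constraint rejection
#'   counts. Zero feasible candidates give an empty data.frame.
#' @export
enumerateCandidates <- function(spec, entries, targets, context,
                                strides = c(entry = 2L, target = 2L),
                                avoidMask = NULL) {
  grid <- context$grid
  if (!spec@entryRole %in% names(entries@masks))
    stop("entry role '", spec@entryRole, "' not available", call. = FALSE)
  entryIdx <- which(entries@masks[[spec@entryRole]])
  if (!length(entryIdx)) stop("entry region is empty", call. = FALSE)
  surfIdx <- sort(unique(context$surfaceFeature[entryIdx]))
  surfIdx <- surfIdx[seq(1, length(surfIdx), by = max(1L, strides[["entry"]]))]
  ePts <- voxelToWorld(grid, arrayInd(surfIdx, grid@dim) - 1)
  normals <- surfaceNormals(context$sdfSmooth, grid, ePts)

  tmask <- targets@masks[[spec@targetRole]]
  tIdx <- sort(which(tmask))
  tIdx <- tIdx[seq(1, length(tIdx), by = max(1L, strides[["target"]]))]
  tPts <- voxelToWorld(grid, arrayInd(tIdx, grid@dim) - 1)
  snap <- targets@points[spec@targetRole, ]
  if (!any(colSums(abs(t(tPts) - snap)) < 1e-9))
    tPts <- rbind(snap, tPts)

  ne <- nrow(ePts); nt <- nrow(tPts)
  ei <- rep(seq_len(ne), times = nt)
  ti <- rep(seq_len(nt), each = ne)
  E <- ePts[ei, , drop = FALSE]
  Tm <- tPts[ti, , drop = FALSE]
  D <- Tm - E
  len <- sqrt(rowSums(D^2))
  rej <- c(pairs = length(len), rejLength = 0, rejAngle = 0,
           rejVentricle = 0, rejAvoid = 0)

  ok <- len <= spec@maxLength & len > 0
  rej[["rejLength"]] <- sum(!ok)
  E <- E[ok, , drop = FALSE]; Tm <- Tm[ok, , drop = FALSE]
  len <- len[ok]; D <- D[ok, , drop = FALSE]; ei <- ei[ok]
  ang <- if (nrow(E)) {
    cosang <- abs(rowSums(D / len * normals[ei, , drop = FALSE]))
    acos(pmin(1, cosang)) * 180 / pi
  } else numeric()
  ok <- ang <= spec@maxAngle
  rej[["rejAngle"]] <- sum(!ok)
  E <- E[ok, , drop = FALSE]; Tm <- Tm[ok, , drop = FALSE]
  len <- len[ok]; ang <- ang[ok]

  if (nrow(E)) {
    hit <- .segments_hit_mask_cpp(E, Tm, as.logical(context$ventricles),
                                  grid@dim, solve(grid@affine), 0.5)
    rej[["rejVentricle"]] <- sum(hit)
    E <- E[!hit, , drop = FALSE]; Tm <- Tm[!hit, , drop = FALSE]
    len <- len[!hit]; ang <- ang[!hit]
  }
  if (!is.null(avoidMask) && nrow(E)) {
    hit <- .segments_hit_mask_cpp(E, Tm, as.logical(avoidMask), grid@dim,
                                  solve(grid@affine), 0.5)
    rej[["rejAvoid"]] <- sum(hit)
    E <- E[!hit, , drop = FALSE]; Tm <- Tm[!hit, , drop = FALSE]
    len <- len[!hit]; ang <- ang[!hit]
  }
  out <- data.frame(entryX = E[, 1], entryY = E[, 2], entryZ = E[, 3],
                    targetX = Tm[, 1], targetY = Tm[, 2], targetZ = Tm[, 3],
                    length = len, angle = ang)
  attr(out, "diagnostics") <- rej
  out
}

# batch metrics for a candidate table
.candidateMetrics <- function(cands, context) {
  n <- nrow(cands)
  grid <- context$grid
  model <- context$model
  E <- as.matrix(cands[, c("entryX", "entryY", "entryZ")])
  Tm <- as.matrix(cands[, c("targetX", "targetY", "targetZ")])
  f <- seq(0, 1, length.out = model@nNodes)
  nodes <- matrix(0, n * model@nNodes, 3)
  for (ax in 1:3)
    nodes[, ax] <- as.vector(outer(f, Tm[, ax] - E[, ax]) +
                               rep(E[, ax], each = model@nNodes))
  d <- matrix(interpWorld(context$dmap, grid, nodes), nrow = model@nNodes)
  r <- matrix(nodeRisk(as.vector(d), model), nrow = model@nNodes)
  cands$riskScore <- if (model@aggregation == "max") apply(r, 2, max)
                     else colMeans(r)
  cands$minVesselDistance <- apply(d, 2, min)

  inv <- solve(grid@affine)
  runs <- .segment_mask_runs_cpp(E, Tm, as.logical(context$brain), grid@dim,
                                 inv, 0.5)
  valid <- runs[, "lastIn"] == runs[, "nSamples"] - 1 & runs[, "firstIn"] >= 0
  icl <- cands$length * (1 - runs[, "firstIn"] / (runs[, "nSamples"] - 1))
  cands$intracerebralLength <- icl
  dir <- (Tm - E) / cands$length
  S <- Tm - dir * pmin(icl, cands$length)
  ccRuns <- .segment_mask_runs_cpp(S, Tm, as.logical(context$cc), grid@dim,
                                   inv, 0.5)
  cands$ccFraction <- ccRuns[, "nIn"] / ccRuns[, "nSamples"]
  cands[valid, , drop = FALSE]
}

#' Rank candidates by the weighted normalised objective
#'
#' Each metric is min-max normalised over the candidate pool; the composite
#' objective (lower is better) weights risk score, negated minimum vessel
#' distance, intracerebral length, drilling angle and negated callosal
#' fraction. Ties are broken by lower risk score, then shorter
#' intracerebral length, then lexicographic entry coordinates, making the
#' ranking a deterministic total order.
#'
#' @param cands candidate `data.frame` with metric columns (from the
#'   planner's metric pass).
#' @param weights an [ObjectiveWeights].
#' @return the data.frame sorted by ascending objective, with an
#'   `objective` column.
#' @export
rankCandidates <- function(cands, weights = ObjectiveWeights()) {
  if (!nrow(cands)) return(cands)
  nrm <- function(x) {
    rng <- range(x)
    if (diff(rng) < 1e-12) rep(0, length(x)) else (x - rng[1]) / diff(rng)
  }
  w <- weights@weights
  cands$objective <- w[["risk"]] * nrm(cands$riskScore) -
    w[["minDistance"]] * nrm(cands$minVesselDistance) +
    w[["length"]] * nrm(cands$intracerebralLength) +
    w[["angle"]] * nrm(cands$angle) -
    w[["ccFraction"]] * nrm(cands$ccFraction)
  ord <- order(cands$objective, cands$riskScore, cands$intracerebralLength,
               cands$entryX, cands$entryY, cands$entryZ,
               cands$targetX, cands$targetY, cands$targetZ)
  out <- cands[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plan the three-trajectory laser callosotomy
#'
#' Runs target generation, per-spec candidate enumeration and ranking for
#' the five default spec rows, then selects the final triple: the anterior
#' trajectory plus, for each of the middle and posterior targets, the
#' better-ranked of its two candidate families (ranked over the pooled
#' candidates of the pair).
#'
#' @param parcellation a [LabelVolume] resolving all planner roles.
#' @param vesselMask binary vessel segmentation ([LabelVolume] or logical
#'   array on the same grid).
#' @param specs list of [TrajectorySpec] (default [defaultTrajectorySpecs()]).
#' @param weights an [ObjectiveWeights].
#' @param model a [RiskModel].
#' @param strides subsampling strides, `c(entry =, target =)`.
#' @param avoidMask optional hard-avoidance mask (e.g. a vessel wall a
#'   surgeon would refuse to transgress).
#' @param targets optionally a precomputed [TargetRegions].
#' @return a [PlanSet]; specs with zero feasible candidates leave the plan
#'   partially infeasible (flagged, with diagnostics).
#' @export
planCallosotomy <- function(parcellation, vesselMask,
                            specs = defaultTrajectorySpecs(),
                            weights = ObjectiveWeights(),
                            model = RiskModel(),
                            strides = c(entry = 2L, target = 2L),
                            avoidMask = NULL, targets = NULL) {
  if (is(vesselMask, "LabelVolume")) vesselMask <- vesselMask@labels != 0L
  context <- planContext(parcellation, vesselMask, model)
  if (is.null(targets)) targets <- generateTargets(parcellation)
  entries <- extractEntryRegions(parcellation)

  candidates <- vector("list", length(specs))
  diagnostics <- vector("list", length(specs))
  feasible <- logical(length(specs))
  for (i in seq_along(specs)) {
    cand <- enumerateCandidates(specs[[i]], entries, targets, context,
                                strides = strides, avoidMask = avoidMask)
    diagnostics[[i]] <- attr(cand, "diagnostics")
    attr(cand, "diagnostics") <- NULL
    if (nrow(cand)) {
      cand <- .candidateMetrics(cand, context)
      cand <- rankCandidates(cand, weights)
      cand$entryRole <- specs[[i]]@entryRole
      cand$targetRole <- specs[[i]]@targetRole
      cand$spec <- i
    }
    feasible[i] <- nrow(cand) > 0
    candidates[[i]] <- cand
  }
  names(candidates) <- vapply(specs, function(s)
    paste0(s@entryRole, ":", s@targetRole), "")

  best <- do.call(rbind, lapply(candidates[feasible],
                                function(df) df[1, , drop = FALSE]))
  if (is.null(best)) best <- data.frame()
  rownames(best) <- NULL

  pickPooled <- function(idx) {
    pool <- do.call(rbind, candidates[intersect(idx, which(feasible))])
    if (is.null(pool) || !nrow(pool)) return(NULL)
    pool$objective <- NULL
    rankCandidates(pool, weights)[1, , drop = FALSE]
  }
  targetOf <- vapply(specs, function(s) s@targetRole, "")
  sel <- list(
    anterior = pickPooled(which(targetOf == "anterior")),
    middle = pickPooled(which(targetOf == "middle")),
    posterior = pickPooled(which(targetOf == "posterior")))
  sel <- sel[!vapply(sel, is.null, TRUE)]
  selected <- if (length(sel)) {
    df <- do.call(rbind, sel)
    df$role <- names(sel)
    rownames(df) <- NULL
    df
  } else data.frame()

  new("PlanSet", specs = specs, candidates = candidates, best = best,
      selected = selected, feasible = feasible, diagnostics = diagnostics,
      weights = weights)
}
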