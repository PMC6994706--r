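#' @useDynLib callosoplan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot slotNames show
#' @importFrom stats runif rnorm
NULL

# ---------------------------------------------------------------------------
# Core volumetric containers
# ---------------------------------------------------------------------------

#' VoxelGrid: a 3D voxel lattice with a world transform
#'
#' Couples the shape of a 3D grid with the 4x4 affine mapping 0-based voxel
#' indices (voxel centres) to world coordinates in mm. World coordinates
#' follow the neuroimaging RAS convention (+x right, +y anterior,
#' +z superior) when the affine is RAS-coded, as all volumes produced by this
#' package are. All geometric operations in the package work in world mm;
#' voxelisation happens only at mask rasterisation and mask lookup.
#'
#' @slot dim integer(3), grid shape (all positive).
#' @slot affine 4x4 numeric matrix, voxel-index -> world-mm transform
#'   (invertible; last row `0 0 0 1`).
#' @export
setClass("VoxelGrid", representation(dim = "integer", affine = "matrix"))

setValidity("VoxelGrid", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 1L))
    return("dim must be 3 positive integers")
  A <- object@affine
  if (!is.numeric(A) || !all(dim(A) == c(4L, 4L)))
    return("affine must be a 4x4 numeric matrix")
  if (any(abs(A[4, ] - c(0, 0, 0, 1)) > 1e-9))
    return("affine last row must be 0 0 0 1")
  d <- abs(det(A[1:3, 1:3]))
  if (!is.finite(d) || d < 1e-12) return("affine must be invertible")
  if (any(voxelSpacing3(A) <= 0)) return("voxel spacing must be positive")
  TRUE
})

voxelSpacing3 <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' @param dim integer(3) grid shape.
#' @param affine 4x4 voxel-to-world matrix; defaults to `spacing`-diagonal
#'   with the world origin at the grid centre.
#' @param spacing numeric(3) voxel edge lengths in mm (used only when
#'   `affine` is missing).
#' @rdname VoxelGrid-class
#' @export
VoxelGrid <- function(dim, affine = NULL, spacing = c(1, 1, 1)) {
  dim <- as.integer(dim)
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
    affine[1:3, 4] <- -spacing * (dim - 1) / 2
  }
  new("VoxelGrid", dim = dim, affine = affine)
}

#' LabelVolume: an integer-labelled 3D volume with a role table
#'
#' Carries a whole-brain parcellation (or any derived mask) together with its
#' [VoxelGrid] and a table mapping semantic role names (e.g.
#' `"corpus_callosum"`) to integer label ids. Label 0 is reserved for
#' background.
#'
#' @slot labels integer 3D array of label ids.
#' @slot grid the [VoxelGrid].
#' @slot table named integer vector, role name -> label id.
#' @export
setClass("LabelVolume",
         representation(labels = "array", grid = "VoxelGrid",
                        table = "integer"))

setValidity("LabelVolume", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3D array")
  if (!all(dim(object@labels) == object@grid@dim))
    return("labels shape disagrees with grid dim")
  if (length(object@table) &&
      (is.null(names(object@table)) || any(!nzchar(names(object@table)))))
    return("table must be a named integer vector")
  if (any(object@table == 0L))
    return("label 0 is reserved for background and cannot be a role id")
  TRUE
})

#' @param labels integer 3D array.
#' @param grid a [VoxelGrid] (defaults to 1 mm centred grid of the array's
#'   shape).
#' @param table named integer role table.
#' @rdname LabelVolume-class
#' @export
LabelVolume <- function(labels, grid = NULL, table = integer()) {
  storage.mode(labels) <- "integer"
  if (is.null(grid)) grid <- VoxelGrid(dim(labels))
  new("LabelVolume", labels = labels, grid = grid,
      table = structure(as.integer(table), names = names(table)))
}

#' StreamlineSet: polylines in world mm
#'
#' A list of streamlines, each an (n >= 2) x 3 matrix of world-mm points with
#' finite coordinates and no repeated consecutive points.
#'
#' @slot streamlines list of numeric matrices.
#' @slot provenance free-text note on where the streamlines came from.
#' @export
setClass("StreamlineSet",
         representation(streamlines = "list", provenance = "character"))

setValidity("StreamlineSet", function(object) {
  for (s in object@streamlines) {
    if (!is.matrix(s) || ncol(s) != 3L || nrow(s) < 2L)
      return("each streamline must be an (n >= 2) x 3 matrix")
    if (!all(is.finite(s)))
      return("streamline contains non-finite coordinates")
    if (any(rowSums(abs(diff(s))) == 0))
      return("streamline has repeated consecutive points")
  }
  TRUE
})

#' @param streamlines list of point matrices.
#' @param provenance character note.
#' @rdname StreamlineSet-class
#' @export
StreamlineSet <- function(streamlines = list(), provenance = "unspecified") {
  new("StreamlineSet", streamlines = streamlines, provenance = provenance)
}

#' VesselTree: parametric vessel centrelines
#'
#' @slot centrelines list of (n x 3) world-mm matrices.
#' @slot radii numeric vector of per-vessel radii in mm (all > 0).
#' @export
setClass("VesselTree", representation(centrelines = "list", radii = "numeric"))

setValidity("VesselTree", function(object) {
  if (length(object@centrelines) != length(object@radii))
    return("one radius per centreline required")
  if (length(object@radii) && any(object@radii <= 0))
    return("radii must be positive")
  for (p in object@centrelines)
    if (!is.matrix(p) || ncol(p) != 3L)
      return("each centreline must be an n x 3 matrix")
  TRUE
})

#' @param centrelines list of point matrices (world mm).
#' @param radii per-vessel radius in mm.
#' @rdname VesselTree-class
#' @export
VesselTree <- function(centrelines = list(), radii = numeric()) {
  new("VesselTree", centrelines = centrelines, radii = as.numeric(radii))
}

# ---------------------------------------------------------------------------
# Trajectories and metrics
# ---------------------------------------------------------------------------

#' Trajectory: a straight stereotactic path
#'
#' Entry point on the scalp/skull surface and target point, both world mm.
#' Direction and length are derived; length must be positive.
#'
#' @slot entry numeric(3) world mm.
#' @slot target numeric(3) world mm.
#' @export
setClass("Trajectory", representation(entry = "numeric", target = "numeric"))

setValidity("Trajectory", function(object) {
  if (length(object@entry) != 3L || length(object@target) != 3L)
    return("entry and target must be length-3 numeric")
  if (!all(is.finite(c(object@entry, object@target))))
    return("entry/target must be finite")
  if (sqrt(sum((object@target - object@entry)^2)) <= 0)
    return("trajectory length must be > 0")
  TRUE
})

#' @param entry,target world-mm points.
#' @rdname Trajectory-class
#' @export
Trajectory <- function(entry, target) {
  new("Trajectory", entry = as.numeric(entry), target = as.numeric(target))
}

#' RiskModel: vascular risk-score parameters
#'
#' The node risk is a piecewise-linear function of the distance to the
#' nearest vessel: 0 beyond `dRisk`, rising to 1 at `dSafe`, and up to 2 at
#' contact. With the default max aggregation the trajectory score is < 1
#' exactly when every sampled node is more than `dSafe` (3 mm) from
#' vasculature.
#'
#' @slot dSafe safety distance in mm (default 3).
#' @slot dRisk distance beyond which a node carries no risk, mm (default 10).
#' @slot nNodes number of nodes sampled along the trajectory (default 128).
#' @slot aggregation `"max"` (default) or `"mean"`.
#' @export
setClass("RiskModel",
         representation(dSafe = "numeric", dRisk = "numeric",
                        nNodes = "integer", aggregation = "character"))

setValidity("RiskModel", function(object) {
  if (!(object@dSafe > 0 && object@dSafe < object@dRisk))
    return("need 0 < dSafe < dRisk")
  if (object@nNodes < 2L) return("nNodes must be >= 2")
  if (!object@aggregation %in% c("max", "mean"))
    return("aggregation must be 'max' or 'mean'")
  TRUE
})

#' @param dSafe,dRisk,nNodes,aggregation see slots.
#' @rdname RiskModel-class
#' @export
RiskModel <- function(dSafe = 3, dRisk = 10, nNodes = 128L,
                      aggregation = "max") {
  new("RiskModel", dSafe = dSafe, dRisk = dRisk, nNodes = as.integer(nNodes),
      aggregation = aggregation)
}

#' TrajectoryMetrics: the five per-trajectory safety parameters
#'
#' @slot intracerebralLength mm from first brain entry to target.
#' @slot drillingAngle degrees from the skull-surface orthogonal.
#' @slot riskScore dimensionless vascular risk score.
#' @slot minVesselDistance mm, minimum over sampled nodes.
#' @slot ccFraction proportion of the catheter within the corpus callosum.
#' @export
setClass("TrajectoryMetrics",
         representation(intracerebralLength = "numeric",
                        drillingAngle = "numeric",
                        riskScore = "numeric",
                        minVesselDistance = "numeric",
                        ccFraction = "numeric"))

setValidity("TrajectoryMetrics", function(object) {
  v <- c(object@intracerebralLength, object@drillingAngle, object@riskScore,
         object@minVesselDistance, object@ccFraction)
  if (!all(is.finite(v))) return("metrics must be finite")
  if (object@ccFraction < 0 || object@ccFraction > 1)
    return("ccFraction must lie in [0, 1]")
  if (object@drillingAngle < 0 || object@drillingAngle > 90)
    return("drillingAngle must lie in [0, 90] degrees")
  TRUE
})

# ---------------------------------------------------------------------------
# Planner types
# ---------------------------------------------------------------------------

#' TrajectorySpec: one row of the default entry/target constraint table
#'
#' @slot entryRole entry gyrus role name.
#' @slot targetRole `"anterior"`, `"middle"` or `"posterior"`.
#' @slot maxLength maximum skull-surface-to-target length, mm.
#' @slot maxAngle maximum drilling angle from the orthogonal, degrees.
#' @export
setClass("TrajectorySpec",
         representation(entryRole = "character", targetRole = "character",
                        maxLength = "numeric", maxAngle = "numeric"))

setValidity("TrajectorySpec", function(object) {
  if (!object@targetRole %in% c("anterior", "middle", "posterior"))
    return("targetRole must be anterior/middle/posterior")
  if (object@maxLength <= 0) return("maxLength must be > 0")
  if (object@maxAngle <= 0 || object@maxAngle >= 90)
    return("maxAngle must lie in (0, 90) degrees")
  TRUE
})

#' @param entryRole,targetRole,maxLength,maxAngle see slots.
#' @rdname TrajectorySpec-class
#' @export
TrajectorySpec <- function(entryRole, targetRole, maxLength, maxAngle) {
  new("TrajectorySpec", entryRole = entryRole, targetRole = targetRole,
      maxLength = maxLength, maxAngle = maxAngle)
}

#' ObjectiveWeights: weights of the planner's composite objective
#'
#' Each candidate metric is min-max normalised to `[0, 1]` over the candidate
#' pool and combined as
#' `risk*n(risk) - minDistance*n(minDist) + length*n(len) + angle*n(angle) -
#' ccFraction*n(ccFrac)`; lower is better. Weights are all >= 0 and at least
#' one must be positive.
#'
#' @slot weights named numeric: `risk`, `minDistance`, `length`, `angle`,
#'   `ccFraction`.
#' @export
setClass("ObjectiveWeights", representation(weights = "numeric"))

setValidity("ObjectiveWeights", function(object) {
  need <- c("risk", "minDistance", "length", "angle", "ccFraction")
  if (!identical(sort(names(object@weights)), sort(need)))
    return(paste("weights must be named:", paste(need, collapse = ", ")))
  if (any(object@weights < 0)) return("weights must be >= 0")
  if (all(object@weights == 0)) return("at least one weight must be > 0")
  TRUE
})

#' @param risk,minDistance,length,angle,ccFraction non-negative weights.
#'   Defaults are the package's own. The callosal fraction carries the
#'   dominant weight because the object of the procedure is complete
#'   disconnection: a catheter that barely enters the callosum cannot ablate
#'   it, however avascular its track, so vascular safety ranks candidates
#'   among coverage-equivalent options rather than overriding coverage.
#' @rdname ObjectiveWeights-class
#' @export
ObjectiveWeights <- function(risk = 0.25, minDistance = 0.1, length = 0.05,
                             angle = 0.05, ccFraction = 0.55) {
  new("ObjectiveWeights",
      weights = c(risk = risk, minDistance = minDistance, length = length,
                  angle = angle, ccFraction = ccFraction))
}

#' TargetRegions: the anterior/middle/posterior callosal target regions
#'
#' @slot masks named list (`anterior`, `middle`, `posterior`) of logical 3D
#'   arrays, each a subset of the corpus-callosum mask, pairwise disjoint.
#' @slot centroids 3 x 3 matrix of per-region world-mm centroids (rows named
#'   as the masks).
#' @slot points 3 x 3 matrix of target points: centroids snapped to the
#'   nearest in-region voxel centre.
#' @slot grid the [VoxelGrid].
#' @export
setClass("TargetRegions",
         representation(masks = "list", centroids = "matrix",
                        points = "matrix", grid = "VoxelGrid"))

#' EntryRegions: the five entry-gyrus cortical masks
#'
#' @slot masks named list of logical 3D arrays (one per entry role).
#' @slot grid the [VoxelGrid].
#' @export
setClass("EntryRegions", representation(masks = "list", grid = "VoxelGrid"))

#' PlanSet: candidate lists and the selected three-trajectory plan
#'
#' @slot specs list of [TrajectorySpec] (the five default rows).
#' @slot candidates list of per-spec ranked candidate `data.frame`s (entry
#'   and target world mm, constraint values, metrics, objective).
#' @slot best `data.frame` of the best candidate per feasible spec.
#' @slot selected `data.frame` of the selected triple, one row per target
#'   role, with a `role` column.
#' @slot feasible logical per spec.
#' @slot diagnostics list of per-spec rejection counts.
#' @slot weights the [ObjectiveWeights] used.
#' @export
setClass("PlanSet",
         representation(specs = "list", candidates = "list",
                        best = "data.frame", selected = "data.frame",
                        feasible = "logical", diagnostics = "list",
                        weights = "ObjectiveWeights"))

setValidity("PlanSet", function(object) {
  if (nrow(object@selected) &&
      anyDuplicated(object@selected$role))
    return("selected triple must have exactly one trajectory per target role")
  TRUE
})

# ---------------------------------------------------------------------------
# Ablation and disconnection types
# ---------------------------------------------------------------------------

#' AblationParams: pull-back ablation parameters
#'
#' Confluence requires the pull-back spacing not to exceed the ablation
#' diameter. The default 15 mm diameter with 7 mm pull-backs is the
#' conservative setting for confluent cavities; valid diameters span the
#' 5--15 mm range achievable by clinical laser systems.
#'
#' @slot diameter ablation diameter in mm (5--15, default 15).
#' @slot spacing pull-back spacing in mm (default 7).
#' @slot clipToCC clip the cavity to the corpus callosum dilated by 2 mm
#'   (thermal margin); default `TRUE`.
#' @export
setClass("AblationParams",
         representation(diameter = "numeric", spacing = "numeric",
                        clipToCC = "logical"))

setValidity("AblationParams", function(object) {
  if (object@diameter < 5 || object@diameter > 15)
    return("diameter must lie in [5, 15] mm")
  if (!(object@spacing > 0 && object@spacing <= object@diameter))
    return("need 0 < spacing <= diameter (confluence condition)")
  TRUE
})

#' @param diameter,spacing,clipToCC see slots.
#' @rdname AblationParams-class
#' @export
AblationParams <- function(diameter = 15, spacing = 7, clipToCC = TRUE) {
  new("AblationParams", diameter = diameter, spacing = spacing,
      clipToCC = clipToCC)
}

#' AblationCavity: the simulated thermal lesion of one catheter
#'
#' @slot mask logical 3D array (single 26-connected component).
#' @slot centres n x 3 matrix of ablation centre points, world mm.
#' @slot nPullbacks number of ablations.
#' @slot grid the [VoxelGrid].
#' @export
setClass("AblationCavity",
         representation(mask = "array", centres = "matrix",
                        nPullbacks = "integer", grid = "VoxelGrid"))

setValidity("AblationCavity", function(object) {
  if (object@nPullbacks < 1L) return("nPullbacks must be >= 1")
  if (nrow(object@centres) != object@nPullbacks)
    return("one centre per pull-back required")
  if (any(object@mask) &&
      .n_components26_cpp(as.logical(object@mask), dim(object@mask)) != 1L)
    return("cavity must be a single 26-connected component (confluent)")
  TRUE
})

#' DisconnectionReport: residual interhemispheric connectivity after ablation
#'
#' All volumes are in cm^3, measured by voxel counting. The anterior and
#' splenium masks partition the corpus callosum exactly, so
#' `anteriorVolume + spleniumVolume == ccVolume`.
#'
#' @slot nInput number of input streamlines.
#' @slot nSurviving streamlines surviving the exclusion masks.
#' @slot residualMask logical 3D array of CC voxels still traversed.
#' @slot residualVolume residual connectivity volume, cm^3.
#' @slot residualAnteriorVolume residual volume within the anterior
#'   two-thirds, cm^3.
#' @slot residualInAnteriorTwoThirds flag.
#' @slot ccVolume,anteriorVolume,spleniumVolume corpus-callosum partition
#'   volumes, cm^3.
#' @slot anteriorPositionFraction anterior-posterior position (0 = most
#'   anterior) of residual anterior connectivity, `NA` when absent.
#' @slot grid the [VoxelGrid].
#' @export
setClass("DisconnectionReport",
         representation(nInput = "integer", nSurviving = "integer",
                        residualMask = "array", residualVolume = "numeric",
                        residualAnteriorVolume = "numeric",
                        residualInAnteriorTwoThirds = "logical",
                        ccVolume = "numeric", anteriorVolume = "numeric",
                        spleniumVolume = "numeric",
                        anteriorPositionFraction = "numeric",
                        grid = "VoxelGrid"))

setValidity("DisconnectionReport", function(object) {
  if (object@nSurviving > object@nInput)
    return("surviving count cannot exceed input count")
  if (abs(object@anteriorVolume + object@spleniumVolume - object@ccVolume) >
      1e-9)
    return("anterior + splenium volumes must equal the CC volume")
  TRUE
})
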