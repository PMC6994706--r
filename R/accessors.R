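# Generics, accessors and show methods.

#' @rdname VoxelGrid-class
#' @param x,object a VoxelGrid (or an object carrying one).
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname VoxelGrid-class
#' @export
setMethod("spacing", "VoxelGrid", function(x) voxelSpacing3(x@affine))

#' @rdname LabelVolume-class
#' @export
setMethod("spacing", "LabelVolume", function(x) spacing(x@grid))

#' @rdname VoxelGrid-class
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' @rdname VoxelGrid-class
#' @export
setMethod("affine", "VoxelGrid", function(x) x@affine)

#' @rdname LabelVolume-class
#' @export
setMethod("affine", "LabelVolume", function(x) x@grid@affine)

#' @rdname VoxelGrid-class
#' @export
setMethod("dim", "VoxelGrid", function(x) x@dim)

#' @rdname LabelVolume-class
#' @export
setMethod("dim", "LabelVolume", function(x) x@grid@dim)

#' @rdname LabelVolume-class
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' @rdname LabelVolume-class
#' @export
setMethod("labelArray", "LabelVolume", function(x) x@labels)

#' @rdname LabelVolume-class
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))

#' @rdname LabelVolume-class
#' @export
setMethod("labelTable", "LabelVolume", function(x) x@table)

#' Extract the binary mask of a semantic role
#'
#' Looks the role up in the volume's role table and fails loudly when the
#' role is absent.
#'
#' @param x a [LabelVolume].
#' @param role role name, e.g. `"corpus_callosum"`.
#' @return logical 3D array.
#' @export
setGeneric("roleMask", function(x, role) standardGeneric("roleMask"))

#' @rdname roleMask
#' @export
setMethod("roleMask", "LabelVolume", function(x, role) {
  if (!role %in% names(x@table))
    stop("schema role '", role, "' is not present in the label table",
         call. = FALSE)
  x@labels == x@table[[role]]
})

#' @rdname StreamlineSet-class
#' @param x a StreamlineSet.
#' @export
setMethod("length", "StreamlineSet", function(x) length(x@streamlines))

#' @rdname StreamlineSet-class
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))

#' @rdname StreamlineSet-class
#' @export
setMethod("streamlines", "StreamlineSet", function(x) x@streamlines)

#' @rdname Trajectory-class
#' @param x a Trajectory.
#' @export
setGeneric("entryPoint", function(x) standardGeneric("entryPoint"))

#' @rdname Trajectory-class
#' @export
setMethod("entryPoint", "Trajectory", function(x) x@entry)

#' @rdname Trajectory-class
#' @export
setGeneric("targetPoint", function(x) standardGeneric("targetPoint"))

#' @rdname Trajectory-class
#' @export
setMethod("targetPoint", "Trajectory", function(x) x@target)

#' @rdname Trajectory-class
#' @export
setGeneric("trajLength", function(x) standardGeneric("trajLength"))

#' @rdname Trajectory-class
#' @export
setMethod("trajLength", "Trajectory",
          function(x) sqrt(sum((x@target - x@entry)^2)))

#' @rdname Trajectory-class
#' @export
setGeneric("trajDirection", function(x) standardGeneric("trajDirection"))

#' @rdname Trajectory-class
#' @export
setMethod("trajDirection", "Trajectory",
          function(x) (x@target - x@entry) / trajLength(x))

#' @rdname TrajectoryMetrics-class
#' @param x a TrajectoryMetrics.
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' One-row data.frame view of trajectory metrics
#' @rdname TrajectoryMetrics-class
#' @export
setMethod("metricsTable", "TrajectoryMetrics", function(x) {
  data.frame(intracerebralLength = x@intracerebralLength,
             drillingAngle = x@drillingAngle,
             riskScore = x@riskScore,
             minVesselDistance = x@minVesselDistance,
             ccFraction = x@ccFraction)
})

#' @rdname PlanSet-class
#' @param x a PlanSet.
#' @export
setGeneric("selectedPlan", function(x) standardGeneric("selectedPlan"))

#' @rdname PlanSet-class
#' @export
setMethod("selectedPlan", "PlanSet", function(x) x@selected)

#' @rdname PlanSet-class
#' @export
setGeneric("bestCandidates", function(x) standardGeneric("bestCandidates"))

#' @rdname PlanSet-class
#' @export
setMethod("bestCandidates", "PlanSet", function(x) x@best)

#' Selected trajectories as a list of Trajectory objects
#' @rdname PlanSet-class
#' @export
setGeneric("selectedTrajectories",
           function(x) standardGeneric("selectedTrajectories"))

#' @rdname PlanSet-class
#' @export
setMethod("selectedTrajectories", "PlanSet", function(x) {
  sel <- x@selected
  out <- lapply(seq_len(nrow(sel)), function(i)
    Trajectory(entry = c(sel$entryX[i], sel$entryY[i], sel$entryZ[i]),
               target = c(sel$targetX[i], sel$targetY[i], sel$targetZ[i])))
  names(out) <- sel$role
  out
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@dim, collapse = " x "),
      "voxels, spacing", paste(signif(spacing(object), 4), collapse = " x "),
      "mm\n")
})

setMethod("show", "LabelVolume", function(object) {
  cat("LabelVolume:", paste(object@grid@dim, collapse = " x "),
      "voxels,", length(object@table), "roles,",
      sum(object@labels != 0L), "foreground voxels\n")
  if (length(object@table))
    cat("  roles:", paste(names(object@table), collapse = ", "), "\n")
})

setMethod("show", "StreamlineSet", function(object) {
  np <- if (length(object@streamlines))
    sum(vapply(object@streamlines, nrow, 1L)) else 0L
  cat("StreamlineSet:", length(object@streamlines), "streamlines,",
      np, "points (", object@provenance, ")\n")
})

setMethod("show", "VesselTree", function(object) {
  cat("VesselTree:", length(object@centrelines), "vessels, radii",
      paste(signif(range(c(object@radii, NA), na.rm = TRUE), 3),
            collapse = "-"), "mm\n")
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: entry (%.1f, %.1f, %.1f) -> target (%.1f, %.1f, %.1f) mm, length %.1f mm\n",
              object@entry[1], object@entry[2], object@entry[3],
              object@target[1], object@target[2], object@target[3],
              trajLength(object)))
})

setMethod("show", "TrajectoryMetrics", function(object) {
  cat(sprintf(paste0("TrajectoryMetrics: intracerebral %.1f mm, angle %.1f deg, ",
                     "risk %.3f, min vessel distance %.2f mm, CC fraction %.2f\n"),
              object@intracerebralLength, object@drillingAngle,
              object@riskScore, object@minVesselDistance, object@ccFraction))
})

setMethod("show", "TrajectorySpec", function(object) {
  cat(sprintf("TrajectorySpec: %s -> %s target, max length %g mm, max angle %g deg\n",
              object@entryRole, object@targetRole, object@maxLength,
              object@maxAngle))
})

setMethod("show", "PlanSet", function(object) {
  cat("PlanSet:", sum(object@feasible), "of", length(object@specs),
      "specs feasible;", nrow(object@selected), "trajectories selected\n")
  if (nrow(object@selected)) {
    sel <- object@selected
    for (i in seq_len(nrow(sel)))
      cat(sprintf("  %-9s %-24s length %6.1f mm, angle %5.1f deg, risk %5.3f, minDist %5.2f mm\n",
                  sel$role[i], sel$entryRole[i], sel$length[i], sel$angle[i],
                  sel$riskScore[i], sel$minVesselDistance[i]))
  }
})

setMethod("show", "AblationCavity", function(object) {
  cat("AblationCavity:", object@nPullbacks, "pull-backs,",
      sum(object@mask), "voxels\n")
})

setMethod("show", "DisconnectionReport", function(object) {
  cat("DisconnectionReport:\n")
  cat(sprintf("  streamlines: %d in, %d surviving\n", object@nInput,
              object@nSurviving))
  cat(sprintf("  corpus callosum %.2f cm^3 = anterior two-thirds %.2f + splenium %.2f\n",
              object@ccVolume, object@anteriorVolume, object@spleniumVolume))
  cat(sprintf("  residual connectivity %.3f cm^3 (anterior two-thirds %.3f cm^3)\n",
              object@residualVolume, object@residualAnteriorVolume))
  cat("  residual in anterior two-thirds:",
      object@residualInAnteriorTwoThirds, "\n")
  if (is.finite(object@anteriorPositionFraction))
    cat(sprintf("  anterior residual AP position fraction: %.2f\n",
                object@anteriorPositionFraction))
})
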