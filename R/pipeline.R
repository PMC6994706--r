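# End-to-end pipeline: inputs (or phantom) -> targets -> plan -> ablation ->
# disconnection, with every intermediate written to disk and a single
# structured-text (JSON) plan report that round-trips losslessly.

#' PlanDocument: the serialisable run report
#'
#' One document per run: the configuration echo (provenance), the selected
#' trajectories with their metrics, the ablation parameters and per-catheter
#' pull-back counts, and the disconnection summary. Round-trips through JSON
#' via [writePlanReport()] / [readPlanReport()].
#'
#' @slot config list: configuration echo.
#' @slot selected data.frame of selected trajectories and metrics.
#' @slot ablation list: parameters and pull-back counts.
#' @slot disconnection list: residual-connectivity summary.
#' @slot status `"complete"` or `"partially-infeasible"`.
#' @export
setClass("PlanDocument",
         representation(config = "list", selected = "data.frame",
                        ablation = "list", disconnection = "list",
                        status = "character"))

setMethod("show", "PlanDocument", function(object) {
  cat("PlanDocument (", object@status, "): ", nrow(object@selected),
      " trajectories\n", sep = "")
  if (length(object@disconnection))
    cat(sprintf("  residual anterior two-thirds volume: %.3f cm^3 (%d/%d streamlines survive)\n",
                object@disconnection$residualAnteriorVolume,
                object@disconnection$nSurviving,
                object@disconnection$nInput))
})

#' Write / read a plan report
#'
#' JSON with full numeric precision; `readPlanReport()` reconstructs an
#' equal [PlanDocument].
#'
#' @param doc a [PlanDocument].
#' @param path output file.
#' @export
writePlanReport <- function(doc, path) {
  payload <- list(format = "callosoplan-report", version = 1L,
                  status = doc@status, config = doc@config,
                  selected = doc@selected, ablation = doc@ablation,
                  disconnection = doc@disconnection)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname writePlanReport
#' @export
readPlanReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(x$format, "callosoplan-report"))
    stop("not a callosoplan report: ", path, call. = FALSE)
  sel <- if (is.data.frame(x$selected)) x$selected else
    as.data.frame(x$selected)
  disc <- as.list(x$disconnection)
  if (length(disc) && is.null(disc$anteriorPositionFraction))
    disc$anteriorPositionFraction <- NA_real_  # JSON null round trip
  new("PlanDocument", config = as.list(x$config), selected = sel,
      ablation = as.list(x$ablation),
      disconnection = disc, status = x$status)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full planning pipeline
#'
#' Either consumes a parcellation / schema / vessel mask / streamline file
#' set, or self-generates every input from the digital head phantom. Writes
#' all intermediate volumes, the candidate and metrics tables and the plan
#' report into `outDir`.
#'
#' @param outDir output directory (created if needed).
#' @param phantom `NULL`, `TRUE` (default phantom) or a [PhantomConfig]:
#'   self-generate inputs.
#' @param parcellation,schema,vessels,streamlines input paths (ignored in
#'   phantom mode).
#' @param seed global seed for the stochastic components (phantom
#'   streamlines).
#' @param specs,weights,model,strides,params,fraction pipeline parameters,
#'   see [planCallosotomy()], [AblationParams()],
#'   [splitAnteriorTwoThirds()].
#' @param avoidMask optional hard-avoidance mask forwarded to the planner.
#' @param verbose log stage timings to stderr.
#' @return a list with `document` (the [PlanDocument]), `plan` (the
#'   [PlanSet]), `report` (the [DisconnectionReport]) and `paths` of the
#'   written artifacts, invisibly.
#' @export
runPipeline <- function(outDir, phantom = NULL, parcellation = NULL,
                        schema = NULL, vessels = NULL, streamlines = NULL,
                        seed = 7L, specs = defaultTrajectorySpecs(),
                        weights = ObjectiveWeights(), model = RiskModel(),
                        strides = c(entry = 2L, target = 2L),
                        params = AblationParams(), fraction = 2 / 3,
                        avoidMask = NULL, verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose)
    message(sprintf("[callosoplan %6.1fs] ", proc.time()[["elapsed"]] - t0),
            ...)
  paths <- list()

  if (isTRUE(phantom)) phantom <- phantomConfig(seed = seed)
  if (!is.null(phantom)) {
    say("generating phantom")
    ph <- .stage("phantom", makeHeadPhantom(phantom))
    vol <- ph$volume
    vmaskVol <- .stage("phantom", rasteriseVessels(ph$vessels, vol@grid))
    streams <- .stage("phantom", makeInterhemisphericStreamlines(
      vol, n = phantom@nStreamlines, seed = seed))
    paths$parcellation <- file.path(outDir, "parcellation.nii.gz")
    paths$vessels <- file.path(outDir, "vessels.nii.gz")
    paths$streamlines <- file.path(outDir, "streamlines.tck")
    paths$schema <- file.path(outDir, "schema.json")
    writeLabelVolume(vol, paths$parcellation)
    writeLabelVolume(vmaskVol, paths$vessels)
    writeStreamlines(streams, paths$streamlines)
    writeLabelSchema(vol@table, paths$schema)
    configEcho <- list(mode = "phantom", seed = seed,
                       phantomDim = phantom@dim,
                       nStreamlines = phantom@nStreamlines,
                       dominance = phantom@dominance)
  } else {
    say("reading inputs")
    if (is.null(parcellation) || !file.exists(parcellation))
      .stage("volio", stop("parcellation volume not found"))
    if (is.null(vessels) || !file.exists(vessels))
      .stage("riskmetrics", stop("vessel segmentation not found (required ",
                                 "for the risk score)"))
    sch <- if (is.character(schema)) readLabelSchema(schema) else schema
    vol <- .stage("volio", readLabelVolume(parcellation, sch))
    vmaskVol <- .stage("volio", readLabelVolume(vessels))
    streams <- if (!is.null(streamlines))
      .stage("volio", readStreamlines(streamlines))
    else StreamlineSet()
    paths$parcellation <- parcellation
    paths$vessels <- vessels
    configEcho <- list(mode = "files", parcellation = parcellation,
                       vessels = vessels,
                       streamlines = streamlines %||% NA_character_,
                       seed = seed)
  }
  configEcho$weights <- as.list(weights@weights)
  configEcho$riskModel <- list(dSafe = model@dSafe, dRisk = model@dRisk,
                               nNodes = model@nNodes,
                               aggregation = model@aggregation)
  configEcho$ablation <- list(diameter = params@diameter,
                              spacing = params@spacing,
                              clipToCC = params@clipToCC)
  configEcho$strides <- as.list(strides)
  configEcho$anteriorFraction <- fraction

  vmask <- vmaskVol@labels != 0L
  ccMask <- roleMask(vol, "corpus_callosum")

  say("generating targets")
  targets <- .stage("targetgen", generateTargets(vol))
  utils::write.csv(data.frame(region = rownames(targets@centroids),
                              targets@centroids),
                   file.path(outDir, "target_centroids.csv"),
                   row.names = FALSE)
  for (r in names(targets@masks))
    writeMaskVolume(targets@masks[[r]], vol@grid,
                    file.path(outDir, paste0("target_", r, ".nii.gz")))

  say("planning trajectories")
  plan <- .stage("planner", planCallosotomy(vol, vmask, specs = specs,
                                            weights = weights, model = model,
                                            strides = strides,
                                            avoidMask = avoidMask,
                                            targets = targets))
  for (i in seq_along(plan@candidates))
    if (nrow(plan@candidates[[i]]))
      utils::write.csv(plan@candidates[[i]],
                       file.path(outDir, sprintf("candidates_spec%d.csv", i)),
                       row.names = FALSE)
  utils::write.csv(plan@best, file.path(outDir, "best_candidates.csv"),
                   row.names = FALSE)
  utils::write.csv(plan@selected, file.path(outDir, "selected_plan.csv"),
                   row.names = FALSE)
  status <- if (all(plan@feasible)) "complete" else "partially-infeasible"
  if (!all(plan@feasible))
    warning("infeasible specs: ",
            paste(names(plan@candidates)[!plan@feasible], collapse = ", "),
            call. = FALSE)

  report <- NULL
  disc <- list()
  ablation <- list(diameter = params@diameter, spacing = params@spacing,
                   clipToCC = params@clipToCC)
  if (nrow(plan@selected)) {
    say("simulating ablation cavities")
    comb <- .stage("ablation", combinedCavity(plan, ccMask, vol@grid,
                                              params))
    ablation$pullbacks <- lapply(comb$cavities,
                                 function(cv) cv@nPullbacks)
    writeMaskVolume(comb$mask, vol@grid,
                    file.path(outDir, "cavity_combined.nii.gz"))
    for (r in names(comb$cavities))
      writeMaskVolume(comb$cavities[[r]]@mask, vol@grid,
                      file.path(outDir, paste0("cavity_", r, ".nii.gz")))

    if (length(streams)) {
      say("assessing disconnection")
      report <- .stage("disconnection",
                       assessPlan(plan, streams, ccMask, vol@grid,
                                  params = params, fraction = fraction,
                                  cavityMask = comb$mask))
      writeMaskVolume(report@residualMask, vol@grid,
                      file.path(outDir, "residual_connectivity.nii.gz"))
      disc <- list(nInput = report@nInput, nSurviving = report@nSurviving,
                   residualVolume = report@residualVolume,
                   residualAnteriorVolume = report@residualAnteriorVolume,
                   residualInAnteriorTwoThirds =
                     report@residualInAnteriorTwoThirds,
                   ccVolume = report@ccVolume,
                   anteriorVolume = report@anteriorVolume,
                   spleniumVolume = report@spleniumVolume,
                   anteriorPositionFraction = report@anteriorPositionFraction)
    }
  }

  doc <- new("PlanDocument", config = configEcho, selected = plan@selected,
             ablation = ablation, disconnection = disc, status = status)
  paths$report <- file.path(outDir, "plan_report.json")
  writePlanReport(doc, paths$report)
  say("done (", status, ")")
  invisible(list(document = doc, plan = plan, report = report,
                 paths = paths))
}
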