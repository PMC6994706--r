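# Automatic target-region generation: morphological dilations and Boolean
# operations on the parcellation.
#
# The subcallosal gyrus and the anterior, middle and posterior cingulate are
# dilated by 7 mm; the overlap of each adjacent pair is intersected with the
# (undilated) corpus callosum, yielding the anterior, middle and posterior
# callosal target regions. The pairing (subcallosal, anterior) -> anterior,
# (anterior, middle) -> middle, (middle, posterior) -> posterior is the only
# arrangement producing three anterior-posterior-ordered regions; voxels
# claimed by two regions are assigned to the more anterior one so the
# regions stay disjoint.

#' Generate the anterior, middle and posterior callosal target regions
#'
#' @param parcellation a [LabelVolume] whose table resolves
#'   `corpus_callosum`, `subcallosal_gyrus`, `anterior_cingulate`,
#'   `middle_cingulate` and `posterior_cingulate`.
#' @param radiusMm dilation radius in mm (default 7).
#' @return a [TargetRegions] object; region masks are subsets of the
#'   corpus-callosum mask, pairwise disjoint and non-empty.
#' @export
generateTargets <- function(parcellation, radiusMm = 7) {
  vol <- parcellation
  grid <- vol@grid
  cc <- roleMask(vol, "corpus_callosum")
  bands <- list(subcallosal = roleMask(vol, "subcallosal_gyrus"),
                anterior = roleMask(vol, "anterior_cingulate"),
                middle = roleMask(vol, "middle_cingulate"),
                posterior = roleMask(vol, "posterior_cingulate"))
  dil <- lapply(bands, dilateMask, grid = grid, radiusMm = radiusMm)
  pairs <- list(anterior = c("subcallosal", "anterior"),
                middle = c("anterior", "middle"),
                posterior = c("middle", "posterior"))
  masks <- lapply(names(pairs), function(region) {
    p <- pairs[[region]]
    m <- dil[[p[1]]] & dil[[p[2]]] & cc
    if (!any(m)) {
      # diagnostic: smallest radius that would bridge the gap via this pair
      dA <- distanceTransform(bands[[p[1]]], grid)
      dB <- distanceTransform(bands[[p[2]]], grid)
      gap <- min(pmax(dA[cc], dB[cc]))
      stop("target generation: region '", region, "' is empty after ",
           radiusMm, " mm dilation and intersection (achieved dilation gap ",
           signif(gap, 4), " mm)", call. = FALSE)
    }
    m
  })
  names(masks) <- names(pairs)
  # disjointness: overlap voxels go to the more anterior region
  masks$middle <- masks$middle & !masks$anterior
  masks$posterior <- masks$posterior & !masks$anterior & !masks$middle
  for (region in names(masks))
    if (!any(masks[[region]]))
      stop("target generation: region '", region,
           "' is empty after disjointness enforcement", call. = FALSE)
  centroids <- do.call(rbind, lapply(masks, function(m)
    colMeans(maskWorldCoords(m, grid))))
  points <- do.call(rbind, lapply(names(masks), function(region) {
    co <- maskWorldCoords(masks[[region]], grid)
    co[which.min(colSums((t(co) - centroids[region, ])^2)), ]
  }))
  dimnames(centroids) <- dimnames(points) <-
    list(names(masks), c("x", "y", "z"))
  new("TargetRegions", masks = masks, centroids = centroids, points = points,
      grid = grid)
}

#' Extract the five entry-gyrus masks
#'
#' Returns the cortical label masks of the five entry regions of the default
#' constraint table, unmodified.
#'
#' @param parcellation a [LabelVolume] resolving all five entry roles.
#' @return an [EntryRegions] object.
#' @export
extractEntryRegions <- function(parcellation) {
  masks <- lapply(entryRoleNames(), function(role) {
    m <- roleMask(parcellation, role)
    if (!any(m))
      stop("entry region '", role, "' is empty", call. = FALSE)
    m
  })
  names(masks) <- entryRoleNames()
  new("EntryRegions", masks = masks, grid = parcellation@grid)
}

setMethod("show", "TargetRegions", function(object) {
  cat("TargetRegions:\n")
  for (r in names(object@masks))
    cat(sprintf("  %-9s %5d voxels, centroid (%.1f, %.1f, %.1f) mm\n", r,
                sum(object@masks[[r]]), object@centroids[r, 1],
                object@centroids[r, 2], object@centroids[r, 3]))
})

setMethod("show", "EntryRegions", function(object) {
  cat("EntryRegions:", paste(sprintf("%s (%d)", names(object@masks),
                                     vapply(object@masks, sum, 1L)),
                             collapse = ", "), "\n")
})
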