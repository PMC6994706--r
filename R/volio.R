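# Coordinate conventions and label-volume I/O.
#
# Voxel indexing is 0-based and addresses voxel centres; the affine maps
# 0-based indices to world mm. R arrays are 1-based, so lookups add 1 at the
# voxel boundary and nowhere else.

#' Convert between world mm and continuous voxel indices
#'
#' `worldToVoxel()` applies the inverse of the grid affine, `voxelToWorld()`
#' the affine itself. Voxel indices are 0-based and continuous; a voxel's
#' index addresses its centre. The two functions are inverse to within
#' 1e-9 relative error.
#'
#' @param grid a [VoxelGrid] (or [LabelVolume], whose grid is used).
#' @param points numeric(3) or an n x 3 matrix.
#' @return matrix (or vector) of the same shape as `points`.
#' @export
worldToVoxel <- function(grid, points) {
  .applyAffine(solve(.gridOf(grid)@affine), points)
}

#' @rdname worldToVoxel
#' @export
voxelToWorld <- function(grid, points) {
  .applyAffine(.gridOf(grid)@affine, points)
}

.gridOf <- function(x) {
  if (is(x, "LabelVolume")) x@grid
  else if (is(x, "VoxelGrid")) x
  else stop("expected a VoxelGrid or LabelVolume")
}

.applyAffine <- function(A, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1) else as.matrix(points)
  stopifnot(ncol(p) == 3L)
  out <- sweep(p %*% t(A[1:3, 1:3]), 2, A[1:3, 4], "+")
  if (vec) drop(out) else out
}

# world-mm coordinates of all TRUE voxels of a mask (n x 3)
maskWorldCoords <- function(mask, grid) {
  idx <- which(mask)
  if (!length(idx)) return(matrix(numeric(), 0, 3))
  voxelToWorld(grid, arrayInd(idx, dim(mask)) - 1)
}

maskVolumeCm3 <- function(mask, grid) {
  sum(mask) * prod(spacing(.gridOf(grid))) / 1000
}

#' Read a labelled parcellation volume
#'
#' Reads a 3D integer NIfTI-1 volume and attaches a role schema. Every role
#' in the schema must map to a label id actually present in the volume;
#' otherwise a schema-validation error naming the role is raised.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param schema named integer vector (role -> label id) or path to a JSON
#'   schema file as written by [writeLabelSchema()].
#' @return a [LabelVolume] with the affine taken from the file header.
#' @export
readLabelVolume <- function(path, schema = integer()) {
  if (is.character(schema)) schema <- readLabelSchema(schema)
  nii <- readNifti(path)
  if (!all(nii$data == round(nii$data)))
    stop("volume at '", path, "' contains non-integer data", call. = FALSE)
  vol <- LabelVolume(array(as.integer(round(nii$data)), dim(nii$data)),
                     grid = VoxelGrid(dim(nii$data), affine = nii$affine),
                     table = schema)
  present <- unique(as.vector(vol@labels))
  for (role in names(schema))
    if (!schema[[role]] %in% present)
      stop("schema validation: role '", role, "' (label ", schema[[role]],
           ") is absent from the volume", call. = FALSE)
  vol
}

#' Write a label volume as NIfTI-1
#'
#' The header affine is the volume's affine (stored through the sform, which
#' NIfTI-1 represents exactly in single precision).
#'
#' @param vol a [LabelVolume].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(vol, path) {
  writeNifti(vol@labels, vol@grid@affine, path, datatype = "int32")
  invisible(path)
}

#' Write a binary mask as NIfTI-1
#'
#' @param mask logical 3D array.
#' @param grid the [VoxelGrid] the mask lives on.
#' @param path output path.
#' @export
writeMaskVolume <- function(mask, grid, path) {
  writeNifti(array(as.integer(mask), dim(mask)), .gridOf(grid)@affine, path,
             datatype = "uint8")
  invisible(path)
}

#' Read or write a label schema (role -> label id map)
#'
#' Schemas are stored as a flat JSON object, e.g.
#' `{"corpus_callosum": 5, ...}`.
#'
#' @param path JSON file path.
#' @return named integer vector.
#' @export
readLabelSchema <- function(path) {
  x <- jsonlite::read_json(path)
  structure(vapply(x, function(v) as.integer(v), 1L), names = names(x))
}

#' @param schema named integer vector.
#' @rdname readLabelSchema
#' @export
writeLabelSchema <- function(schema, path) {
  jsonlite::write_json(as.list(as.integer(schema) |>
                                 stats::setNames(names(schema))),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Composite brain mask for intracerebral measurements
#'
#' The union of all intracranial roles (brain tissue, ventricles, corpus
#' callosum, subcallosal gyrus, cingulate subregions and the entry gyri) --
#' everything inside the skull. Roles absent from the table are skipped
#' except `"brain"`, which is required.
#'
#' @param vol a [LabelVolume].
#' @return logical 3D array.
#' @export
brainCompositeMask <- function(vol) {
  roles <- c("brain", "ventricles", "corpus_callosum", "subcallosal_gyrus",
             "anterior_cingulate", "middle_cingulate", "posterior_cingulate",
             entryRoleNames())
  if (!"brain" %in% names(vol@table))
    stop("role 'brain' is required in the schema", call. = FALSE)
  ids <- vol@table[intersect(roles, names(vol@table))]
  array(vol@labels %in% ids, dim(vol@labels))
}

#' Head mask (all non-background labels)
#'
#' The outer boundary of this mask is the scalp surface on which trajectory
#' entry points live.
#'
#' @param vol a [LabelVolume].
#' @export
headMask <- function(vol) vol@labels != 0L

entryRoleNames <- function() {
  c("right_superior_frontal", "right_superior_parietal", "right_angular",
    "left_superior_frontal", "left_middle_frontal")
}
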