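# Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz).
#
# Only what this package needs: 3D volumes, the common datatypes, sform (and
# qform fallback) affines, little- or big-endian input, little-endian output
# with the affine carried in the sform rows. No R NIfTI package is available
# in the target environment, hence the hand-rolled implementation.

.niftiDatatypes <- list(
  "2"   = list(what = "integer", size = 1L, signed = FALSE, name = "uint8"),
  "4"   = list(what = "integer", size = 2L, signed = TRUE,  name = "int16"),
  "8"   = list(what = "integer", size = 4L, signed = TRUE,  name = "int32"),
  "16"  = list(what = "double",  size = 4L, signed = TRUE,  name = "float32"),
  "64"  = list(what = "double",  size = 8L, signed = TRUE,  name = "float64"),
  "256" = list(what = "integer", size = 1L, signed = TRUE,  name = "int8"),
  "512" = list(what = "integer", size = 2L, signed = FALSE, name = "uint16")
)

.niftiOpen <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume (internal)
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array) and `affine` (4x4 voxel->world).
#' @keywords internal
readNifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- .niftiOpen(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, 4, endian = endian)
  if (!identical(sizeof_hdr, 348L)) {
    endian <- "big"
    close(con)
    con <- .niftiOpen(path, "rb")
    on.exit(close(con), add = FALSE)
    sizeof_hdr <- readBin(con, "integer", 1, 4, endian = endian)
    if (!identical(sizeof_hdr, 348L))
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
  }
  readBin(con, "raw", 35)                     # data_type..dim_info
  dims <- readBin(con, "integer", 8, 2, endian = endian)
  readBin(con, "numeric", 3, 4, endian = endian)       # intent_p1..p3
  readBin(con, "integer", 1, 2, endian = endian)       # intent_code
  datatype <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "integer", 2, 2, endian = endian)       # bitpix, slice_start
  pixdim <- readBin(con, "numeric", 8, 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, 4, endian = endian)
  readBin(con, "raw", 2 + 1 + 1)              # slice_end, slice_code, xyzt
  readBin(con, "numeric", 4, 4, endian = endian)       # cal/slice_dur/toffset
  readBin(con, "integer", 2, 4, endian = endian)       # glmax, glmin
  readBin(con, "raw", 80 + 24)                # descrip, aux_file
  qform_code <- readBin(con, "integer", 1, 2, endian = endian)
  sform_code <- readBin(con, "integer", 1, 2, endian = endian)
  quat <- readBin(con, "numeric", 6, 4, endian = endian)  # b c d, offsets
  srow <- matrix(readBin(con, "numeric", 12, 4, endian = endian), 3, 4,
                 byrow = TRUE)
  readBin(con, "raw", 16)                     # intent_name
  magic <- rawToChar(readBin(con, "raw", 4), multiple = FALSE)
  if (!startsWith(magic, "n+1") && !startsWith(magic, "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)

  ndim <- dims[1]
  if (ndim < 3L) stop("expected a 3D volume in ", path, call. = FALSE)
  shape <- dims[2:4]
  nextra <- if (ndim > 3L) prod(pmax(dims[5:(1 + ndim)], 1L)) else 1L
  if (nextra != 1L)
    stop("expected a single 3D volume, got ", ndim, "D data", call. = FALSE)

  dt <- .niftiDatatypes[[as.character(datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)
  # skip to vox_offset (we are at byte 352 incl. the 4-byte extension flag
  # already consumed as part of magic? no: magic ends at 348) -> consume
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  data <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(data) != n)
    stop("truncated NIfTI data in ", path, call. = FALSE)
  if (dt$name == "uint16") data[data < 0] <- data[data < 0] + 65536
  data <- as.numeric(data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter

  aff <- if (sform_code > 0L) {
    rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    .qformAffine(quat, pixdim)
  } else {
    A <- diag(4); diag(A)[1:3] <- ifelse(pixdim[2:4] > 0, pixdim[2:4], 1); A
  }
  list(data = array(data, shape), affine = aff)
}

.qformAffine <- function(quat, pixdim) {
  b <- quat[1]; c <- quat[2]; d <- quat[3]
  a <- sqrt(max(0, 1 - b^2 - c^2 - d^2))
  R <- matrix(c(a*a+b*b-c*c-d*d, 2*(b*c-a*d),     2*(b*d+a*c),
                2*(b*c+a*d),     a*a+c*c-b*b-d*d, 2*(c*d-a*b),
                2*(b*d-a*c),     2*(c*d+a*b),     a*a+d*d-b*b-c*c),
              3, 3, byrow = TRUE)
  qfac <- if (pixdim[1] < 0) -1 else 1
  sp <- ifelse(pixdim[2:4] > 0, pixdim[2:4], 1)
  R <- R %*% diag(c(sp[1], sp[2], qfac * sp[3]))
  rbind(cbind(R, quat[4:6]), c(0, 0, 0, 1))
}

#' Write a NIfTI-1 volume (internal)
#'
#' Writes little-endian single-file NIfTI-1 with the affine in the sform
#' rows (sform_code 2, qform_code 0).
#'
#' @param data numeric/integer 3D array.
#' @param affine 4x4 voxel->world matrix.
#' @param path output path (`.gz` suffix gives gzip compression).
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @keywords internal
writeNifti <- function(data, affine, path,
                       datatype = c("int32", "uint8", "int16", "float32",
                                    "float64")) {
  datatype <- match.arg(datatype)
  code <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
            float64 = 64L)[[datatype]]
  size <- c(uint8 = 1L, int16 = 2L, int32 = 4L, float32 = 4L,
            float64 = 8L)[[datatype]]
  shape <- dim(data)
  stopifnot(length(shape) == 3L)
  con <- tryCatch(.niftiOpen(path, "wb"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  wI <- function(x, s) writeBin(as.integer(x), con, s, endian = "little")
  wF <- function(x) writeBin(as.numeric(x), con, 4L, endian = "little")
  wI(348L, 4)                                  # sizeof_hdr
  writeBin(raw(35), con)                       # data_type..dim_info
  wI(c(3L, shape, 1L, 1L, 1L, 1L), 2)          # dim
  wF(c(0, 0, 0))                               # intent_p
  wI(0L, 2)                                    # intent_code
  wI(code, 2)                                  # datatype
  wI(8L * size, 2)                             # bitpix
  wI(0L, 2)                                    # slice_start
  wF(c(1, voxelSpacing3(affine), 0, 0, 0, 0))  # pixdim (qfac = 1)
  wF(352)                                      # vox_offset
  wF(c(1, 0))                                  # scl_slope, scl_inter
  wI(0L, 2); writeBin(raw(1), con)             # slice_end, slice_code
  writeBin(as.raw(2L), con)                    # xyzt_units: mm
  wF(c(0, 0, 0, 0))                            # cal_max..toffset
  wI(c(0L, 0L), 4)                             # glmax, glmin
  writeBin(raw(80 + 24), con)                  # descrip, aux_file
  wI(0L, 2)                                    # qform_code
  wI(2L, 2)                                    # sform_code (aligned)
  wF(c(0, 0, 0))                               # quatern b c d
  wF(c(0, 0, 0))                               # qoffset
  wF(t(affine[1:3, , drop = FALSE]))           # srow_x, srow_y, srow_z
  writeBin(raw(16), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)                        # extension flag
  vals <- as.vector(data)
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.numeric(vals), con, size, endian = "little")
  } else {
    writeBin(as.integer(vals), con, size, endian = "little")
  }
  invisible(path)
}
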