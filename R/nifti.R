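# Minimal NIfTI-1 I/O.
#
# The pipeline only needs axis-aligned scale+translation geometry, which the
# sform row matrix encodes exactly; oblique affines are rejected with a clear
# error. Both .nii and .nii.gz are handled (gzfile sniffs the magic bytes).
# Supported on read: uint8, int16, int32, float32, float64; writes are uint8
# for binary masks and float32 otherwise.

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE))   # float64

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii` or `.nii.gz` file into a [voxel_grid()]. The affine must be
#' axis-aligned (pure per-axis scaling plus translation); world coordinates
#' are taken from the sform when present (`sform_code > 0`), otherwise from
#' `pixdim` and `qoffset`.
#'
#' @param path file path.
#' @return a [voxel_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("corrupt NIfTI file (truncated header): ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  dim_field <- rd(40L, "integer", 8L, 2L)
  ndim <- dim_field[1]
  if (ndim < 3L) stop("NIfTI volume must be at least 3-D: ", path)
  dims <- dim_field[2:4]
  if (ndim > 3L && any(dim_field[5:(1 + ndim)] > 1L))
    stop("4-D+ NIfTI volumes are not supported: ", path)
  datatype <- rd(70L, "integer", 1L, 2L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, ": ", path)
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  qform_code <- rd(252L, "integer", 1L, 2L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  qoffset <- rd(268L, "double", 3L, 4L)
  srow <- matrix(rd(280L, "double", 12L, 4L), nrow = 3, byrow = TRUE)

  if (sform_code > 0L) {
    lin <- srow[, 1:3]
    if (max(abs(lin - diag(diag(lin)))) > 1e-5 * max(abs(lin), 1))
      stop("oblique/rotated NIfTI affine not supported (axis-aligned only): ",
           path)
    spacing <- abs(diag(lin))
    if (any(diag(lin) < 0))
      stop("axis-flipping NIfTI affine not supported: ", path)
    origin <- srow[, 4]
  } else {
    spacing <- abs(pixdim[2:4])
    origin <- if (qform_code > 0L) qoffset else c(0, 0, 0)
  }
  if (any(spacing <= 0)) stop("non-positive voxel spacing in NIfTI header: ", path)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n_vox) stop("corrupt NIfTI file (truncated data): ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  voxel_grid(array(as.numeric(vals), dim = dims), spacing = spacing,
             origin = origin)
}

#' Write a NIfTI-1 volume
#'
#' Writes a [voxel_grid()] as a single-file NIfTI-1 (`.nii` or `.nii.gz`,
#' chosen by extension). Binary masks are stored as uint8 and round-trip
#' bit-exactly; other volumes are stored as float32. The sform encodes
#' spacing and origin.
#'
#' @param grid a [voxel_grid()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  binary <- is_binary_grid(grid)
  datatype <- if (binary) 2L else 16L
  bitpix <- if (binary) 8L else 32L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")

  w(348L, 4L)                                   # sizeof_hdr
  w(raw(36L), 1L)                               # data_type..dim_info
  w(as.integer(c(3L, grid$dims, 1L, 1L, 1L, 1L)), 2L)   # dim[8]
  w(raw(14L), 1L)                               # intent_p1..intent_code
  w(as.integer(c(datatype, bitpix, 0L)), 2L)    # datatype, bitpix, slice_start
  w(c(1, grid$spacing, 0, 0, 0, 0), 4L)         # pixdim[8] (qfac = 1)
  w(352, 4L)                                    # vox_offset
  w(c(1, 0), 4L)                                # scl_slope, scl_inter
  w(raw(4L), 1L)                                # slice_end(2), slice_code, xyzt_units
  w(c(0, 0, 0), 4L)                             # cal_max, cal_min, slice_duration
  w(c(0), 4L)                                   # toffset
  w(c(0L, 0L), 4L)                              # glmax, glmin
  w(raw(104L), 1L)                              # descrip[80] + aux_file[24]
  w(c(0L, 1L), 2L)                              # qform_code, sform_code
  w(c(0, 0, 0, 0, 0, 0), 4L)                    # quatern_b/c/d + qoffset_x/y/z
  srow <- cbind(diag(grid$spacing), grid$origin)
  w(as.numeric(t(srow)), 4L)                    # srow_x/y/z
  w(raw(16L), 1L)                               # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)   # magic
  w(raw(4L), 1L)                                # extension flag

  vals <- as.vector(grid$values)
  if (binary) {
    writeBin(as.raw(vals), con)
  } else {
    w(as.numeric(vals), 4L)
  }
  invisible(path)
}
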