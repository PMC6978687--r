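# Minimal NIfTI-1 reader/writer.
#
# Only the single-file (.nii / .nii.gz) variant is supported, with the
# datatypes that feature maps and label volumes actually use. The sform
# (srow_*) carries the grid-to-world affine; voxel index (i-1, j-1, k-1) maps
# to world coordinates, matching the NIfTI convention.

NIFTI_DATATYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)   # float64
)

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into an
#' array plus its voxel spacing and grid-to-world affine. 3D volumes return a
#' 3D array; a 4D file returns a 4D array.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a list with elements `data` (array), `spacing` (mm triple) and
#'   `affine` (4x4 matrix mapping 0-based voxel indices to world mm).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("NIfTI file not found: %s", path)
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stopf("truncated NIfTI header in %s", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stopf("%s is not a NIfTI-1 file", path)
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n = n, size = 2L, endian = endian)
  rd_i32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "integer", n = n, size = 4L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "double", n = n, size = 4L, endian = endian)

  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stopf("unsupported NIfTI magic '%s' in %s", magic, path)
  if (magic == "ni1") stopf("two-file NIfTI (.hdr/.img) is not supported: %s", path)

  dim_field <- rd_i16(40L, 8L)
  ndim <- dim_field[1]
  if (ndim < 3L || ndim > 4L) stopf("%s: only 3D or 4D NIfTI supported (ndim = %d)", path, ndim)
  dims <- dim_field[2:(1 + ndim)]
  datatype <- rd_i16(70L, 1L)
  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) stopf("%s: unsupported NIfTI datatype code %d", path, datatype)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  sform_code <- rd_i16(254L, 1L)
  srow <- rbind(rd_f32(280L, 4L), rd_f32(296L, 4L), rd_f32(312L, 4L))

  spacing <- abs(pixdim[2:4])
  if (sform_code > 0L) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else {
    affine <- diag(c(spacing, 1))
  }

  skip <- round(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  values <- readBin(con, dt$what, n = n_vox, size = dt$size,
                    signed = dt$signed, endian = endian)
  if (length(values) != n_vox) stopf("%s: expected %d voxels, read %d", path, n_vox, length(values))
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    values <- values * scl_slope + scl_inter
  }
  list(data = array(values, dim = dims), spacing = spacing, affine = affine)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D or 4D array as a single-file NIfTI-1 image with the sform
#' affine set. Integer arrays are stored as int32, doubles as float32 (or
#' float64 when `datatype = "float64"`).
#'
#' @param data numeric/integer 3D or 4D array.
#' @param path output path (`.nii`, or `.nii.gz` for gzip compression).
#' @param spacing voxel spacing in mm (triple).
#' @param affine optional 4x4 grid-to-world matrix; default diagonal spacing.
#' @param datatype one of `"auto"`, `"int32"`, `"float32"`, `"float64"`.
#' @return the path, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), affine = NULL,
                        datatype = c("auto", "int32", "float32", "float64")) {
  datatype <- match.arg(datatype)
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L))) {
    stopf("`data` must be a 3D or 4D array")
  }
  spacing <- check_triple(spacing, "spacing", positive = TRUE)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  if (datatype == "auto") {
    datatype <- if (is.integer(data) || all(data == round(data), na.rm = TRUE)) "int32" else "float32"
  }
  code <- switch(datatype, int32 = 8L, float32 = 16L, float64 = 64L)
  size <- switch(datatype, int32 = 4L, float32 = 4L, float64 = 8L)
  bitpix <- 8L * size

  dims <- dim(data)
  ndim <- length(dims)
  dim_field <- integer(8L)
  dim_field[1] <- ndim
  dim_field[2:(1 + ndim)] <- dims
  if (ndim == 3L) dim_field[5:8] <- c(1L, 1L, 1L, 1L) else dim_field[6:8] <- 1L
  pixdim <- numeric(8L)
  pixdim[1] <- 1
  pixdim[2:4] <- spacing
  pixdim[5:8] <- 1

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr_raw <- function(n) writeBin(raw(n), con)
  wr_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wr_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wr_chr <- function(s, width) {
    b <- charToRaw(s)
    b <- b[seq_len(min(length(b), width))]
    writeBin(c(b, raw(width - length(b))), con)
  }

  wr_i32(348L)                 # sizeof_hdr
  wr_raw(10L); wr_raw(18L)     # data_type, db_name
  wr_i32(0L); wr_i16(0L)       # extents, session_error
  wr_chr("r", 1L); wr_raw(1L)  # regular, dim_info
  wr_i16(dim_field)            # dim
  wr_f32(c(0, 0, 0))           # intent_p1..p3
  wr_i16(0L)                   # intent_code
  wr_i16(code); wr_i16(bitpix) # datatype, bitpix
  wr_i16(0L)                   # slice_start
  wr_f32(pixdim)               # pixdim
  wr_f32(352)                  # vox_offset
  wr_f32(1); wr_f32(0)         # scl_slope, scl_inter
  wr_i16(0L); wr_raw(1L)       # slice_end, slice_code
  writeBin(as.raw(10L), con)   # xyzt_units: mm
  wr_f32(c(0, 0, 0, 0))        # cal_max, cal_min, slice_duration, toffset
  wr_i32(c(0L, 0L))            # glmax, glmin
  wr_chr("radionet", 80L)      # descrip
  wr_raw(24L)                  # aux_file
  wr_i16(0L); wr_i16(1L)       # qform_code, sform_code
  wr_f32(c(0, 0, 0))           # quatern_b, c, d
  wr_f32(c(0, 0, 0))           # qoffset_x, y, z
  wr_f32(affine[1, ]); wr_f32(affine[2, ]); wr_f32(affine[3, ])
  wr_raw(16L)                  # intent_name
  wr_chr("n+1", 4L)            # magic
  wr_raw(4L)                   # extension indicator

  if (datatype == "int32") {
    wr_i32(as.vector(data))
  } else {
    writeBin(as.numeric(as.vector(data)), con, size = size, endian = "little")
  }
  invisible(path)
}
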