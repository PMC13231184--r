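# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# Only what the pipeline needs: 3-D grids, datatypes uint8/int16/int32/
# float32/float64, voxel spacing from pixdim, scl_slope/scl_inter applied on
# read. Orientation matrices are ignored: the pipeline's (X, Y, Z) axis
# convention is documented in `volume3d()` and volumes written here are read
# back on the same convention.

.nifti_dt <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, r = "uint8"),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  r = "int16"),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  r = "int32"),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  r = "float32"),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  r = "float64")
)

.open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return list with `values` (3-D array), `spacing` (mm, from `pixdim`).
#' @keywords internal
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- .open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file: truncated header")
  endian <- "little"
  if (readBin(hdr[1:4], "integer", 1L, size = 4L, endian = "little") != 348L) {
    if (readBin(hdr[1:4], "integer", 1L, size = 4L, endian = "big") == 348L)
      endian <- "big"
    else stop("not a NIfTI-1 file: bad header size")
  }
  geti16 <- function(off, n = 1L) readBin(hdr[(off + 1L):(off + 2L * n)], "integer", n, size = 2L, endian = endian)
  getf32 <- function(off, n = 1L) readBin(hdr[(off + 1L):(off + 4L * n)], "double", n, size = 4L, endian = endian)
  dim_ <- geti16(40L, 8L)
  datatype <- geti16(70L)
  pixdim <- getf32(76L, 8L)
  vox_offset <- getf32(108L)
  scl_slope <- getf32(112L)
  scl_inter <- getf32(116L)
  ndim <- dim_[1]
  trailing <- if (ndim > 3L) dim_[5:(ndim + 1L)] else integer(0)
  if (ndim < 3L || any(trailing > 1L)) stop("not a 3-D volume")
  dims <- dim_[2:4]
  if (any(dims < 1L)) stop("not a 3-D volume")
  dt <- .nifti_dt[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("unsupported NIfTI datatype code %d", datatype))
  n <- prod(dims)
  skip <- as.integer(round(vox_offset)) - 352L
  if (skip > 0L) readBin(con, "raw", skip)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed, endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data section")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(values = array(as.numeric(vals), dims), spacing = pixdim[2:4])
}

#' Write a NIfTI-1 volume
#'
#' @param values 3-D array.
#' @param spacing voxel size in mm (length 3).
#' @param path output `.nii` or `.nii.gz` path.
#' @param datatype one of `"float32"`, `"float64"`, `"int16"`, `"int32"`, `"uint8"`.
#' @keywords internal
write_nifti <- function(values, spacing, path, datatype = "float32") {
  stopifnot(length(dim(values)) == 3L)
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unsupported datatype"))
  dt <- .nifti_dt[[as.character(code)]]
  con <- .open_maybe_gz(path, "wb")
  on.exit(close(con))
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                      # sizeof_hdr
  w_raw(36L)                       # data_type, db_name, extents, session_error, regular, dim_info
  w_i16(c(3L, dim(values), 1L, 1L, 1L, 1L))  # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)     # intent_p1..p3, intent_code
  w_i16(code)                      # datatype
  w_i16(8L * dt$size)              # bitpix
  w_i16(0L)                        # slice_start
  w_f32(c(1, spacing, 1, 1, 1, 1)) # pixdim[8]
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope, scl_inter
  w_raw(4L)                        # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_raw(80L + 24L)                 # descrip, aux_file
  w_i16(c(0L, 0L))                 # qform_code, sform_code
  w_f32(rep(0, 6))                 # quatern_b..qoffset_z
  w_f32(rep(0, 12))                # srow_x/y/z
  w_raw(16L)                       # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL); w_raw(1L)  # magic
  w_raw(4L)                        # extension flag
  if (dt$what == "integer") {
    writeBin(as.integer(round(values)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(values), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Load a volume from disk
#'
#' Reads a 3-D NIfTI-1 file (`.nii`, `.nii.gz`) and attaches modality and
#' wavelength metadata. Spacing is taken from the NIfTI header unless
#' overridden.
#'
#' @param path file path.
#' @param spacing optional length-3 voxel size in mm overriding the header.
#' @param modality `"US"` or `"PA"`.
#' @param wavelength_nm wavelength in nm (required for PA).
#' @return A [volume3d()] object.
#' @export
load_volume <- function(path, spacing = NULL, modality = c("US", "PA"),
                        wavelength_nm = NULL) {
  modality <- match.arg(modality)
  nii <- read_nifti(path)
  sp <- spacing %||% nii$spacing
  volume3d(nii$values, sp, modality, wavelength_nm)
}

#' Save a volume to disk as NIfTI-1
#'
#' @param v a [volume3d()] object.
#' @param path output `.nii` or `.nii.gz` path.
#' @param datatype storage type; `"float64"` round-trips doubles bit-exactly,
#'   `"int16"` suits integer-valued data.
#' @export
save_volume <- function(v, path, datatype = "float32") {
  stopifnot(is_volume3d(v))
  write_nifti(v$values, v$spacing, path, datatype)
  invisible(path)
}
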