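#' 3-D image volume with physical voxel spacing
#'
#' The basic container of the pipeline: a 3-D non-negative scalar grid indexed
#' as (X, Y, Z) = (lateral, elevational, depth), with Z = 0 at the top of the
#' water column and Z increasing downward into tissue. Ultrasound (`"US"`)
#' volumes carry no wavelength; photoacoustic (`"PA"`) volumes must carry one.
#'
#' @param values numeric 3-D array of finite, non-negative voxel values.
#' @param spacing numeric length-3 vector of voxel sizes in mm (X, Y, Z), all
#'   strictly positive.
#' @param modality `"US"` or `"PA"`.
#' @param wavelength_nm excitation wavelength in nm (PA only).
#' @return An object of class `Volume3D`.
#' @examples
#' v <- volume3d(array(1, c(4, 4, 6)), spacing = c(0.1, 0.1, 0.1), modality = "US")
#' dim(v$values)
#' @export
volume3d <- function(values, spacing, modality = c("US", "PA"), wavelength_nm = NULL) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("not a 3-D volume: `values` must be a 3-D array")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite voxel at (%d, %d, %d)", bad[1], bad[2], bad[3]))
  }
  if (min(values) < 0)
    stop("voxel values must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm (X, Y, Z)")
  if (modality == "PA") {
    if (is.null(wavelength_nm) || !is.numeric(wavelength_nm) || wavelength_nm <= 0)
      stop("PA volumes must carry a positive `wavelength_nm`")
  } else if (!is.null(wavelength_nm)) {
    stop("US volumes must not carry a wavelength")
  }
  structure(
    list(values = values, spacing = spacing, modality = modality,
         wavelength_nm = if (is.null(wavelength_nm)) NULL else as.numeric(wavelength_nm)),
    class = "Volume3D"
  )
}

#' @export
print.Volume3D <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Volume3D [%s%s]: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$modality,
              if (is.null(x$wavelength_nm)) "" else sprintf(" %g nm", x$wavelength_nm),
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.Volume3D <- function(x) dim(x$values)

is_volume3d <- function(x) inherits(x, "Volume3D")

#' Resample a volume to isotropic voxel spacing
#'
#' Trilinear interpolation onto a grid of `target_mm` isotropic voxels covering
#' the same physical extent (to within one voxel). Values are sampled at voxel
#' centres; coordinates outside the input grid are clamped to the border value.
#' The study default is 0.1 mm isotropic.
#'
#' @param v a [volume3d()] object.
#' @param target_mm target isotropic voxel size in mm (default 0.1).
#' @return A `Volume3D` with spacing `c(target_mm, target_mm, target_mm)`.
#' @export
resample_isotropic <- function(v, target_mm = 0.1) {
  stopifnot(is_volume3d(v))
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("`target_mm` must be a positive scalar")
  d <- dim(v$values)
  deg <- which(d == 1L)
  if (length(deg))
    stop(sprintf("cannot resample: degenerate axis %s (length 1)",
                 paste(c("X", "Y", "Z")[deg], collapse = ", ")))
  if (all(abs(v$spacing - target_mm) < 1e-12)) return(v)
  out_vals <- resample_trilinear(v$values, v$spacing, rep(target_mm, 3L))
  volume3d(pmax(out_vals, 0), rep(target_mm, 3L), v$modality, v$wavelength_nm)
}

# Trilinear resampling between voxel-centre grids sharing an origin at the
# physical corner of the volume. Border values are clamped.
resample_trilinear <- function(vals, sp_in, sp_out) {
  d <- dim(vals)
  extent <- d * sp_in
  d_out <- pmax(1L, as.integer(round(extent / sp_out)))

  ax <- function(n_out, sp_o, sp_i, n_in) {
    centers <- (seq_len(n_out) - 0.5) * sp_o
    idx <- centers / sp_i + 0.5            # fractional input voxel index
    idx <- pmin(pmax(idx, 1), n_in)        # clamp to border centres
    i0 <- pmin(floor(idx), n_in - 1L)
    list(i0 = as.integer(i0), f = idx - i0)
  }
  X <- ax(d_out[1], sp_out[1], sp_in[1], d[1])
  Y <- ax(d_out[2], sp_out[2], sp_in[2], d[2])
  Z <- ax(d_out[3], sp_out[3], sp_in[3], d[3])

  out <- array(0, d_out)
  nxy <- d_out[1] * d_out[2]
  for (dz in 0:1) {
    wz <- if (dz == 0) 1 - Z$f else Z$f
    for (dy in 0:1) {
      wy <- if (dy == 0) 1 - Y$f else Y$f
      for (dx in 0:1) {
        wx <- if (dx == 0) 1 - X$f else X$f
        corner <- vals[X$i0 + dx, Y$i0 + dy, Z$i0 + dz, drop = FALSE]
        w <- wx * rep(wy, each = d_out[1])          # (X x Y) weights
        out <- out + corner * as.vector(outer(w, wz))
      }
    }
  }
  out
}
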