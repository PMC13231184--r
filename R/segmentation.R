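#' Segment tissue from water in a 3-D ultrasound volume
#'
#' Thresholds the US amplitude (Otsu's method by default) and, per lateral
#' column along Z, takes the first super-threshold run of at least `min_run`
#' voxels as the water-skin interface. The interface-depth map is median
#' filtered (3 x 3 laterally) to suppress speckle-induced spikes. Columns with
#' no detected tissue are flagged, excluded from the interface map and from
#' both masks, and counted.
#'
#' @param us an ultrasound [volume3d()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold amplitude threshold when `method = "fixed"`.
#' @param min_run minimum consecutive super-threshold voxels that start
#'   tissue (default 2; resists isolated noise spikes).
#' @return list with `tissue_mask`, `water_mask` (logical arrays),
#'   `interface_depth` (X x Y matrix, mm, `NA` where undetected),
#'   `threshold`, and `n_empty_columns`.
#' @export
find_tissue_mask <- function(us, method = c("otsu", "fixed"), threshold = NULL,
                             min_run = 2L) {
  stopifnot(is_volume3d(us))
  method <- match.arg(method)
  vals <- us$values
  if (max(vals) <= 0 || diff(range(vals)) == 0)
    stop("no tissue detected: ultrasound volume has no contrast")
  thr <- switch(method,
                otsu = otsu_threshold(vals),
                fixed = { stopifnot(is.numeric(threshold)); threshold })
  d <- dim(vals)
  nz <- d[3]
  # first index of a run of >= min_run super-threshold voxels, per column
  above <- vals >= thr
  runlen <- array(0L, d)
  runlen[, , 1] <- above[, , 1]
  for (k in 2:nz) runlen[, , k] <- ifelse(above[, , k], runlen[, , k - 1] + 1L, 0L)
  hit <- runlen >= min_run
  # index of first hit along Z, minus (min_run - 1) to point at run start
  first_hit <- apply(hit, c(1, 2), function(col) {
    i <- which(col)[1]
    if (is.na(i)) NA_integer_ else i
  })
  k0 <- first_hit - (min_run - 1L)
  n_empty <- sum(is.na(k0))
  if (n_empty == length(k0)) stop("no tissue detected")
  # despike: replace only interface samples far (> 2 voxels) from their 3x3
  # lateral median, so smooth curved surfaces pass through unchanged
  med <- .median3x3(k0)
  spike <- !is.na(k0) & !is.na(med) & abs(k0 - med) > 2L
  k0[spike] <- med[spike]
  tissue <- array(FALSE, d); water <- array(FALSE, d)
  valid <- !is.na(k0)
  k0v <- k0; k0v[!valid] <- nz + 1L
  for (k in seq_len(nz)) {
    tissue[, , k] <- valid & k >= k0v
    water[, , k] <- valid & k < k0v
  }
  interface_depth <- (k0 - 1L) * us$spacing[3]
  list(tissue_mask = tissue, water_mask = water,
       interface_depth = interface_depth, threshold = thr,
       n_empty_columns = n_empty)
}

# 3x3 median filter on an integer matrix, NA-tolerant, edges use available
# neighbours.
.median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(m)
  out <- m
  neigh <- array(NA_real_, c(nr, nc, 9L))
  idx <- 0L
  for (di in -1:1) for (dj in -1:1) {
    idx <- idx + 1L
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    cj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    neigh[, , idx] <- m[ri, cj]
  }
  med <- apply(neigh, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_integer_ else as.integer(round(stats::median(v)))
  })
  med[is.na(m)] <- NA_integer_   # do not resurrect flagged columns
  med
}

#' Extract the skin shell from a tissue mask
#'
#' Erodes `thickness_mm` from the water-skin interface along Z (a Z-directed
#' structuring element of `round(thickness_mm / spacing_z)` voxels) and
#' subtracts the eroded mask from the tissue mask: the shell is the first
#' `N` tissue voxels of every lateral column. At the study spacing of 0.1 mm
#' a 0.5 mm shell is exactly 5 voxels deep.
#'
#' @param tissue_mask logical 3-D array.
#' @param spacing voxel size in mm (length 3 or the Z spacing alone).
#' @param thickness_mm shell thickness (default 0.5).
#' @return logical 3-D `skin_mask`.
#' @export
extract_skin_shell <- function(tissue_mask, spacing, thickness_mm = 0.5) {
  stopifnot(is.logical(tissue_mask) || all(tissue_mask %in% c(0, 1)),
            length(dim(tissue_mask)) == 3L, thickness_mm > 0)
  sp_z <- if (length(spacing) == 3L) spacing[3] else spacing
  n <- as.integer(round(thickness_mm / sp_z))
  if (n < 1L)
    stop(sprintf("shell thickness %.3g mm is below one voxel at %.3g mm spacing; resample finer",
                 thickness_mm, sp_z))
  d <- dim(tissue_mask)
  eroded <- array(FALSE, d)
  if (n < d[3])
    eroded[, , (n + 1L):d[3]] <- tissue_mask[, , seq_len(d[3] - n)]
  tissue_mask & !eroded
}

#' Lateral region-of-interest mask
#'
#' The study uses a manually placed 14 x 14 mm square over cube implants, an
#' 18 mm diameter circle over dome implants, and the full 23 x 23 mm field
#' for controls. Placement comes from the manifest; there is no
#' auto-detection.
#'
#' @param shape `"square"`, `"circle"` or `"full"`.
#' @param dims lateral grid size (X, Y) in pixels.
#' @param spacing_mm lateral pixel size in mm.
#' @param size_mm square edge length or circle diameter in mm.
#' @param center_mm ROI centre (x, y) in mm; default the field centre.
#' @return logical X x Y matrix.
#' @export
make_roi_mask <- function(shape = c("square", "circle", "full"), dims,
                          spacing_mm, size_mm = NULL, center_mm = NULL) {
  shape <- match.arg(shape)
  stopifnot(length(dims) == 2L)
  if (shape == "full") return(matrix(TRUE, dims[1], dims[2]))
  stopifnot(is.numeric(size_mm), size_mm > 0)
  ext <- dims * spacing_mm
  if (is.null(center_mm)) center_mm <- ext / 2
  half <- size_mm / 2
  lo <- center_mm - half; hi <- center_mm + half
  if (any(lo < -1e-9) || any(hi > ext + 1e-9))
    stop(sprintf("ROI exceeds field of view: spans [%.2f, %.2f] x [%.2f, %.2f] mm in a %.2f x %.2f mm field",
                 lo[1], hi[1], lo[2], hi[2], ext[1], ext[2]))
  x <- (seq_len(dims[1]) - 0.5) * spacing_mm
  y <- (seq_len(dims[2]) - 0.5) * spacing_mm
  if (shape == "square") {
    inx <- x >= lo[1] - 1e-9 & x < hi[1] - 1e-9
    iny <- y >= lo[2] - 1e-9 & y < hi[2] - 1e-9
    outer(inx, iny, `&`)
  } else {
    outer((x - center_mm[1])^2, (y - center_mm[2])^2, `+`) <= half^2 + 1e-9
  }
}

#' Normalize a photoacoustic volume to the water reference
#'
#' Divides the PA volume by its mean amplitude over the water mask,
#' compensating day-to-day laser fluence fluctuations; the output has unit
#' mean over water by construction, so all downstream biomarkers are
#' invariant to global rescaling of the raw PA data.
#'
#' @param pa a PA [volume3d()].
#' @param water_mask logical 3-D array.
#' @return a [volume3d()] in water-relative units.
#' @export
normalize_to_water <- function(pa, water_mask) {
  stopifnot(is_volume3d(pa), identical(dim(water_mask), dim(pa$values)))
  if (!any(water_mask)) stop("empty water mask: no water reference available")
  m <- mean(pa$values[water_mask])
  if (!is.finite(m) || m <= 0)
    stop("water reference amplitude is not positive; water normalization impossible")
  volume3d(pa$values / m, pa$spacing, pa$modality, pa$wavelength_nm)
}

#' Full skin segmentation of one session
#'
#' Convenience wrapper running [find_tissue_mask()] and
#' [extract_skin_shell()] and attaching a lateral ROI.
#'
#' @param us ultrasound [volume3d()].
#' @param roi_mask_2d logical lateral mask (default full field).
#' @param thickness_mm shell thickness (default 0.5).
#' @param ... passed to [find_tissue_mask()].
#' @return list of class `SkinSegmentation` with `tissue_mask`, `skin_mask`,
#'   `water_mask`, `roi_mask_2d`, `interface_depth`.
#' @export
segment_skin <- function(us, roi_mask_2d = NULL, thickness_mm = 0.5, ...) {
  seg <- find_tissue_mask(us, ...)
  skin <- extract_skin_shell(seg$tissue_mask, us$spacing, thickness_mm)
  if (is.null(roi_mask_2d))
    roi_mask_2d <- matrix(TRUE, dim(us$values)[1], dim(us$values)[2])
  structure(list(tissue_mask = seg$tissue_mask, skin_mask = skin,
                 water_mask = seg$water_mask, roi_mask_2d = roi_mask_2d,
                 interface_depth = seg$interface_depth,
                 n_empty_columns = seg$n_empty_columns),
            class = "SkinSegmentation")
}
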