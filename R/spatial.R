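#' Flatten a THb volume into a 2-D hemoglobin map
#'
#' Per lateral position, the maximum of THb over the masked Z extent
#' (maximum intensity projection, consistent with the vasculature pathway; a
#' sum projection is available via `method = "sum"`), zeroed outside the
#' lateral ROI.
#'
#' @param thb 3-D THb array.
#' @param skin_mask logical 3-D skin-shell mask.
#' @param roi_mask_2d logical lateral ROI.
#' @param method `"mip"` (default) or `"sum"`.
#' @return X x Y numeric map.
#' @export
flatten_thb <- function(thb, skin_mask, roi_mask_2d, method = c("mip", "sum")) {
  method <- match.arg(method)
  stopifnot(identical(dim(thb), dim(skin_mask)),
            identical(dim(roi_mask_2d), dim(thb)[1:2]))
  if (!any(skin_mask)) stop("empty skin mask")
  map <- if (method == "mip") {
    mip_2d(thb, skin_mask)
  } else {
    v <- thb; v[!skin_mask] <- 0
    apply(v, c(1, 2), sum)
  }
  map[!roi_mask_2d] <- 0
  map
}

#' Normalize a map to unit mean over the ROI
#'
#' Divides by the ROI mean, making consecutive-week comparisons invariant to
#' global per-week scale (laser fluence, coupling): only spatial
#' redistribution of hemoglobin registers in the difference maps.
#'
#' @param map numeric matrix.
#' @param roi logical matrix, co-shaped.
#' @return map with ROI mean exactly 1.
#' @export
mean_normalize <- function(map, roi) {
  stopifnot(identical(dim(map), dim(roi)))
  if (!any(roi)) stop("empty ROI")
  m <- mean(map[roi])
  if (!is.finite(m) || m <= 0) stop("ROI mean is not positive; cannot normalize")
  map / m
}

#' Gaussian smoothing of a 2-D map
#'
#' Separable Gaussian convolution with reflective boundaries; `sigma_mm` is
#' converted to pixels by the lateral spacing. `sigma_mm = 0` is the
#' identity.
#'
#' @param map numeric matrix.
#' @param sigma_mm smoothing width in mm (default 0.3).
#' @param spacing_mm lateral pixel size in mm (default 0.1).
#' @return smoothed map.
#' @export
gaussian_smooth <- function(map, sigma_mm = 0.3, spacing_mm = 0.1) {
  if (!is.numeric(sigma_mm) || sigma_mm < 0) stop("`sigma_mm` must be >= 0")
  if (sigma_mm == 0) return(map)
  k <- gaussian_kernel_1d(sigma_mm / spacing_mm, 0L)
  conv2_sep(map, k, k)
}

#' Hemoglobin reduction map between consecutive sessions
#'
#' Difference of two mean-normalized, smoothed 2-D hemoglobin maps
#' (`map_w2 - map_w1`) and the binary reduction mask where the drop exceeds
#' the threshold. The study excludes the week 0 -> 2 pair (early
#' post-implantation skin movement); that policy lives in
#' [study_reduction_maps()].
#'
#' @param map_w1,map_w2 mean-normalized smoothed maps on the same grid.
#' @param threshold reduction threshold in mean-normalized units
#'   (default 0.15).
#' @param roi logical lateral ROI restricting the mask (default all).
#' @return list of class `ReductionMap`: `delta`, `mask`, `threshold`.
#' @export
reduction_map <- function(map_w1, map_w2, threshold = 0.15, roi = NULL) {
  if (!identical(dim(map_w1), dim(map_w2))) stop("maps differ in shape")
  if (is.null(roi)) roi <- array(TRUE, dim(map_w1))
  delta <- map_w2 - map_w1
  structure(list(delta = delta, mask = (delta < -threshold) & roi,
                 threshold = threshold),
            class = "ReductionMap")
}

#' Reduction maps across a subject's weekly hemoglobin maps
#'
#' Applies mean normalization, smoothing and consecutive differencing across
#' an ordered list of flattened THb maps. By default the first pair
#' (week 0 -> 2) is excluded.
#'
#' @param maps named list of 2-D THb maps ordered by week (names = weeks).
#' @param roi logical lateral ROI.
#' @param sigma_mm,spacing_mm smoothing parameters.
#' @param threshold reduction threshold.
#' @param skip_first drop the first consecutive pair (default TRUE).
#' @return named list of [reduction_map()] results (`"w1->w2"`).
#' @export
study_reduction_maps <- function(maps, roi, sigma_mm = 0.3, spacing_mm = 0.1,
                                 threshold = 0.15, skip_first = TRUE) {
  stopifnot(length(maps) >= 2L)
  prep <- lapply(maps, function(m)
    gaussian_smooth(mean_normalize(m, roi), sigma_mm, spacing_mm))
  pairs <- seq_len(length(maps) - 1L)
  if (skip_first && length(pairs) > 1L) pairs <- pairs[-1L]
  out <- list()
  wk <- names(maps) %||% as.character(seq_along(maps))
  for (i in pairs)
    out[[sprintf("%s->%s", wk[i], wk[i + 1L])]] <-
      reduction_map(prep[[i]], prep[[i + 1L]], threshold, roi)
  out
}

#' Overlap of reduction masks with a ground-truth at-risk region
#'
#' Scores the union of reduction masks preceding the score-drop week against
#' the true at-risk region (available in synthetic runs): Dice, precision
#' and recall.
#'
#' @param reduction_masks list of logical masks (or `ReductionMap` objects).
#' @param truth_region logical matrix.
#' @return list with `dice`, `precision`, `recall`, `union_mask`.
#' @export
localization_score <- function(reduction_masks, truth_region) {
  if (is.null(truth_region)) stop("no ground-truth region available")
  masks <- lapply(reduction_masks, function(m)
    if (inherits(m, "ReductionMap")) m$mask else m)
  u <- Reduce(`|`, masks)
  stopifnot(identical(dim(u), dim(truth_region)))
  tp <- sum(u & truth_region)
  list(dice = dice(u, truth_region),
       precision = if (sum(u)) tp / sum(u) else 0,
       recall = if (sum(truth_region)) tp / sum(truth_region) else 0,
       union_mask = u)
}
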