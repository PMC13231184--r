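#' Photoacoustic vasculature biomarker
#'
#' Mean water-normalized 532 nm PA amplitude over the skin shell, restricted
#' laterally to the ROI (the 2-D ROI is broadcast down all Z). Hemoglobin
#' absorbs strongly and water negligibly at 532 nm, so this tracks blood
#' content in the superficial skin.
#'
#' @param pa532_normalized water-normalized 532 nm PA [volume3d()].
#' @param skin_mask logical 3-D skin-shell mask.
#' @param roi_mask_2d logical lateral ROI.
#' @return scalar biomarker value.
#' @export
pa_vasculature <- function(pa532_normalized, skin_mask, roi_mask_2d) {
  vals <- if (is_volume3d(pa532_normalized)) pa532_normalized$values else pa532_normalized
  m <- skin_mask & broadcast_roi(roi_mask_2d, dim(vals))
  if (!any(m)) stop("empty skin/ROI intersection")
  mean(vals[m])
}

#' Vascular density biomarker
#'
#' Mean of the (vertically suppressed) Jerman-enhanced vascular structure map
#' over the lateral ROI; lies in \[0, 1\] and weights major horizontal
#' vessels.
#'
#' @param suppressed_map 2-D enhanced map in \[0, 1\] (suppressed by default
#'   upstream; pass the raw enhanced map to skip suppression).
#' @param roi_mask_2d logical lateral ROI, co-shaped.
#' @return scalar in \[0, 1\].
#' @export
vascular_density <- function(suppressed_map, roi_mask_2d) {
  stopifnot(identical(dim(suppressed_map), dim(roi_mask_2d)))
  if (!any(roi_mask_2d)) stop("empty ROI")
  mean(suppressed_map[roi_mask_2d])
}

#' Total hemoglobin biomarker
#'
#' Mean of THb (= Hb + HbO2 from spectral unmixing) over the skin shell
#' intersected with the lateral ROI.
#'
#' @param thb 3-D THb array (from [unmix()]).
#' @param skin_mask logical 3-D skin-shell mask.
#' @param roi_mask_2d logical lateral ROI.
#' @return scalar biomarker value.
#' @export
total_hemoglobin_level <- function(thb, skin_mask, roi_mask_2d) {
  stopifnot(identical(dim(thb), dim(skin_mask)))
  m <- skin_mask & broadcast_roi(roi_mask_2d, dim(thb))
  if (!any(m)) stop("empty skin/ROI intersection")
  mean(thb[m])
}

#' Assemble baseline-normalized longitudinal biomarker series
#'
#' Takes per-session biomarker values in long format and normalizes each
#' subject x biomarker series to its week-0 value. Missing intermediate
#' weeks are kept as gaps (no imputation); a truncated series (e.g. death at
#' week 4) is returned at its observed length.
#'
#' @param series long data.frame with columns `subject_id`, `group`, `week`,
#'   `score`, `biomarker`, `raw`.
#' @return the same data.frame with a `normalized` column (`raw` divided by
#'   the subject's week-0 value of that biomarker), ordered by subject,
#'   biomarker, week.
#' @export
assemble_series <- function(series) {
  need <- c("subject_id", "group", "week", "score", "biomarker", "raw")
  stopifnot(is.data.frame(series), all(need %in% names(series)))
  series <- series[order(series$subject_id, series$biomarker, series$week), ]
  out <- lapply(split(series, list(series$subject_id, series$biomarker), drop = TRUE),
    function(g) {
      if (!0 %in% g$week)
        stop(sprintf("subject %s lacks a week-0 baseline for %s",
                     g$subject_id[1], g$biomarker[1]))
      base <- g$raw[g$week == 0]
      if (!is.finite(base) || base <= 0)
        stop(sprintf("subject %s has a non-positive week-0 baseline for %s",
                     g$subject_id[1], g$biomarker[1]))
      g$normalized <- g$raw / base
      g
    })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$subject_id, res$biomarker, res$week), ]
}
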