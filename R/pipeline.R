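#' Process one imaging session end to end
#'
#' Runs the full per-session pipeline: skin segmentation from US, water
#' normalization of every PA volume, spectral unmixing of the six 700-950 nm
#' volumes, vessel enhancement of the 532 nm map, and the three biomarkers.
#'
#' @param session an [imaging_session()].
#' @param roi_mask_2d logical lateral ROI (default full field).
#' @param thickness_mm skin shell thickness (default 0.5).
#' @param scale_vox,tau,band vessel-enhancement parameters (see
#'   [vessel_map()]).
#' @param ... passed to [find_tissue_mask()].
#' @return list with `segmentation`, `chromophores`, `vessel_map`,
#'   `thb_map_2d` (flattened THb), and `biomarkers` (named numeric vector
#'   `pa_vasculature`, `vascular_density`, `total_hemoglobin`).
#' @export
process_session <- function(session, roi_mask_2d = NULL, thickness_mm = 0.5,
                            scale_vox = 4, tau = 0.5, band = c(-0.5, 0.5), ...) {
  stopifnot(inherits(session, "ImagingSession"))
  seg <- segment_skin(session$us, roi_mask_2d, thickness_mm, ...)
  pa_norm <- lapply(session$pa, normalize_to_water, water_mask = seg$water_mask)
  chrom <- unmix(pa_norm)
  vm <- vessel_map(pa_norm[["532"]], seg$skin_mask, scale_vox, tau, band)
  thb2d <- flatten_thb(chrom$THb, seg$skin_mask, seg$roi_mask_2d)
  bm <- c(
    pa_vasculature = pa_vasculature(pa_norm[["532"]], seg$skin_mask, seg$roi_mask_2d),
    vascular_density = vascular_density(vm$suppressed, seg$roi_mask_2d),
    total_hemoglobin = total_hemoglobin_level(chrom$THb, seg$skin_mask, seg$roi_mask_2d))
  list(segmentation = seg, chromophores = chrom, vessel_map = vm,
       thb_map_2d = thb2d, biomarkers = bm)
}

#' Process a rendered study into a normalized biomarker table
#'
#' Runs [process_session()] over every session of a rendered synthetic (or
#' loaded) study and assembles the baseline-normalized long table used by
#' the statistics modules.
#'
#' @param sessions list of [imaging_session()] objects.
#' @param manifest the matching [study_manifest()] (provides group labels).
#' @param roi_mask_2d logical lateral ROI applied to every session.
#' @param ... passed to [process_session()].
#' @return list with `table` (output of [assemble_series()]) and
#'   `per_session` (raw per-session results).
#' @export
process_study <- function(sessions, manifest, roi_mask_2d = NULL, ...) {
  stopifnot(inherits(manifest, "StudyManifest"))
  grp <- stats::setNames(manifest$subjects$group, manifest$subjects$subject_id)
  rows <- list(); per <- list()
  for (s in sessions) {
    res <- process_session(s, roi_mask_2d, ...)
    per[[sprintf("%s_w%02d", s$subject_id, s$week)]] <- res
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = s$subject_id, group = grp[[s$subject_id]], week = s$week,
      score = as.integer(s$score), biomarker = names(res$biomarkers),
      raw = as.numeric(res$biomarkers))
  }
  list(table = assemble_series(do.call(rbind, rows)), per_session = per)
}
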