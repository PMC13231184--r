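#' Ordinal skin-health score
#'
#' Five-point rubric adapted from the National Pressure Injury Advisory Panel
#' staging: 5 no visible skin damage; 4 minor spots or blisters with intact
#' skin; 3 small dehiscence without implant exposure; 2 moderate dehiscence
#' with slight exposure; 1 severe dehiscence with significant exposure.
#'
#' @param value integer in 1..5.
#' @return integer of class `SkinScore` with a `label` attribute.
#' @export
skin_score <- function(value) {
  if (length(value) != 1L || !is.numeric(value) || is.na(value) ||
      value != round(value) || value < 1 || value > 5)
    stop("skin score must be a single integer in 1..5")
  labels <- c("severe dehiscence with significant implant exposure",
              "moderate dehiscence with slight implant exposure",
              "small skin dehiscence without implant exposure",
              "minor spots or blisters with intact skin",
              "no visible skin damage")
  structure(as.integer(value), label = labels[value], class = "SkinScore")
}

#' One subject x one week imaging session
#'
#' Binds the ultrasound volume, the seven co-registered photoacoustic volumes
#' and the manual skin-health score for a single visit. All volumes must share
#' one grid (shape and spacing) — US and PA are acquired by the same
#' transducer and are inherently co-registered.
#'
#' @param subject_id character id.
#' @param week non-negative integer week.
#' @param us ultrasound [volume3d()].
#' @param pa named list of PA volumes, names the seven study wavelengths.
#' @param score [skin_score()] or an integer 1..5.
#' @return object of class `ImagingSession`.
#' @export
imaging_session <- function(subject_id, week, us, pa, score) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (!is.numeric(week) || week < 0 || week != round(week))
    stop("`week` must be a non-negative integer")
  stopifnot(is_volume3d(us), us$modality == "US")
  want <- pa_wavelengths()
  got <- sort(as.numeric(names(pa)))
  if (!identical(got, sort(want)))
    stop(sprintf("PA stack must contain exactly the seven study wavelengths (%s)",
                 paste(want, collapse = ", ")))
  for (w in names(pa)) {
    v <- pa[[w]]
    stopifnot(is_volume3d(v), v$modality == "PA")
    if (!isTRUE(all.equal(v$wavelength_nm, as.numeric(w))))
      stop(sprintf("PA volume stored under %s nm carries wavelength %g nm", w, v$wavelength_nm))
    if (!identical(dim(v$values), dim(us$values)) ||
        max(abs(v$spacing - us$spacing)) > 1e-9)
      stop(sprintf("PA volume at %s nm is not on the US grid (co-registration violated)", w))
  }
  if (!inherits(score, "SkinScore")) score <- skin_score(score)
  structure(list(subject_id = subject_id, week = as.integer(week),
                 us = us, pa = pa[as.character(want)], score = score),
            class = "ImagingSession")
}

.study_groups <- c("unimodal_cube", "bimodal_cube", "unimodal_dome", "control",
                   "healthy", "exposed")

#' Study manifest binding a longitudinal cohort together
#'
#' @param subjects data.frame with columns `subject_id` and `group`.
#' @param sessions data.frame with columns `subject_id`, `week`, `score`, and
#'   optionally file-path columns `us` and `pa_<wavelength>` for on-disk
#'   studies.
#' @param spacing_mm working isotropic voxel size (default 0.1).
#' @return object of class `StudyManifest`.
#' @export
study_manifest <- function(subjects, sessions, spacing_mm = 0.1) {
  stopifnot(is.data.frame(subjects), all(c("subject_id", "group") %in% names(subjects)),
            is.data.frame(sessions), all(c("subject_id", "week", "score") %in% names(sessions)))
  bad <- setdiff(subjects$group, .study_groups)
  if (length(bad))
    stop(sprintf("unknown group label(s): %s", paste(unique(bad), collapse = ", ")))
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject ids")
  orphan <- setdiff(sessions$subject_id, subjects$subject_id)
  if (length(orphan)) stop(sprintf("sessions for unlisted subject(s): %s",
                                   paste(unique(orphan), collapse = ", ")))
  for (sid in unique(sessions$subject_id)) {
    w <- sessions$week[sessions$subject_id == sid]
    if (any(diff(w) <= 0))
      stop(sprintf("weeks must be strictly increasing for subject %s", sid))
  }
  structure(list(subjects = subjects, sessions = sessions,
                 spacing_mm = spacing_mm), class = "StudyManifest")
}

#' @export
print.StudyManifest <- function(x, ...) {
  cat(sprintf("StudyManifest: %d subjects, %d sessions, working spacing %.3g mm\n",
              nrow(x$subjects), nrow(x$sessions), x$spacing_mm))
  print(table(x$subjects$group))
  invisible(x)
}

#' Read / write a study manifest as JSON
#'
#' The on-disk schema is a JSON object with `spacing_mm`, `subjects`
#' (`subject_id`, `group`) and `sessions` (`subject_id`, `week`, `score`, plus
#' optional volume file paths: `us` and `pa_532` ... `pa_950`).
#'
#' @param path JSON file path.
#' @return a [study_manifest()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  j <- jsonlite::fromJSON(path)
  study_manifest(as.data.frame(j$subjects), as.data.frame(j$sessions),
                 spacing_mm = j$spacing_mm %||% 0.1)
}

#' @rdname read_manifest
#' @param manifest a [study_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "StudyManifest"))
  jsonlite::write_json(
    list(spacing_mm = manifest$spacing_mm, subjects = manifest$subjects,
         sessions = manifest$sessions),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
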