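#' Specification of a synthetic longitudinal cohort
#'
#' Emulates the study design: biweekly imaging from week 0 to 12, a healthy
#' group whose vascular biomarkers stay flat (up to multiplicative jitter) and
#' whose skin scores remain 5, and an exposed group whose biomarkers decline
#' geometrically from `onset_week` to reach `final_fraction` of baseline at
#' the last week, with skin scores stepping down 5 -> 4 -> 3 -> 2 -> 1 one
#' visit at a time starting `lag_weeks` after the biomarker decline onset.
#'
#' @param n_healthy,n_exposed group sizes (study values 11 and 5).
#' @param weeks visit weeks (default `seq(0, 12, 2)`).
#' @param final_fraction exposed biomarker level at the last week as a
#'   fraction of baseline (default 0.5, mirroring the reported decline of up
#'   to about half by week 12).
#' @param onset_week week at which the exposed decline begins (default 2).
#' @param lag_weeks delay from biomarker decline onset to score decline onset;
#'   must be a multiple of the visit interval (default 4, inside the reported
#'   2-4 week lead).
#' @param noise_sd multiplicative noise s.d. on observed biomarkers
#'   (default 0.05).
#' @param subject_sd s.d. of per-subject log baseline levels (default 0.1).
#' @return object of class `CohortSpec`.
#' @export
cohort_spec <- function(n_healthy = 11L, n_exposed = 5L, weeks = seq(0, 12, 2),
                        final_fraction = 0.5, onset_week = 2,
                        lag_weeks = 4, noise_sd = 0.05, subject_sd = 0.1) {
  stopifnot(n_healthy >= 0, n_exposed >= 0, length(weeks) >= 2,
            all(diff(weeks) > 0), final_fraction > 0, final_fraction <= 1,
            noise_sd >= 0, subject_sd >= 0)
  step <- unique(diff(weeks))
  if (length(step) != 1L)
    stop("`weeks` must be evenly spaced")
  if (lag_weeks %% step != 0)
    stop(sprintf("`lag_weeks` must be a multiple of the %g-week visit interval", step))
  if (!onset_week %in% weeks) stop("`onset_week` must be a visit week")
  structure(list(n_healthy = as.integer(n_healthy), n_exposed = as.integer(n_exposed),
                 weeks = weeks, step = step, final_fraction = final_fraction,
                 onset_week = onset_week, lag_weeks = lag_weeks,
                 noise_sd = noise_sd, subject_sd = subject_sd),
            class = "CohortSpec")
}

# True multiplicative trajectory d(w) of an exposed subject: 1 before onset,
# then geometric decline reaching `final_fraction` at the last week.
decline_multiplier <- function(spec, weeks = spec$weeks) {
  last <- max(spec$weeks)
  ifelse(weeks <= spec$onset_week, 1,
         spec$final_fraction^((weeks - spec$onset_week) / (last - spec$onset_week)))
}

# Stepwise score series: one grade lost per visit, the first reduced grade
# appearing one visit after onset_week + lag_weeks (mirroring the biomarker,
# whose first sub-baseline value appears one visit after onset_week), clipped
# to [1, 5].
score_trajectory <- function(spec, exposed) {
  if (!exposed) return(rep(5L, length(spec$weeks)))
  onset <- spec$onset_week + spec$lag_weeks
  steps_after <- pmax(0, floor((spec$weeks - onset) / spec$step))
  as.integer(pmin(5, pmax(1, 5 - steps_after)))
}

#' Generate a synthetic longitudinal cohort with ground truth
#'
#' Produces per-subject, per-week observed values of the three photoacoustic
#' biomarkers (baseline level x true multiplier x multiplicative noise) and
#' skin scores, together with a [study_manifest()] and a ground-truth record
#' (true multipliers, decline onset, configured lag) sufficient to score any
#' downstream recovery test. Deterministic for a fixed seed.
#'
#' When `render = TRUE`, each session is additionally rendered as full US/PA
#' volumes from `phantom` (a [phantom_spec()]) with all vessel concentrations
#' scaled by the subject's true multiplier for that week; this is expensive
#' and intended for small grids.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed.
#' @param render logical; also render imaging volumes per session.
#' @param phantom base [phantom_spec()] used when `render = TRUE`.
#' @return list with `manifest`, `series` (long data.frame: `subject_id`,
#'   `group`, `week`, `score`, `biomarker`, `raw`), `ground_truth`, and
#'   (if rendered) `sessions`, a list of [imaging_session()] objects.
#' @export
generate_longitudinal_cohort <- function(spec, seed = 1L, render = FALSE,
                                         phantom = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(derive_seed(seed, 7L))
  biom <- c("pa_vasculature", "vascular_density", "total_hemoglobin")
  ids <- c(sprintf("H%02d", seq_len(spec$n_healthy)),
           sprintf("E%02d", seq_len(spec$n_exposed)))
  groups <- rep(c("healthy", "exposed"), c(spec$n_healthy, spec$n_exposed))
  nw <- length(spec$weeks)

  rows <- list(); truth_rows <- list()
  for (s in seq_along(ids)) {
    exposed <- groups[s] == "exposed"
    mult <- if (exposed) decline_multiplier(spec) else rep(1, nw)
    scores <- score_trajectory(spec, exposed)
    base <- exp(stats::rnorm(length(biom), 0, spec$subject_sd))
    for (b in seq_along(biom)) {
      eps <- stats::rnorm(nw, 0, spec$noise_sd)
      raw <- base[b] * mult * (1 + eps)
      raw <- pmax(raw, 1e-6)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[s], group = groups[s], week = spec$weeks,
        score = scores, biomarker = biom[b], raw = raw)
    }
    truth_rows[[s]] <- data.frame(subject_id = ids[s], group = groups[s],
                                  week = spec$weeks, multiplier = mult,
                                  score = scores)
  }
  series <- do.call(rbind, rows)
  sessions_df <- unique(series[, c("subject_id", "week", "score")])
  manifest <- study_manifest(
    data.frame(subject_id = ids, group = groups),
    sessions_df[order(sessions_df$subject_id, sessions_df$week), ])
  out <- list(
    manifest = manifest, series = series,
    ground_truth = list(
      trajectories = do.call(rbind, truth_rows),
      onset_week = spec$onset_week, lag_weeks = spec$lag_weeks,
      final_fraction = spec$final_fraction))

  if (render) {
    if (is.null(phantom)) stop("`phantom` is required when render = TRUE")
    sessions <- list()
    for (s in seq_along(ids)) {
      exposed <- groups[s] == "exposed"
      mult <- if (exposed) decline_multiplier(spec) else rep(1, nw)
      scores <- score_trajectory(spec, exposed)
      for (k in seq_len(nw)) {
        ph <- phantom
        ph$vessels <- lapply(ph$vessels, function(v) {
          v$hb <- (v$hb %||% 0) * mult[k]; v$hbo2 <- (v$hbo2 %||% 0) * mult[k]; v
        })
        sseed <- derive_seed(seed, 1000L * s + k)
        sessions[[sprintf("%s_w%02d", ids[s], spec$weeks[k])]] <-
          imaging_session(ids[s], spec$weeks[k],
                          generate_us_volume(ph, sseed),
                          generate_pa_stack(ph, sseed),
                          scores[k])
      }
    }
    out$sessions <- sessions
  }
  out
}
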