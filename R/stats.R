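#' Mixed-model test of differing temporal profiles between groups
#'
#' Fits a linear mixed-effects model of the baseline-normalized biomarker on
#' time, group and their interaction, with a subject-specific random
#' intercept to account for repeated measurements:
#' `normalized ~ week * group + (1 | subject_id)`. The significance of the
#' week x group interaction — whether the temporal profile differs between
#' healthy and exposed subjects — is assessed by a likelihood-ratio test
#' between maximum-likelihood fits with and without the interaction term
#' (the standard inferential route in lme4, which provides no
#' denominator-df ANOVA F-test). If the mixed model fails to fit, the test
#' falls back to ordinary least squares with the same fixed effects and
#' reports that in the model description.
#'
#' @param long_table data.frame with columns `subject_id`, `group`, `week`,
#'   `normalized` for a single biomarker (time continuous, group two-level).
#' @param biomarker optional biomarker name recorded in the result.
#' @return list of class `InteractionTestResult`: `biomarker`, `p_value`,
#'   `model`, `group_sizes`.
#' @export
fit_group_time_interaction <- function(long_table, biomarker = NA_character_) {
  need <- c("subject_id", "group", "week", "normalized")
  stopifnot(is.data.frame(long_table), all(need %in% names(long_table)))
  d <- long_table[stats::complete.cases(long_table[, need]), need]
  d$group <- factor(d$group)
  if (nlevels(d$group) != 2L) stop("exactly two groups are required")
  if (length(unique(d$week)) < 3L)
    stop("at least three time points are required for a temporal interaction test")
  sizes <- vapply(split(d$subject_id, d$group), function(s) length(unique(s)), 1L)
  if (any(sizes < 2L)) stop("at least two subjects per group are required")

  p <- tryCatch({
    full <- suppressMessages(suppressWarnings(
      lme4::lmer(normalized ~ week * group + (1 | subject_id), data = d, REML = FALSE)))
    null <- suppressMessages(suppressWarnings(
      lme4::lmer(normalized ~ week + group + (1 | subject_id), data = d, REML = FALSE)))
    a <- stats::anova(null, full)
    list(p = a[["Pr(>Chisq)"]][2], model = "lmer LRT: week * group + (1 | subject)")
  }, error = function(e) {
    full <- stats::lm(normalized ~ week * group, data = d)
    null <- stats::lm(normalized ~ week + group, data = d)
    a <- stats::anova(null, full)
    list(p = a[["Pr(>F)"]][2],
         model = sprintf("OLS fallback (mixed model failed: %s)", conditionMessage(e)))
  })
  structure(list(biomarker = biomarker, p_value = p$p, model = p$model,
                 group_sizes = sizes),
            class = "InteractionTestResult")
}

#' Cross-correlation lag between a biomarker series and skin scores
#'
#' For each admissible integer shift on the common sampling grid, computes
#' the Pearson correlation between biomarker values and skin scores with the
#' score series shifted by the candidate lag, and returns the lag maximizing
#' the correlation. Sign convention: a negative lag means the biomarker
#' changes precede the score changes (`r(lag)` pairs `biomarker(w)` with
#' `score(w - lag)`), so a biomarker that predicts later dehiscence yields a
#' negative lag with a high coefficient. Ties are broken toward the smallest
#' absolute lag, then toward the negative (predictive) lag. Lags whose
#' overlap has fewer than `min_overlap` points, or over which either series
#' is constant, are skipped.
#'
#' @param biomarker_series numeric biomarker values on `weeks` (NA gaps
#'   allowed).
#' @param score_series numeric skin scores on the same `weeks`.
#' @param weeks evenly spaced sampling weeks.
#' @param max_lag_weeks maximum absolute lag examined (default 8).
#' @param min_overlap minimum paired points per lag (default 3).
#' @param subject_id,biomarker optional labels recorded in the result.
#' @return list of class `LagResult`: `lag_weeks`, `r`, `n`, plus labels.
#' @export
xcorr_lag <- function(biomarker_series, score_series, weeks,
                      max_lag_weeks = 8, min_overlap = 3L,
                      subject_id = NA_character_, biomarker = NA_character_) {
  stopifnot(length(biomarker_series) == length(weeks),
            length(score_series) == length(weeks), length(weeks) >= 2)
  step <- unique(diff(weeks))
  if (length(step) != 1L) stop("`weeks` must be evenly spaced")
  kmax <- floor(max_lag_weeks / step)
  n <- length(weeks)
  best <- NULL
  for (k in -kmax:kmax) {
    # lag = k * step; pair biomarker[i] with score[i - k]
    i <- seq_len(n)
    j <- i - k
    ok <- j >= 1 & j <= n
    b <- biomarker_series[i[ok]]
    s <- score_series[j[ok]]
    keep <- is.finite(b) & is.finite(s)
    b <- b[keep]; s <- s[keep]
    if (length(b) < min_overlap) next
    if (stats::sd(b) == 0 || stats::sd(s) == 0) next   # correlation undefined
    r <- stats::cor(b, s)
    cand <- list(lag_weeks = k * step, r = r, n = length(b))
    if (is.null(best) ||
        r > best$r + 1e-12 ||
        (abs(r - best$r) <= 1e-12 &&
           (abs(cand$lag_weeks) < abs(best$lag_weeks) ||
              (abs(cand$lag_weeks) == abs(best$lag_weeks) &&
                 cand$lag_weeks < best$lag_weeks))))
      best <- cand
  }
  if (is.null(best))
    stop("correlation undefined for constant series at every admissible lag")
  structure(c(best, list(subject_id = subject_id, biomarker = biomarker)),
            class = "LagResult")
}

#' One-sided t-test that correlation coefficients are positive
#'
#' Single-sample t-test of the group's per-subject maximum correlation
#' coefficients against zero, alternative mean > 0.
#'
#' @param coefficients numeric vector of correlation coefficients (>= 2).
#' @return one-sided p-value.
#' @export
ttest_positive_correlation <- function(coefficients) {
  coefficients <- coefficients[is.finite(coefficients)]
  if (length(coefficients) < 2L)
    stop("at least two correlation coefficients are required")
  if (stats::sd(coefficients) == 0) {
    # degenerate: all equal; decide by sign
    return(if (mean(coefficients) > 0) 0 else 1)
  }
  stats::t.test(coefficients, mu = 0, alternative = "greater")$p.value
}

#' Per-subject lag analysis over a whole study
#'
#' Runs [xcorr_lag()] for every subject x biomarker in a normalized long
#' table (see [assemble_series()]); subjects whose score series is constant
#' over every admissible overlap (typically healthy subjects scoring 5
#' throughout) have no defined correlation and are skipped with a notice.
#'
#' @param normalized_table output of [assemble_series()].
#' @param max_lag_weeks maximum absolute lag (default 8).
#' @return data.frame with one row per defined subject x biomarker lag:
#'   `subject_id`, `group`, `biomarker`, `lag_weeks`, `r`, `n`.
#' @export
study_lag_analysis <- function(normalized_table, max_lag_weeks = 8) {
  rows <- list()
  for (g in split(normalized_table,
                  list(normalized_table$subject_id, normalized_table$biomarker),
                  drop = TRUE)) {
    res <- tryCatch(
      xcorr_lag(g$normalized, g$score, g$week, max_lag_weeks,
                subject_id = g$subject_id[1], biomarker = g$biomarker[1]),
      error = function(e) NULL)
    if (is.null(res)) {
      message(sprintf("subject %s / %s: correlation undefined (constant series); excluded",
                      g$subject_id[1], g$biomarker[1]))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = g$subject_id[1], group = g$group[1], biomarker = g$biomarker[1],
      lag_weeks = res$lag_weeks, r = res$r, n = res$n)
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
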