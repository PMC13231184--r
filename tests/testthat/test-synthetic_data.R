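test_that("extinction table has the canonical spectral ordering and range", {
  expect_gt(tabulated_extinction("Hb", 700), tabulated_extinction("HbO2", 700))
  expect_gt(tabulated_extinction("HbO2", 900), tabulated_extinction("Hb", 900))
  expect_error(tabulated_extinction("Hb", 1200), "outside")
  expect_error(tabulated_extinction("HbO2", 400), "outside")
  A <- extinction_matrix()
  expect_equal(dim(A), c(6L, 2L))
  expect_true(all(A > 0))
})

test_that("US phantom: exact step interface, determinism, noise separation", {
  spec <- small_phantom()  # noiseless, flat interface at 3 mm
  us <- generate_us_volume(spec, 1)
  gt <- phantom_ground_truth(spec)
  # exact step function in Z: water 0, tissue 1
  expect_identical(us$values > 0.5, gt$tissue_mask)
  expect_true(all(us$values %in% c(spec$water_echo, spec$tissue_echo)))

  spec_n <- small_phantom(noise_us = 0.05)
  expect_identical(generate_us_volume(spec_n, 7)$values,
                   generate_us_volume(spec_n, 7)$values)
  expect_false(identical(generate_us_volume(spec_n, 7)$values,
                         generate_us_volume(spec_n, 8)$values))
  # water / tissue separation > 5 sigma at sigma = 5% of contrast
  usn <- generate_us_volume(spec_n, 7)
  sep <- mean(usn$values[gt$tissue_mask]) - mean(usn$values[!gt$tissue_mask])
  expect_gt(sep, 5 * 0.05)

  # surface leaving the grid is rejected
  expect_error(generate_us_volume(small_phantom(surface_depth_mm = 10), 1),
               "outside grid")
})

test_that("PA phantom is linear in concentration with tabulated spectral ratios", {
  zero <- small_phantom(vessels = list(list(from_mm = c(1, 2), to_mm = c(3, 2),
                                            radius_mm = 0.2, hb = 0, hbo2 = 0)))
  pa0 <- generate_pa_stack(zero, 1)
  gt <- phantom_ground_truth(zero)
  for (wl in names(pa0))  # zero concentration -> vessel voxels all zero
    expect_true(all(pa0[[wl]]$values[gt$tissue_mask] == 0))

  one <- small_phantom()
  two <- small_phantom(vessels = lapply(one$vessels, function(v) {
    v$hb <- 2 * v$hb; v$hbo2 <- 2 * v$hbo2; v
  }))
  pa1 <- generate_pa_stack(one, 1)
  pa2 <- generate_pa_stack(two, 1)
  gt1 <- phantom_ground_truth(one)
  for (wl in names(pa1))  # doubling both concentrations doubles amplitudes
    expect_equal(pa2[[wl]]$values[gt1$tissue_mask],
                 2 * pa1[[wl]]$values[gt1$tissue_mask], tolerance = 1e-12)

  # pure-Hb vessel: 700/900 amplitude ratio equals the extinction ratio
  pure <- small_phantom(vessels = list(list(from_mm = c(1, 2), to_mm = c(3, 2),
                                            radius_mm = 0.2, depth_frac = 0.5,
                                            hb = 1, hbo2 = 0)))
  pa <- generate_pa_stack(pure, 1)
  gtp <- phantom_ground_truth(pure)
  vx <- which(gtp$Hb == max(gtp$Hb), arr.ind = TRUE)[1, ]
  ratio <- pa[["700"]]$values[vx[1], vx[2], vx[3]] /
    pa[["900"]]$values[vx[1], vx[2], vx[3]]
  expect_equal(ratio, tabulated_extinction("Hb", 700) / tabulated_extinction("Hb", 900),
               tolerance = 1e-10)
})

test_that("cohort generator encodes decline, lag, and determinism", {
  sp <- cohort_spec(noise_sd = 0, subject_sd = 0)
  coh <- generate_longitudinal_cohort(sp, seed = 3)
  # configured 50% decline at week 12, sigma = 0
  e <- coh$series[coh$series$group == "exposed" &
                    coh$series$biomarker == "total_hemoglobin", ]
  one_subj <- e[e$subject_id == e$subject_id[1], ]
  expect_equal(one_subj$raw[one_subj$week == 12] / one_subj$raw[one_subj$week == 0],
               0.5, tolerance = 1e-12)
  # lag 0: score decline onset equals biomarker decline onset
  sp0 <- cohort_spec(lag_weeks = 0, noise_sd = 0, subject_sd = 0)
  coh0 <- generate_longitudinal_cohort(sp0, seed = 3)
  tr <- coh0$ground_truth$trajectories
  ex <- tr[tr$group == "exposed" & tr$subject_id == "E01", ]
  biom_onset <- min(ex$week[ex$multiplier < 1])
  score_onset <- min(ex$week[ex$score < 5])
  expect_equal(biom_onset, score_onset)
  # decline fraction 1 -> exposed indistinguishable in expectation
  flat <- generate_longitudinal_cohort(cohort_spec(final_fraction = 1, noise_sd = 0,
                                                   subject_sd = 0), seed = 3)
  expect_true(all(flat$ground_truth$trajectories$multiplier == 1))
  # fixed seed => bit-identical cohort
  expect_identical(generate_longitudinal_cohort(cohort_spec(), seed = 5)$series,
                   generate_longitudinal_cohort(cohort_spec(), seed = 5)$series)
  # invalid lag
  expect_error(cohort_spec(lag_weeks = 3), "multiple")
})

test_that("rendered cohort sessions carry the trajectory into the volumes", {
  sp <- cohort_spec(n_healthy = 1, n_exposed = 1, noise_sd = 0, subject_sd = 0,
                    weeks = seq(0, 12, 2))
  coh <- generate_longitudinal_cohort(sp, seed = 2, render = TRUE,
                                      phantom = small_phantom())
  expect_length(coh$sessions, 2 * 7)
  s0 <- coh$sessions[["E01_w00"]]
  s12 <- coh$sessions[["E01_w12"]]
  # noiseless vessel amplitudes at week 12 are half of week 0
  gt <- phantom_ground_truth(small_phantom())
  vessel <- gt$Hb > 0.5 * max(gt$Hb)
  expect_equal(s12$pa[["532"]]$values[vessel],
               0.5 * s0$pa[["532"]]$values[vessel], tolerance = 1e-10)
  # score onset 6 (decline onset 2 + lag 4), first reduced grade at week 8
  expect_equal(as.integer(s12$score), 2L)
  expect_equal(as.integer(s0$score), 5L)
})
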