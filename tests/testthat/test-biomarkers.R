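test_that("pa_vasculature is the masked mean with ROI restriction", {
  d <- c(10, 10, 12)
  shell <- array(FALSE, d); shell[, , 4:8] <- TRUE
  roi <- matrix(TRUE, 10, 10)
  vals <- array(0, d); vals[shell] <- 2.5
  expect_equal(pa_vasculature(vals, shell, roi), 2.5)
  expect_error(pa_vasculature(vals, array(FALSE, d), roi), "empty")

  # ROI excluding all vessels -> biomarker equals the background mean
  spec <- small_phantom(water_pa = 0.05)
  us <- generate_us_volume(spec, 1); seg <- segment_skin(us)
  pa <- generate_pa_stack(spec, 1)
  pan <- normalize_to_water(pa[["532"]], seg$water_mask)
  roi_off <- make_roi_mask("square", dims = c(40, 40), spacing_mm = 0.1,
                           size_mm = 0.8, center_mm = c(3.5, 3.5))
  # the vessel runs along y = 2 mm; this 0.8 mm ROI at (3.5, 3.5) avoids it
  bg <- pa_vasculature(pan, seg$skin_mask, roi_off)
  expect_lt(bg, 1e-6)  # background tissue has zero PA in the phantom
})

test_that("halving vessel amplitudes halves the vessel-attributable signal", {
  # vessel deep in the shell so its Gaussian tail does not reach the water
  # mask (which would couple the normalization constant to concentration)
  spec_full <- small_phantom(vessels = list(
    list(from_mm = c(0.5, 2), to_mm = c(3.5, 2), radius_mm = 0.15,
         depth_frac = 0.9, hb = 1, hbo2 = 0.5)))
  spec_half <- small_phantom(vessels = lapply(spec_full$vessels, function(v) {
    v$hb <- v$hb / 2; v$hbo2 <- v$hbo2 / 2; v
  }))
  spec_zero <- small_phantom(vessels = lapply(spec_full$vessels, function(v) {
    v$hb <- 0; v$hbo2 <- 0; v
  }))
  roi <- matrix(TRUE, 40, 40)
  bm <- function(spec) {
    us <- generate_us_volume(spec, 1); seg <- segment_skin(us)
    pa <- generate_pa_stack(spec, 1)
    pan <- normalize_to_water(pa[["532"]], seg$water_mask)
    pa_vasculature(pan, seg$skin_mask, roi)
  }
  full <- bm(spec_full); half <- bm(spec_half); zero <- bm(spec_zero)
  expect_equal(full - zero, 2 * (half - zero), tolerance = 1e-9)
})

test_that("vascular density is the ROI mean of the suppressed map", {
  roi <- matrix(TRUE, 30, 30)
  expect_equal(vascular_density(matrix(0, 30, 30), roi), 0)
  expect_equal(vascular_density(matrix(1, 30, 30), roi), 1)
  expect_error(vascular_density(matrix(1, 30, 30), matrix(FALSE, 30, 30)), "empty ROI")

  # adding a second horizontal vessel strictly increases the value
  one <- small_phantom()
  two <- small_phantom(vessels = c(one$vessels,
    list(list(from_mm = c(0.5, 3.2), to_mm = c(3.5, 3.2), radius_mm = 0.2,
              depth_frac = 0.5, hb = 1, hbo2 = 0.5))))
  vd <- function(spec) {
    us <- generate_us_volume(spec, 1); seg <- segment_skin(us)
    pan <- normalize_to_water(generate_pa_stack(spec, 1)[["532"]], seg$water_mask)
    vascular_density(vessel_map(pan, seg$skin_mask)$suppressed,
                     matrix(TRUE, 40, 40))
  }
  expect_gt(vd(two), vd(one))
})

test_that("total hemoglobin biomarker is linear and symmetric in species", {
  d <- c(8, 8, 10)
  shell <- array(FALSE, d); shell[, , 3:7] <- TRUE
  roi <- matrix(TRUE, 8, 8)
  expect_equal(total_hemoglobin_level(array(0, d), shell, roi), 0)
  thb <- array(runif(prod(d)), d)
  expect_equal(total_hemoglobin_level(3 * thb, shell, roi),
               3 * total_hemoglobin_level(thb, shell, roi), tolerance = 1e-12)

  # pure-Hb vs pure-HbO2 phantoms with equal total concentration
  mk <- function(hb, hbo2) {
    spec <- small_phantom(vessels = list(list(from_mm = c(0.5, 2), to_mm = c(3.5, 2),
      radius_mm = 0.2, depth_frac = 0.5, hb = hb, hbo2 = hbo2)))
    us <- generate_us_volume(spec, 1); seg <- segment_skin(us)
    pan <- lapply(generate_pa_stack(spec, 1), normalize_to_water,
                  water_mask = seg$water_mask)
    total_hemoglobin_level(unmix(pan)$THb, seg$skin_mask, matrix(TRUE, 40, 40))
  }
  expect_equal(mk(1, 0), mk(0, 1), tolerance = 0.02)
})

test_that("assemble_series normalizes to week 0 and tolerates truncation", {
  s <- data.frame(subject_id = "A", group = "exposed", week = c(0, 2),
                  score = c(5, 4), biomarker = "pa_vasculature", raw = c(2, 1))
  out <- assemble_series(s)
  expect_equal(out$normalized, c(1.0, 0.5))

  # death at week 4: a 3-visit series is processed without error
  tr <- data.frame(subject_id = "B", group = "exposed", week = c(0, 2, 4),
                   score = c(5, 5, 4), biomarker = "total_hemoglobin",
                   raw = c(1, 0.9, 0.7))
  out_tr <- assemble_series(tr)
  expect_equal(nrow(out_tr), 3L)
  expect_equal(out_tr$normalized[1], 1)

  no_base <- s; no_base$week <- c(2, 4)
  expect_error(assemble_series(no_base), "week-0")
  zero_base <- s; zero_base$raw <- c(0, 1)
  expect_error(assemble_series(zero_base), "non-positive")
})

test_that("normalized THb tracks the true decline within 2% (noiseless)", {
  sp <- cohort_spec(n_healthy = 0, n_exposed = 1, noise_sd = 0, subject_sd = 0)
  coh <- generate_longitudinal_cohort(sp, seed = 1, render = TRUE,
                                      phantom = small_phantom(water_pa = 0.05))
  d_true <- paskin:::decline_multiplier(sp)
  roi <- matrix(TRUE, 40, 40)
  got <- sapply(seq_along(sp$weeks), function(k) {
    s <- coh$sessions[[sprintf("E01_w%02d", sp$weeks[k])]]
    seg <- segment_skin(s$us)
    pan <- lapply(s$pa, normalize_to_water, water_mask = seg$water_mask)
    total_hemoglobin_level(unmix(pan)$THb, seg$skin_mask, roi)
  })
  expect_equal(got / got[1], d_true, tolerance = 0.02)
})
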