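# Shared fixture builders: everything is generated in code at test time.

# Bright Gaussian tube through the image centre at `angle` radians from the
# image-vertical (Y) axis; X = rows, Y = columns.
mk_tube <- function(n = 80, angle = 0, sigma = 2, amp = 1) {
  x <- matrix(seq_len(n) - n / 2, n, n)
  y <- matrix(seq_len(n) - n / 2, n, n, byrow = TRUE)
  d <- x * cos(angle) - y * sin(angle)   # perpendicular distance to the axis
  amp * exp(-d^2 / (2 * sigma^2))
}

# Isotropic Gaussian blob at the image centre.
mk_blob <- function(n = 80, sigma = 2, amp = 1) {
  x <- matrix(seq_len(n) - n / 2, n, n)
  amp * exp(-(x^2 + t(x)^2) / (2 * sigma^2))
}

# Small default phantom: flat interface at 3 mm, one horizontal vessel in the
# shell, optional noise/ridges.
small_phantom <- function(noise_us = 0, noise_pa = 0, vessels = NULL,
                          ridges = list(), dims = c(40, 40, 60),
                          surface_depth_mm = 3, ...) {
  if (is.null(vessels))
    vessels <- list(list(from_mm = c(0.5, 2), to_mm = c(3.5, 2), radius_mm = 0.2,
                         depth_frac = 0.5, hb = 1, hbo2 = 0.5))
  phantom_spec(dims = dims, surface_depth_mm = surface_depth_mm,
               vessels = vessels, ridges = ridges,
               noise_us = noise_us, noise_pa = noise_pa, ...)
}

# Dehiscence-site scenario: three horizontal vessels; the central one loses
# `drop` of its concentration from `drop_week` on, the score falls
# `lag_weeks` later. Returns per-week flattened THb maps, the truth
# footprint of the dropping vessel, and the score-drop week.
dehiscence_scenario <- function(seed, drop = 0.6, drop_week = 8,
                                lag_weeks = 2, noise_us = 0.05,
                                noise_pa = 0.01, dims = c(60, 60, 60)) {
  base_vessels <- list(
    list(from_mm = c(0.5, 1.5), to_mm = c(5.5, 1.5), radius_mm = 0.25,
         depth_frac = 0.5, hb = 1.0, hbo2 = 0.5),
    list(from_mm = c(0.5, 3.0), to_mm = c(5.5, 3.0), radius_mm = 0.25,
         depth_frac = 0.5, hb = 0.8, hbo2 = 0.8),
    list(from_mm = c(0.5, 4.5), to_mm = c(5.5, 4.5), radius_mm = 0.25,
         depth_frac = 0.5, hb = 0.6, hbo2 = 1.0))
  weeks <- seq(2, 12, 2)
  roi <- matrix(TRUE, dims[1], dims[2])
  maps <- list()
  for (w in weeks) {
    vs <- base_vessels
    if (w >= drop_week) {
      vs[[2]]$hb <- vs[[2]]$hb * (1 - drop)
      vs[[2]]$hbo2 <- vs[[2]]$hbo2 * (1 - drop)
    }
    spec <- phantom_spec(dims = dims, surface_depth_mm = 2.5, vessels = vs,
                         noise_us = noise_us, noise_pa = noise_pa)
    us <- generate_us_volume(spec, w * 1000L + seed)
    seg <- segment_skin(us)
    pa <- generate_pa_stack(spec, w * 1000L + seed)
    pan <- lapply(pa, normalize_to_water, water_mask = seg$water_mask)
    ch <- unmix(pan)
    maps[[as.character(w)]] <- flatten_thb(ch$THb, seg$skin_mask, roi)
  }
  truth_spec <- phantom_spec(dims = dims, surface_depth_mm = 2.5,
                             vessels = base_vessels)
  list(maps = maps, roi = roi, weeks = weeks,
       truth = phantom_ground_truth(truth_spec)$footprints[[2]],
       score_drop_week = drop_week + lag_weeks)
}

# Default study decline trajectory and its 4-week-delayed copy on the
# biweekly grid (the lag-recovery stated world).
lag_world <- function() {
  sp <- cohort_spec()
  w <- sp$weeks
  b <- paskin:::decline_multiplier(sp, w)
  s <- paskin:::decline_multiplier(sp, w - sp$lag_weeks)
  list(weeks = w, biomarker = b, score = s, lag = -sp$lag_weeks)
}
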