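test_that("volume3d enforces its invariants", {
  vals <- array(1, c(4, 4, 4))
  expect_error(volume3d(matrix(1, 4, 4), c(0.1, 0.1, 0.1), "US"), "3-D")
  expect_error(volume3d(vals, c(0.1, 0, 0.1), "US"), "positive")
  expect_error(volume3d(vals, c(0.1, 0.1, 0.1), "PA"), "wavelength")
  expect_error(volume3d(vals, c(0.1, 0.1, 0.1), "US", wavelength_nm = 532),
               "must not carry")
  bad <- vals; bad[2, 3, 1] <- NA
  expect_error(volume3d(bad, c(0.1, 0.1, 0.1), "US"), "non-finite voxel at \\(2, 3, 1\\)")
  v <- volume3d(vals, c(0.05, 0.23, 0.05), "PA", wavelength_nm = 800)
  expect_s3_class(v, "Volume3D")
  expect_identical(dim(v), c(4L, 4L, 4L))
})

test_that("NIfTI round trip is bit-exact for integer data and keeps metadata", {
  set.seed(11)
  vals <- array(as.numeric(sample.int(1000L, 23 * 10 * 20, TRUE)), c(23, 10, 20))
  v <- volume3d(vals, c(0.05, 0.23, 0.05), "US")
  for (ext in c(".nii", ".nii.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    save_volume(v, path, datatype = "int16")
    v2 <- load_volume(path, modality = "US")
    expect_identical(v2$values, v$values)
    expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  }
  # float64 round-trips doubles bit-exactly
  path <- withr::local_tempfile(fileext = ".nii")
  vf <- volume3d(array(runif(60), c(3, 4, 5)), c(0.1, 0.1, 0.1), "US")
  save_volume(vf, path, datatype = "float64")
  expect_identical(load_volume(path, modality = "US")$values, vf$values)
})

test_that("load_volume rejects missing files and non-3-D content", {
  expect_error(load_volume("/nonexistent/vol.nii", modality = "US"), "not found")
  # craft a 2-D NIfTI by writing a 3-D file with a degenerate header via the
  # internal writer, then truncating dim[0]
  path <- withr::local_tempfile(fileext = ".nii")
  paskin:::write_nifti(array(1, c(4, 4, 1)), c(1, 1, 1), path)
  raw <- readBin(path, "raw", file.size(path))
  raw[41:42] <- writeBin(2L, raw(), size = 2, endian = "little")  # dim[0] = 2
  writeBin(raw, path)
  expect_error(load_volume(path, modality = "US"), "not a 3-D")
})

test_that("resampling reaches the 0.1 mm study grid from scanner spacing", {
  # scanner voxels 0.05 x 0.23 x 0.05 mm -> 0.1 mm isotropic
  v <- volume3d(array(runif(46 * 23 * 40), c(46, 23, 40)),
                c(0.05, 0.23, 0.05), "US")
  r <- resample_isotropic(v, 0.1)
  expect_equal(r$spacing, rep(0.1, 3))
  # physical extent preserved to within one voxel
  expect_true(all(abs(dim(r$values) * 0.1 - dim(v$values) * v$spacing) <= 0.1))
})

test_that("resampling is exact on constants, identity at target, linear on ramps", {
  const <- volume3d(array(3.7, c(8, 8, 8)), c(0.05, 0.23, 0.05), "US")
  rc <- resample_isotropic(const, 0.1)
  expect_lt(max(abs(rc$values - 3.7)), 1e-6)

  v <- volume3d(array(runif(512), c(8, 8, 8)), c(0.1, 0.1, 0.1), "US")
  expect_identical(resample_isotropic(v, 0.1)$values, v$values)

  # linear ramp along X resampled at half resolution: trilinear interpolation
  # reproduces the analytic ramp away from clamped borders
  nx <- 40
  ramp <- volume3d(array(rep((seq_len(nx) - 0.5) * 0.1, 6 * 6), c(nx, 6, 6)),
                   c(0.1, 0.1, 0.1), "US")
  r2 <- resample_isotropic(ramp, 0.2)
  expected <- (seq_len(dim(r2$values)[1]) - 0.5) * 0.2
  inner <- 2:(length(expected) - 1)
  expect_equal(r2$values[inner, 3, 3], expected[inner], tolerance = 1e-10)
})

test_that("resampling errors on degenerate axes and round-trips smooth volumes", {
  flat <- volume3d(array(1, c(8, 1, 8)), c(0.1, 0.1, 0.1), "US")
  expect_error(resample_isotropic(flat, 0.05), "degenerate axis Y")

  # band-limited phantom: smooth low-frequency field survives a down-up cycle
  # in the interior (borders are clamped by design)
  n <- 24
  g <- seq(0, pi, length.out = n)
  smooth <- array(outer(outer(sin(g), cos(g / 2)), sin(g / 3) + 1.5), c(n, n, n))
  v <- volume3d(pmax(smooth + 2, 0), c(0.1, 0.1, 0.1), "US")
  down <- resample_isotropic(v, 0.2)
  back <- resample_isotropic(down, 0.1)
  inner <- 3:(n - 2)
  err <- max(abs(back$values[inner, inner, inner] - v$values[inner, inner, inner]))
  expect_lt(err, 0.05 * diff(range(v$values)))
})

test_that("skin scores and sessions validate their contracts", {
  expect_error(skin_score(0), "1..5")
  expect_error(skin_score(6), "1..5")
  expect_error(skin_score(2.5), "1..5")
  expect_match(attr(skin_score(5), "label"), "no visible")
  expect_match(attr(skin_score(1), "label"), "severe dehiscence")

  spec <- small_phantom()
  us <- generate_us_volume(spec, 1)
  pa <- generate_pa_stack(spec, 1)
  s <- imaging_session("m1", 0, us, pa, 5)
  expect_s3_class(s, "ImagingSession")
  expect_error(imaging_session("m1", 0, us, pa[-1], 5), "seven study wavelengths")
  # co-registration violation
  pa_bad <- pa
  pa_bad[["532"]] <- volume3d(array(1, c(2, 2, 2)), rep(0.1, 3), "PA", 532)
  expect_error(imaging_session("m1", 0, us, pa_bad, 5), "co-registration")
})

test_that("study manifests validate and round-trip through JSON", {
  subjects <- data.frame(subject_id = c("A", "B"), group = c("healthy", "exposed"))
  sessions <- data.frame(subject_id = c("A", "A", "B"), week = c(0, 2, 0),
                         score = c(5, 5, 4))
  m <- study_manifest(subjects, sessions)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(m, path)
  m2 <- read_manifest(path)
  expect_equal(m2$subjects$subject_id, m$subjects$subject_id)
  expect_equal(m2$sessions$week, m$sessions$week)

  bad <- sessions; bad$week <- c(0, 0, 0)
  expect_error(study_manifest(subjects, bad), "strictly increasing")
  expect_error(study_manifest(data.frame(subject_id = "A", group = "whatever"),
                              sessions[1, ]), "unknown group")
})
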