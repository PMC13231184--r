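#' Specification of a synthetic US/PA skin phantom
#'
#' Describes a stated imaging world: an anechoic water layer over a
#' hyperechoic tissue block whose upper surface z0(x, y) is flat or raised
#' into a Gaussian mound (emulating the skin tented over an implant), a skin
#' shell of fixed thickness below the surface, tubular blood vessels running
#' inside the shell with Gaussian cross-sections and wavelength-dependent
#' photoacoustic contrast from their Hb/HbO2 content, and vertical
#' implant-surface ridge artifacts.
#'
#' @param dims grid size (X, Y, Z) in voxels.
#' @param spacing_mm isotropic voxel size in mm.
#' @param surface_depth_mm depth of the flat water-skin interface (mm).
#' @param mound_height_mm height of the Gaussian mound raising the surface
#'   toward the transducer (0 = flat interface).
#' @param mound_sigma_mm lateral standard deviation of the mound.
#' @param mound_center_mm lateral (x, y) centre of the mound; default the
#'   field centre.
#' @param skin_thickness_mm skin shell thickness (study value 0.5 mm).
#' @param vessels list of vessels; each a list with `from_mm`, `to_mm`
#'   (lateral endpoints, mm), `radius_mm`, `depth_frac` (centreline depth as a
#'   fraction of the shell thickness below the surface), `hb`, `hbo2`
#'   (concentrations, arbitrary units).
#' @param ridges list of vertical ridge artifacts; each a list with `x_mm`
#'   (lateral position), `amplitude`, and optional `width_mm` (default 0.2).
#'   Ridges run along the full Y extent (the image-vertical of the en-face
#'   map) and through the skin shell in depth.
#' @param tissue_echo,water_echo mean US amplitudes of tissue and water.
#' @param water_pa small constant PA amplitude of water (exercises water
#'   normalization; default 0.05).
#' @param noise_us,noise_pa additive Gaussian noise standard deviations.
#' @param fluence named numeric vector of relative fluence per wavelength;
#'   default 1 at all seven study wavelengths.
#' @param pa_scale global scale applied to extinction x concentration
#'   products to keep amplitudes O(1) (arbitrary units).
#' @return object of class `PhantomSpec`.
#' @export
phantom_spec <- function(dims = c(64, 64, 80), spacing_mm = 0.1,
                         surface_depth_mm = 3, mound_height_mm = 0,
                         mound_sigma_mm = 2, mound_center_mm = NULL,
                         skin_thickness_mm = 0.5,
                         vessels = list(), ridges = list(),
                         tissue_echo = 1, water_echo = 0, water_pa = 0.05,
                         noise_us = 0, noise_pa = 0,
                         fluence = NULL, pa_scale = 1e-3) {
  stopifnot(length(dims) == 3L, all(dims >= 2), spacing_mm > 0,
            skin_thickness_mm > 0, surface_depth_mm > 0,
            noise_us >= 0, noise_pa >= 0, water_pa >= 0)
  if (is.null(fluence)) fluence <- stats::setNames(rep(1, 7), pa_wavelengths())
  if (!all(as.character(pa_wavelengths()) %in% names(fluence)))
    stop("`fluence` must be named by the seven study wavelengths")
  if (is.null(mound_center_mm)) mound_center_mm <- dims[1:2] * spacing_mm / 2
  for (v in vessels) {
    stopifnot(length(v$from_mm) == 2L, length(v$to_mm) == 2L)
    if (v$radius_mm <= 0) stop("vessel radii must be > 0")
    if ((v$hb %||% 0) < 0 || (v$hbo2 %||% 0) < 0) stop("concentrations must be >= 0")
    df <- v$depth_frac %||% 0.5
    if (df < 0 || df > 1) stop("vessels must lie within the skin shell (depth_frac in [0,1])")
  }
  structure(list(dims = as.integer(dims), spacing_mm = spacing_mm,
                 surface_depth_mm = surface_depth_mm,
                 mound_height_mm = mound_height_mm,
                 mound_sigma_mm = mound_sigma_mm,
                 mound_center_mm = mound_center_mm,
                 skin_thickness_mm = skin_thickness_mm,
                 vessels = vessels, ridges = ridges,
                 tissue_echo = tissue_echo, water_echo = water_echo,
                 water_pa = water_pa, noise_us = noise_us, noise_pa = noise_pa,
                 fluence = fluence, pa_scale = pa_scale),
            class = "PhantomSpec")
}

# Lateral voxel-centre coordinate vectors (mm).
.lateral_coords <- function(spec) {
  list(x = (seq_len(spec$dims[1]) - 0.5) * spec$spacing_mm,
       y = (seq_len(spec$dims[2]) - 0.5) * spec$spacing_mm)
}

# Skin surface depth z0(x, y) in mm: flat minus a Gaussian mound.
phantom_surface <- function(spec) {
  co <- .lateral_coords(spec)
  z0 <- matrix(spec$surface_depth_mm, spec$dims[1], spec$dims[2])
  if (spec$mound_height_mm != 0) {
    r2 <- outer((co$x - spec$mound_center_mm[1])^2,
                (co$y - spec$mound_center_mm[2])^2, `+`)
    z0 <- z0 - spec$mound_height_mm * exp(-r2 / (2 * spec$mound_sigma_mm^2))
  }
  z0
}

# 3-D concentration fields (noiseless ground truth), plus per-vessel lateral
# footprints (|lateral distance to centreline| <= radius).
phantom_concentrations <- function(spec) {
  d <- spec$dims
  co <- .lateral_coords(spec)
  zc <- (seq_len(d[3]) - 0.5) * spec$spacing_mm
  z0 <- phantom_surface(spec)
  hb <- array(0, d); hbo2 <- array(0, d)
  footprints <- list()
  gx <- matrix(co$x, d[1], d[2])
  gy <- matrix(co$y, d[1], d[2], byrow = TRUE)
  for (i in seq_along(spec$vessels)) {
    v <- spec$vessels[[i]]
    sig <- v$radius_mm / 2
    # lateral distance of every column to the centreline segment
    ab <- v$to_mm - v$from_mm
    len2 <- sum(ab^2)
    if (len2 == 0) {
      t_par <- 0
      dl2 <- (gx - v$from_mm[1])^2 + (gy - v$from_mm[2])^2
    } else {
      t_par <- pmin(1, pmax(0, ((gx - v$from_mm[1]) * ab[1] + (gy - v$from_mm[2]) * ab[2]) / len2))
      px <- v$from_mm[1] + t_par * ab[1]
      py <- v$from_mm[2] + t_par * ab[2]
      dl2 <- (gx - px)^2 + (gy - py)^2
    }
    zv <- z0 + (v$depth_frac %||% 0.5) * spec$skin_thickness_mm
    lat <- exp(-dl2 / (2 * sig^2))                       # (X x Y)
    prof <- array(0, d)
    for (k in seq_len(d[3]))
      prof[, , k] <- lat * exp(-(zc[k] - zv)^2 / (2 * sig^2))
    hb <- hb + (v$hb %||% 0) * prof
    hbo2 <- hbo2 + (v$hbo2 %||% 0) * prof
    footprints[[i]] <- dl2 <= v$radius_mm^2
  }
  list(Hb = hb, HbO2 = hbo2, footprints = footprints)
}

#' Ground truth of a phantom
#'
#' Analytic masks and fields implied by a [phantom_spec()], used to score the
#' pipeline: tissue/water/skin-shell masks on the same first-voxel-centre
#' convention as the segmentation stage, the interface depth map, noiseless
#' chromophore fields, and per-vessel lateral footprints.
#'
#' @param spec a [phantom_spec()].
#' @return list with `tissue_mask`, `water_mask`, `skin_mask`,
#'   `interface_depth`, `Hb`, `HbO2`, `footprints`.
#' @export
phantom_ground_truth <- function(spec) {
  d <- spec$dims
  zc <- (seq_len(d[3]) - 0.5) * spec$spacing_mm
  z0 <- phantom_surface(spec)
  if (any(z0 <= 0) || any(z0 >= d[3] * spec$spacing_mm))
    stop("skin surface outside grid")
  tissue <- array(FALSE, d); shell <- array(FALSE, d)
  k0 <- matrix(findInterval(z0 - 1e-9, zc) + 1L, d[1], d[2]) # first centre >= z0
  nsh <- max(1L, as.integer(round(spec$skin_thickness_mm / spec$spacing_mm)))
  for (k in seq_len(d[3])) {
    tissue[, , k] <- k >= k0
    shell[, , k] <- k >= k0 & k < k0 + nsh
  }
  conc <- phantom_concentrations(spec)
  list(tissue_mask = tissue, water_mask = !tissue, skin_mask = shell,
       interface_depth = z0, Hb = conc$Hb, HbO2 = conc$HbO2,
       footprints = conc$footprints)
}

#' Generate a synthetic ultrasound volume
#'
#' Water voxels take `water_echo`, tissue voxels `tissue_echo`, plus additive
#' Gaussian noise (clamped at zero). Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @return a [volume3d()] of modality `"US"`.
#' @export
generate_us_volume <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "PhantomSpec"))
  gt <- phantom_ground_truth(spec)
  vals <- ifelse(gt$tissue_mask, spec$tissue_echo, spec$water_echo)
  vals <- array(vals, spec$dims)
  if (spec$noise_us > 0) {
    set.seed(derive_seed(seed, 1L))
    vals <- vals + stats::rnorm(length(vals), sd = spec$noise_us)
  }
  volume3d(pmax(vals, 0), rep(spec$spacing_mm, 3L), "US")
}

#' Generate a synthetic photoacoustic stack at the seven study wavelengths
#'
#' Vessel voxel amplitude at wavelength `l` is
#' `fluence(l) * pa_scale * (eps_Hb(l) * C_Hb + eps_HbO2(l) * C_HbO2)` with a
#' Gaussian radial profile (sigma = radius / 2); ridge artifacts are added as
#' depth-extended sheets along Y through the skin shell; water voxels carry a
#' small constant reference amplitude so downstream water normalization is
#' exercised. Additive Gaussian noise, clamped at zero.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer RNG seed.
#' @return named list of PA [volume3d()] objects, one per wavelength.
#' @export
generate_pa_stack <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "PhantomSpec"))
  gt <- phantom_ground_truth(spec)
  d <- spec$dims
  co <- .lateral_coords(spec)
  ridge <- array(0, d)
  if (length(spec$ridges)) {
    for (r in spec$ridges) {
      w <- r$width_mm %||% 0.2
      lat <- exp(-(co$x - r$x_mm)^2 / (2 * (w / 2)^2))   # profile across X
      sheet <- matrix(lat, d[1], d[2])                   # full Y extent
      for (k in seq_len(d[3]))
        ridge[, , k] <- ridge[, , k] + r$amplitude * sheet * gt$skin_mask[, , k]
    }
  }
  out <- list()
  for (i in seq_along(pa_wavelengths())) {
    wl <- pa_wavelengths()[i]
    amp <- spec$fluence[[as.character(wl)]] * spec$pa_scale *
      (tabulated_extinction("Hb", wl) * gt$Hb +
         tabulated_extinction("HbO2", wl) * gt$HbO2)
    amp <- amp + spec$fluence[[as.character(wl)]] * ridge
    amp[gt$water_mask] <- amp[gt$water_mask] + spec$water_pa
    if (spec$noise_pa > 0) {
      set.seed(derive_seed(seed, 100L + i))
      amp <- amp + stats::rnorm(length(amp), sd = spec$noise_pa)
    }
    out[[as.character(wl)]] <- volume3d(pmax(amp, 0), rep(spec$spacing_mm, 3L),
                                        "PA", wavelength_nm = wl)
  }
  out
}
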