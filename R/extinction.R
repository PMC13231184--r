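#' @title Hemoglobin molar extinction spectra
#' @description
#' Tabulated molar extinction coefficients (cm^-1 M^-1) of oxyhemoglobin and
#' deoxyhemoglobin over 500-1000 nm, an approximate digitization of the
#' standard compiled whole-blood spectra (S. Prahl's OMLC compilation of
#' oxy/deoxyhemoglobin absorption). Only relative values matter in this
#' pipeline: photoacoustic amplitudes are in arbitrary units and unmixed
#' concentrations are reported relative, so a smooth approximation of the
#' canonical spectra is sufficient and is documented as such.
#' @name extinction
NULL

# wavelength_nm, eps_HbO2, eps_Hb (cm^-1 / M); approximate values
.hb_extinction <- data.frame(
  wavelength_nm = c(500, 520, 532, 540, 550, 560, 570, 576, 580, 600, 620, 650,
                    680, 700, 710, 730, 750, 760, 780, 800, 820, 840, 850, 860,
                    880, 900, 920, 940, 950, 970, 1000),
  HbO2 = c(20932, 24600, 44500, 53236, 43016, 32610, 44496, 55540, 50104, 3200,
           942, 368, 276, 290, 314, 390, 518, 586, 710, 816, 916, 1022, 1058,
           1092, 1154, 1198, 1232, 1258, 1266, 1280, 1200),
  Hb   = c(20862, 25770, 41000, 46592, 53412, 53788, 45072, 38750, 37020, 14677,
           6510, 3750, 2407, 1794, 1540, 1300, 1405, 1548, 1171, 762, 693, 694,
           691, 700, 726, 761, 796, 900, 930, 990, 1050)
)

#' Molar extinction coefficient of a hemoglobin species
#'
#' Linear interpolation of the bundled 500-1000 nm compilation (see
#' [extinction]). Deoxyhemoglobin dominates at 700 nm, oxyhemoglobin at
#' 900 nm, with the isosbestic point near 800 nm.
#'
#' @param chromophore `"Hb"` (deoxy) or `"HbO2"` (oxy).
#' @param wavelength_nm wavelength in nm, within 500-1000.
#' @return extinction coefficient in cm^-1 M^-1.
#' @examples
#' tabulated_extinction("Hb", 700) > tabulated_extinction("HbO2", 700)
#' @export
tabulated_extinction <- function(chromophore = c("Hb", "HbO2"), wavelength_nm) {
  chromophore <- match.arg(chromophore)
  stopifnot(is.numeric(wavelength_nm))
  rng <- range(.hb_extinction$wavelength_nm)
  if (any(wavelength_nm < rng[1] | wavelength_nm > rng[2]))
    stop(sprintf("wavelength outside bundled extinction table (%g-%g nm)", rng[1], rng[2]))
  stats::approx(.hb_extinction$wavelength_nm, .hb_extinction[[chromophore]],
                xout = wavelength_nm)$y
}

#' The seven study wavelengths (nm)
#' @export
pa_wavelengths <- function() c(532, 700, 750, 800, 850, 900, 950)

#' The six wavelengths used for spectral unmixing (532 nm excluded)
#' @export
unmixing_wavelengths <- function() c(700, 750, 800, 850, 900, 950)

#' Extinction matrix for spectral unmixing
#'
#' @param wavelengths_nm wavelengths (rows), default the six unmixing bands.
#' @return numeric matrix, one row per wavelength, columns `Hb` and `HbO2`.
#' @export
extinction_matrix <- function(wavelengths_nm = unmixing_wavelengths()) {
  m <- cbind(Hb = tabulated_extinction("Hb", wavelengths_nm),
             HbO2 = tabulated_extinction("HbO2", wavelengths_nm))
  rownames(m) <- as.character(wavelengths_nm)
  m
}
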