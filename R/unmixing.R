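#' Linear spectral unmixing of hemoglobin from a multiwavelength PA stack
#'
#' Open stand-in for the proprietary unmixing tool: per voxel, solves
#' \deqn{\min_{C \ge 0} \| A C - p \|_2}
#' where `A` is the extinction matrix (rows = wavelengths, columns = Hb,
#' HbO2, optionally fluence-weighted) and `p` the vector of PA amplitudes at
#' the six unmixing wavelengths (700-950 nm; 532 nm is excluded). With two
#' chromophores the non-negative least-squares solution is available in
#' closed form — the unconstrained solution when it is feasible, otherwise
#' the better of the two single-chromophore fits clamped at zero — and is
#' computed fully vectorized over voxels. Deterministic.
#'
#' @param pa_stack named list of co-registered PA [volume3d()] objects
#'   containing (at least) the six unmixing wavelengths.
#' @param spectra 6 x 2 extinction matrix (columns `Hb`, `HbO2`); default
#'   [extinction_matrix()].
#' @param fluence optional length-6 relative fluence weights applied to the
#'   rows of `spectra`.
#' @param so2 logical; also compute oxygen saturation (see
#'   [oxygen_saturation()]).
#' @param thb_floor total-hemoglobin floor below which sO2 is undefined;
#'   default 1\% of the 99th percentile of THb.
#' @return object of class `ChromophoreMaps`: list with 3-D arrays `Hb`,
#'   `HbO2`, `THb` (= Hb + HbO2 exactly), optional `sO2` (NA where
#'   undefined), plus `spacing`.
#' @export
unmix <- function(pa_stack, spectra = extinction_matrix(), fluence = NULL,
                  so2 = FALSE, thb_floor = NULL) {
  wl <- unmixing_wavelengths()
  missing_wl <- setdiff(as.character(wl), names(pa_stack))
  if (length(missing_wl))
    stop(sprintf("missing wavelength(s) for unmixing: %s nm",
                 paste(missing_wl, collapse = ", ")))
  vols <- pa_stack[as.character(wl)]
  d <- dim(vols[[1]]$values)
  sp <- vols[[1]]$spacing
  for (v in vols)
    if (!identical(dim(v$values), d)) stop("unmixing stack is not co-registered")
  A <- as.matrix(spectra)
  stopifnot(nrow(A) == length(wl), ncol(A) == 2L)
  if (!is.null(fluence)) {
    stopifnot(length(fluence) == nrow(A), all(fluence > 0))
    A <- A * fluence
  }
  if (qr(A)$rank < 2L) stop("rank-deficient extinction matrix")

  P <- vapply(vols, function(v) as.vector(v$values), numeric(prod(d)))  # nvox x 6
  G <- crossprod(A)                 # 2 x 2
  B <- P %*% A                      # nvox x 2, = t(A) p per voxel
  Cunc <- B %*% solve(G)            # unconstrained LS
  hb <- Cunc[, 1]; hbo2 <- Cunc[, 2]
  infeas <- hb < 0 | hbo2 < 0
  if (any(infeas)) {
    b1 <- B[infeas, 1]; b2 <- B[infeas, 2]
    c1 <- pmax(0, b1 / G[1, 1])     # Hb-only fit
    c2 <- pmax(0, b2 / G[2, 2])     # HbO2-only fit
    # residual difference (constant ||p||^2 dropped)
    f1 <- -2 * c1 * b1 + c1^2 * G[1, 1]
    f2 <- -2 * c2 * b2 + c2^2 * G[2, 2]
    use1 <- f1 <= f2
    hb[infeas] <- ifelse(use1, c1, 0)
    hbo2[infeas] <- ifelse(use1, 0, c2)
  }
  maps <- structure(list(Hb = array(hb, d), HbO2 = array(hbo2, d),
                         THb = array(hb + hbo2, d), spacing = sp),
                    class = "ChromophoreMaps")
  if (so2) maps$sO2 <- oxygen_saturation(maps, thb_floor)
  maps
}

#' Oxygen saturation from unmixed chromophore maps
#'
#' sO2 = HbO2 / (Hb + HbO2) wherever total hemoglobin reaches `thb_floor`;
#' masked (`NA`) elsewhere, so near-zero-signal voxels never contribute to
#' any mean.
#'
#' @param maps a `ChromophoreMaps` object from [unmix()].
#' @param thb_floor minimum THb; default 1\% of the volume's 99th-percentile
#'   THb.
#' @return 3-D array of sO2 in \[0, 1\] with `NA` where undefined.
#' @export
oxygen_saturation <- function(maps, thb_floor = NULL) {
  stopifnot(inherits(maps, "ChromophoreMaps"))
  thb <- maps$THb
  if (is.null(thb_floor))
    thb_floor <- 0.01 * stats::quantile(thb, 0.99, names = FALSE)
  s <- maps$HbO2 / thb
  s[!(thb > 0 & thb >= thb_floor)] <- NA_real_
  s
}
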