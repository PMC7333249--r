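#' Per-wavelength correlation between spectra and leaf N
#'
#' Computes the band-wise Pearson correlation between each spectral band
#' and leaf N concentration. In vegetation spectra this reproduces the
#' canonical pattern: negative correlation across the visible (chlorophyll
#' absorption deepens with N) and positive correlation across the NIR
#' (canopy structure grows with N). Bands with zero variance get `r = 0`
#' with a warning.
#'
#' @param dataset a [spectral_dataset()] (any domain) with at least 3
#'   samples and non-constant leaf N.
#' @return A `correlation_profile`: data frame with columns
#'   `wavelength_nm` and `r`, plus attributes `n` (sample count) and
#'   `technique` (the dataset's domain tag).
#' @export
wavelength_correlations <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  n <- nrow(dataset$reflectance)
  if (n < 3L) stop_nspec("size", "need at least 3 samples")
  if (sd(dataset$leaf_n) == 0)
    stop_nspec("degenerate", "leaf_n is constant; correlations undefined")
  band_sd <- apply(dataset$reflectance, 2L, sd)
  r <- rep(0, length(band_sd))
  ok <- band_sd > 0
  if (any(!ok))
    warning(sprintf("%d constant band(s) set to r = 0", sum(!ok)))
  r[ok] <- drop(cor(dataset$reflectance[, ok, drop = FALSE], dataset$leaf_n))
  structure(data.frame(wavelength_nm = dataset$wavelengths, r = r),
            n = n,
            technique = if (dataset$domain_tag == "reflectance") "raw"
                        else dataset$domain_tag,
            class = c("correlation_profile", "data.frame"))
}

#' Mean correlation per spectral region
#'
#' Averages the per-band correlation over named closed wavelength
#' intervals (e.g. the conventional UV/visible/NIR split).
#'
#' @param profile a `correlation_profile` from [wavelength_correlations()].
#' @param regions named list of length-2 numeric vectors `c(lo, hi)` (nm).
#'   Defaults follow the study's regions: "uv" 400-420, "visible" 420-700,
#'   "nir" 700-950, with boundary bands assigned to the lower region.
#' @return Named numeric vector of per-region mean r.
#' @export
region_mean_r <- function(profile,
                          regions = list(uv = c(400, 420),
                                         visible = c(420, 700),
                                         nir = c(700, 950))) {
  stopifnot(inherits(profile, "correlation_profile"))
  wl <- profile$wavelength_nm
  assigned <- rep(FALSE, length(wl))
  out <- vapply(regions, function(iv) {
    sel <- wl >= iv[1] & wl <= iv[2] & !assigned
    assigned <<- assigned | sel
    if (!any(sel)) stop_nspec("region", "empty region [%g, %g]", iv[1], iv[2])
    mean(profile$r[sel])
  }, numeric(1))
  names(out) <- names(regions)
  out
}

#' Write a correlation profile as CSV
#'
#' Two columns: `wavelength_nm`, `r`.
#'
#' @param profile a `correlation_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
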