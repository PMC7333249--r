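#' Spectral dataset container
#'
#' Bundles a wavelength grid, a samples-by-wavelengths spectral matrix and
#' the per-sample leaf nitrogen concentration (%). The `domain_tag` records
#' which spectral domain the matrix lives in: `"reflectance"` (values in
#' \[0, 1\]), `"fdr"` (first-derivative reflectance, 1/nm) or `"cr"`
#' (continuum-removed, values in (0, 1\]).
#'
#' @param wavelengths strictly increasing numeric vector of wavelengths (nm).
#' @param reflectance numeric matrix, one row per sample, one column per
#'   wavelength.
#' @param leaf_n numeric vector of leaf N concentration (%), one per sample.
#' @param sample_ids optional character vector of sample labels.
#' @param domain_tag one of `"reflectance"`, `"fdr"`, `"cr"`.
#' @return An object of class `spectral_dataset`: a list with elements
#'   `wavelengths`, `reflectance`, `leaf_n`, `sample_ids`, `domain_tag`.
#' @examples
#' wl <- 400:410
#' refl <- matrix(runif(2 * length(wl), 0.1, 0.5), nrow = 2)
#' ds <- spectral_dataset(wl, refl, leaf_n = c(2.1, 4.3))
#' ds
#' @export
spectral_dataset <- function(wavelengths, reflectance, leaf_n,
                             sample_ids = NULL,
                             domain_tag = c("reflectance", "fdr", "cr")) {
  domain_tag <- match.arg(domain_tag)
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.matrix(reflectance)
  leaf_n <- as.numeric(leaf_n)
  if (length(wavelengths) < 1L || any(diff(wavelengths) <= 0))
    stop_nspec("domain", "`wavelengths` must be strictly increasing")
  if (ncol(reflectance) != length(wavelengths))
    stop_nspec("shape", "reflectance has %d columns but %d wavelengths given",
               ncol(reflectance), length(wavelengths))
  if (nrow(reflectance) != length(leaf_n))
    stop_nspec("shape", "reflectance has %d rows but %d leaf_n values",
               nrow(reflectance), length(leaf_n))
  if (!all(is.finite(reflectance)))
    stop_nspec("domain", "reflectance values must all be finite")
  if (length(reflectance)) {
    if (domain_tag == "reflectance" &&
        (min(reflectance) < 0 || max(reflectance) > 1))
      stop_nspec("domain", "reflectance-domain values must lie in [0, 1]")
    if (domain_tag == "cr" &&
        (min(reflectance) <= 0 || max(reflectance) > 1 + 1e-10))
      stop_nspec("domain", "continuum-removed values must lie in (0, 1]")
  }
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%04d", seq_len(nrow(reflectance)))
  if (length(sample_ids) != nrow(reflectance))
    stop_nspec("shape", "sample_ids length does not match sample count")
  dimnames(reflectance) <- list(sample_ids, format_wavelength(wavelengths))
  structure(list(wavelengths = wavelengths,
                 reflectance = reflectance,
                 leaf_n = leaf_n,
                 sample_ids = as.character(sample_ids),
                 domain_tag = domain_tag),
            class = "spectral_dataset")
}

format_wavelength <- function(wl) {
  ifelse(wl == round(wl), sprintf("%d", as.integer(round(wl))),
         sub("0+$", "", sprintf("%.4f", wl)))
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d samples x %d bands (%g-%g nm), domain '%s'\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths), x$domain_tag))
  cat(sprintf("  leaf N: %.2f-%.2f %% (mean %.2f)\n",
              min(x$leaf_n), max(x$leaf_n), mean(x$leaf_n)))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$reflectance)

# row subset, keeping all metadata aligned
subset_samples <- function(dataset, idx) {
  spectral_dataset(dataset$wavelengths,
                   dataset$reflectance[idx, , drop = FALSE],
                   dataset$leaf_n[idx],
                   dataset$sample_ids[idx],
                   dataset$domain_tag)
}

#' Read and write spectral datasets as CSV
#'
#' The on-disk dialect is one header row with columns `sample_id`,
#' `leaf_n_pct`, then one column per band named by its wavelength in nm;
#' UTF-8, `.` decimal separator. Transformed datasets (`fdr`, `cr`) carry an
#' extra leading comment line `# domain_tag: <tag>` so the spectral domain
#' survives a round trip; plain reflectance files have no comment line.
#'
#' @param dataset a [spectral_dataset()].
#' @param path file path.
#' @return `write_spectra_csv()` returns `path` invisibly;
#'   `read_spectra_csv()` returns a [spectral_dataset()].
#' @export
write_spectra_csv <- function(dataset, path) {
  df <- data.frame(sample_id = dataset$sample_ids,
                   leaf_n_pct = dataset$leaf_n,
                   dataset$reflectance,
                   check.names = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (dataset$domain_tag != "reflectance")
    writeLines(sprintf("# domain_tag: %s", dataset$domain_tag), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  first <- readLines(path, n = 1L)
  tag <- "reflectance"
  skip <- 0L
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("domain_tag:\\s*(\\w+)", first))[[1]]
    if (length(m) == 2L) tag <- m[2]
    skip <- 1L
  }
  df <- read.csv(path, skip = skip, check.names = FALSE)
  if (!all(c("sample_id", "leaf_n_pct") %in% names(df)[1:2]))
    stop_nspec("format", "expected columns sample_id, leaf_n_pct in %s", path)
  wl <- as.numeric(names(df)[-(1:2)])
  if (anyNA(wl))
    stop_nspec("format", "band columns must be named by wavelength (nm)")
  spectral_dataset(wl, as.matrix(df[, -(1:2), drop = FALSE]),
                   df$leaf_n_pct, df$sample_id, tag)
}
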