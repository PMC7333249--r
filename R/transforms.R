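#' First-derivative reflectance (FDR)
#'
#' Central-difference derivative of each spectrum with respect to
#' wavelength: interior band i gets
#' `(R[i + 1] - R[i - 1]) / (2 * dl)`; the two endpoint bands get one-sided
#' differences so the wavelength grid (and hence band/VIP index alignment)
#' is preserved. Because differencing cancels additive terms, FDR is
#' exactly invariant to a constant baseline offset - the mechanism by which
#' it suppresses soil and atmospheric background in canopy spectra.
#'
#' @param dataset a [spectral_dataset()] on an equally spaced grid with at
#'   least 3 bands.
#' @return A [spectral_dataset()] with `domain_tag = "fdr"` (units 1/nm).
#' @export
first_derivative <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  p <- length(dataset$wavelengths)
  if (p < 3L) stop_nspec("size", "first derivative needs >= 3 bands")
  dl <- check_equal_spacing(dataset$wavelengths)
  R <- dataset$reflectance
  D <- matrix(0, nrow(R), p)
  D[, 2:(p - 1L)] <- (R[, 3:p, drop = FALSE] - R[, 1:(p - 2L), drop = FALSE]) /
    (2 * dl)
  D[, 1L] <- (R[, 2L] - R[, 1L]) / dl
  D[, p] <- (R[, p] - R[, p - 1L]) / dl
  spectral_dataset(dataset$wavelengths, D, dataset$leaf_n,
                   dataset$sample_ids, "fdr")
}

#' Continuum removal (CR)
#'
#' Divides each spectrum by its continuum line: the upper convex hull of
#' the points (wavelength, reflectance), the piecewise-linear concave
#' envelope connecting the local maxima of the spectrum. The quotient lies
#' in (0, 1] and equals exactly 1 at every hull vertex, including both grid
#' endpoints. Collinear hull points are kept as vertices.
#'
#' @param dataset a [spectral_dataset()] in the `reflectance` domain with
#'   strictly positive values.
#' @return A list with elements
#'   \describe{
#'     \item{dataset}{[spectral_dataset()] with `domain_tag = "cr"`,}
#'     \item{hulls}{a list (one entry per sample) of `continuum_hull`
#'       objects with fields `vertex_wavelengths`, `vertex_reflectances`
#'       and `hull_line` (the per-band continuum value).}
#'   }
#' @export
continuum_removal <- function(dataset) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (dataset$domain_tag != "reflectance")
    stop_nspec("domain", "continuum removal expects reflectance spectra")
  if (min(dataset$reflectance) <= 0)
    stop_nspec("domain", "continuum removal requires positive reflectance")
  wl <- dataset$wavelengths
  R <- dataset$reflectance
  n <- nrow(R)
  cr <- matrix(0, n, ncol(R))
  hulls <- vector("list", n)
  for (i in seq_len(n)) {
    hull <- upper_hull(wl, R[i, ])
    q <- R[i, ] / hull$hull_line
    q[hull$vertex_index] <- 1 # exact at vertices
    cr[i, ] <- pmin(q, 1)
    hulls[[i]] <- hull
  }
  names(hulls) <- dataset$sample_ids
  list(dataset = spectral_dataset(wl, cr, dataset$leaf_n,
                                  dataset$sample_ids, "cr"),
       hulls = hulls)
}

# Upper convex hull of (x, y) with x strictly increasing, by Andrew's
# monotone chain. Points collinear with the hull are kept as vertices.
upper_hull <- function(x, y) {
  n <- length(x)
  stack <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    # pop while the last vertex lies strictly below the chord formed by
    # its neighbours (strict left turn); '>= 0' would drop collinear points
    while (top >= 2L) {
      o <- stack[top - 1L]
      a <- stack[top]
      cross <- (x[a] - x[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (x[i] - x[o])
      if (cross > 0) top <- top - 1L else break
    }
    top <- top + 1L
    stack[top] <- i
  }
  idx <- stack[seq_len(top)]
  line <- approx(x[idx], y[idx], xout = x)$y
  structure(list(vertex_wavelengths = x[idx],
                 vertex_reflectances = y[idx],
                 vertex_index = idx,
                 hull_line = pmax(line, y)), # guard interpolation round-off
            class = "continuum_hull")
}

#' Apply a named spectral transform
#'
#' Dispatch over the three spectral techniques compared in the workflow:
#' `"raw"` (identity), `"fdr"` ([first_derivative()]) and `"cr"`
#' ([continuum_removal()], returning only the transformed dataset).
#'
#' @param dataset a [spectral_dataset()] in the `reflectance` domain.
#' @param kind one of `"raw"`, `"fdr"`, `"cr"`.
#' @return A [spectral_dataset()].
#' @export
apply_transform <- function(dataset, kind) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (dataset$domain_tag != "reflectance")
    stop_nspec("domain", "transforms start from reflectance spectra")
  if (!is.character(kind) || length(kind) != 1L ||
      !kind %in% c("raw", "fdr", "cr"))
    stop_nspec("config", "unknown transform kind '%s'", paste(kind, collapse = ","))
  switch(kind,
         raw = dataset,
         fdr = first_derivative(dataset),
         cr = continuum_removal(dataset)$dataset)
}
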