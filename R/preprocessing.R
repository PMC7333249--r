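#' Savitzky-Golay smoothing of reflectance spectra
#'
#' Smooths every spectrum with a local least-squares polynomial filter
#' (default: second-order polynomial, five-band window, the classic
#' interior convolution weights (-3, 12, 17, 12, -3)/35). The wavelength
#' grid, sample order and leaf N values are untouched.
#'
#' Two edge policies are available. `"reflect"` (default) mirror-pads the
#' spectrum (without repeating the edge band) so every band is filtered
#' with the full window. `"shrink"` symmetrically shrinks the window near
#' the edges to what fits, refitting the polynomial on the smaller window;
#' the outermost bands, where no window larger than the polynomial order
#' fits, are returned unchanged.
#'
#' @param dataset a [spectral_dataset()] in the `reflectance` domain on an
#'   equally spaced grid.
#' @param window odd window size in bands, `> polyorder`.
#' @param polyorder polynomial order of the local fit.
#' @param edge_policy `"reflect"` or `"shrink"`.
#' @return A smoothed [spectral_dataset()] of identical shape.
#' @examples
#' ds <- simulate_canopy_dataset(simulation_config(n_samples = 5, seed = 1))
#' sm <- savgol_smooth(ds)
#' @export
savgol_smooth <- function(dataset, window = 5L, polyorder = 2L,
                          edge_policy = c("reflect", "shrink")) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  edge_policy <- match.arg(edge_policy)
  window <- check_count(window, "window", min = 3L)
  polyorder <- check_count(polyorder, "polyorder", min = 0L)
  if (dataset$domain_tag != "reflectance")
    stop_nspec("domain", "smoothing expects a reflectance-domain dataset")
  if (window %% 2L == 0L || window <= polyorder)
    stop_nspec("config", "window must be odd and > polyorder")
  p <- length(dataset$wavelengths)
  if (window > p)
    stop_nspec("size", "window (%d) exceeds band count (%d)", window, p)
  check_equal_spacing(dataset$wavelengths)

  S <- savgol_matrix(p, window, polyorder, edge_policy)
  smoothed <- dataset$reflectance %*% t(S)
  smoothed <- pmin(pmax(smoothed, 1e-6), 1) # filter ringing can leave [0,1]
  spectral_dataset(dataset$wavelengths, smoothed, dataset$leaf_n,
                   dataset$sample_ids, "reflectance")
}

check_equal_spacing <- function(wl) {
  d <- diff(wl)
  if (length(d) && (max(d) - min(d)) > 1e-8 * max(abs(d)))
    stop_nspec("grid", "wavelength grid must be equally spaced")
  invisible(d[1])
}

# p x p linear smoothing operator: row i holds the weights producing the
# smoothed value at band i. Interior rows are the central Savitzky-Golay
# convolution weights; edge rows implement the chosen policy.
savgol_matrix <- function(p, window, polyorder, edge_policy) {
  h <- (window - 1L) %/% 2L
  w <- savgol_center_weights(window, polyorder)
  S <- matrix(0, p, p)
  for (i in seq_len(p)) {
    lo <- i - h
    hi <- i + h
    if (lo >= 1L && hi <= p) {
      S[i, lo:hi] <- w
    } else if (edge_policy == "reflect") {
      idx <- reflect_index(lo:hi, p)
      for (k in seq_along(idx)) S[i, idx[k]] <- S[i, idx[k]] + w[k]
    } else { # shrink
      hh <- min(i - 1L, p - i)
      win <- 2L * hh + 1L
      if (win > polyorder) {
        S[i, (i - hh):(i + hh)] <- savgol_center_weights(win, polyorder)
      } else {
        S[i, i] <- 1
      }
    }
  }
  S
}

# central row of the SG filter matrix, via the least-squares projection
# of signal::sgolay
savgol_center_weights <- function(window, polyorder) {
  F <- signal::sgolay(p = polyorder, n = window)
  as.numeric(F[(window + 1L) %/% 2L, ])
}

# mirror indices 0, -1, ... -> 2, 3, ...; p+1, p+2 -> p-1, p-2 (no edge repeat)
reflect_index <- function(idx, p) {
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  ifelse(idx > p, 2L * p - idx, idx)
}

#' Crop and resample the wavelength grid
#'
#' Restricts the grid to `[start, stop]` at the requested step, linearly
#' interpolating where the new grid falls between original bands. Band
#' count of the result is `(stop - start)/step + 1`.
#'
#' @param dataset a [spectral_dataset()].
#' @param start,stop,step target grid (nm); must lie within the available
#'   wavelength range.
#' @return A [spectral_dataset()] on the new grid.
#' @examples
#' cfg <- simulation_config(n_samples = 3, wavelength_start = 350,
#'                          wavelength_stop = 1000, seed = 2)
#' ds <- simulate_canopy_dataset(cfg)
#' cropped <- crop_resample(ds, 400, 950, 1)
#' length(cropped$wavelengths) # 551
#' @export
crop_resample <- function(dataset, start, stop, step = 1) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  wl <- dataset$wavelengths
  if (start < min(wl) || stop > max(wl) || start >= stop)
    stop_nspec("range", "requested range [%g, %g] outside data [%g, %g]",
               start, stop, min(wl), max(wl))
  grid <- seq(start, stop, by = step)
  if (abs(grid[length(grid)] - stop) > 1e-8)
    stop_nspec("config", "step must divide (stop - start)")
  if (identical(as.numeric(grid), as.numeric(wl))) return(dataset)
  out <- t(apply(dataset$reflectance, 1L, function(row)
    approx(wl, row, xout = grid)$y))
  if (length(grid) == 1L) out <- matrix(out, ncol = 1L)
  spectral_dataset(grid, out, dataset$leaf_n, dataset$sample_ids,
                   dataset$domain_tag)
}
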