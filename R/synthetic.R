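#' Configuration for the synthetic canopy-spectra generator
#'
#' Defaults reproduce the statistical frame of the study the package
#' emulates: 315 winter-wheat plots whose leaf N concentration spans
#' 1.06-6.16 % with mean 3.80 % and SD 1.24 %, canopy reflectance on a
#' 400-950 nm grid at 1 nm (551 bands), 60 spectroradiometer scans averaged
#' per plot, and six nitrogen-informative wavelengths at 525, 573, 710,
#' 780, 875 and 924 nm.
#'
#' @param n_samples number of samples to simulate.
#' @param n_mean,n_sd target mean and SD of leaf N (%) after truncation.
#' @param n_min,n_max truncation bounds of leaf N (%).
#' @param wavelength_start,wavelength_stop,wavelength_step grid (nm).
#' @param informative_centers wavelengths (nm) carrying narrow
#'   N-informative spectral features.
#' @param noise_sd per-scan white-noise SD (reflectance units).
#' @param drift_amplitude SD scale of the per-sample smooth additive
#'   baseline drift (reflectance units).
#' @param physiology_sd SD (% N units) of the per-sample scatter between
#'   leaf N and the pigment/protein pools expressed in the narrow
#'   absorption features; this is the irreducible spectral-estimation
#'   floor shared by full-spectrum and reduced-band models.
#' @param structure_sd SD (% N units) of the per-sample scatter between
#'   leaf N and the broad canopy-structure components (NIR level,
#'   chlorophyll depths, red-edge position), emulating LAI/biomass
#'   variation not driven by N.
#' @param scans_per_sample number of scans averaged into each spectrum.
#' @param seed integer seed making the whole dataset reproducible.
#' @return A list of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_samples = 50, seed = 7)
#' ds <- simulate_canopy_dataset(cfg)
#' ds
#' @export
simulation_config <- function(n_samples = 315L,
                              n_mean = 3.80, n_sd = 1.24,
                              n_min = 1.06, n_max = 6.16,
                              wavelength_start = 400, wavelength_stop = 950,
                              wavelength_step = 1,
                              informative_centers = c(525, 573, 710, 780, 875, 924),
                              noise_sd = 0.008,
                              drift_amplitude = 0.04,
                              physiology_sd = 0.33,
                              structure_sd = 1.5,
                              scans_per_sample = 60L,
                              seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  scans_per_sample <- check_count(scans_per_sample, "scans_per_sample")
  seed <- check_count(seed, "seed", min = 0L)
  if (n_sd < 0) stop_nspec("config", "n_sd must be >= 0")
  if (n_sd > 0 && !(n_min < n_mean && n_mean < n_max))
    stop_nspec("config", "need n_min < n_mean < n_max (got %g, %g, %g)",
               n_min, n_mean, n_max)
  span <- wavelength_stop - wavelength_start
  if (span <= 0 || wavelength_step <= 0 ||
      abs(span / wavelength_step - round(span / wavelength_step)) > 1e-8)
    stop_nspec("config", "wavelength_step must divide (stop - start)")
  if (noise_sd < 0 || drift_amplitude < 0 || physiology_sd < 0 ||
      structure_sd < 0)
    stop_nspec("config", "noise and scatter SDs must be >= 0")
  structure(list(n_samples = n_samples, n_mean = n_mean, n_sd = n_sd,
                 n_min = n_min, n_max = n_max,
                 wavelength_start = wavelength_start,
                 wavelength_stop = wavelength_stop,
                 wavelength_step = wavelength_step,
                 informative_centers = sort(informative_centers),
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 physiology_sd = physiology_sd, structure_sd = structure_sd,
                 scans_per_sample = scans_per_sample, seed = seed),
            class = "simulation_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds a mapping whose keys mirror the arguments of
#' [simulation_config()]; missing keys take the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_nspec("config", "unknown config fields: %s",
               paste(unknown, collapse = ", "))
  do.call(simulation_config, vals)
}

# truncated-normal moments in closed form (mean and variance of
# N(mu, sigma^2) restricted to [a, b])
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  dphi <- dnorm(al) - dnorm(be)
  m <- mu + sigma * dphi / z
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z - (dphi / z)^2)
  c(mean = m, var = v)
}

# solve for the underlying normal whose truncation to [a, b] has the
# requested mean and SD, so the generated leaf N matches all four printed
# summary statistics (mean, SD, min, max), not just the bounds
solve_truncnorm_params <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), a, b)
    (mo["mean"] - target_mean)^2 + (sqrt(mo["var"]) - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), objective = fit$value)
}

#' Simulate leaf nitrogen concentrations
#'
#' Draws leaf N (%) from a normal distribution truncated to
#' `[n_min, n_max]` by rejection sampling. The underlying normal parameters
#' are solved numerically so that the *truncated* distribution has mean
#' `n_mean` and SD `n_sd`, i.e. large samples reproduce all four summary
#' statistics the generator is configured with.
#'
#' @param config a [simulation_config()].
#' @return Numeric vector of length `config$n_samples`, values in
#'   `[n_min, n_max]`.
#' @export
simulate_leaf_n <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_sd == 0) return(rep(config$n_mean, config$n_samples))
  if (config$n_min >= config$n_max)
    stop_nspec("config", "infeasible truncation: n_min >= n_max")
  par <- solve_truncnorm_params(config$n_mean, config$n_sd,
                                config$n_min, config$n_max)
  set.seed(config$seed)
  out <- numeric(0)
  while (length(out) < config$n_samples) {
    draw <- rnorm(2L * config$n_samples, par$mu, par$sigma)
    out <- c(out, draw[draw >= config$n_min & draw <= config$n_max])
  }
  out[seq_len(config$n_samples)]
}

# Deterministic (noise-free) canopy spectrum model. Returns samples x bands.
#
# The spectrum responds to leaf N through two channels: `n_narrow` drives
# the narrow absorption features (pigment/protein pools) and `n_broad`
# drives the broad components (chlorophyll depths, NIR level, red-edge
# position; canopy-structure proxies). In the noise-free limit both equal
# leaf N; simulate_spectra() perturbs them independently per sample.
#
# Construction, per sample with leaf N = N (%):
#   * visible: flat base minus broad Gaussian chlorophyll absorptions in the
#     blue (450 nm) and red (672 nm) whose depth increases linearly with N,
#     leaving the usual green peak near 550 nm;
#   * red edge: logistic transition at ~712-720 nm whose inflection shifts
#     to longer wavelengths as N rises;
#   * NIR: plateau whose level rises with N (canopy-structure proxy) with a
#     gentle slope and a fixed shallow water feature near 945 nm;
#   * narrow Gaussian features (sd 6 nm) at the configured informative
#     centers, deepening with N below 700 nm and growing with N at/above.
# All N-coefficients are signed so that reflectance is non-increasing in N
# at every visible band (400-700 nm) and non-decreasing at every NIR band
# (750-950 nm).
canopy_signal <- function(wavelengths, leaf_n, informative_centers,
                          n_narrow = leaf_n, n_broad = leaf_n) {
  wl <- wavelengths
  n <- length(leaf_n)
  gauss <- function(center, s) exp(-(wl - center)^2 / (2 * s^2))
  logistic <- function(x) 1 / (1 + exp(-x))
  n_narrow <- pmax(n_narrow, 0)

  # visible chlorophyll absorptions; the shallow green term keeps the
  # 520-580 nm peak responsive to canopy chlorophyll, as in real canopies
  depth_blue <- 0.06 + 0.012 * n_broad
  depth_red <- 0.07 + 0.016 * n_broad
  depth_green <- 0.005 * n_broad
  vis <- 0.26 - outer(depth_blue, gauss(450, 55)) -
    outer(depth_red, gauss(672, 45)) -
    outer(depth_green, gauss(550, 30))

  # NIR plateau with mild slope and a fixed shallow water dip
  nir_level <- 0.30 + 0.022 * n_broad
  nir <- outer(nir_level, 1 + 2e-4 * (wl - 750)) -
    matrix(0.015 * gauss(945, 18), n, length(wl), byrow = TRUE)

  # red edge: logistic mixing, inflection shifting with N
  infl <- 712 + 1.3 * n_broad
  s_edge <- 11
  S <- logistic((matrix(wl, n, length(wl), byrow = TRUE) - infl) / s_edge)
  out <- vis * (1 - S) + nir * S

  # narrow informative features at the configured centers: absorption
  # dips that deepen with N below 700 nm, a red-edge bump growing with N
  # in 700-750 nm, and NIR dips that fill in (shrink) as N rises - so the
  # band value is monotone in N everywhere while the local slopes feeding
  # the derivative spectrum stay N-informative
  for (c0 in informative_centers) {
    amp <- if (c0 < 700) {
      -0.012 * n_narrow
    } else if (c0 < 750) {
      0.012 * n_narrow
    } else {
      -0.012 * pmax(6.5 - n_narrow, 0)
    }
    out <- out + outer(amp, gauss(c0, 6))
  }
  out
}

#' Simulate canopy reflectance spectra for given leaf N values
#'
#' Builds one mechanistic spectrum per sample (see Details), then adds a
#' per-sample smooth additive baseline drift (random low-order polynomial
#' series of scale `drift_amplitude`, emulating soil background and
#' illumination changes) and white measurement noise. Averaging
#' `scans_per_sample` scans is realized as scaling the per-scan noise SD by
#' `1/sqrt(scans_per_sample)`, which has the identical distribution.
#' Output is clipped to (0, 1).
#'
#' @details The deterministic spectrum combines broad Gaussian chlorophyll
#' absorptions in the blue and red (depth increasing with leaf N), a
#' logistic red-edge transition whose inflection shifts with N, an NIR
#' plateau whose level rises with N, and narrow Gaussian features at the
#' configured informative centers. The narrow features respond to leaf N
#' through a per-sample "expressed N" `leaf_n + rnorm(physiology_sd)`
#' (pigment pools track N imperfectly), the broad components through an
#' independent `leaf_n + rnorm(structure_sd)` (canopy structure varies
#' beyond its N dependence). With zero noise, drift and scatter,
#' reflectance is non-increasing in leaf N at every visible band
#' (400-700 nm) and non-decreasing at every NIR band (750-950 nm).
#'
#' @param leaf_n numeric vector of leaf N concentration (%), positive.
#' @param config a [simulation_config()]; the noise draw is seeded from
#'   `config$seed + 1`.
#' @return A [spectral_dataset()] in the `reflectance` domain.
#' @export
simulate_spectra <- function(leaf_n, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!all(is.finite(leaf_n)) || any(leaf_n <= 0))
    stop_nspec("domain", "leaf_n must be finite and positive")
  wl <- seq(config$wavelength_start, config$wavelength_stop,
            by = config$wavelength_step)
  n <- length(leaf_n)
  p <- length(wl)

  set.seed(config$seed + 1L)
  n_narrow <- leaf_n + rnorm(n, 0, config$physiology_sd)
  n_broad <- leaf_n + rnorm(n, 0, config$structure_sd)
  det <- canopy_signal(wl, leaf_n, config$informative_centers,
                       n_narrow = n_narrow, n_broad = n_broad)
  # smooth additive baseline: orthogonal-polynomial series (degree <= 8)
  # with decaying random coefficients; smooth enough that differentiation
  # suppresses it, high-order enough that it is not a trivial subspace
  deg <- min(8L, p - 1L)
  basis <- cbind(rep(1, p),
                 if (deg >= 1L) unclass(stats::poly(seq_len(p), degree = deg)))
  col_sd <- apply(basis, 2L, sd)
  col_sd[1L] <- 1
  basis <- sweep(basis, 2L, pmax(col_sd, 1e-12), `/`) # unit per-band SD
  coef_sd <- config$drift_amplitude / seq_len(deg + 1L)
  drift_coef <- matrix(rnorm(n * (deg + 1L)), n) %*% diag(coef_sd, deg + 1L)
  drift <- drift_coef %*% t(basis)
  noise <- matrix(rnorm(n * p, 0, config$noise_sd), n, p) /
    sqrt(config$scans_per_sample)

  refl <- pmin(pmax(det + drift + noise, 1e-4), 1 - 1e-4)
  spectral_dataset(wl, refl, leaf_n)
}

#' Simulate a complete canopy dataset
#'
#' Convenience wrapper: draws leaf N with [simulate_leaf_n()] and spectra
#' with [simulate_spectra()] from one configuration. Identical
#' configurations (including seed) give bit-identical datasets.
#'
#' @inheritParams simulate_leaf_n
#' @return A [spectral_dataset()].
#' @export
simulate_canopy_dataset <- function(config) {
  simulate_spectra(simulate_leaf_n(config), config)
}

#' Split a dataset into calibration and validation subsets
#'
#' Random, seeded, disjoint row partition (every sample appears in at most
#' one subset).
#'
#' @param dataset a [spectral_dataset()].
#' @param n_cal,n_val subset sizes; `n_cal + n_val` must not exceed the
#'   sample count.
#' @param seed integer seed for the permutation.
#' @return A list with elements `calibration` and `validation`, both
#'   [spectral_dataset()]s.
#' @export
split_dataset <- function(dataset, n_cal, n_val, seed = 1L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  n_cal <- check_count(n_cal, "n_cal", min = 0L)
  n_val <- check_count(n_val, "n_val", min = 0L)
  n <- nrow(dataset$reflectance)
  if (n_cal + n_val > n)
    stop_nspec("size", "requested %d + %d rows but only %d available",
               n_cal, n_val, n)
  set.seed(seed)
  perm <- sample.int(n)
  list(calibration = subset_samples(dataset, sort(perm[seq_len(n_cal)])),
       validation = subset_samples(dataset,
                                   sort(perm[n_cal + seq_len(n_val)])))
}
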