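test_that("simulated leaf N respects truncation bounds and degenerate sd", {
  cfg <- simulation_config(n_samples = 315, seed = 1)
  n <- simulate_leaf_n(cfg)
  expect_length(n, 315)
  expect_true(all(n >= cfg$n_min & n <= cfg$n_max))

  cfg0 <- simulation_config(n_samples = 20, n_sd = 0, seed = 1)
  expect_identical(simulate_leaf_n(cfg0), rep(3.80, 20))

  expect_error(simulation_config(n_samples = 10, n_min = 5, n_mean = 4,
                                 n_max = 3),
               class = "nspec_config_error")
})

test_that("large-sample leaf N moments match the truncated-normal oracle", {
  cfg <- simulation_config(n_samples = 10000, seed = 99)
  n <- simulate_leaf_n(cfg)
  # the generator solves for an underlying normal whose truncation has the
  # target moments; the integration oracle checks that solution
  par <- nspec:::solve_truncnorm_params(3.80, 1.24, 1.06, 6.16)
  oracle <- truncnorm_integration_oracle(par$mu, par$sigma, 1.06, 6.16)
  expect_equal(unname(oracle["mean"]), 3.80, tolerance = 1e-6)
  expect_equal(unname(oracle["sd"]), 1.24, tolerance = 1e-6)
  expect_lt(abs(mean(n) - 3.80), 0.05)
  expect_lt(abs(sd(n) - 1.24), 0.08)
})

test_that("noise-free spectra are monotone in leaf N band-wise", {
  wl <- 400:950
  Ngrid <- seq(1.06, 6.16, length.out = 30)
  sig <- nspec:::canopy_signal(wl, Ngrid, c(525, 573, 710, 780, 875, 924))
  dN <- apply(sig, 2, diff)
  expect_lte(max(dN[, wl <= 700]), 0) # visible: non-increasing in N
  expect_gte(min(dN[, wl >= 750]), 0) # NIR: non-decreasing in N
  expect_true(all(sig > 0 & sig < 1))

  # two-sample contract: green reflectance higher at low N, NIR at high N
  cfg <- simulation_config(n_samples = 2, noise_sd = 0, drift_amplitude = 0,
                           physiology_sd = 0, structure_sd = 0, seed = 3)
  ds <- simulate_spectra(c(2.0, 5.0), cfg)
  i550 <- match(550, ds$wavelengths)
  i850 <- match(850, ds$wavelengths)
  expect_gt(ds$reflectance[1, i550], ds$reflectance[2, i550])
  expect_lt(ds$reflectance[1, i850], ds$reflectance[2, i850])
})

test_that("identical configuration gives bit-identical datasets", {
  cfg <- simulation_config(n_samples = 25, seed = 17)
  d1 <- simulate_canopy_dataset(cfg)
  d2 <- simulate_canopy_dataset(cfg)
  expect_identical(d1, d2)
})

test_that("scan averaging shrinks noise by sqrt(scans)", {
  leaf_n <- rep(3.5, 40)
  base <- simulate_spectra(leaf_n, simulation_config(
    n_samples = 40, noise_sd = 0, drift_amplitude = 0,
    physiology_sd = 0, structure_sd = 0, seed = 5))
  mk <- function(scans) simulate_spectra(leaf_n, simulation_config(
    n_samples = 40, noise_sd = 0.01, drift_amplitude = 0,
    physiology_sd = 0, structure_sd = 0, scans_per_sample = scans, seed = 5))
  r1 <- mk(1)$reflectance - base$reflectance
  r60 <- mk(60)$reflectance - base$reflectance
  expect_equal(sd(r1) / sd(r60), sqrt(60), tolerance = 1e-6)
})

test_that("per-wavelength correlations have the vegetation sign structure", {
  ds <- simulate_canopy_dataset(simulation_config(n_samples = 300, seed = 11))
  pr <- wavelength_correlations(ds)
  green <- pr$wavelength_nm >= 525 & pr$wavelength_nm <= 570
  nir <- pr$wavelength_nm >= 750 & pr$wavelength_nm <= 950
  expect_true(all(pr$r[green] < 0))
  expect_true(all(pr$r[nir] > 0))
})

test_that("split_dataset partitions reproducibly and disjointly", {
  ds <- simulate_canopy_dataset(simulation_config(n_samples = 315, seed = 2))
  sp <- split_dataset(ds, 165, 150, seed = 7)
  expect_equal(nrow(sp$calibration$reflectance), 165)
  expect_equal(nrow(sp$validation$reflectance), 150)
  expect_length(intersect(sp$calibration$sample_ids,
                          sp$validation$sample_ids), 0)
  sp2 <- split_dataset(ds, 165, 150, seed = 7)
  expect_identical(sp, sp2)

  empty <- split_dataset(ds, 0, 10, seed = 1)
  expect_equal(nrow(empty$calibration$reflectance), 0)
  expect_equal(nrow(empty$validation$reflectance), 10)
  expect_error(split_dataset(ds, 300, 100, seed = 1),
               class = "nspec_size_error")
})

test_that("spectra CSV dialect round-trips, including domain tags", {
  ds <- simulate_canopy_dataset(simulation_config(n_samples = 4, seed = 9,
                                                  wavelength_stop = 420))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ds, path)
  expect_false(startsWith(readLines(path, n = 1), "#"))
  back <- read_spectra_csv(path)
  expect_equal(back$reflectance, ds$reflectance, ignore_attr = FALSE)
  expect_equal(back$leaf_n, ds$leaf_n)

  fdr <- first_derivative(ds)
  write_spectra_csv(fdr, path)
  expect_true(startsWith(readLines(path, n = 1), "# domain_tag: fdr"))
  back2 <- read_spectra_csv(path)
  expect_equal(back2$domain_tag, "fdr")
  expect_equal(back2$reflectance, fdr$reflectance)
})

test_that("simulation config can be read from YAML and JSON", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_samples: 12", "seed: 4", "noise_sd: 0.0"), y)
  cfg <- read_simulation_config(y)
  expect_equal(cfg$n_samples, 12L)
  expect_equal(cfg$noise_sd, 0)
  j <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n_samples": 8, "seed": 2}', j)
  expect_equal(read_simulation_config(j)$n_samples, 8L)
  writeLines("bogus_field: 1", y)
  expect_error(read_simulation_config(y), class = "nspec_config_error")
})
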