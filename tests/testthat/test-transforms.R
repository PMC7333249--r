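test_that("first derivative matches hand-evaluated differences", {
  ds <- toy_dataset(c(0.10, 0.12, 0.16, 0.22, 0.30))
  fd <- first_derivative(ds)
  expect_equal(unname(fd$reflectance[1, ]), c(0.02, 0.03, 0.05, 0.07, 0.08))
  expect_equal(fd$domain_tag, "fdr")

  # constant -> zero; affine -> constant slope everywhere incl. endpoints
  expect_equal(unname(first_derivative(toy_dataset(rep(0.3, 9)))$reflectance),
               matrix(0, 1, 9))
  wl <- 500:520
  aff <- toy_dataset(0.1 + 0.004 * (wl - 500), wl)
  expect_equal(unname(first_derivative(aff)$reflectance),
               matrix(0.004, 1, 21), tolerance = 1e-12)

  expect_error(first_derivative(toy_dataset(c(0.1, 0.2))),
               class = "nspec_size_error")
})

test_that("first derivative is exactly invariant to additive baselines", {
  set.seed(21)
  m <- matrix(runif(5 * 30, 0.1, 0.6), 5)
  shifted <- sweep(m, 1, runif(5, 0, 0.3), `+`)
  d1 <- first_derivative(toy_dataset(pmin(m, 1)))
  d2 <- first_derivative(toy_dataset(pmin(shifted, 1)))
  # equality up to the last-ulp rounding of (x + c) - (y + c)
  expect_equal(d1$reflectance, d2$reflectance, tolerance = 1e-13)
})

test_that("continuum removal reproduces the hand-worked hull example", {
  ds <- toy_dataset(c(0.5, 0.3, 0.2, 0.35, 0.6))
  cr <- continuum_removal(ds)
  expect_equal(unname(cr$dataset$reflectance[1, ]),
               c(1, 0.3 / 0.525, 0.2 / 0.55, 0.35 / 0.575, 1),
               tolerance = 1e-12)
  expect_equal(cr$hulls[[1]]$vertex_wavelengths, c(400, 404))
  expect_equal(round(unname(cr$dataset$reflectance[1, ]), 4),
               c(1.0000, 0.5714, 0.3636, 0.6087, 1.0000))

  # affine spectrum is its own hull
  wl <- 400:410
  aff <- toy_dataset(0.2 + 0.01 * (wl - 400), wl)
  expect_equal(unname(continuum_removal(aff)$dataset$reflectance),
               matrix(1, 1, 11), tolerance = 1e-12)

  # interior local maximum above the endpoint chord becomes a vertex
  pk <- toy_dataset(c(0.30, 0.25, 0.50, 0.28, 0.26, 0.27, 0.29))
  crp <- continuum_removal(pk)
  expect_true(402 %in% crp$hulls[[1]]$vertex_wavelengths)
  expect_equal(unname(crp$dataset$reflectance[1, 3]), 1)

  bad <- spectral_dataset(400:404, matrix(c(0, 0.1, 0.2, 0.1, 0.2), 1), 3)
  expect_error(continuum_removal(bad), class = "nspec_domain_error")
})

test_that("monotone-chain hull agrees with the brute-force envelope oracle", {
  set.seed(33)
  for (rep in 1:100) {
    p <- sample(10:50, 1)
    y <- random_spectrum(p)
    x <- seq(400, by = sample(1:3, 1), length.out = p)
    hull <- nspec:::upper_hull(x, y)
    oracle <- brute_force_upper_envelope(x, y)
    expect_equal(hull$hull_line, oracle, tolerance = 1e-10)
    expect_true(all(hull$hull_line >= y - 1e-12))
    expect_true(all(c(x[1], x[p]) %in% hull$vertex_wavelengths))
    # concavity of the hull line
    expect_true(all(diff(diff(hull$hull_line) / diff(x)) < 1e-9))
  }
})

test_that("continuum removal is scale invariant and 1 at its own hull", {
  set.seed(44)
  y <- random_spectrum(40)
  ds <- toy_dataset(y)
  scaled <- toy_dataset(y * 1.05)
  cr1 <- continuum_removal(ds)$dataset$reflectance
  cr2 <- continuum_removal(scaled)$dataset$reflectance
  expect_equal(cr1, cr2, tolerance = 1e-12)

  # hull of the CR output at the original vertices is exactly 1
  hull <- nspec:::upper_hull(ds$wavelengths, y)
  expect_true(all(cr1[1, hull$vertex_index] == 1))
  rehull <- nspec:::upper_hull(ds$wavelengths, cr1[1, ])
  expect_equal(rehull$hull_line[hull$vertex_index],
               rep(1, length(hull$vertex_index)), tolerance = 1e-12)
})

test_that("apply_transform dispatches raw, fdr and cr correctly", {
  ds <- toy_dataset(matrix(runif(3 * 20, 0.2, 0.6), 3))
  expect_identical(apply_transform(ds, "raw"), ds)
  expect_equal(apply_transform(toy_dataset(matrix(0.3, 2, 8)), "fdr")$reflectance,
               matrix(0, 2, 8), ignore_attr = TRUE)
  wl <- 400:415
  aff <- toy_dataset(rbind(0.2 + 0.01 * (wl - 400), 0.5 - 0.005 * (wl - 400)), wl)
  expect_equal(apply_transform(aff, "cr")$reflectance,
               matrix(1, 2, 16), ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(apply_transform(ds, "sqrt"), class = "nspec_config_error")
  expect_error(apply_transform(first_derivative(ds), "fdr"),
               class = "nspec_domain_error")
})
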