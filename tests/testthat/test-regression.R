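test_that("MLR recovers exact affine relationships and handles p > n", {
  set.seed(101)
  X <- matrix(rnorm(10 * 2), 10, 2)
  y <- 1.5 + 2 * X[, 1] - 0.7 * X[, 2]
  m <- fit_mlr(X, y)
  expect_equal(unname(m$coefficients), c(2, -0.7), tolerance = 1e-10)
  expect_equal(predict(m, X), y, tolerance = 1e-10)

  # duplicated column: minimum-norm fit predicts identically
  Xd <- cbind(X, X[, 1])
  md <- fit_mlr(Xd, y)
  Xn <- matrix(rnorm(6 * 2), 6, 2)
  expect_equal(predict(md, cbind(Xn, Xn[, 1])), predict(m, Xn),
               tolerance = 1e-8)

  # p >> n completes with ~zero training residuals
  Xw <- matrix(rnorm(20 * 300), 20, 300)
  yw <- rnorm(20)
  mw <- fit_mlr(Xw, yw)
  expect_lt(max(abs(predict(mw, Xw) - yw)), 1e-8)
  expect_error(fit_mlr(X[0, , drop = FALSE], numeric(0)),
               class = "nspec_size_error")
})

test_that("PCR selects a single component for one-factor data", {
  set.seed(102)
  n <- 30; p <- 12
  direction <- rnorm(p); direction <- direction / sqrt(sum(direction^2))
  scores <- rnorm(n, 0, 3)
  X <- scores %o% direction # exactly rank one
  y <- 2 + 0.5 * scores
  fit <- fit_pcr(X, y, max_components = 5, cv_scheme = cv_kfold(5))
  expect_equal(attr(fit$cv_trace, "selected")$n_components, 1)
  expect_lt(min(fit$cv_trace$rmsecv), 1e-3)
  expect_equal(nrow(fit$cv_trace), 5)
  expect_equal(which.min(fit$cv_trace$rmsecv),
               attr(fit$cv_trace, "selected")$n_components)
})

test_that("full-order PCR and PLS predictions equal MLR", {
  set.seed(103)
  n <- 25; p <- 7
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rnorm(p)) + rnorm(n, 0, 0.2)
  Xnew <- matrix(rnorm(8 * p), 8, p)
  ref <- predict(fit_mlr(X, y), Xnew)

  core <- nspec:::pcr_core(X, y, p)
  beta <- drop(core$loadings %*% core$q)
  pcr_pred <- drop(Xnew %*% beta) + core$y_center - sum(core$x_center * beta)
  expect_equal(pcr_pred, ref, tolerance = 1e-8)

  nip <- nspec:::nipals_pls(X, y, p)
  b <- nspec:::pls_beta(nip, nip$ncomp)
  pls_pred <- drop(Xnew %*% b) + nip$y_center - sum(nip$x_center * b)
  expect_equal(pls_pred, ref, tolerance = 1e-8)
})

test_that("NIPALS components have unit weights, orthogonal scores and nested fit", {
  set.seed(104)
  n <- 40; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rnorm(p)) + rnorm(n)
  nip <- nspec:::nipals_pls(X, y, 6)
  expect_equal(colSums(nip$W^2), rep(1, 6), tolerance = 1e-10)
  G <- crossprod(nip$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # calibration RMSE non-increasing in the number of latent variables
  rmse_k <- vapply(1:6, function(k) {
    b <- nspec:::pls_beta(nip, k)
    sqrt(mean((nip$y_center + drop(sweep(X, 2, nip$x_center) %*% b) - y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse_k) <= 1e-10))
})

test_that("PLS identifies an exact one-component model", {
  set.seed(105)
  n <- 30; p <- 10
  t <- rnorm(n)
  pload <- rnorm(p)
  X <- t %o% pload
  y <- 3 + 2 * t
  fit <- fit_pls(X, y, max_lv = 4, cv_scheme = cv_kfold(5))
  expect_equal(fit$model$selected_order, 1)
  expect_lt(fit$cv_trace$rmsecv[1], 1e-8)
  expect_error(fit_pls(X, rep(2, n), max_lv = 2),
               class = "nspec_degenerate_error")
})

test_that("PLS matches the mixOmics reference implementation", {
  set.seed(106)
  n <- 30; p <- 12
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("b", 1:p)))
  y <- drop(X %*% rnorm(p)) + rnorm(n, 0, 0.5)
  Xn <- matrix(rnorm(9 * p), 9, p, dimnames = list(NULL, paste0("b", 1:p)))
  nip <- nspec:::nipals_pls(X, y, 4)
  b4 <- nspec:::pls_beta(nip, 4)
  mine <- drop(Xn %*% b4) + nip$y_center - sum(nip$x_center * b4)
  mo <- mixOmics::pls(X, y, ncomp = 4, mode = "regression", scale = FALSE)
  theirs <- predict(mo, Xn)$predict[, 1, 4]
  expect_equal(mine, unname(theirs), tolerance = 1e-8)
})

test_that("SVR handles degenerate and near-linear responses", {
  set.seed(107)
  X <- matrix(rnorm(30 * 4), 30, 4)
  grid <- list(c = c(1, 100), g = c(0.01, 0.1), epsilon = c(0.1))
  const <- fit_svr_rbf(X, rep(2.5, 30), grid, cv_kfold(5))
  expect_equal(predict(const$model, X), rep(2.5, 30), tolerance = 1e-6)

  y <- drop(X %*% c(1, -0.5, 0.3, 0.2))
  lin <- fit_svr_rbf(X, y, list(c = 1000, g = 0.01, epsilon = 0.001),
                     cv_kfold(5))
  Xv <- matrix(rnorm(20 * 4), 20, 4)
  yv <- drop(Xv %*% c(1, -0.5, 0.3, 0.2))
  expect_lt(sqrt(mean((predict(lin$model, Xv) - yv)^2)), 0.15)

  expect_error(fit_svr_rbf(X, y, list(c = -1, g = 1, epsilon = 0.1)),
               class = "nspec_config_error")
})

test_that("the default SVR grid contains the canonical optimum triple", {
  grid <- svr_default_grid()
  expect_true(any(abs(grid$c - 100) < 1e-9))
  expect_true(any(abs(grid$g - 10^0.5) < 1e-9))
  expect_true(any(abs(grid$epsilon - 0.1) < 1e-9))
})

test_that("rmsecv matches hand-enumerated leave-one-out folds", {
  # n = 3, single predictor: each fold fits a line on 2 points
  X <- matrix(c(1, 2, 4), 3, 1)
  y <- c(1.0, 2.5, 3.5)
  hand <- numeric(3)
  for (i in 1:3) {
    fit <- lm(yy ~ xx, data.frame(xx = X[-i, 1], yy = y[-i]))
    hand[i] <- y[i] - unname(predict(fit, data.frame(xx = X[i, 1])))
  }
  expect_equal(rmsecv(X, y, fit_mlr, cv_loo()),
               sqrt(mean(hand^2)), tolerance = 1e-10)

  # constant response: zero held-out error
  expect_equal(rmsecv(matrix(rnorm(12), 6), rep(2, 6), fit_mlr,
                      cv_kfold(3), seed = 1), 0, tolerance = 1e-10)

  # seeded k-fold is deterministic
  set.seed(108)
  Xr <- matrix(rnorm(40 * 3), 40)
  yr <- rnorm(40)
  v1 <- rmsecv(Xr, yr, fit_mlr, cv_kfold(20), seed = 9)
  v2 <- rmsecv(Xr, yr, fit_mlr, cv_kfold(20), seed = 9)
  expect_identical(v1, v2)
  expect_error(make_folds <- nspec:::make_folds(cv_kfold(10), 5),
               class = "nspec_config_error")
})

test_that("predictions are row-wise and survive JSON persistence", {
  set.seed(109)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(20, 0, 0.1)
  models <- list(
    mlr = fit_mlr(X, y),
    pcr = fit_pcr(X, y, 4, cv_kfold(4))$model,
    pls = fit_pls(X, y, 4, cv_kfold(4))$model,
    svm = fit_svr_rbf(X, y, list(c = 10, g = 0.1, epsilon = 0.1),
                      cv_kfold(4))$model)
  Xn <- matrix(rnorm(7 * 6), 7, 6)
  perm <- sample(7)
  for (m in models) {
    p1 <- predict(m, Xn)
    expect_equal(predict(m, Xn[perm, ]), p1[perm])
    path <- withr::local_tempfile(fileext = ".json")
    write_model_json(m, path)
    back <- read_model_json(path)
    expect_s3_class(back, "nspec_model")
    expect_equal(predict(back, Xn), p1, tolerance = 1e-9)
    expect_error(predict(m, Xn[, 1:5]), class = "nspec_shape_error")
  }
})
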