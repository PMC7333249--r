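#' Cross-validation schemes
#'
#' Constructors for the two resampling schemes used for model-order and
#' hyperparameter selection: leave-one-out (`cv_loo()`, the default
#' throughout) and seeded random k-fold (`cv_kfold()`).
#'
#' @param k number of folds.
#' @return A `cv_scheme` object.
#' @export
cv_loo <- function() {
  structure(list(type = "loo"), class = "cv_scheme")
}

#' @rdname cv_loo
#' @export
cv_kfold <- function(k = 20L) {
  k <- check_count(k, "k", min = 2L)
  structure(list(type = "kfold", k = k), class = "cv_scheme")
}

scheme_label <- function(scheme) {
  if (scheme$type == "loo") "leave_one_out" else sprintf("k_fold(%d)", scheme$k)
}

make_folds <- function(scheme, n, seed = 1L) {
  stopifnot(inherits(scheme, "cv_scheme"))
  if (scheme$type == "loo") return(as.list(seq_len(n)))
  if (scheme$k > n)
    stop_nspec("config", "fold count %d exceeds sample count %d", scheme$k, n)
  set.seed(seed)
  assignment <- sample(rep(seq_len(scheme$k), length.out = n))
  unname(split(seq_len(n), assignment))
}

new_cv_trace <- function(candidates, rmsecv, selected, scheme) {
  df <- cbind(as.data.frame(candidates), rmsecv = rmsecv)
  structure(df, selected = selected, cv_scheme = scheme_label(scheme),
            class = c("cv_trace", "data.frame"))
}

#' @export
print.cv_trace <- function(x, ...) {
  cat(sprintf("<cv_trace> %d candidates, scheme %s\n", nrow(x),
              attr(x, "cv_scheme")))
  sel <- attr(x, "selected")
  cat("  selected:", paste(names(sel), unlist(sel), sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Export a cross-validation trace as CSV
#'
#' @param trace a `cv_trace` (candidate columns plus `rmsecv`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cv_trace_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Cross-validated RMSE of an arbitrary fitting function
#'
#' Root mean square error of held-out predictions over all folds: each
#' fold's samples are predicted by a model fitted on the remaining
#' samples, and the squared errors are pooled before taking the root.
#'
#' @param X predictor matrix (samples x bands).
#' @param y response vector (%).
#' @param fit_fun function `(X, y) -> model` where the model has a
#'   [predict()] method taking a matrix of new rows.
#' @param cv_scheme a [cv_loo()] or [cv_kfold()] scheme.
#' @param seed seed for the random fold assignment (k-fold only).
#' @return The RMSECV value (same units as `y`).
#' @export
rmsecv <- function(X, y, fit_fun, cv_scheme = cv_loo(), seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- make_folds(cv_scheme, n, seed)
  pred <- rep(NA_real_, n)
  for (fold in folds) {
    model <- fit_fun(X[-fold, , drop = FALSE], y[-fold])
    pred[fold] <- predict(model, X[fold, , drop = FALSE])
  }
  sqrt(mean((pred - y)^2))
}

new_model <- function(method, fields) {
  structure(c(list(method = method), fields),
            class = c(paste0("nspec_", tolower(method)), "nspec_model"))
}

#' @export
print.nspec_model <- function(x, ...) {
  extra <- if (!is.null(x$selected_order))
    sprintf(", %d component(s)", x$selected_order)
  else if (!is.null(x$hyperparameters))
    sprintf(", c=%g g=%g eps=%g", x$hyperparameters$c,
            x$hyperparameters$g, x$hyperparameters$epsilon)
  else ""
  cat(sprintf("<nspec_model> %s over %d band(s)%s\n", x$method,
              length(x$wavelengths), extra))
  invisible(x)
}

model_wavelengths <- function(X) {
  wl <- suppressWarnings(as.numeric(colnames(X)))
  if (length(wl) == 0L || anyNA(wl)) wl <- seq_len(ncol(X))
  wl
}

#' Multiple linear regression on spectra
#'
#' Ordinary least squares of the response on all bands (intercept
#' included). When the bands outnumber the samples or are collinear - the
#' normal situation for 551-band spectra - the fit is the minimum-norm
#' least-squares solution computed from the singular value decomposition,
#' so the training residuals are those of the orthogonal projection and
#' the coefficient vector is the shortest one achieving them.
#'
#' @param X predictor matrix (samples x bands).
#' @param y response vector (%).
#' @return An `nspec_model` with fields `coefficients`, `intercept`,
#'   `x_center`, `rank`.
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop_nspec("size", "no samples")
  if (nrow(X) != length(y)) stop_nspec("shape", "rows(X) != length(y)")
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xc <- sweep(X, 2L, x_center)
  s <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(s$d, 0)
  r <- sum(s$d > tol)
  beta <- if (r > 0) {
    drop(s$v[, seq_len(r), drop = FALSE] %*%
           (crossprod(s$u[, seq_len(r), drop = FALSE], y - y_center) /
              s$d[seq_len(r)]))
  } else rep(0, ncol(X))
  new_model("MLR", list(wavelengths = model_wavelengths(X),
                        coefficients = beta,
                        intercept = y_center - sum(x_center * beta),
                        x_center = x_center, rank = r))
}

# ---- PCR ------------------------------------------------------------

# scores/loadings of mean-centered X; returns enough for k-truncated fits
pcr_core <- function(X, y, kmax) {
  x_center <- colMeans(X)
  Xc <- sweep(X, 2L, x_center)
  s <- svd(Xc, nu = kmax, nv = kmax)
  keep <- which(s$d[seq_len(kmax)] > max(dim(Xc)) * .Machine$double.eps * s$d[1])
  k <- length(keep)
  scores <- s$u[, keep, drop = FALSE] %*% diag(s$d[keep], k, k)
  q <- drop(crossprod(scores, y - mean(y))) / s$d[keep]^2
  list(x_center = x_center, y_center = mean(y),
       loadings = s$v[, keep, drop = FALSE], q = q, k = k)
}

pcr_predict_all <- function(core, Xnew) {
  Z <- sweep(Xnew, 2L, core$x_center) %*% core$loadings
  contrib <- sweep(Z, 2L, core$q, `*`)
  cum <- contrib # n x k, cumulative over leading PCs
  if (core$k > 1L)
    for (j in 2:core$k) cum[, j] <- cum[, j - 1L] + contrib[, j]
  core$y_center + cum
}

#' Principal component regression with RMSECV order selection
#'
#' Mean-centers the predictors (no variance scaling: all bands share
#' reflectance units), extracts principal components ordered by explained
#' predictor variance, and regresses the response on the leading k scores.
#' k is chosen as the minimizer of the cross-validated RMSE over
#' `1..max_components`; ties go to the smallest k.
#'
#' @param X predictor matrix (samples x bands).
#' @param y response vector (%).
#' @param max_components largest number of components considered; capped
#'   at `min(n - 1, p)`.
#' @param cv_scheme a [cv_loo()] or [cv_kfold()] scheme.
#' @param seed fold-assignment seed (k-fold only).
#' @return A list with elements `model` (an `nspec_model`) and `cv_trace`.
#' @export
fit_pcr <- function(X, y, max_components = 20L, cv_scheme = cv_loo(),
                    seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (max_components < 1L) stop_nspec("config", "max_components must be >= 1")
  kmax <- min(max_components, n - 1L, ncol(X))
  folds <- make_folds(cv_scheme, n, seed)
  pred <- matrix(NA_real_, n, kmax)
  for (fold in folds) {
    ktr <- min(kmax, n - length(fold) - 1L, ncol(X))
    core <- pcr_core(X[-fold, , drop = FALSE], y[-fold], ktr)
    ph <- pcr_predict_all(core, X[fold, , drop = FALSE])
    ph <- matrix(ph, length(fold))
    # components beyond what the fold supports keep the largest-k estimate
    pred[fold, ] <- ph[, pmin(seq_len(kmax), core$k), drop = FALSE]
  }
  rms <- sqrt(colMeans((pred - y)^2))
  sel <- which.min(rms)
  trace <- new_cv_trace(data.frame(n_components = seq_len(kmax)), rms,
                        list(n_components = sel), cv_scheme)
  core <- pcr_core(X, y, sel)
  beta <- drop(core$loadings %*% core$q)
  model <- new_model("PCR", list(
    wavelengths = model_wavelengths(X),
    x_center = core$x_center, loadings = core$loadings,
    score_coefficients = core$q,
    coefficients = beta,
    intercept = core$y_center - sum(core$x_center * beta),
    selected_order = core$k))
  list(model = model, cv_trace = trace)
}

# ---- PLS (NIPALS, single response) ----------------------------------

# NIPALS PLS1: unit-norm weight vectors, X deflation only (equivalent to
# X+y deflation for a single response)
nipals_pls <- function(X, y, ncomp) {
  n <- nrow(X)
  p <- ncol(X)
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xd <- sweep(X, 2L, x_center)
  y0 <- y - y_center
  if (sd(y) == 0) stop_nspec("degenerate", "zero-variance response")
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  Tss <- numeric(ncomp)
  scores <- matrix(0, n, ncomp)
  a <- 0L
  for (i in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, y0))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    a <- i
    W[, i] <- w
    P[, i] <- drop(crossprod(Xd, t)) / tt
    Q[i] <- sum(y0 * t) / tt
    Tss[i] <- tt
    scores[, i] <- t
    Xd <- Xd - tcrossprod(t, P[, i])
  }
  if (a == 0L) stop_nspec("degenerate", "no usable PLS component")
  idx <- seq_len(a)
  list(x_center = x_center, y_center = y_center,
       W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       Q = Q[idx], Tss = Tss[idx], scores = scores[, idx, drop = FALSE],
       ncomp = a)
}

pls_beta <- function(fit, k) {
  Wk <- fit$W[, seq_len(k), drop = FALSE]
  Pk <- fit$P[, seq_len(k), drop = FALSE]
  drop(Wk %*% solve(crossprod(Pk, Wk), fit$Q[seq_len(k)]))
}

pls_predict_all <- function(fit, Xnew, kmax) {
  Z <- sweep(Xnew, 2L, fit$x_center)
  out <- matrix(NA_real_, nrow(Xnew), kmax)
  for (k in seq_len(kmax)) {
    kk <- min(k, fit$ncomp)
    out[, k] <- fit$y_center + Z %*% pls_beta(fit, kk)
  }
  out
}

#' Partial least squares regression (NIPALS) with RMSECV order selection
#'
#' Single-response NIPALS: each latent variable has a unit-norm weight
#' vector proportional to the covariance of the (deflated) predictors with
#' the response; scores, x-loadings and the y-loading follow, and the
#' predictors are deflated by the rank-one fit. The optimal number of
#' latent variables (ONLV) is the minimizer of the cross-validated RMSE;
#' ties go to the smallest number.
#'
#' @inheritParams fit_pcr
#' @param max_lv largest number of latent variables considered; capped at
#'   `min(n - 1, p)`.
#' @return A list with elements `model` and `cv_trace`. The model stores
#'   the loading weights, x-loadings, y-loadings, score sums of squares
#'   and scores for the selected components, which [vip_scores()] and
#'   [loading_weight_profile()] consume.
#' @export
fit_pls <- function(X, y, max_lv = 20L, cv_scheme = cv_loo(), seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (max_lv < 1L) stop_nspec("config", "max_lv must be >= 1")
  kmax <- min(max_lv, n - 1L, ncol(X))
  folds <- make_folds(cv_scheme, n, seed)
  pred <- matrix(NA_real_, n, kmax)
  for (fold in folds) {
    fit <- nipals_pls(X[-fold, , drop = FALSE], y[-fold],
                      min(kmax, n - length(fold) - 1L, ncol(X)))
    pred[fold, ] <- pls_predict_all(fit, X[fold, , drop = FALSE], kmax)
  }
  rms <- sqrt(colMeans((pred - y)^2))
  sel <- which.min(rms)
  trace <- new_cv_trace(data.frame(n_latent = seq_len(kmax)), rms,
                        list(n_latent = sel), cv_scheme)
  fit <- nipals_pls(X, y, sel)
  beta <- pls_beta(fit, fit$ncomp)
  model <- new_model("PLS", list(
    wavelengths = model_wavelengths(X),
    x_center = fit$x_center, y_center = fit$y_center,
    loading_weights = fit$W, x_loadings = fit$P, y_loadings = fit$Q,
    score_ss = fit$Tss, x_scores = fit$scores,
    coefficients = beta,
    intercept = fit$y_center - sum(fit$x_center * beta),
    selected_order = fit$ncomp))
  list(model = model, cv_trace = trace)
}

# ---- SVR ------------------------------------------------------------

# libsvm regression decision: sum_i coef_i K(z, sv_i) - rho; a model with
# no support vectors (all residuals within epsilon) predicts -rho
rbf_decision <- function(Z, SV, coefs, rho, gamma) {
  if (nrow(SV) == 0L) return(rep(-rho, nrow(Z)))
  d2 <- outer(rowSums(Z^2), rowSums(SV^2), `+`) - 2 * tcrossprod(Z, SV)
  drop(exp(-gamma * pmax(d2, 0)) %*% coefs) - rho
}

#' Default hyperparameter grid for RBF epsilon-SVR
#'
#' Log-spaced with half-decade steps so that values such as
#' 3.16 (= 10^0.5) are representable: cost in 10^(-2..3), gamma in
#' 10^(-4..2), epsilon in \{0.01, 0.1, 0.5\}. The gamma axis reaches down
#' to 1e-4 because on standardized full spectra the squared distances
#' scale with the band count (~2p for 551 bands), so useful kernel widths
#' for full-spectrum fits sit near g ~ 1/p, while reduced band sets favor
#' g of order 1.
#'
#' @return A list with components `c`, `g`, `epsilon`.
#' @export
svr_default_grid <- function() {
  list(c = 10^seq(-2, 3, by = 0.5),
       g = 10^seq(-4, 2, by = 0.5),
       epsilon = c(0.01, 0.1, 0.5))
}

#' Epsilon-SVR with RBF kernel and grid-searched hyperparameters
#'
#' Support vector regression with the Gaussian kernel
#' `exp(-g * ||u - v||^2)`. Predictors are z-score standardized
#' internally; the response stays in its own units, so `epsilon` is in %
#' leaf N. The `(c, g, epsilon)` triple is chosen by minimum RMSECV over
#' the Cartesian grid. The underlying quadratic-programming solver is
#' libsvm via \pkg{e1071}; the fitted support vectors, dual coefficients
#' and offset are stored so predictions are reproducible from the model
#' object alone.
#'
#' @inheritParams fit_pcr
#' @param grid list with components `c`, `g`, `epsilon` (see
#'   [svr_default_grid()]).
#' @param cv_scheme resampling scheme for the grid search; defaults to
#'   5-fold, which keeps the 297-point default grid tractable.
#' @return A list with elements `model` and `cv_trace`.
#' @export
fit_svr_rbf <- function(X, y, grid = svr_default_grid(),
                        cv_scheme = cv_kfold(5L), seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!length(grid$c) || !length(grid$g) || !length(grid$epsilon))
    stop_nspec("config", "all three grids must be non-empty")
  if (any(grid$c <= 0) || any(grid$g <= 0))
    stop_nspec("config", "c and g must be positive")
  x_center <- colMeans(X)
  x_scale <- apply(X, 2L, sd)
  x_scale[x_scale == 0] <- 1
  Z <- sweep(sweep(X, 2L, x_center), 2L, x_scale, `/`)
  combos <- expand.grid(c = grid$c, g = grid$g, epsilon = grid$epsilon,
                        KEEP.OUT.ATTRS = FALSE)
  folds <- make_folds(cv_scheme, n, seed)
  rms <- numeric(nrow(combos))
  for (j in seq_len(nrow(combos))) {
    sq <- 0
    for (fold in folds) {
      fit <- e1071::svm(x = Z[-fold, , drop = FALSE], y = y[-fold],
                        type = "eps-regression", kernel = "radial",
                        cost = combos$c[j], gamma = combos$g[j],
                        epsilon = combos$epsilon[j], scale = FALSE,
                        fitted = FALSE)
      ph <- rbf_decision(Z[fold, , drop = FALSE], as.matrix(fit$SV),
                         drop(fit$coefs), fit$rho, combos$g[j])
      sq <- sq + sum((ph - y[fold])^2)
    }
    rms[j] <- sqrt(sq / n)
  }
  sel <- which.min(rms)
  trace <- new_cv_trace(combos, rms, as.list(combos[sel, ]), cv_scheme)
  fit <- e1071::svm(x = Z, y = y, type = "eps-regression",
                    kernel = "radial", cost = combos$c[sel],
                    gamma = combos$g[sel], epsilon = combos$epsilon[sel],
                    scale = FALSE, fitted = FALSE)
  SV <- if (is.null(fit$SV) || !length(fit$SV)) {
    matrix(numeric(0), 0L, ncol(Z))
  } else unname(as.matrix(fit$SV))
  model <- new_model("SVM", list(
    wavelengths = model_wavelengths(X),
    x_center = x_center, x_scale = x_scale,
    support_vectors = SV,
    dual_coefficients = drop(fit$coefs),
    rho = fit$rho,
    hyperparameters = list(c = combos$c[sel], g = combos$g[sel],
                           epsilon = combos$epsilon[sel])))
  list(model = model, cv_trace = trace)
}

# ---- prediction & persistence ---------------------------------------

#' Predict from a fitted nspec model
#'
#' Applies the stored centering/scaling statistics and functional form.
#'
#' @param object an `nspec_model`.
#' @param newdata matrix of new spectra with the training band count.
#' @param ... unused.
#' @return Numeric vector of predicted leaf N (%).
#' @export
predict.nspec_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$wavelengths))
    stop_nspec("shape", "model expects %d bands, got %d",
               length(object$wavelengths), ncol(X))
  if (object$method == "SVM") {
    Z <- sweep(sweep(X, 2L, object$x_center), 2L, object$x_scale, `/`)
    rbf_decision(Z, object$support_vectors, object$dual_coefficients,
                 object$rho, object$hyperparameters$g)
  } else {
    drop(X %*% object$coefficients) + object$intercept
  }
}

#' Save or load a fitted model as self-describing JSON
#'
#' The JSON document records the method, selected order or
#' hyperparameters, coefficient arrays and centering/scaling statistics -
#' everything [predict.nspec_model()] needs.
#'
#' @param model an `nspec_model`.
#' @param path file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns the reconstructed `nspec_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "nspec_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("loading_weights", "x_loadings", "x_scores", "loadings")) {
    if (!is.null(obj[[f]]) && !is.matrix(obj[[f]]))
      obj[[f]] <- matrix(obj[[f]], nrow = 1L)
  }
  if (!is.null(obj$support_vectors) && !is.matrix(obj$support_vectors)) {
    obj$support_vectors <- if (length(obj$support_vectors)) {
      matrix(obj$support_vectors, nrow = 1L)
    } else matrix(numeric(0), 0L, length(obj$x_center))
  }
  if (!is.null(obj$dual_coefficients))
    obj$dual_coefficients <- as.numeric(obj$dual_coefficients)
  if (!is.null(obj$hyperparameters))
    obj$hyperparameters <- as.list(obj$hyperparameters)
  method <- obj$method
  new_model(method, obj[setdiff(names(obj), "method")])
}
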