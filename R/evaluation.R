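#' Ratio of performance to deviation
#'
#' `rpd = sd_reference / rmse`, with `sd_reference` the standard deviation
#' (n - 1 denominator) of the observed values of the split being
#' evaluated. RPD expresses the prediction error relative to the natural
#' spread of the property; values above 2.0 are conventionally classed
#' "excellent" for agricultural calibrations.
#'
#' @param sd_reference reference SD of the observed values (%).
#' @param rmse root mean square error of prediction (%).
#' @return The RPD (unitless); `Inf` when `rmse` is 0.
#' @export
rpd <- function(sd_reference, rmse) {
  if (rmse < 0 || sd_reference < 0)
    stop_nspec("domain", "sd_reference and rmse must be >= 0")
  if (rmse == 0) Inf else sd_reference / rmse
}

#' Classify model performance from r2 and RPD
#'
#' Three-way banding used throughout the workflow:
#' r2 below 0.50 unacceptable, 0.50-0.75 (closed) acceptable, above 0.75
#' excellent; RPD below 1.40 unacceptable, 1.40-2.00 (closed) acceptable,
#' above 2.00 excellent.
#'
#' @param r2 coefficient of determination in \[0, 1\].
#' @param rpd ratio of performance to deviation (>= 0; may be `Inf`).
#' @return Named character vector with elements `r2` and `rpd`.
#' @export
classify_performance <- function(r2, rpd) {
  if (is.na(r2) || r2 < 0 || r2 > 1)
    stop_nspec("domain", "r2 must lie in [0, 1]")
  if (is.na(rpd) || rpd < 0) stop_nspec("domain", "rpd must be >= 0")
  band <- function(x, lo, hi) {
    if (x < lo) "unacceptable" else if (x <= hi) "acceptable" else "excellent"
  }
  c(r2 = band(r2, 0.50, 0.75), rpd = band(rpd, 1.40, 2.00))
}

#' Evaluate predictions against observations
#'
#' Computes the squared Pearson correlation (r2), the RMSE, the RPD
#' relative to `sd_reference`, the least-squares slope and intercept of
#' predicted on observed, and the performance class of
#' [classify_performance()].
#'
#' @param y_obs observed leaf N (%), non-constant, length >= 3.
#' @param y_pred predicted leaf N (%), same length.
#' @param sd_reference reference SD for the RPD; defaults to the SD of
#'   `y_obs` (n - 1 denominator).
#' @param split optional label (`"calibration"` or `"validation"`) carried
#'   into the report.
#' @return An `evaluation_report` list with fields `split`, `n`, `r2`,
#'   `rmse`, `rpd`, `sd_reference`, `slope`, `intercept`,
#'   `performance_class`.
#' @examples
#' obs <- c(2.1, 3.4, 4.2, 5.0, 2.8)
#' evaluate(obs, obs + rnorm(5, 0, 0.2))
#' @export
evaluate <- function(y_obs, y_pred, sd_reference = sd(y_obs), split = NULL) {
  if (length(y_obs) != length(y_pred))
    stop_nspec("shape", "y_obs and y_pred lengths differ")
  if (length(y_obs) < 3L) stop_nspec("size", "need at least 3 pairs")
  if (sd(y_obs) == 0)
    stop_nspec("degenerate", "constant y_obs; evaluation undefined")
  rmse <- sqrt(mean((y_obs - y_pred)^2))
  r2 <- if (sd(y_pred) == 0) 0 else cor(y_obs, y_pred)^2
  line <- coef(lm(y_pred ~ y_obs))
  report <- list(split = split, n = length(y_obs), r2 = r2, rmse = rmse,
                 rpd = rpd(sd_reference, rmse), sd_reference = sd_reference,
                 slope = unname(line[2]), intercept = unname(line[1]))
  report$performance_class <- classify_performance(min(max(r2, 0), 1),
                                                   report$rpd)
  structure(report, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation> %sn=%d  r2=%.3f  RMSE=%.3f  RPD=%.3f (%s/%s)\n",
              if (is.null(x$split)) "" else paste0(x$split, ": "),
              x$n, x$r2, x$rmse, x$rpd,
              x$performance_class["r2"], x$performance_class["rpd"]))
  invisible(x)
}

#' Summary statistics of a leaf N vector
#'
#' @param leaf_n numeric vector (%), length >= 2.
#' @return Named vector: `n`, `mean`, `max`, `min`, `sd` (n - 1
#'   denominator) and `cv_pct` (= 100 sd/mean).
#' @export
dataset_summary <- function(leaf_n) {
  if (length(leaf_n) < 2L) stop_nspec("size", "need at least 2 values")
  s <- sd(leaf_n)
  m <- mean(leaf_n)
  c(n = length(leaf_n), mean = m, max = max(leaf_n), min = min(leaf_n),
    sd = s, cv_pct = 100 * s / m)
}

#' Pool split summaries into whole-dataset mean and SD
#'
#' Reconstructs the pooled mean and SD (n - 1 denominator) of a dataset
#' from the `(n, mean, sd)` summaries of its disjoint splits, using the
#' within- plus between-split decomposition of the total sum of squares.
#'
#' @param ... numeric vectors `c(n = , mean = , sd = )`, one per split
#'   (e.g. outputs of [dataset_summary()]).
#' @return Named vector `n`, `mean`, `sd`.
#' @export
pool_summaries <- function(...) {
  parts <- list(...)
  n <- vapply(parts, function(p) p[["n"]], numeric(1))
  m <- vapply(parts, function(p) p[["mean"]], numeric(1))
  s <- vapply(parts, function(p) p[["sd"]], numeric(1))
  N <- sum(n)
  gm <- sum(n * m) / N
  ss <- sum((n - 1) * s^2 + n * (m - gm)^2)
  c(n = N, mean = gm, sd = sqrt(ss / (N - 1)))
}
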