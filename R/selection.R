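#' VIP scores of a fitted PLS model
#'
#' Variable importance in projection for band j over the A selected latent
#' variables:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a}}
#' with `SSY_a = q_a^2 t_a' t_a` the response variance explained by
#' component a, `w_a` the unit-norm loading weights and p the band count.
#' The normalization makes the squared scores average to 1 over all bands,
#' which is why 1.0 is the conventional selection threshold; raising it
#' (the workflow uses 2.0) isolates only the dominant bands.
#'
#' @param model a PLS `nspec_model` from [fit_pls()].
#' @param threshold selection threshold stored with the profile
#'   (default 1.0).
#' @return A `vip_profile`: data frame with columns `wavelength_nm`,
#'   `vip` and `selected_flag`, plus attribute `threshold`.
#' @export
vip_scores <- function(model, threshold = 1.0) {
  stopifnot(inherits(model, "nspec_model"))
  if (model$method != "PLS")
    stop_nspec("config", "VIP scores require a PLS model")
  W <- model$loading_weights
  ssy <- model$y_loadings^2 * model$score_ss
  if (sum(ssy) <= 0)
    stop_nspec("degenerate", "model explains no response variance")
  p <- nrow(W)
  w2 <- sweep(W, 2L, sqrt(colSums(W^2)), `/`)^2 # guard: unit norm anyway
  vip <- sqrt(p * drop(w2 %*% ssy) / sum(ssy))
  sel <- vip >= threshold
  structure(data.frame(wavelength_nm = model$wavelengths, vip = vip,
                       selected_flag = sel),
            threshold = threshold,
            class = c("vip_profile", "data.frame"))
}

#' Select effective wavelengths from a VIP profile
#'
#' Bands with `vip >= threshold` are grouped into maximal contiguous runs
#' along the grid and each run contributes its VIP-argmax band, reducing
#' broad high-VIP plateaus to discrete effective wavelengths. An empty
#' selection is valid and returned as a zero-row frame with a message.
#'
#' @param profile a `vip_profile` from [vip_scores()].
#' @param threshold VIP selection threshold (> 0); defaults to the
#'   profile's stored threshold.
#' @return Data frame with columns `wavelength_nm` and `vip`, sorted by
#'   wavelength.
#' @export
select_effective_wavelengths <- function(profile,
                                         threshold = attr(profile, "threshold")) {
  stopifnot(inherits(profile, "vip_profile"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop_nspec("config", "threshold must be positive")
  above <- profile$vip >= threshold
  if (!any(above)) {
    message("no band reaches the VIP threshold ", threshold)
    return(data.frame(wavelength_nm = numeric(0), vip = numeric(0)))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  picks <- integer(0)
  for (k in which(runs$values)) {
    span <- starts[k]:ends[k]
    picks <- c(picks, span[which.max(profile$vip[span])])
  }
  out <- data.frame(wavelength_nm = profile$wavelength_nm[picks],
                    vip = profile$vip[picks])
  out[order(out$wavelength_nm), , drop = FALSE]
}

#' Loading-weight profile of one PLS component
#'
#' Returns the stored unit-norm loading-weight column for a component,
#' for reporting the per-band contribution to each latent variable.
#'
#' @param model a PLS `nspec_model`.
#' @param component component index, `1..selected_order`.
#' @return Named numeric vector (names are wavelengths).
#' @export
loading_weight_profile <- function(model, component = 1L) {
  stopifnot(inherits(model, "nspec_model"))
  if (model$method != "PLS")
    stop_nspec("config", "loading weights require a PLS model")
  component <- check_count(component, "component")
  if (component > model$selected_order)
    stop_nspec("index", "component %d exceeds selected order %d",
               component, model$selected_order)
  w <- model$loading_weights[, component]
  names(w) <- format_wavelength(model$wavelengths)
  w
}

#' Write a VIP profile as CSV
#'
#' Columns: `wavelength_nm`, `vip`, `selected_flag`.
#'
#' @param profile a `vip_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vip_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
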