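#' Bootstrap configuration
#'
#' Nonparametric bootstrap resampling respondents with equal probability and
#' with replacement within domain-wave strata; percentile confidence
#' intervals from the replicate estimates.
#'
#' @param n_replicates number of bootstrap replicates (default 1000).
#' @param alpha two-sided level (default 0.05 for 95% intervals).
#' @param seed integer RNG seed.
#' @return object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_replicates = 1000, alpha = 0.05, seed = 1) {
  stopifnot(n_replicates >= 2, alpha > 0, alpha < 1)
  structure(list(n_replicates = as.integer(n_replicates), alpha = alpha,
                 seed = as.integer(seed)), class = "bootstrap_config")
}

#' Draw one stratified bootstrap replicate
#'
#' Within each (domain, wave) stratum, draws rows with replacement; the
#' replicate stratum size equals the original stratum size. Deterministic
#' given `(config$seed, replicate_index)`.
#'
#' @param records respondent records with `domain`, `wave`.
#' @param config a [bootstrap_config()].
#' @param replicate_index 1-based replicate number.
#' @return resampled records (same columns, same per-stratum sizes).
#' @export
resample <- function(records, config, replicate_index) {
  stopifnot(inherits(config, "bootstrap_config"), replicate_index >= 1)
  key <- interaction(records$domain, records$wave, drop = TRUE)
  if (any(tabulate(key) == 0)) stop("empty stratum", call. = FALSE)
  with_stream(config$seed, 7000 + replicate_index, {
    idx <- unlist(lapply(split(seq_len(nrow(records)), key), function(i)
      i[sample.int(length(i), length(i), replace = TRUE)]), use.names = FALSE)
    records[sort(idx), , drop = FALSE]
  })
}

#' Percentile confidence interval from replicate estimates
#'
#' Empirical `alpha/2` and `1 - alpha/2` quantiles with linear interpolation
#' between order statistics (type 7).
#'
#' @param x replicate estimates (>= 2 finite values).
#' @param alpha two-sided level.
#' @return named numeric `c(ci_low, ci_high)`.
#' @export
percentile_ci <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need >= 2 finite replicate values", call. = FALSE)
  q <- stats::quantile(x, c(alpha / 2, 1 - alpha / 2), type = 7, names = FALSE)
  c(ci_low = q[1], ci_high = q[2])
}

#' Bootstrap confidence intervals for post-stratified prevalences
#'
#' Resamples the outcome survey within domain-wave strata, refits the
#' selected model on each replicate (the post-stratification frame is held
#' fixed), post-stratifies, and attaches percentile intervals to the
#' point estimates. Replicates whose refit does not converge are dropped
#' (hard failure if more than 10% drop).
#'
#' @param records outcome-survey respondent records.
#' @param frame raked post-stratification frame.
#' @param spec the selected [model_spec()].
#' @param labor_force domain-wave rate table.
#' @param config a [bootstrap_config()].
#' @param subgroups if TRUE, the full subgroup battery; otherwise overall
#'   only.
#' @param outcome outcome column name.
#' @param nAGQ integration setting for the replicate refits (default 0:
#'   fast penalized least squares; the point estimate is not affected).
#' @param point_fit optional pre-computed full-data `mrp_fit` for the point
#'   estimates (fitted at nAGQ = 1 if omitted).
#' @return estimates data frame with `p_hat`, `ci_low`, `ci_high`, and the
#'   number of contributing replicates as attribute `n_replicates_used`.
#' @export
bootstrap_pipeline <- function(records, frame, spec, labor_force, config,
                               subgroups = FALSE, outcome = "y", nAGQ = 0,
                               point_fit = NULL) {
  stopifnot(inherits(config, "bootstrap_config"))
  domains <- unique(frame$domain)
  waves <- unique(frame$wave)
  est_fun <- function(fit) {
    pred <- predict_cells(fit, domains, waves, labor_force)
    if (subgroups) estimate_subgroups(pred, frame)
    else poststratified_prevalence(pred, frame, "overall")
  }
  if (is.null(point_fit))
    point_fit <- fit_mrp_model(rescale_weights(records), spec, labor_force,
                               outcome = outcome)
  point <- est_fun(point_fit)
  reps <- matrix(NA_real_, config$n_replicates, nrow(point))
  dropped <- 0L
  for (b in seq_len(config$n_replicates)) {
    rb <- resample(records, config, b)
    fb <- fit_mrp_model(rescale_weights(rb), spec, labor_force,
                        outcome = outcome, nAGQ = nAGQ)
    if (!isTRUE(fb$converged)) { dropped <- dropped + 1L; next }
    eb <- est_fun(fb)
    reps[b, ] <- eb$p_hat
  }
  if (dropped > 0.10 * config$n_replicates)
    stop(sprintf("bootstrap failed: %d of %d replicates did not converge",
                 dropped, config$n_replicates), call. = FALSE)
  if (dropped > 0)
    message(sprintf("bootstrap: dropped %d non-converged replicate(s)", dropped))
  ci <- t(apply(reps, 2, function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(c(NA_real_, NA_real_))
    percentile_ci(x, config$alpha)
  }))
  point$ci_low <- ci[, 1]
  point$ci_high <- ci[, 2]
  attr(point, "n_replicates_used") <- config$n_replicates - dropped
  attr(point, "replicates") <- reps
  point
}
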