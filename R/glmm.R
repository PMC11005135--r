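#' Rescale survey weights to sample size within domain-wave strata
#'
#' Within each (domain, wave) stratum, weights are multiplied by a constant
#' so they sum to the stratum's respondent count; relative weights are
#' preserved. This is the standard rescaling for pseudo-likelihood estimation
#' of multilevel models from weighted survey data.
#'
#' @param records respondent records with `domain`, `wave`, `weight`.
#' @return the records with an added column `w` of rescaled weights.
#' @export
rescale_weights <- function(records) {
  if (!all(c("domain", "wave", "weight") %in% names(records)))
    stop("records need columns domain, wave, weight", call. = FALSE)
  bad <- which(!(is.finite(records$weight) & records$weight > 0))
  if (length(bad))
    stop(sprintf("nonpositive weight at record %d", bad[1]), call. = FALSE)
  key <- interaction(records$domain, records$wave, drop = TRUE)
  sums <- tapply(records$weight, key, sum)
  ns <- tapply(records$weight, key, length)
  records$w <- records$weight * as.numeric(ns[key]) / as.numeric(sums[key])
  records
}

# muffle the cosmetic "non-integer #successes" warning raised by the binomial
# family when survey weights are non-integer; leave every other warning alone
quiet_binomial <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("non-integer", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Fit one multilevel logistic regression candidate
#'
#' Fits the weighted logistic mixed model described by `spec` via the Laplace
#' approximation (lme4), treating the rescaled survey weights as frequency
#' weights. Optimizer failure is reported through `converged = FALSE` rather
#' than an error; genuinely unusable inputs (single domain, rank-deficient
#' design) raise.
#'
#' @param records respondent records with covariates, `wave`, an outcome
#'   column, `weight`, and `lf_c` (or pass `labor_force`).
#' @param spec an [model_spec()].
#' @param labor_force optional domain-wave rate table.
#' @param outcome name of the binary outcome column (default "y").
#' @param nAGQ lme4 integration setting. The default 0 profiles the fixed
#'   effects inside the penalized IRLS step and optimizes only the variance
#'   parameters in the outer optimizer; with the 28-40 fixed effects of
#'   these models it is orders of magnitude faster than `nAGQ = 1` (which
#'   performs derivative-free outer optimization over all parameters) and
#'   is the closer analogue of the pseudo-likelihood fits this procedure
#'   descends from. Set `nAGQ = 1` for the full Laplace criterion.
#' @param fix_sigma_zero if TRUE, all variance components are pinned at zero
#'   and the model collapses to weighted fixed-effects logistic regression.
#' @return object of class `mrp_fit` with elements `spec`, `beta`,
#'   `variance_components`, `random_effect_modes`, `loglik`, `aic`, `bic`,
#'   `converged`, `n_obs`, and the underlying `fit` object.
#' @export
fit_mrp_model <- function(records, spec, labor_force = NULL, outcome = "y",
                          nAGQ = 0, fix_sigma_zero = FALSE) {
  stopifnot(inherits(spec, "mrp_model_spec"))
  if (!outcome %in% names(records))
    stop(sprintf("records lack outcome column '%s'", outcome), call. = FALSE)
  d <- prepare_frame(records, spec, labor_force)
  d$y <- records[[outcome]]
  if (nlevels(droplevels(d$domain)) < 2)
    stop("need >= 2 domains: domain variance is not identifiable", call. = FALSE)
  d$w <- if (spec$use_weights) {
    if (!"w" %in% names(d)) d <- rescale_weights(d)
    d$w
  } else rep(1, nrow(d))

  X <- stats::model.matrix(fixed_formula(spec, NULL), d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  p <- count_parameters(spec)
  n <- nrow(d)
  if (fix_sigma_zero) {
    fit <- quiet_binomial(stats::glm(fixed_formula(spec), family = stats::binomial(),
                                     data = d, weights = w))
    ll <- as.numeric(stats::logLik(fit))
    p0 <- length(stats::coef(fit))  # no variance components in this branch
    res <- list(spec = spec, fit = fit, beta = stats::coef(fit),
                variance_components = stats::setNames(
                  rep(0, length(spec$random_intercepts)), spec$random_intercepts),
                random_effect_modes = NULL,
                loglik = ll, aic = -2 * ll + 2 * p0, bic = -2 * ll + p0 * log(n),
                converged = fit$converged, n_obs = n, message = NULL)
    return(structure(res, class = "mrp_fit"))
  }

  form <- mixed_formula(spec)
  ctrl <- lme4::glmerControl(optimizer = "bobyqa",
                             check.conv.singular = "ignore",
                             optCtrl = list(maxfun = 100000))
  fit <- tryCatch(
    quiet_binomial(lme4::glmer(form, data = d, family = stats::binomial(),
                               weights = w, nAGQ = nAGQ, control = ctrl)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(spec = spec, fit = NULL, beta = NULL,
                          variance_components = NULL, random_effect_modes = NULL,
                          loglik = NA_real_, aic = NA_real_, bic = NA_real_,
                          converged = FALSE, n_obs = n,
                          message = conditionMessage(fit)),
                     class = "mrp_fit"))
  }
  msgs <- fit@optinfo$conv$lme4$messages
  conv <- fit@optinfo$conv$opt == 0 &&
    (is.null(msgs) || !any(grepl("fail|unable", tolower(unlist(msgs)))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  # map lme4 grouping names back to spec term names
  grp_name <- c(domain = "domain", race_in_domain = "domain:race_eth",
                wave = "wave_f")
  vcomp <- stats::setNames(
    vc$vcov[match(grp_name[spec$random_intercepts], vc$grp)],
    spec$random_intercepts)
  ll <- as.numeric(stats::logLik(fit))
  structure(list(spec = spec, fit = fit, beta = lme4::fixef(fit),
                 variance_components = vcomp,
                 random_effect_modes = lme4::ranef(fit),
                 loglik = ll, aic = -2 * ll + 2 * p, bic = -2 * ll + p * log(n),
                 converged = conv, n_obs = n,
                 message = if (length(msgs)) paste(unlist(msgs), collapse = "; ")
                           else NULL),
            class = "mrp_fit")
}

#' @export
print.mrp_fit <- function(x, ...) {
  cat(sprintf("<mrp_fit %s: %s, AIC %.2f, BIC %.2f, %d obs>\n", x$spec$id,
              if (x$converged) "converged" else "NOT converged",
              x$aic, x$bic, x$n_obs))
  invisible(x)
}

#' Predict cell probabilities on the full domain x wave x cell grid
#'
#' Builds the complete grid (72 cells per domain-wave), evaluates the fixed
#' linear predictor plus the posterior-mode (empirical Bayes) random
#' intercepts of observed groups (unobserved groups contribute 0), and
#' inverse-logit transforms.
#'
#' @param model an `mrp_fit` (must have converged).
#' @param domains,waves vectors defining the grid.
#' @param labor_force domain-wave rate table covering the grid (columns
#'   domain, wave, rate or lf_c).
#' @param cells cell table (default [build_cells()]).
#' @return data frame: domain, wave, cell columns, `pi_hat` in (0, 1).
#' @export
predict_cells <- function(model, domains, waves, labor_force,
                          cells = build_cells()) {
  stopifnot(inherits(model, "mrp_fit"))
  if (!isTRUE(model$converged))
    stop("cannot predict from a non-converged fit", call. = FALSE)
  grid <- merge(expand.grid(domain = domains, wave = waves,
                            stringsAsFactors = FALSE), cells)
  grid <- grid[do.call(order, grid[c("domain", "wave", "sex", "age_group",
                                     "race_eth", "ses")]), ]
  rownames(grid) <- NULL
  d <- prepare_frame(grid, model$spec, labor_force)
  if (inherits(model$fit, "glm")) {
    grid$pi_hat <- as.numeric(stats::predict(model$fit, newdata = d,
                                             type = "response"))
  } else {
    grid$pi_hat <- as.numeric(stats::predict(model$fit, newdata = d,
                                             type = "response",
                                             allow.new.levels = TRUE))
  }
  grid
}

#' Select the best-fitting candidate by information criteria
#'
#' Smallest AIC among converged fits; ties broken by smaller BIC, then by
#' fewer parameters.
#'
#' @param fits list of `mrp_fit` objects.
#' @return the selected `mrp_fit`.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1)
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) stop("no converged fit to select from", call. = FALSE)
  aic <- vapply(conv, `[[`, numeric(1), "aic")
  bic <- vapply(conv, `[[`, numeric(1), "bic")
  np <- vapply(conv, function(f) count_parameters(f$spec), numeric(1))
  conv[[order(aic, bic, np)[1]]]
}
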