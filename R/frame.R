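#' Direct cell estimates of smoking prevalence
#'
#' Weighted prevalence of current smoking per (domain, wave, cell), with a
#' Kish effective-sample-size binomial variance
#' `v = p(1-p)/n_eff`, `n_eff = (sum w)^2 / sum w^2`. Empty cells are
#' emitted with `n_direct = 0` and `NA` estimates; the fallback rules treat
#' them as data.
#'
#' @param smoking respondent records with `domain`, `wave`, cell columns,
#'   `weight`, and binary `smoker`.
#' @param cells cell grid (default [build_cells()]).
#' @return data frame per (domain, wave, cell): `n_direct`, `p_direct`,
#'   `v_direct`.
#' @export
direct_estimates <- function(smoking, cells = build_cells()) {
  stopifnot(all(c("domain", "wave", "weight", "smoker") %in% names(smoking)))
  grid <- merge(expand.grid(domain = unique(smoking$domain),
                            wave = unique(smoking$wave),
                            stringsAsFactors = FALSE), cells)
  key <- function(df) paste(df$domain, df$wave, df$sex, df$age_group,
                            df$race_eth, df$ses)
  k <- key(smoking)
  sw <- tapply(smoking$weight, k, sum)
  sw2 <- tapply(smoking$weight^2, k, sum)
  swy <- tapply(smoking$weight * smoking$smoker, k, sum)
  nn <- tapply(smoking$weight, k, length)
  gk <- key(grid)
  idx <- match(gk, names(sw))
  grid$n_direct <- ifelse(is.na(idx), 0L, as.integer(nn[idx]))
  p <- as.numeric(swy[idx] / sw[idx])
  neff <- as.numeric(sw[idx]^2 / sw2[idx])
  grid$p_direct <- ifelse(grid$n_direct > 0, p, NA_real_)
  grid$v_direct <- ifelse(grid$n_direct > 0, p * (1 - p) / neff, NA_real_)
  grid <- grid[do.call(order, grid[c("domain", "wave", "sex", "age_group",
                                     "race_eth", "ses")]), ]
  rownames(grid) <- NULL
  grid
}

# terms of the frame-smoothing logistic model: domain, the four demographic
# main effects, and the four stated two-way interactions
frame_model_formula <- stats::as.formula(
  smoker ~ domain + sex + age_group + race_eth + ses +
    domain:race_eth + sex:age_group + sex:race_eth + age_group:race_eth,
  env = globalenv())

#' Model-smoothed cell estimates of smoking prevalence
#'
#' Per wave, fits a weighted fixed-effects logistic regression of smoking
#' status on domain, sex, age group, race/ethnicity, and SES with the
#' two-way interactions domain:race, sex:age, sex:race, and age:race, then
#' predicts every (domain, cell) with a delta-method variance from the
#' coefficient covariance.
#'
#' @inheritParams direct_estimates
#' @return data frame per (domain, wave, cell): `p_model`, `v_model`.
#' @export
model_estimates <- function(smoking, cells = build_cells()) {
  out <- vector("list", 0L)
  for (w in sort(unique(smoking$wave))) {
    s <- smoking[smoking$wave == w, ]
    s$domain <- factor(s$domain)
    for (v in names(cell_levels)) s[[v]] <- cell_factor(s[[v]], v)
    fit <- quiet_binomial(stats::glm(frame_model_formula, family = stats::binomial(),
                                     data = s, weights = weight))
    if (anyNA(stats::coef(fit))) {
      aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient smoking model at wave ", w, "; aliased terms: ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
    grid <- merge(data.frame(domain = levels(s$domain)), cells)
    grid$wave <- w
    pr <- stats::predict(fit, newdata = grid, type = "link", se.fit = TRUE)
    p <- stats::plogis(pr$fit)
    grid$p_model <- as.numeric(p)
    grid$v_model <- as.numeric((p * (1 - p) * pr$se.fit)^2)
    out[[length(out) + 1L]] <- grid
  }
  res <- do.call(rbind, out)
  res <- res[do.call(order, res[c("domain", "wave", "sex", "age_group",
                                  "race_eth", "ses")]), ]
  res <- res[, c("domain", "wave", "sex", "age_group", "race_eth", "ses",
                 "p_model", "v_model")]
  rownames(res) <- NULL
  res
}

#' Composite (variance-weighted) small-domain estimator
#'
#' `theta = a * p_direct + (1 - a) * p_model` with
#' `a = v_model / (v_model + v_direct)`: the direct estimate receives more
#' weight when the model-based estimate is relatively unstable.
#'
#' @param p_direct,v_direct direct prevalence and its variance.
#' @param p_model,v_model model-based prevalence and its variance.
#' @return list with vectors `a` and `theta`.
#' @export
composite <- function(p_direct, v_direct, p_model, v_model) {
  if (any(v_direct < 0 | v_model < 0, na.rm = TRUE))
    stop("variances must be nonnegative", call. = FALSE)
  both0 <- !is.na(v_direct) & !is.na(v_model) & v_direct == 0 & v_model == 0
  if (any(both0))
    stop("composite undefined: both variances are zero", call. = FALSE)
  a <- v_model / (v_model + v_direct)
  list(a = a, theta = a * p_direct + (1 - a) * p_model)
}

#' Fallback rules choosing between composite and model-based estimates
#'
#' The model-based estimate replaces the composite when the direct estimate
#' is unusable: cell sample size below 5, direct prevalence exactly 0 or 1,
#' or an implied smoker count below one (`n_direct * p_direct < 1`).
#'
#' @param frame data frame carrying `n_direct`, `p_direct`, `v_direct`,
#'   `p_model`, `v_model`.
#' @return the frame with added columns `a`, `theta`, `chosen`
#'   ("composite"/"model") and `p_chosen`.
#' @export
apply_fallback <- function(frame) {
  use_model <- frame$n_direct < 5 |
    is.na(frame$p_direct) |
    frame$p_direct == 0 | frame$p_direct == 1 |
    frame$n_direct * frame$p_direct < 1
  frame$a <- NA_real_
  frame$theta <- NA_real_
  ok <- !use_model
  if (any(ok)) {
    cc <- composite(frame$p_direct[ok], frame$v_direct[ok],
                    frame$p_model[ok], frame$v_model[ok])
    frame$a[ok] <- cc$a
    frame$theta[ok] <- cc$theta
  }
  frame$chosen <- ifelse(use_model, "model", "composite")
  frame$p_chosen <- ifelse(use_model, frame$p_model, frame$theta)
  frame
}

#' Pre-raking smoker totals
#'
#' @param frame output of [apply_fallback()].
#' @param population population table keyed by (domain, wave, cell).
#' @return the frame with columns `population` and `N_raw = p_chosen *
#'   population`.
#' @export
smoker_totals <- function(frame, population) {
  kf <- paste(frame$domain, frame$wave, frame$sex, frame$age_group,
              frame$race_eth, frame$ses)
  kp <- paste(population$domain, population$wave, population$sex,
              population$age_group, population$race_eth, population$ses)
  idx <- match(kf, kp)
  if (anyNA(idx))
    stop("missing population for cell: ", kf[which(is.na(idx))[1]],
         call. = FALSE)
  frame$population <- population$population[idx]
  frame$N_raw <- frame$p_chosen * frame$population
  frame
}

#' Iterative proportional fitting of a nonnegative array to margins
#'
#' Rescales `seed` so that its marginal sums over each dimension match
#' `margins`, sweeping the dimensions in order until the maximum relative
#' margin error falls below `tol`.
#'
#' @param seed nonnegative numeric array.
#' @param margins list of target margin vectors, one per dimension of
#'   `seed`, in dimension order. All margin totals must agree.
#' @param tol relative margin tolerance (default 1e-8).
#' @param max_iter maximum sweeps (default 1000).
#' @return array of the same shape with matching margins.
#' @export
ipf_rake <- function(seed, margins, tol = 1e-8, max_iter = 1000) {
  dims <- dim(seed)
  if (is.null(dims)) { dims <- length(seed); seed <- array(seed, dims) }
  stopifnot(length(margins) == length(dims))
  for (f in seq_along(margins)) {
    stopifnot(length(margins[[f]]) == dims[f])
    cur <- apply(seed, f, sum)
    if (any(cur == 0 & margins[[f]] > 0))
      stop(sprintf("zero seed mass in dimension %d level %d with positive margin",
                   f, which(cur == 0 & margins[[f]] > 0)[1]), call. = FALSE)
  }
  totals <- vapply(margins, sum, numeric(1))
  if (max(abs(totals - totals[1])) > 1e-6 * max(totals))
    stop("margin grand totals disagree across factors", call. = FALSE)
  rel_err <- function(x) {
    e <- 0
    for (f in seq_along(margins)) {
      m <- margins[[f]]
      cur <- apply(x, f, sum)
      pos <- m > 0
      if (any(pos)) e <- max(e, max(abs(cur[pos] - m[pos]) / m[pos]))
    }
    e
  }
  for (it in seq_len(max_iter)) {
    for (f in seq_along(margins)) {
      cur <- apply(seed, f, sum)
      fac <- ifelse(cur > 0, margins[[f]] / cur, 1)
      seed <- sweep(seed, f, fac, `*`)
    }
    if (rel_err(seed) < tol) return(seed)
  }
  stop(sprintf("IPF did not converge in %d sweeps (relative error %.3g)",
               max_iter, rel_err(seed)), call. = FALSE)
}

#' Raking margins from the smoking survey
#'
#' For each domain-wave and each of the four demographic factors, the target
#' margin of a level is the weighted smoking prevalence among respondents of
#' that level times the total population of that level. Each factor's
#' margins are rescaled to the common grand total (overall weighted
#' prevalence times total population) so that raking is well posed.
#'
#' @param smoking smoking-survey records.
#' @param population population table.
#' @return data frame: domain, wave, factor, level, margin.
#' @export
rake_margins <- function(smoking, population) {
  out <- vector("list", 0L)
  for (d in unique(smoking$domain)) for (w in unique(smoking$wave)) {
    s <- smoking[smoking$domain == d & smoking$wave == w, ]
    p <- population[population$domain == d & population$wave == w, ]
    prev_all <- sum(s$weight * s$smoker) / sum(s$weight)
    grand <- prev_all * sum(p$population)
    for (f in names(cell_levels)) {
      lv <- cell_levels[[f]]
      prev_l <- vapply(lv, function(l) {
        sl <- s[s[[f]] == l, ]
        if (!nrow(sl)) return(0)
        sum(sl$weight * sl$smoker) / sum(sl$weight)
      }, numeric(1))
      pop_l <- vapply(lv, function(l) sum(p$population[p[[f]] == l]),
                      numeric(1))
      m <- prev_l * pop_l
      if (sum(m) > 0) m <- m * grand / sum(m)
      out[[length(out) + 1L]] <- data.frame(domain = d, wave = w, factor = f,
                                            level = lv, margin = m)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rake frame smoker totals to domain-wave margins
#'
#' Within each domain-wave, adjusts the 72 pre-raking totals `N_raw` by
#' iterative proportional fitting over the four demographic factors so the
#' single-factor marginal totals match the supplied margins.
#'
#' @param frame output of [smoker_totals()].
#' @param margins output of [rake_margins()].
#' @param tol,max_iter IPF controls.
#' @return the frame with a raked column `N`.
#' @export
rake_frame <- function(frame, margins, tol = 1e-8, max_iter = 1000) {
  frame$N <- NA_real_
  dims <- vapply(cell_levels, length, integer(1))
  for (d in unique(frame$domain)) for (w in unique(frame$wave)) {
    sel <- frame$domain == d & frame$wave == w
    sub <- frame[sel, ]
    # array indexed [sex, age, race, ses]
    idx <- cbind(match(sub$sex, cell_levels$sex),
                 match(sub$age_group, cell_levels$age_group),
                 match(sub$race_eth, cell_levels$race_eth),
                 match(sub$ses, cell_levels$ses))
    arr <- array(0, dims)
    arr[idx] <- sub$N_raw
    mg <- lapply(names(cell_levels), function(f) {
      m <- margins[margins$domain == d & margins$wave == w &
                     margins$factor == f, ]
      m$margin[match(cell_levels[[f]], m$level)]
    })
    raked <- ipf_rake(arr, mg, tol = tol, max_iter = max_iter)
    frame$N[sel] <- raked[idx]
  }
  frame
}

#' Build the complete post-stratification frame
#'
#' Direct estimates, model smoothing, composite blending with fallback
#' rules, population multiplication, and IPF raking, in one call.
#'
#' @param smoking smoking-survey records.
#' @param population population table.
#' @param cells cell grid.
#' @param tol,max_iter IPF controls.
#' @return frame data frame with all intermediate columns and the raked `N`.
#' @export
build_frame <- function(smoking, population, cells = build_cells(),
                        tol = 1e-8, max_iter = 1000) {
  de <- direct_estimates(smoking, cells)
  me <- model_estimates(smoking, cells)
  kd <- paste(de$domain, de$wave, de$sex, de$age_group, de$race_eth, de$ses)
  km <- paste(me$domain, me$wave, me$sex, me$age_group, me$race_eth, me$ses)
  idx <- match(kd, km)
  if (anyNA(idx)) stop("model estimates missing cells", call. = FALSE)
  de$p_model <- me$p_model[idx]
  de$v_model <- me$v_model[idx]
  fr <- apply_fallback(de)
  fr <- smoker_totals(fr, population)
  rake_frame(fr, rake_margins(smoking, population), tol = tol,
             max_iter = max_iter)
}
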