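#' Configuration of the synthetic ground-truth world
#'
#' Describes a data-generating process with the same statistical structure
#' the analysis assumes: a binary outcome (e.g. menthol use among people who
#' smoke) following a logistic model with fixed demographic effects, a linear
#' (or piecewise) time trend, domain random intercepts and optionally
#' race-within-domain intercepts; a smoking-status model that sets the true
#' smoker population of every cell; lognormal unit-mean survey weights.
#'
#' Coefficients are named on the design coding of [design_matrix()] (e.g.
#' `"sexfemale"`, `"age_group18-29"`, `"race_ethnh_black"`, `"time"`,
#' `"(Intercept)"`); unnamed terms default to zero.
#'
#' @param n_domains number of geographic domains (>= 2).
#' @param n_waves number of survey waves (>= 2).
#' @param fixed_effects named numeric vector of outcome-model coefficients
#'   (log-odds scale).
#' @param sigma_domain SD of domain random intercepts (log-odds, >= 0).
#' @param sigma_nested SD of race-within-domain intercepts (>= 0; 0 disables).
#' @param time_spec [time_basis_spec()] of the generative time trend.
#' @param smoking_model_coefs named numeric vector for the smoking-status
#'   probability (main effects coding; log-odds).
#' @param cell_population_range integer min/max population per cell.
#' @param sample_sizes named list with per-domain-wave respondent counts
#'   `outcome`, `smoking`, `gold`.
#' @param weight_sdlog lognormal sdlog of the synthetic survey weights.
#' @param seed integer; fixes every generated artifact.
#' @return object of class `truth_config`.
#' @export
truth_config <- function(n_domains = 3, n_waves = 4,
                         fixed_effects = default_truth_coefs(),
                         sigma_domain = 0.3, sigma_nested = 0,
                         time_spec = NULL,
                         smoking_model_coefs = default_smoking_coefs(),
                         cell_population_range = c(2000, 50000),
                         sample_sizes = list(outcome = 5000, smoking = 5000,
                                             gold = 5000),
                         weight_sdlog = 0.5, seed = 1) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid truth_config field '%s': %s", field, msg),
                  call. = FALSE)
  }
  chk(is.numeric(n_domains) && n_domains >= 2, "n_domains", "must be >= 2")
  chk(is.numeric(n_waves) && n_waves >= 2, "n_waves", "must be >= 2")
  chk(is.numeric(sigma_domain) && sigma_domain >= 0, "sigma_domain", "must be >= 0")
  chk(is.numeric(sigma_nested) && sigma_nested >= 0, "sigma_nested", "must be >= 0")
  chk(is.numeric(cell_population_range) && length(cell_population_range) == 2 &&
        all(cell_population_range >= 1) && diff(cell_population_range) >= 0,
      "cell_population_range", "must be increasing positive pair")
  chk(is.list(sample_sizes) &&
        all(c("outcome", "smoking", "gold") %in% names(sample_sizes)) &&
        all(unlist(sample_sizes) >= 1),
      "sample_sizes", "needs outcome/smoking/gold entries, all >= 1")
  chk(is.numeric(weight_sdlog) && weight_sdlog >= 0, "weight_sdlog", "must be >= 0")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed",
      "must be a single integer")
  if (is.null(time_spec)) time_spec <- time_basis_spec("linear", n_waves = n_waves)
  chk(inherits(time_spec, "time_basis_spec") && time_spec$n_waves == n_waves,
      "time_spec", "must be a time_basis_spec with matching n_waves")
  structure(list(n_domains = as.integer(n_domains), n_waves = as.integer(n_waves),
                 fixed_effects = fixed_effects, sigma_domain = sigma_domain,
                 sigma_nested = sigma_nested, time_spec = time_spec,
                 smoking_model_coefs = smoking_model_coefs,
                 cell_population_range = as.integer(cell_population_range),
                 sample_sizes = sample_sizes, weight_sdlog = weight_sdlog,
                 seed = as.integer(seed)),
            class = "truth_config")
}

#' Default generative outcome coefficients (log-odds)
#'
#' Chosen to mimic the qualitative structure of US menthol-use surveillance:
#' baseline (male, 50+, NH White, high SES) around 28%, markedly higher odds
#' for NH Black respondents, moderately higher for Hispanic respondents,
#' higher among females and younger adults, a gently rising time trend, and
#' small interactions.
#' @export
default_truth_coefs <- function() {
  c("(Intercept)" = stats::qlogis(0.28),
    "sexfemale" = 0.25,
    "age_group30-49" = 0.25, "age_group18-29" = 0.55,
    "race_ethnh_black" = 2.2, "race_ethhispanic" = 0.7,
    "race_ethother_nh" = 0.3,
    "sesmoderate" = 0.05, "seslow" = 0.15,
    "lf_c" = 0.03, "time" = 0.06,
    "sexfemale:race_ethnh_black" = -0.2,
    "age_group18-29:race_ethnh_black" = 0.3)
}

#' Default generative smoking-status coefficients (log-odds)
#'
#' Roughly 20% baseline adult smoking, higher at lower SES, slightly lower
#' among females and Hispanic adults.
#' @export
default_smoking_coefs <- function() {
  c("(Intercept)" = stats::qlogis(0.20),
    "sexfemale" = -0.15,
    "age_group30-49" = 0.15, "age_group18-29" = 0.05,
    "race_ethnh_black" = 0.05, "race_ethhispanic" = -0.4,
    "race_ethother_nh" = -0.2,
    "sesmoderate" = 0.3, "seslow" = 0.6)
}

# run expr with a deterministic RNG substream, restoring the caller's state
with_stream <- function(seed, offset, expr) {
  s <- (as.numeric(seed) * 97 + offset * 1000003) %% 2147483647
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(s))
  expr
}

domain_names <- function(n) sprintf("D%02d", seq_len(n))

# linear predictor contribution of named coefficients on a design matrix;
# unknown coefficient names are an error (they would silently vanish).
coef_eta <- function(X, coefs) {
  unknown <- setdiff(names(coefs), colnames(X))
  if (length(unknown))
    stop("coefficient name(s) not in design coding: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta[names(coefs)] <- coefs
  drop(X %*% beta)
}

# Internal: the full deterministic truth of a configured world.
# Returns labor_force, population, truth table (pi_true, p_smoke, N_true),
# and the realized random effects.
build_truth <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  doms <- domain_names(config$n_domains)
  waves <- 0:(config$n_waves - 1)
  cells <- build_cells()

  lf <- with_stream(config$seed, 2, {
    g <- expand.grid(domain = doms, wave = waves, stringsAsFactors = FALSE)
    g <- g[order(g$domain, g$wave), ]
    g$rate <- 62 + rep(stats::rnorm(length(doms), 0, 2), each = length(waves)) -
      0.15 * g$wave + stats::rnorm(nrow(g), 0, 0.5)
    rownames(g) <- NULL
    g
  })
  lf <- center_labor_force(lf)

  pop <- with_stream(config$seed, 1, {
    g <- merge(expand.grid(domain = doms, wave = waves, stringsAsFactors = FALSE),
               cells)
    g <- g[do.call(order, g[c("domain", "wave", "sex", "age_group",
                              "race_eth", "ses")]), ]
    rownames(g) <- NULL
    r <- config$cell_population_range
    g$population <- if (r[1] == r[2]) rep(r[1], nrow(g)) else
      sample(seq(r[1], r[2]), nrow(g), replace = TRUE)
    g
  })

  re <- with_stream(config$seed, 3, {
    u_dom <- stats::setNames(stats::rnorm(length(doms), 0, config$sigma_domain), doms)
    nested <- expand.grid(domain = doms, race_eth = cell_levels$race_eth,
                          stringsAsFactors = FALSE)
    nested$u <- if (config$sigma_nested > 0)
      stats::rnorm(nrow(nested), 0, config$sigma_nested) else 0
    list(u_domain = u_dom, u_nested = nested)
  })

  gen_spec <- model_spec("generator", config$time_spec,
                         random_intercepts = if (config$sigma_nested > 0)
                           c("domain", "race_in_domain") else "domain")
  grid <- pop
  grid$lf_c <- lf$lf_c[match(paste(grid$domain, grid$wave),
                             paste(lf$domain, lf$wave))]
  dm <- design_matrix(grid, gen_spec, labor_force = NULL)
  eta <- coef_eta(dm$X, config$fixed_effects)
  eta <- eta + re$u_domain[grid$domain]
  nk <- paste(re$u_nested$domain, re$u_nested$race_eth)
  eta <- eta + re$u_nested$u[match(paste(grid$domain, grid$race_eth), nk)]
  grid$pi_true <- stats::plogis(eta)

  eta_s <- coef_eta(dm$X, config$smoking_model_coefs)
  grid$p_smoke_true <- stats::plogis(eta_s)
  grid$N_true <- grid$population * grid$p_smoke_true

  list(labor_force = lf, population = pop,
       truth = grid[, c("domain", "wave", "sex", "age_group", "race_eth",
                        "ses", "pi_true", "p_smoke_true", "N_true",
                        "population")],
       random_effects = re)
}

#' Generate the cell population table
#'
#' One positive integer population per (domain, wave, cell), uniform on the
#' configured range; a stand-in for census population totals.
#'
#' @param config a [truth_config()].
#' @return data frame: domain, wave, sex, age_group, race_eth, ses, population.
#' @export
generate_population <- function(config) build_truth(config)$population

#' Generate the ground-truth table
#'
#' @param config a [truth_config()].
#' @return data frame keyed by (domain, wave, cell) with the true outcome
#'   probability `pi_true`, true smoking probability `p_smoke_true`, true
#'   smoker population `N_true`, and the cell population.
#' @export
generate_truth <- function(config) build_truth(config)$truth

#' Generate the domain-wave labor-force participation table
#' @param config a [truth_config()].
#' @return data frame: domain, wave, rate, lf_c (centered within domain).
#' @export
generate_labor_force <- function(config) build_truth(config)$labor_force

# draw one survey: cell membership multinomial proportional to `size_col`,
# outcome Bernoulli(prob_col), weights lognormal normalized to mean 1 per
# domain-wave; education/income indicators consistent with the cell's SES.
draw_survey <- function(config, truth, n_per, prob_col, size_col, offset,
                        outcome_name) {
  with_stream(config$seed, offset, {
    out <- vector("list", 0L)
    for (d in unique(truth$domain)) for (w in unique(truth$wave)) {
      cells <- truth[truth$domain == d & truth$wave == w, ]
      idx <- sample.int(nrow(cells), n_per, replace = TRUE,
                        prob = cells[[size_col]])
      rec <- cells[idx, c("domain", "wave", "sex", "age_group", "race_eth",
                          "ses")]
      p <- cells[[prob_col]][idx]
      rec[[outcome_name]] <- stats::rbinom(n_per, 1, p)
      w_raw <- stats::rlnorm(n_per, -config$weight_sdlog^2 / 2,
                             config$weight_sdlog)
      rec$weight <- w_raw / mean(w_raw)
      rec$education_gt_hs <- rec$ses == "high" |
        (rec$ses == "moderate" & stats::runif(n_per) < 0.5)
      rec$income_ge_threshold <- ifelse(rec$ses == "high", TRUE,
                                        ifelse(rec$ses == "low", FALSE,
                                               !rec$education_gt_hs))
      out[[length(out) + 1L]] <- rec
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Generate the outcome survey (the small multi-wave panel)
#'
#' Respondents per domain-wave are drawn with cell membership proportional to
#' cell population; the binary outcome is Bernoulli(`pi_true`); weights are
#' lognormal with mean one within each domain-wave.
#'
#' @param config a [truth_config()].
#' @return respondent-level data frame with columns domain, wave, sex,
#'   age_group, race_eth, ses, y, weight, education_gt_hs,
#'   income_ge_threshold.
#' @export
generate_outcome_survey <- function(config) {
  truth <- build_truth(config)$truth
  draw_survey(config, truth, config$sample_sizes$outcome, "pi_true",
              "population", 4, "y")
}

#' Generate the large smoking-status survey (frame source)
#'
#' @param config a [truth_config()].
#' @return respondent-level data frame as in [generate_outcome_survey()] but
#'   with binary column `smoker` (Bernoulli of the true cell smoking
#'   probability).
#' @export
generate_smoking_survey <- function(config) {
  truth <- build_truth(config)$truth
  draw_survey(config, truth, config$sample_sizes$smoking, "p_smoke_true",
              "population", 5, "smoker")
}

#' Generate the independent gold validation survey
#'
#' Simulates an external survey of people who smoke (membership proportional
#' to the true smoker population) and reports direct prevalence estimates
#' per domain, wave, and subgroup family (overall, sex, age group,
#' race/ethnicity) with a design-based binomial variance, not microdata.
#'
#' @param config a [truth_config()].
#' @return data frame: domain, wave, group ("overall", "sex", "age_group",
#'   "race_eth"), level, n, p_gold, v_gold.
#' @export
generate_gold_survey <- function(config) {
  truth <- build_truth(config)$truth
  micro <- draw_survey(config, truth, config$sample_sizes$gold, "pi_true",
                       "N_true", 6, "y")
  agg <- function(df, group, level) {
    n <- nrow(df)
    p <- sum(df$weight * df$y) / sum(df$weight)
    neff <- sum(df$weight)^2 / sum(df$weight^2)
    data.frame(domain = df$domain[1], wave = df$wave[1], group = group,
               level = level, n = n, p_gold = p,
               v_gold = p * (1 - p) / neff)
  }
  out <- vector("list", 0L)
  for (d in unique(micro$domain)) for (w in unique(micro$wave)) {
    s <- micro[micro$domain == d & micro$wave == w, ]
    out[[length(out) + 1L]] <- agg(s, "overall", "overall")
    for (g in c("sex", "age_group", "race_eth")) {
      for (lv in cell_levels[[g]]) {
        ss <- s[s[[g]] == lv, ]
        if (nrow(ss) > 0) out[[length(out) + 1L]] <- agg(ss, g, lv)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' True prevalence aggregates from a truth table
#'
#' The N_true-weighted mean of `pi_true` per domain and wave over the cells
#' passing the subgroup filter.
#'
#' @param truth a truth table from [generate_truth()].
#' @param subgroup `NULL`/"overall", or a named list such as
#'   `list(sex = "female")` restricting the cells.
#' @return data frame: domain, wave, p_true.
#' @export
true_aggregates <- function(truth, subgroup = NULL) {
  sel <- rep(TRUE, nrow(truth))
  if (!is.null(subgroup) && !identical(subgroup, "overall")) {
    stopifnot(is.list(subgroup), length(names(subgroup)) == length(subgroup))
    for (nm in names(subgroup)) {
      if (!nm %in% names(cell_levels)) stop("unknown subgroup variable: ", nm,
                                            call. = FALSE)
      sel <- sel & truth[[nm]] %in% subgroup[[nm]]
    }
  }
  if (!any(sel)) stop("subgroup filter selects no cells", call. = FALSE)
  t2 <- truth[sel, ]
  num <- tapply(t2$N_true * t2$pi_true, list(t2$domain, t2$wave), sum)
  den <- tapply(t2$N_true, list(t2$domain, t2$wave), sum)
  out <- expand.grid(domain = rownames(num), wave = as.numeric(colnames(num)),
                     stringsAsFactors = FALSE)
  out$p_true <- as.vector(num / den)
  out[order(out$domain, out$wave), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Generate every artifact of a synthetic study at once
#'
#' @param config a [truth_config()].
#' @return list with `population`, `labor_force`, `truth`, `outcome_survey`,
#'   `smoking_survey`, `gold`, and the realized `random_effects`.
#' @export
simulate_study <- function(config) {
  tr <- build_truth(config)
  list(population = tr$population, labor_force = tr$labor_force,
       truth = tr$truth, random_effects = tr$random_effects,
       outcome_survey = generate_outcome_survey(config),
       smoking_survey = generate_smoking_survey(config),
       gold = generate_gold_survey(config))
}
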