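#' Demographic cell structure
#'
#' The post-stratification cell grid crosses sex (2) x age group (3) x
#' race/ethnicity (4) x socioeconomic status (3) = 72 cells. Reference levels
#' (first level of each factor) are male, age 50+, non-Hispanic White, and
#' high SES; predictions are invariant to this choice.
#'
#' @format A named list of character vectors, one per factor.
#' @export
cell_levels <- list(
  sex       = c("male", "female"),
  age_group = c("50+", "30-49", "18-29"),
  race_eth  = c("nh_white", "nh_black", "hispanic", "other_nh"),
  ses       = c("high", "moderate", "low")
)

cell_factor <- function(x, which) {
  lv <- cell_levels[[which]]
  if (is.factor(x)) x <- as.character(x)
  bad <- !is.na(x) & !(x %in% lv)
  if (any(bad)) {
    stop(sprintf("unknown level(s) for '%s': %s (record %s)", which,
                 paste(unique(x[bad]), collapse = ", "),
                 which(bad)[1]), call. = FALSE)
  }
  factor(x, levels = lv)
}

#' Enumerate the 72 post-stratification cells
#'
#' @return A data frame with 72 rows and factor columns `sex`, `age_group`,
#'   `race_eth`, `ses`, in a fixed deterministic order (ses varies fastest).
#' @export
build_cells <- function() {
  g <- expand.grid(ses = cell_levels$ses, race_eth = cell_levels$race_eth,
                   age_group = cell_levels$age_group, sex = cell_levels$sex,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = TRUE)
  g <- g[, c("sex", "age_group", "race_eth", "ses")]
  rownames(g) <- NULL
  g
}

#' Derive the three-level SES composite
#'
#' SES combines a binary education indicator (more than high school) and a
#' binary household-income indicator (at or above the threshold). Respondents
#' with both indicators true are "high"; with both false (not-reported counts
#' as false for both) are "low"; all others "moderate".
#'
#' @param education_gt_hs logical; more than a high-school education. `NA`
#'   (not reported) is treated as `FALSE`.
#' @param income_ge_threshold logical; household income at/above the
#'   threshold. `NA` is treated as `FALSE`.
#' @return factor with levels high, moderate, low.
#' @export
derive_ses <- function(education_gt_hs, income_ge_threshold) {
  e <- !is.na(education_gt_hs) & education_gt_hs
  i <- !is.na(income_ge_threshold) & income_ge_threshold
  out <- ifelse(e & i, "high", ifelse(!e & !i, "low", "moderate"))
  factor(out, levels = cell_levels$ses)
}

#' Mean-center labor-force participation rates within domain
#'
#' @param rates data frame with columns `domain`, `wave`, `rate`; one row per
#'   domain-wave pair (every domain must have a rate for every wave).
#' @return the input with an added column `lf_c = rate - mean(rate within
#'   domain)`.
#' @export
center_labor_force <- function(rates) {
  stopifnot(all(c("domain", "wave", "rate") %in% names(rates)))
  full <- expand.grid(domain = unique(rates$domain), wave = unique(rates$wave))
  key <- paste(rates$domain, rates$wave)
  miss <- !(paste(full$domain, full$wave) %in% key)
  if (any(miss)) {
    m <- full[which(miss)[1], ]
    stop(sprintf("missing labor-force rate for domain '%s', wave %s",
                 m$domain, m$wave), call. = FALSE)
  }
  if (anyDuplicated(key)) stop("duplicate domain-wave rate rows", call. = FALSE)
  mu <- tapply(rates$rate, rates$domain, mean)
  rates$lf_c <- rates$rate - as.numeric(mu[as.character(rates$domain)])
  rates
}

#' Time basis specification
#'
#' Waves are indexed 0, 1, ..., `n_waves - 1` (the first wave is time 0).
#' Three basis kinds are supported: `linear` (a single slope column),
#' `categorical` (wave indicators, wave 0 as reference), and `pwlt`
#' (piecewise-linear trend: a slope plus one hinge `max(0, t - k)` per knot,
#' allowing a bend in the trend at each knot).
#'
#' @param kind one of "linear", "categorical", "pwlt".
#' @param knots integer wave indices, strictly increasing, each strictly
#'   inside (0, n_waves - 1). Required for "pwlt".
#' @param n_waves number of waves (>= 2).
#' @return an object of class `time_basis_spec`.
#' @export
time_basis_spec <- function(kind = c("linear", "categorical", "pwlt"),
                            knots = NULL, n_waves) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(n_waves), n_waves >= 2)
  n_waves <- as.integer(n_waves)
  if (kind == "pwlt") {
    if (is.null(knots) || length(knots) < 1)
      stop("pwlt basis requires at least one knot", call. = FALSE)
    knots <- as.numeric(knots)
    if (any(diff(knots) <= 0)) stop("knots must be strictly increasing", call. = FALSE)
    if (any(knots <= 0 | knots >= n_waves - 1))
      stop("knots must lie strictly inside (0, n_waves - 1)", call. = FALSE)
  } else {
    knots <- NULL
  }
  structure(list(kind = kind, knots = knots, n_waves = n_waves),
            class = "time_basis_spec")
}

#' Number of columns contributed by a time basis
#' @param spec a `time_basis_spec`.
#' @export
n_time_columns <- function(spec) {
  switch(spec$kind,
         linear = 1L,
         categorical = spec$n_waves - 1L,
         pwlt = 1L + length(spec$knots))
}

time_basis_names <- function(spec) {
  switch(spec$kind,
         linear = "time",
         categorical = paste0("wave_", seq_len(spec$n_waves - 1L)),
         pwlt = c("time", paste0("hinge_", spec$knots)))
}

#' Evaluate a time basis at wave indices
#'
#' @param wave_index 0-based wave indices (vectorized).
#' @param spec a `time_basis_spec`.
#' @return numeric matrix, one row per index, named columns.
#' @export
time_basis <- function(wave_index, spec) {
  stopifnot(inherits(spec, "time_basis_spec"))
  t <- as.numeric(wave_index)
  if (any(t < 0 | t > spec$n_waves - 1))
    stop(sprintf("wave_index out of range [0, %d]", spec$n_waves - 1L), call. = FALSE)
  m <- switch(spec$kind,
    linear = matrix(t, ncol = 1),
    categorical = {
      mm <- matrix(0, length(t), spec$n_waves - 1L)
      for (w in seq_len(spec$n_waves - 1L)) mm[, w] <- as.numeric(t == w)
      mm
    },
    pwlt = cbind(t, matrix(vapply(spec$knots, function(k) pmax(0, t - k),
                                  numeric(length(t))), nrow = length(t))))
  colnames(m) <- time_basis_names(spec)
  m
}

#' Model specification for the multilevel logistic regression
#'
#' All candidate models share the same fixed-effect structure: main effects
#' for sex, age group, race/ethnicity, and SES, the domain-level mean-centred
#' labor-force participation rate, the time basis, and the interactions
#' sex:race, age:race, sex:age, and sex:age:race (so the three-way
#' interaction is modeled). They differ in the time basis and the random
#' intercept structure, and in whether survey weights are used.
#'
#' @param id label, e.g. "model1".
#' @param time_spec a [time_basis_spec()].
#' @param random_intercepts character subset of
#'   `c("domain", "race_in_domain", "wave")`, at least one.
#' @param use_weights logical; `FALSE` only for the unweighted candidate.
#' @return object of class `mrp_model_spec`.
#' @export
model_spec <- function(id, time_spec, random_intercepts = "domain",
                       use_weights = TRUE) {
  stopifnot(inherits(time_spec, "time_basis_spec"))
  ok <- c("domain", "race_in_domain", "wave")
  if (length(random_intercepts) < 1 || !all(random_intercepts %in% ok))
    stop("random_intercepts must be a nonempty subset of ",
         paste(ok, collapse = ", "), call. = FALSE)
  structure(list(id = id, time_spec = time_spec,
                 random_intercepts = random_intercepts,
                 use_weights = isTRUE(use_weights)),
            class = "mrp_model_spec")
}

#' @export
print.mrp_model_spec <- function(x, ...) {
  cat(sprintf("<mrp_model_spec %s: %s time (%s), RI: %s, %s>\n", x$id,
              x$time_spec$kind,
              if (is.null(x$time_spec$knots)) "-" else
                paste(x$time_spec$knots, collapse = ","),
              paste(x$random_intercepts, collapse = "+"),
              if (x$use_weights) "weighted" else "unweighted"))
  invisible(x)
}

# Scale the canonical 13-wave knot positions (6 = bend at 2008, 7 = lagged
# bend at 2010, 10 = bend at 2016) onto a shorter timeline; knots must land
# on integers strictly inside (0, n_waves - 1).
scale_knot <- function(k, n_waves) {
  kk <- round(k * (n_waves - 1) / 12)
  min(max(kk, 1L), n_waves - 2L)
}

two_knots <- function(k1, k2, n_waves) {
  a <- scale_knot(k1, n_waves); b <- scale_knot(k2, n_waves)
  if (a >= b) a <- b - 1L
  if (a < 1L) stop("n_waves too small to host two distinct knots", call. = FALSE)
  c(a, b)
}

#' The nine candidate model specifications
#'
#' Model 1: linear time; 2: categorical time; 3-5: one-bend piecewise trends
#' (bend at the "2008", "2010", and "2016" knots respectively); 6: bends at
#' 2008 and 2016; 7: bends at 2010 and 2016. Models 1-7 have a domain random
#' intercept. Model 8 adds a race/ethnicity intercept nested in domain to
#' model 7's structure; model 9 has domain and wave intercepts, model 7's
#' time basis, and is fit unweighted. At the canonical 13 waves the knots are
#' wave indices 6, 7, and 10; for other `n_waves` they are scaled
#' proportionally.
#'
#' @param n_waves number of waves (default 13).
#' @return named list of nine `mrp_model_spec` objects.
#' @export
default_model_specs <- function(n_waves = 13) {
  n_waves <- as.integer(n_waves)
  if (n_waves < 4) stop("default specs need n_waves >= 4", call. = FALSE)
  cc  <- scale_knot(6, n_waves)
  lag <- scale_knot(7, n_waves)
  v4  <- scale_knot(10, n_waves)
  tb <- function(kind, knots = NULL) time_basis_spec(kind, knots, n_waves)
  specs <- list(
    model1 = model_spec("model1", tb("linear")),
    model2 = model_spec("model2", tb("categorical")),
    model3 = model_spec("model3", tb("pwlt", cc)),
    model4 = model_spec("model4", tb("pwlt", lag)),
    model5 = model_spec("model5", tb("pwlt", v4)),
    model6 = model_spec("model6", tb("pwlt", two_knots(6, 10, n_waves))),
    model7 = model_spec("model7", tb("pwlt", two_knots(7, 10, n_waves))),
    model8 = model_spec("model8", tb("pwlt", two_knots(7, 10, n_waves)),
                        random_intercepts = c("domain", "race_in_domain")),
    model9 = model_spec("model9", tb("pwlt", two_knots(7, 10, n_waves)),
                        random_intercepts = c("domain", "wave"),
                        use_weights = FALSE)
  )
  specs
}

# Fixed-effect columns shared by every spec: intercept, female, age (2),
# race (3), ses (2), lf_c, plus interactions sex:race (3), age:race (6),
# sex:age (2), sex:age:race (6) = 27, plus the time basis columns.
N_SHARED_FIXED <- 27L

#' Total parameter count of a model specification
#'
#' Fixed-effect columns plus one variance component per random intercept.
#'
#' @param spec an `mrp_model_spec`.
#' @return integer.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "mrp_model_spec"))
  N_SHARED_FIXED + n_time_columns(spec$time_spec) + length(spec$random_intercepts)
}

fixed_formula <- function(spec, response = "y") {
  tb <- paste0("`", time_basis_names(spec$time_spec), "`")
  rhs <- c("sex", "age_group", "race_eth", "ses", "lf_c", tb,
           "sex:race_eth", "age_group:race_eth", "sex:age_group",
           "sex:age_group:race_eth")
  lhs <- if (is.null(response)) "" else response
  stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")),
                    env = globalenv())
}

re_terms <- c(domain = "(1 | domain)",
              race_in_domain = "(1 | domain:race_eth)",
              wave = "(1 | wave_f)")

mixed_formula <- function(spec, response = "y") {
  f <- fixed_formula(spec, response)
  re <- paste(re_terms[spec$random_intercepts], collapse = " + ")
  stats::as.formula(paste(deparse1(f), "+", re), env = globalenv())
}

# Attach typed factor columns, time-basis columns, and centered labor force
# to respondent records; shared by fitting and prediction.
prepare_frame <- function(records, spec, labor_force = NULL) {
  d <- as.data.frame(records)
  for (v in names(cell_levels)) {
    if (!v %in% names(d)) stop(sprintf("records lack column '%s'", v), call. = FALSE)
    d[[v]] <- cell_factor(d[[v]], v)
  }
  if (!"wave" %in% names(d)) stop("records lack column 'wave'", call. = FALSE)
  if (!is.null(labor_force)) {
    lf <- labor_force
    if (!"lf_c" %in% names(lf)) lf <- center_labor_force(lf)
    key <- paste(d$domain, d$wave)
    lkey <- paste(lf$domain, lf$wave)
    idx <- match(key, lkey)
    if (anyNA(idx)) {
      m <- d[which(is.na(idx))[1], ]
      stop(sprintf("no labor-force rate for domain '%s', wave %s",
                   m$domain, m$wave), call. = FALSE)
    }
    d$lf_c <- lf$lf_c[idx]
  }
  if (!"lf_c" %in% names(d))
    stop("records need a centered labor-force column 'lf_c' (or pass labor_force)",
         call. = FALSE)
  tb <- time_basis(d$wave, spec$time_spec)
  for (j in seq_len(ncol(tb))) d[[colnames(tb)[j]]] <- tb[, j]
  d$domain <- factor(d$domain)
  d$wave_f <- factor(d$wave)
  d
}

#' Fixed-effects design matrix and random-effect grouping labels
#'
#' @param records respondent records with columns `domain`, `wave`, `sex`,
#'   `age_group`, `race_eth`, `ses`, and `lf_c` (or supply `labor_force`).
#' @param spec an `mrp_model_spec`.
#' @param labor_force optional domain-wave rate table (see
#'   [center_labor_force()]).
#' @return list with `X` (design matrix) and `groups` (named list of grouping
#'   factors, one per random intercept).
#' @export
design_matrix <- function(records, spec, labor_force = NULL) {
  d <- prepare_frame(records, spec, labor_force)
  X <- stats::model.matrix(fixed_formula(spec, response = NULL), d)
  groups <- list()
  for (g in spec$random_intercepts) {
    groups[[g]] <- switch(g,
      domain = d$domain,
      race_in_domain = interaction(d$domain, d$race_eth, drop = FALSE),
      wave = d$wave_f)
  }
  list(X = X, groups = groups)
}
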