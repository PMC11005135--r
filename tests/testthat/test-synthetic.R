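test_that("config validation names the offending field", {
  expect_error(truth_config(n_domains = 1), "n_domains")
  expect_error(truth_config(sigma_domain = -1), "sigma_domain")
  expect_error(truth_config(cell_population_range = c(10, 5)),
               "cell_population_range")
  expect_error(truth_config(sample_sizes = list(outcome = 10)), "sample_sizes")
})

test_that("population generation: counts, bounds, degenerate range", {
  cfg <- truth_config(n_domains = 3, n_waves = 2,
                      cell_population_range = c(100, 1000),
                      sample_sizes = list(outcome = 5, smoking = 5, gold = 5),
                      seed = 9)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 3 * 2 * 72)
  expect_true(all(pop$population >= 100 & pop$population <= 1000))
  expect_true(all(pop$population == round(pop$population)))

  cfg500 <- truth_config(cell_population_range = c(500, 500), seed = 9)
  expect_true(all(generate_population(cfg500)$population == 500))
})

test_that("generators are deterministic and byte-stable given the seed", {
  cfg <- truth_config(n_domains = 2, n_waves = 2,
                      sample_sizes = list(outcome = 50, smoking = 50, gold = 50),
                      seed = 123)
  w1 <- simulate_study(cfg)
  w2 <- simulate_study(cfg)
  expect_identical(w1, w2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_table(w1$outcome_survey, f1)
  write_table(w2$outcome_survey, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and the generator does not disturb the caller's RNG stream
  set.seed(77); a <- runif(1)
  set.seed(77); invisible(generate_population(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("outcome rates match the configured intercept", {
  # flat world: intercept logit(0.2), no other effects, sigma = 0
  cfg <- truth_config(n_domains = 2, n_waves = 2,
                      fixed_effects = c("(Intercept)" = qlogis(0.2)),
                      sigma_domain = 0,
                      sample_sizes = list(outcome = 2500, smoking = 10,
                                          gold = 10),
                      seed = 5)
  sv <- generate_outcome_survey(cfg)
  n <- nrow(sv)
  expect_equal(n, 2 * 2 * 2500)
  expect_lt(abs(mean(sv$y) - 0.2), 3 * sqrt(0.2 * 0.8 / n))

  # all-zero coefficients: rate ~ 0.5, smoking rate ~ 0.5 likewise
  cfg0 <- truth_config(n_domains = 2, n_waves = 2,
                       fixed_effects = c("(Intercept)" = 0), sigma_domain = 0,
                       smoking_model_coefs = c("(Intercept)" = 0),
                       sample_sizes = list(outcome = 2500, smoking = 2500,
                                           gold = 10),
                       seed = 6)
  expect_lt(abs(mean(generate_outcome_survey(cfg0)$y) - 0.5),
            3 * sqrt(0.25 / n))
  expect_lt(abs(mean(generate_smoking_survey(cfg0)$smoker) - 0.5),
            3 * sqrt(0.25 / n))
})

test_that("domain intercept offsets move domain rates in the right direction", {
  # sigma_domain large enough that realized domain effects differ
  cfg <- truth_config(n_domains = 2, n_waves = 2,
                      fixed_effects = c("(Intercept)" = 0), sigma_domain = 1,
                      sample_sizes = list(outcome = 2000, smoking = 10,
                                          gold = 10),
                      seed = 8)
  w <- simulate_study(cfg)
  u <- w$random_effects$u_domain
  rates <- tapply(w$outcome_survey$y, w$outcome_survey$domain, mean)
  expect_equal(sign(diff(rates[names(u)])), sign(diff(u)),
               ignore_attr = TRUE)
})

test_that("weights are positive with unit mean per domain-wave", {
  w <- world_small()
  sv <- w$outcome_survey
  expect_true(all(sv$weight > 0))
  means <- tapply(sv$weight, paste(sv$domain, sv$wave), mean)
  expect_close(means, 1, 1e-12)
})

test_that("education/income indicators reproduce the cell SES", {
  sv <- world_small()$outcome_survey
  expect_equal(as.character(derive_ses(sv$education_gt_hs,
                                       sv$income_ge_threshold)),
               as.character(sv$ses))
})

test_that("empirical cell rates converge to pi_true", {
  cfg <- truth_config(n_domains = 2, n_waves = 2,
                      sample_sizes = list(outcome = 150000, smoking = 10,
                                          gold = 10),
                      seed = 13)
  w <- simulate_study(cfg)
  sv <- w$outcome_survey
  k <- paste(sv$domain, sv$wave, sv$sex, sv$age_group, sv$race_eth, sv$ses)
  cnt <- tapply(sv$y, k, length)
  rate <- tapply(sv$y, k, mean)
  big <- names(cnt)[cnt >= 2500]  # binomial SE < 0.01
  expect_gt(length(big), 10)
  kt <- paste(w$truth$domain, w$truth$wave, w$truth$sex, w$truth$age_group,
              w$truth$race_eth, w$truth$ses)
  pi_true <- w$truth$pi_true[match(big, kt)]
  expect_true(all(abs(rate[big] - pi_true) < 3 * 0.01))
})

test_that("gold estimates land within 3 SEs of truth at large n", {
  cfg <- truth_config(n_domains = 2, n_waves = 2,
                      sample_sizes = list(outcome = 10, smoking = 10,
                                          gold = 8000),
                      seed = 14)
  gold <- generate_gold_survey(cfg)
  truth <- generate_truth(cfg)
  ov <- gold[gold$group == "overall", ]
  tr <- true_aggregates(truth)
  idx <- match(paste(ov$domain, ov$wave), paste(tr$domain, tr$wave))
  expect_true(all(abs(ov$p_gold - tr$p_true[idx]) <= 3 * sqrt(ov$v_gold)))
})

test_that("true_aggregates is the N_true-weighted mean", {
  truth <- data.frame(domain = "A", wave = 0,
                      sex = c("male", "female"), age_group = "50+",
                      race_eth = "nh_white", ses = "high",
                      pi_true = c(0.2, 0.4), N_true = c(100, 300))
  expect_equal(true_aggregates(truth)$p_true, 0.35)
  expect_equal(true_aggregates(truth, list(sex = "male"))$p_true, 0.2)
  # constant pi -> constant aggregate in every subgroup
  truth$pi_true <- 0.3
  expect_equal(true_aggregates(truth, list(sex = "female"))$p_true, 0.3)
  expect_error(true_aggregates(truth, list(sex = character(0))),
               "no cells")
  # grand-mean bookkeeping identity on a full world
  w <- world_small()
  agg <- true_aggregates(w$truth)
  grand <- sum(w$truth$N_true * w$truth$pi_true) / sum(w$truth$N_true)
  wt <- tapply(w$truth$N_true, paste(w$truth$domain, w$truth$wave), sum)
  wt <- wt[paste(agg$domain, agg$wave)]
  expect_equal(sum(agg$p_true * wt) / sum(wt), grand, tolerance = 1e-12)
})
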