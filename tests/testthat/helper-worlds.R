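# Lazily built, cached synthetic worlds shared across test files.
.world_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .world_cache)) assign(key, builder(), .world_cache)
  get(key, .world_cache)
}

# the workhorse world: 3 domains x 4 waves, moderate n
world_small <- function() cached("small", function() {
  cfg <- truth_config(n_domains = 3, n_waves = 4,
                      sample_sizes = list(outcome = 800, smoking = 1500,
                                          gold = 1500),
                      seed = 42)
  c(simulate_study(cfg), list(config = cfg))
})

# a fitted model + frame on the small world
world_small_fitted <- function() cached("small_fitted", function() {
  w <- world_small()
  spec <- default_model_specs(4)$model1
  fit <- fit_mrp_model(rescale_weights(w$outcome_survey), spec,
                       labor_force = w$labor_force)
  frame <- build_frame(w$smoking_survey, w$population)
  pred <- predict_cells(fit, unique(w$truth$domain),
                        sort(unique(w$truth$wave)), w$labor_force)
  list(world = w, spec = spec, fit = fit, frame = frame, pred = pred)
})

# large smoking survey for frame-construction consistency checks
world_frame_big <- function() cached("frame_big", function() {
  cfg <- truth_config(n_domains = 3, n_waves = 2,
                      sample_sizes = list(outcome = 10, smoking = 8000,
                                          gold = 10), seed = 77)
  simulate_study(cfg)
})

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) < tol),
              label = sprintf("max|diff| = %.3g", max(abs(object - expected))))
}
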