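stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  stage_log(stage, "done in %.1fs", proc.time()[["elapsed"]] - t0)
  res
}

#' Pipeline configuration
#'
#' @param input_dir directory holding the five input CSVs (`population.csv`,
#'   `outcome_survey.csv`, `smoking_survey.csv`, `gold.csv`, `truth.csv`,
#'   `labor_force.csv`); ignored in simulate mode.
#' @param out_dir output directory (created if needed).
#' @param truth a [truth_config()] to simulate inputs, or NULL to read them
#'   from `input_dir`.
#' @param specs list of candidate [model_spec()]s; defaults to the nine
#'   standard candidates sized to the data's wave count.
#' @param bootstrap a [bootstrap_config()] or NULL to skip intervals.
#' @param subgroups estimate the subgroup battery in addition to overall.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = tempfile("mrp_out_"),
                            truth = NULL, specs = NULL, bootstrap = NULL,
                            subgroups = TRUE) {
  if (is.null(truth)) {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop("run mode needs an existing input_dir", call. = FALSE)
  }
  structure(list(input_dir = input_dir, out_dir = out_dir, truth = truth,
                 specs = specs, bootstrap = bootstrap, subgroups = subgroups),
            class = "pipeline_config")
}

#' Run the full estimation pipeline
#'
#' Simulate (optional) -> fit the candidate models -> select by AIC/BIC ->
#' predict the 72 x domains x waves cell grid -> build the raked
#' post-stratification frame -> post-stratify overall and subgroup
#' prevalences -> bootstrap intervals (optional) -> validate against the
#' gold survey and, when truth is available, report recovery metrics.
#' Deterministic given the seeds in the configuration.
#'
#' @param config a [pipeline_config()].
#' @return list with `fits`, `selected`, `predictions`, `frame`,
#'   `estimates`, `agreement`, `recovery`; artifacts are also written to
#'   `config$out_dir` as CSV.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$truth)) {
    world <- run_stage("simulate", simulate_study(config$truth))
    inputs <- world[c("population", "labor_force", "truth", "outcome_survey",
                      "smoking_survey", "gold")]
    for (nm in names(inputs))
      write_table(inputs[[nm]], file.path(config$out_dir, paste0(nm, ".csv")))
  } else {
    inputs <- run_stage("read", {
      rd <- function(nm, schema) read_table(file.path(config$input_dir,
                                                      paste0(nm, ".csv")), schema)
      tr_path <- file.path(config$input_dir, "truth.csv")
      list(population = rd("population", "population"),
           labor_force = rd("labor_force", "labor_force"),
           outcome_survey = rd("outcome_survey", "outcome_survey"),
           smoking_survey = rd("smoking_survey", "smoking_survey"),
           gold = rd("gold", "gold"),
           truth = if (file.exists(tr_path)) read_table(tr_path, "truth") else NULL)
    })
  }

  waves <- sort(unique(inputs$outcome_survey$wave))
  domains <- sort(unique(inputs$outcome_survey$domain))
  specs <- config$specs
  if (is.null(specs)) specs <- default_model_specs(length(waves))

  records <- rescale_weights(inputs$outcome_survey)
  fits <- run_stage("fit", lapply(specs, function(s)
    fit_mrp_model(records, s, labor_force = inputs$labor_force)))
  for (f in fits) stage_log("fit", "%s: AIC %.2f BIC %.2f converged=%s",
                            f$spec$id, f$aic, f$bic, f$converged)
  selected <- run_stage("select", select_model(fits))
  stage_log("select", "selected %s", selected$spec$id)

  predictions <- run_stage("predict", predict_cells(selected, domains, waves,
                                                    inputs$labor_force))
  stage_log("predict", "%d cell predictions", nrow(predictions))
  write_table(predictions, file.path(config$out_dir, "cell_predictions.csv"))

  frame <- run_stage("frame", build_frame(inputs$smoking_survey,
                                          inputs$population))
  write_table(frame, file.path(config$out_dir, "frame.csv"))

  estimates <- run_stage("estimate", {
    if (config$subgroups) estimate_subgroups(predictions, frame)
    else poststratified_prevalence(predictions, frame, "overall")
  })

  if (!is.null(config$bootstrap)) {
    estimates <- run_stage("bootstrap", bootstrap_pipeline(
      inputs$outcome_survey, frame, selected$spec, inputs$labor_force,
      config$bootstrap, subgroups = config$subgroups, point_fit = selected))
  } else {
    estimates$ci_low <- NA_real_
    estimates$ci_high <- NA_real_
  }
  write_table(estimates, file.path(config$out_dir, "estimates.csv"))

  agreement <- run_stage("validate", agreement_report(estimates, inputs$gold))
  write_table(agreement, file.path(config$out_dir, "agreement.csv"))

  recovery <- NULL
  if (!is.null(inputs$truth)) {
    recovery <- run_stage("recovery", recovery_metrics(estimates, inputs$truth))
    write_table(recovery, file.path(config$out_dir, "recovery.csv"))
  }

  invisible(list(fits = fits, selected = selected, predictions = predictions,
                 frame = frame, estimates = estimates, agreement = agreement,
                 recovery = recovery, out_dir = config$out_dir))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write the synthetic inputs), `all` (full
#' pipeline). Arguments: `--config FILE` (JSON with fields `n_domains`,
#' `n_waves`, `sample_sizes`, `replicates`, ...), `--seed N`, `--out DIR`.
#'
#' @param args character vector (default: the process command line).
#' @return exit status, invisibly.
#' @export
mrp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: mrp-prev <simulate|all> [--config FILE] [--seed N] [--out DIR] [--replicates B]"
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(seed = 1L, out = "mrp_out", config = NULL, replicates = 0L)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args))
      stop("bad argument: ", args[i], "\n", usage, call. = FALSE)
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) jsonlite::read_json(opt$config,
                                                       simplifyVector = TRUE)
         else list()
  tc <- truth_config(
    n_domains = cfg$n_domains %||% 3, n_waves = cfg$n_waves %||% 5,
    sample_sizes = cfg$sample_sizes %||%
      list(outcome = 1000, smoking = 2000, gold = 2000),
    seed = as.integer(opt$seed))
  bs <- if (as.integer(opt$replicates) >= 2)
    bootstrap_config(as.integer(opt$replicates), seed = as.integer(opt$seed))
  if (cmd == "simulate") {
    world <- simulate_study(tc)
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("population", "labor_force", "truth", "outcome_survey",
                 "smoking_survey", "gold"))
      write_table(world[[nm]], file.path(opt$out, paste0(nm, ".csv")))
    message("wrote synthetic inputs to ", opt$out)
  } else if (cmd == "all") {
    run_pipeline(pipeline_config(out_dir = opt$out, truth = tc,
                                 bootstrap = bs))
    message("pipeline complete; outputs in ", opt$out)
  } else {
    stop("unknown subcommand: ", cmd, "\n", usage, call. = FALSE)
  }
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
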