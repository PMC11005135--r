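#' Column schemas of the pipeline's delimited-text tables
#'
#' Comma-separated, header row, UTF-8, empty field = missing.
#' @export
mrp_schemas <- list(
  population = c(domain = "character", wave = "numeric", sex = "character",
                 age_group = "character", race_eth = "character",
                 ses = "character", population = "numeric"),
  outcome_survey = c(domain = "character", wave = "numeric", sex = "character",
                     age_group = "character", race_eth = "character",
                     ses = "character", y = "numeric", weight = "numeric",
                     education_gt_hs = "logical",
                     income_ge_threshold = "logical"),
  smoking_survey = c(domain = "character", wave = "numeric", sex = "character",
                     age_group = "character", race_eth = "character",
                     ses = "character", smoker = "numeric", weight = "numeric",
                     education_gt_hs = "logical",
                     income_ge_threshold = "logical"),
  gold = c(domain = "character", wave = "numeric", group = "character",
           level = "character", n = "numeric", p_gold = "numeric",
           v_gold = "numeric"),
  truth = c(domain = "character", wave = "numeric", sex = "character",
            age_group = "character", race_eth = "character", ses = "character",
            pi_true = "numeric", p_smoke_true = "numeric", N_true = "numeric",
            population = "numeric"),
  labor_force = c(domain = "character", wave = "numeric", rate = "numeric",
                  lf_c = "numeric"),
  estimates = c(domain = "character", wave = "numeric", subgroup = "character",
                p_hat = "numeric", note = "character", ci_low = "numeric",
                ci_high = "numeric")
)

#' Write a pipeline table as CSV
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_table <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) if (is.factor(df[[j]])) df[[j]] <- as.character(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

#' Read a pipeline table, checking its schema
#'
#' @param path CSV path.
#' @param schema either a name in [mrp_schemas] or a named character vector
#'   of column classes.
#' @return typed data frame.
#' @export
read_table <- function(path, schema) {
  if (is.character(schema) && length(schema) == 1) {
    if (!schema %in% names(mrp_schemas))
      stop("unknown schema: ", schema, call. = FALSE)
    schema <- mrp_schemas[[schema]]
  }
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  missing <- setdiff(names(schema), hdr)
  extra <- setdiff(hdr, names(schema))
  if (length(missing) || length(extra))
    stop(sprintf("schema mismatch for %s: missing [%s], extra [%s]", path,
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")), call. = FALSE)
  utils::read.csv(path, colClasses = schema[hdr], na.strings = "",
                  fileEncoding = "UTF-8", check.names = FALSE)
}
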