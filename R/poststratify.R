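cell_key <- function(df) paste(df$domain, df$wave, df$sex, df$age_group,
                               df$race_eth, df$ses)

subgroup_filter <- function(df, subgroup) {
  sel <- rep(TRUE, nrow(df))
  if (!is.null(subgroup) && !identical(subgroup, "overall")) {
    stopifnot(is.list(subgroup))
    for (nm in names(subgroup)) {
      if (!nm %in% names(cell_levels))
        stop("unknown subgroup variable: ", nm, call. = FALSE)
      sel <- sel & df[[nm]] %in% subgroup[[nm]]
    }
  }
  sel
}

subgroup_label <- function(subgroup) {
  if (is.null(subgroup) || identical(subgroup, "overall")) return("overall")
  paste(sprintf("%s=%s", names(subgroup), unlist(subgroup)), collapse = ",")
}

#' Post-stratified prevalence per domain and wave
#'
#' The population-weighted average of the cell predictions over the cells in
#' the requested subgroup:
#' `p_hat = sum(N_j * pi_hat_j) / sum(N_j)`.
#' A subgroup with zero total N in a domain-wave has no support; its
#' estimate is `NA` with `note = "no_support"` (absence of people, not
#' absence of the behaviour).
#'
#' @param predictions cell predictions ([predict_cells()]): one row per
#'   (domain, wave, cell) with `pi_hat`.
#' @param frame raked frame ([build_frame()]): same grid with `N`.
#' @param subgroup `NULL`/"overall" or a named list such as
#'   `list(sex = "female")`.
#' @return data frame: domain, wave, subgroup, p_hat, note.
#' @export
poststratified_prevalence <- function(predictions, frame,
                                      subgroup = "overall") {
  kp <- cell_key(predictions)
  kf <- cell_key(frame)
  idx <- match(kp, kf)
  if (anyNA(idx) || length(kp) != length(kf))
    stop("prediction/frame grid mismatch; e.g. missing key: ",
         c(kp[is.na(idx)], setdiff(kf, kp))[1], call. = FALSE)
  df <- predictions
  df$N <- frame$N[idx]
  sel <- subgroup_filter(df, subgroup)
  if (!any(sel)) stop("subgroup filter selects no cells", call. = FALSE)
  df <- df[sel, ]
  num <- tapply(df$N * df$pi_hat, list(df$domain, df$wave), sum)
  den <- tapply(df$N, list(df$domain, df$wave), sum)
  out <- expand.grid(domain = rownames(num), wave = as.numeric(colnames(num)),
                     stringsAsFactors = FALSE)
  out$subgroup <- subgroup_label(subgroup)
  p <- as.vector(num) / as.vector(den)
  out$p_hat <- ifelse(as.vector(den) > 0, p, NA_real_)
  out$note <- ifelse(as.vector(den) > 0, "", "no_support")
  out <- out[order(out$domain, out$wave), ]
  rownames(out) <- NULL
  out
}

#' Standard subgroup battery: overall, by sex, by age group, by race/ethnicity
#'
#' @inheritParams poststratified_prevalence
#' @return long data frame of [poststratified_prevalence()] results, one row
#'   per (domain, wave, subgroup).
#' @export
estimate_subgroups <- function(predictions, frame) {
  subs <- c(list("overall"),
            unlist(lapply(c("sex", "age_group", "race_eth"), function(f)
              lapply(cell_levels[[f]], function(l)
                stats::setNames(list(l), f))), recursive = FALSE))
  res <- lapply(subs, function(s)
    poststratified_prevalence(predictions, frame, s))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
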