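#' Concordance correlation between two paired series
#'
#' Lin's concordance correlation coefficient (the two-rater reduction of the
#' overall CCC), computed with population (1/n) moment estimators:
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`.
#' It factors into a precision component (the Pearson correlation) and an
#' accuracy (bias-correction) component `ccc / r`.
#'
#' @param modeled,gold equal-length numeric vectors, n >= 3, finite.
#' @return list of class `concordance_result`: `occc`, `precision`,
#'   `accuracy`, `n_pairs`.
#' @export
concordance <- function(modeled, gold) {
  x <- as.numeric(modeled); y <- as.numeric(gold)
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("series must be finite", call. = FALSE)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 || sy2 == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  sxy <- mean((x - mx) * (y - my))
  occc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  structure(list(occc = occc, precision = r,
                 accuracy = if (r == 0) 1 else occc / r, n_pairs = n),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("oCCC %.3f (precision %.3f, accuracy %.3f, n = %d)\n",
              x$occc, x$precision, x$accuracy, x$n_pairs))
  invisible(x)
}

#' Agreement report between modeled and gold estimates
#'
#' Pairs modeled and gold prevalences on (domain, wave) within each subgroup
#' family and reports the concordance correlation plus the least-squares
#' line of modeled on gold. Groups with fewer than 3 pairs are skipped with
#' a warning.
#'
#' @param modeled estimates data frame: domain, wave, subgroup, p_hat
#'   (from [estimate_subgroups()]).
#' @param gold gold-survey table from [generate_gold_survey()] (columns
#'   domain, wave, group, level, p_gold), or any table with those columns.
#' @return data frame: group, n_pairs, occc, precision, accuracy, slope,
#'   intercept.
#' @export
agreement_report <- function(modeled, gold) {
  gold$subgroup <- ifelse(gold$group == "overall", "overall",
                          sprintf("%s=%s", gold$group, gold$level))
  out <- vector("list", 0L)
  for (g in unique(modeled$subgroup)) {
    m <- modeled[modeled$subgroup == g, ]
    gg <- gold[gold$subgroup == g, ]
    idx <- match(paste(m$domain, m$wave), paste(gg$domain, gg$wave))
    ok <- !is.na(idx) & is.finite(m$p_hat)
    if (sum(ok) < 3) {
      warning(sprintf("group '%s': fewer than 3 pairs, skipped", g),
              call. = FALSE)
      next
    }
    x <- m$p_hat[ok]
    y <- gg$p_gold[idx[ok]]
    cc <- concordance(x, y)
    ls <- stats::lm.fit(cbind(1, y), x)$coefficients
    out[[length(out) + 1L]] <- data.frame(
      group = g, n_pairs = cc$n_pairs, occc = cc$occc,
      precision = cc$precision, accuracy = cc$accuracy,
      slope = ls[2], intercept = ls[1])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recovery metrics of estimates against synthetic truth
#'
#' @param estimates estimates data frame (domain, wave, subgroup, p_hat,
#'   optional ci_low/ci_high).
#' @param truth a truth table from [generate_truth()].
#' @return data frame per subgroup: n, bias, rmse, coverage (NA when no
#'   intervals are present).
#' @export
recovery_metrics <- function(estimates, truth) {
  out <- vector("list", 0L)
  for (g in unique(estimates$subgroup)) {
    e <- estimates[estimates$subgroup == g, ]
    sub <- if (g == "overall") "overall" else {
      kv <- strsplit(g, "=", fixed = TRUE)[[1]]
      stats::setNames(list(kv[2]), kv[1])
    }
    tr <- true_aggregates(truth, sub)
    idx <- match(paste(e$domain, e$wave), paste(tr$domain, tr$wave))
    if (anyNA(idx))
      stop("missing truth row for ", paste(e$domain, e$wave)[is.na(idx)][1],
           call. = FALSE)
    err <- e$p_hat - tr$p_true[idx]
    cov <- if (all(c("ci_low", "ci_high") %in% names(e)))
      mean(e$ci_low <= tr$p_true[idx] & tr$p_true[idx] <= e$ci_high,
           na.rm = TRUE) else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      subgroup = g, n = sum(is.finite(err)),
      bias = mean(err, na.rm = TRUE),
      rmse = sqrt(mean(err^2, na.rm = TRUE)), coverage = cov)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
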