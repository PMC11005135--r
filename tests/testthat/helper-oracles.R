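# Independent oracles used to cross-check package code. These deliberately
# re-derive results from first principles and must not call the package
# functions they are checking.

# weighted logistic regression by plain iteratively-reweighted least squares
irls_logistic <- function(X, y, w, iter = 40) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    Wd <- w * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    beta <- solve(crossprod(X, Wd * X), crossprod(X, Wd * z))
  }
  drop(beta)
}

# brute-force iterative proportional fitting on a 2-d table
ipf_oracle_2d <- function(seed, row_margins, col_margins, iterations = 20) {
  x <- seed
  for (i in seq_len(iterations)) {
    x <- x * (row_margins / rowSums(x))
    x <- t(t(x) * (col_margins / colSums(x)))
  }
  x
}

# Lin concordance by direct spreadsheet-style evaluation (1/n moments)
ccc_direct <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}
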