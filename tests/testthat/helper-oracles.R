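# Independent brute-force oracles used to cross-check the package's
# statistics.  These deliberately avoid the code paths (and where possible
# the library routines) they verify.

oracle_odds_ratio <- function(a, b, c, d) (a * d) / (b * c)

oracle_chisq <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  sum((o - e)^2 / e)
}

# exact Mann-Whitney by enumeration of all labelings of the pooled data
oracle_mwu <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(i) u_of(pooled[i], pooled[-i]))
  lo <- mean(us <= u_obs)
  hi <- mean(us >= u_obs)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(lo, hi)),
              less = lo,
              greater = hi)
  list(U = u_obs, p = p)
}

# hand product-limit estimator; events precede censorings at tied times
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(event & time == ts[i])
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# two-group log-rank chi-square from first principles
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  ts <- sort(unique(time[event]))
  o <- e <- v <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & g1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# Newton-Raphson on the Breslow partial likelihood
oracle_cox <- function(time, event, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in 1:200) {
    w <- exp(drop(X %*% beta))
    grad <- rep(0, p)
    hess <- matrix(0, p, p)
    for (i in which(event)) {
      risk <- which(time >= time[i])
      wr <- w[risk]
      s0 <- sum(wr)
      xr <- X[risk, , drop = FALSE]
      xbar <- colSums(xr * wr) / s0
      grad <- grad + X[i, ] - xbar
      hess <- hess + crossprod(xr * sqrt(wr)) / s0 - tcrossprod(xbar)
    }
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# IRLS logistic regression from first principles (X includes intercept)
oracle_logistic <- function(X, y) {
  beta <- rep(0, ncol(X))
  for (it in 1:200) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(crossprod(X, w * X), crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < 1e-13) { beta <- beta_new; break }
    beta <- beta_new
  }
  beta
}

# order-statistic ranks for the distribution-free median CI, by direct
# enumeration of binomial tail coverage
oracle_median_ci_ranks <- function(n) {
  lower_tail <- cumsum(stats::dbinom(0:n, n, 0.5))
  l <- 0L
  for (k in seq_len(n)) {
    if (lower_tail[k] <= 0.025) l <- k else break  # P(Bin <= k-1)
  }
  l <- max(l, 1L)
  c(l, n - l + 1L)
}
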