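# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact two-sided Fisher p by hypergeometric enumeration over tables with
# the observed margins, summing probabilities <= the observed table's.
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive Benjamini-Hochberg step-up.
bh_naive <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Best within-cluster SSE over all 2-partitions of <= ~15 points.
best_sse_2partition <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- Inf
  best_assign <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    assign <- c(0, as.integer(intToBits(code))[seq_len(n - 1)])
    if (all(assign == assign[1])) next
    sse <- 0
    for (g in 0:1) {
      pts <- x[assign == g, , drop = FALSE]
      if (nrow(pts) == 0) { sse <- Inf; break }
      ctr <- colMeans(pts)
      sse <- sse + sum(sweep(pts, 2, ctr)^2)
    }
    if (sse < best) {
      best <- sse
      best_assign <- assign
    }
  }
  list(sse = best, assign = best_assign)
}

# Direct running-sum ssGSEA for one sample (Barbie-style weights rank^alpha).
ssgsea_oracle_one <- function(x, set_genes, alpha = 0.25) {
  r <- rank(x, ties.method = "first")
  ord <- order(r, decreasing = TRUE)
  ind <- names(x)[ord] %in% set_genes
  w <- r[ord]^alpha
  n <- length(x)
  es <- 0
  p_in <- 0
  p_out <- 0
  win_total <- sum(w * ind)
  for (i in seq_len(n)) {
    if (ind[i]) p_in <- p_in + w[i] / win_total else
      p_out <- p_out + 1 / (n - sum(ind))
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# Hand product-limit estimator.
km_oracle <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(et))
  for (i in seq_along(et)) {
    n_risk <- sum(time >= et[i])
    d <- sum(time == et[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  tibble::tibble(time = et, surv = out)
}

# Weighted O-E sums for a two-group weighted log-rank test.
wlr_oracle <- function(time, event, group, gehan = FALSE) {
  g <- as.integer(factor(group))
  et <- sort(unique(time[event == 1]))
  u <- 0
  v <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(at)
    if (n <= 1) next
    n1 <- sum(at & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    w <- if (gehan) n else 1
    u <- u + w * (d1 - d * n1 / n)
    v <- v + w^2 * d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- u^2 / v
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Closed-form OLS via normal equations.
ols_oracle <- function(x, y) {
  xm <- cbind(1, x)
  unname(solve(t(xm) %*% xm, t(xm) %*% y)[, 1])
}
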