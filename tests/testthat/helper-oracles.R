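# Independent brute-force oracles used to verify the package's
# implementations. These deliberately share no code with R/.

# MICA by exhaustive enumeration of all common ancestors.
oracle_mica_ic <- function(t1, t2, ic_vec, dag) {
  anc <- function(t) {
    out <- t
    repeat {
      new <- unique(unlist(dag$parents[out]))
      new <- setdiff(new, out)
      if (length(new) == 0L) break
      out <- c(out, new)
    }
    out
  }
  common <- intersect(anc(t1), anc(t2))
  max(ic_vec[common])
}

oracle_lin <- function(t1, t2, ic_vec, dag) {
  denom <- ic_vec[[t1]] + ic_vec[[t2]]
  if (denom == 0) return(if (t1 == t2) 1 else 0)
  2 * oracle_mica_ic(t1, t2, ic_vec, dag) / denom
}

# BMA by naive double loop.
oracle_bma <- function(m) {
  total <- 0
  for (i in seq_len(nrow(m))) total <- total + max(m[i, ])
  for (j in seq_len(ncol(m))) total <- total + max(m[, j])
  total / (nrow(m) + ncol(m))
}

# Hypergeometric upper tail P(X >= k) by exhaustive pmf summation.
oracle_hyper_tail <- function(k, n, K, M) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(M - K, n - ks)) / choose(M, n)
}

# AUC as the Mann-Whitney U statistic with half credit for ties.
oracle_auc <- function(pos, neg) {
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Two-group log-rank chi-square by explicit event-table tabulation.
oracle_logrank <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == 1L)
    n <- sum(at_risk)
    d1 <- sum(time == t & event == 1 & group == 1L)
    d <- sum(time == t & event == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1L)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Kaplan-Meier product-limit estimate by direct multiplication.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    out[i] <- s
  }
  data.frame(time = ts, survival = out)
}

# Spearman rank correlation from the rank formula with mid-ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# small fixture shared by several tests: perfect binary tree on 7 terms
tree7 <- function() make_dag(7, branching = 2)
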