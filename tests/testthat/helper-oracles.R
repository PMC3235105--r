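# Independent oracle implementations used only by the tests. Each is a
# deliberately naive, brute-force computation kept separate from the package
# code paths it checks.

# Benjamini-Hochberg step-up, literal double loop over the definition:
# adj_(i) = min over j >= i of n * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    vals <- numeric(0)
    for (j in i:n) vals <- c(vals, n / j * sorted[j])
    adj_sorted[i] <- min(1, min(vals))
  }
  out <- numeric(n)
  out[ord] <- adj_sorted
  out
}

# Hypergeometric upper tail P(X >= k) by direct summation of the pmf.
hyper_oracle <- function(k, m, K, N) {
  js <- k:min(m, K)
  sum(choose(K, js) * choose(N - K, m - js)) / choose(N, m)
}

# Tukey median polish written from the sweep definition, independent of
# stats::medpolish. Returns overall + column effects (the gene summary).
medpolish_oracle <- function(x, max_iter = 10L, tol = 1e-6) {
  row_eff <- numeric(nrow(x)); col_eff <- numeric(ncol(x)); overall <- 0
  res <- x
  for (iter in seq_len(max_iter)) {
    rmed <- apply(res, 1, median)
    res <- res - rmed
    row_eff <- row_eff + rmed
    shift <- median(row_eff)
    row_eff <- row_eff - shift
    overall <- overall + shift
    cmed <- apply(res, 2, median)
    res <- sweep(res, 2, cmed)
    col_eff <- col_eff + cmed
    shift <- median(col_eff)
    col_eff <- col_eff - shift
    overall <- overall + shift
    if (max(abs(apply(res, 1, median))) < tol &&
        max(abs(apply(res, 2, median))) < tol) break
  }
  list(summary = overall + col_eff, residuals = res)
}

# Exact two-sided Wilcoxon rank-sum p-value by enumerating every subset of
# positions for the x-sample (midranks for ties), using recursion rather
# than utils::combn so the code path differs from the implementation.
wilcox_oracle <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  sums <- c()
  recurse <- function(start, left, acc) {
    if (left == 0) {
      sums <<- c(sums, acc)
      return(invisible())
    }
    for (i in start:(n - left + 1)) recurse(i + 1, left - 1, acc + ranks[i])
  }
  recurse(1, nx, 0)
  mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-12)
}

# Grid-plus-bisection inverse trigamma, independent of uniroot.
trigamma_inverse_oracle <- function(x) {
  lo <- 1e-6; hi <- 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > x) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}
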