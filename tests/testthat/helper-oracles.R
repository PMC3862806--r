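# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# direct, loop-based evaluation of the moderated d-statistic
oracle_d <- function(vals, idx1, idx2, s0 = 0) {
  n1 <- length(idx1); n2 <- length(idx2)
  out <- matrix(NA_real_, nrow(vals), 3,
                dimnames = list(rownames(vals), c("r", "s", "d")))
  for (i in seq_len(nrow(vals))) {
    x1 <- vals[i, idx1]; x2 <- vals[i, idx2]
    r <- mean(x1) - mean(x2)
    pooled <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
    s <- sqrt((1 / n1 + 1 / n2) * pooled)
    out[i, ] <- c(r, s, r / (s + s0))
  }
  out
}

# independent grid search for the fudge factor: same definition, different code
oracle_s0 <- function(r, s, percentiles = seq(0, 100, by = 5), nw = 100) {
  cand <- quantile(s, percentiles / 100, names = FALSE)
  nw <- max(2, min(nw, floor(length(s) / 5)))
  win <- cut(rank(s, ties.method = "first"), breaks = nw, labels = FALSE)
  cvs <- sapply(cand, function(s0) {
    d <- r / (s + s0)
    m <- sapply(split(d, win), mad)
    sd(m) / mean(m)
  })
  list(s0 = cand[which.min(cvs)], percentile = percentiles[which.min(cvs)],
       cv = cvs)
}

# exact upper-tail hypergeometric probability by enumeration of all query
# draws from a small universe
oracle_hyper_tail <- function(k, m, N, n) {
  draws <- combn(N, n)
  members <- seq_len(m)  # WLOG the first m universe elements form the group
  hits <- apply(draws, 2, function(q) sum(q %in% members))
  mean(hits >= k)
}

# plain null matrix with iid normal genes, outside the synthio generator
null_matrix <- function(n_genes, n1, n2, seed, sd = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * (n1 + n2), 0, sd), n_genes, n1 + n2)
  rownames(v) <- sprintf("g%04d", seq_len(n_genes))
  colnames(v) <- c(sprintf("a%02d", seq_len(n1)), sprintf("b%02d", seq_len(n2)))
  expression_matrix(v)
}

null_groups <- function(n1, n2) {
  setNames(rep(c("A", "B"), c(n1, n2)),
           c(sprintf("a%02d", seq_len(n1)), sprintf("b%02d", seq_len(n2))))
}
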