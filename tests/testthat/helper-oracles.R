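# Independent oracles used across the suite.

# Brute-force ACMG rule evaluator, data-driven: each rule is a vector of
# minimum evidence counts; a category fires when any of its rules is
# satisfied elementwise. Operates on raw counts, independent of the token
# parsing and boolean logic inside combine_criteria().
oracle_acmg_class <- function(vs = 0, s = 0, m = 0, p = 0,
                              ba = 0, bs = 0, bp = 0) {
  counts <- c(vs = vs, s = s, m = m, p = p, ba = ba, bs = bs, bp = bp)
  satisfied <- function(rules) {
    any(vapply(rules, function(r) {
      need <- counts; need[] <- 0; need[names(r)] <- r
      all(counts >= need)
    }, logical(1)))
  }
  path5 <- list(c(vs = 1, s = 1), c(vs = 1, m = 2), c(vs = 1, m = 1, p = 1),
                c(vs = 1, p = 2), c(s = 2), c(s = 1, m = 3),
                c(s = 1, m = 2, p = 2), c(s = 1, m = 1, p = 4))
  path4 <- list(c(vs = 1, m = 1), c(s = 1, m = 1), c(s = 1, p = 2),
                c(m = 3), c(m = 2, p = 2), c(m = 1, p = 4))
  ben1 <- list(c(ba = 1), c(bs = 2))
  ben2 <- list(c(bs = 1, bp = 1), c(bp = 2))
  p_hit <- satisfied(path5) || satisfied(path4)
  b_hit <- satisfied(ben1) || satisfied(ben2)
  if (p_hit && b_hit) return(3L)
  if (satisfied(path5)) return(5L)
  if (satisfied(path4)) return(4L)
  if (satisfied(ben1)) return(1L)
  if (satisfied(ben2)) return(2L)
  3L
}

# Map evidence counts to distinct criterion tokens for combine_criteria().
tokens_for_counts <- function(s = 0, m = 0, p = 0, bs = 0, bp = 0) {
  c(if (s) paste0("PS", seq_len(s)),
    if (m) paste0("PM", seq_len(m)),
    if (p) paste0("PP", seq_len(p)),
    if (bs) paste0("BS", seq_len(bs)),
    if (bp) paste0("BP", seq_len(bp)))
}

# All multisets of total size <= n drawn from the five atom types
# {pathogenic strong/moderate/supporting, benign strong/supporting}.
atom_multisets <- function(n = 4) {
  grid <- expand.grid(s = 0:n, m = 0:n, p = 0:n, bs = 0:n, bp = 0:n)
  grid[rowSums(grid) <= n, , drop = FALSE]
}

# Textbook pooled-variance two-sample t-test p-value (two-tailed), written
# from the formula rather than via stats::t.test.
oracle_pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# Textbook Welch t-test p-value, one-tailed for mean(x) > mean(y).
oracle_welch_t_p_greater <- function(x, y) {
  nx <- length(x); ny <- length(y)
  se2 <- var(x) / nx + var(y) / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / nx)^2 / (nx - 1) + (var(y) / ny)^2 / (ny - 1))
  pt(tstat, df = df, lower.tail = FALSE)
}
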