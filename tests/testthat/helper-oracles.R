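# Independent oracles, implemented from first principles so they share no
# code path with the package functions they check.

# Two-sided Fisher exact p for a 2x2 table (a b / c d): enumerate the
# hypergeometric distribution over the feasible cell range with explicit
# binomial coefficients and sum the probabilities of tables at most as
# probable as the observed one.
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; N <- r1 + r2
  if (N == 0) return(1)
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-sided hypergeometric over-representation tail P(X >= k) by summation.
oracle_hyper_tail <- function(k, set_size, universe, list_size) {
  xs <- k:min(set_size, list_size)
  sum(choose(set_size, xs) * choose(universe - set_size, list_size - xs) /
        choose(universe, list_size))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (no ties assumed).
oracle_mannwhitney <- function(x, y) {
  ranks <- rank(c(x, y))
  nx <- length(x)
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(ranks), nx)
  us <- apply(combos, 2L, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# Codon-by-codon translation oracle: first stop at/after cds_start (0-based),
# via Biostrings::translate of the trimmed frame.
oracle_first_stop <- function(seq, cds_start) {
  n_codons <- (nchar(seq) - cds_start) %/% 3L
  if (n_codons < 1L) return(NA_integer_)
  frame <- substr(seq, cds_start + 1L, cds_start + 3L * n_codons)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(frame)))
  hit <- regexpr("*", aa, fixed = TRUE)
  if (hit < 0L) return(NA_integer_)
  as.integer(cds_start + 3L * (hit - 1L))
}
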