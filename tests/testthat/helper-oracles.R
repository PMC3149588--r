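# Independent brute-force oracles used to check the analytic routines.

# P(X >= k) by exhaustive enumeration of all C(N, n) draws from a population
# of N genes of which the first K are annotated.
hyper_enum_oracle <- function(k, N, K, n) {
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  annotated <- colSums(draws <= K)
  mean(annotated >= k)
}

# One-sided WMW p-value by full enumeration of group-label assignments:
# for every subset of size n_test of the pooled values, the U statistic is
# recomputed by direct pair counting (test > ref, ties at half weight).
wmw_enum_oracle <- function(test_values, ref_values) {
  x <- c(test_values, ref_values)
  nt <- length(test_values)
  N <- length(x)
  gt <- outer(x, x, ">") + 0.5 * outer(x, x, "==")
  u_obs <- sum(gt[seq_len(nt), -seq_len(nt), drop = FALSE])
  subsets <- utils::combn(N, nt)
  u_all <- apply(subsets, 2, function(s) sum(gt[s, -s, drop = FALSE]))
  mean(u_all >= u_obs - 1e-9)
}

# Benjamini-Hochberg step-up rejection set computed directly from the
# definition: reject the i smallest p-values where i is the largest rank
# with p_(i) <= i * alpha / m.
bh_stepup_reject <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(below)) reject[ord[seq_len(max(below))]] <- TRUE
  reject
}

# Tiny universe with fixed exon lengths for boundary fixtures.
make_tiny_universe <- function(lengths = c(1000, 3100, 3101, 9000)) {
  gene_universe(sprintf("g%d", seq_along(lengths)), lengths)
}

write_tsv_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
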