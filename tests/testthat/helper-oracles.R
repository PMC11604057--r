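# Independent brute-force oracle for the masked Jaccard distance: per pair,
# build the 2x2 contingency table over jointly covered loci.
jaccard_brute <- function(m_t, p_t, m_q, p_q) {
  d <- matrix(1, nrow(m_t), nrow(m_q))
  for (i in seq_len(nrow(m_t))) {
    for (j in seq_len(nrow(m_q))) {
      cov <- p_t[i, ] == 1 & p_q[j, ] == 1
      a <- sum(cov & m_t[i, ] == 1 & m_q[j, ] == 1)
      b <- sum(cov & m_t[i, ] == 0 & m_q[j, ] == 1)
      cc <- sum(cov & m_t[i, ] == 1 & m_q[j, ] == 0)
      if (a + b + cc > 0) d[i, j] <- 1 - a / (a + b + cc)
    }
  }
  d
}

# Random binary masks with m <= p.
random_masks <- function(n_rows, n_snps, p_cov = 0.5, p_alt = 0.5) {
  p <- matrix(rbinom(n_rows * n_snps, 1, p_cov), n_rows)
  m <- p * matrix(rbinom(n_rows * n_snps, 1, p_alt), n_rows)
  list(m = m, p = p)
}

# Drop the shared/flagged attributes jaccard_missing attaches, leaving a
# bare numeric matrix for comparisons.
as_plain <- function(d) matrix(as.numeric(d), nrow(d), ncol(d))

# Small snp_calls builder with auto-generated labels.
make_snp <- function(mat) {
  snp_call_matrix(mat, paste0("bc", seq_len(nrow(mat))),
                  paste0("s", seq_len(ncol(mat))))
}

# Union rule spelled out case by case, independent of the pmax trick.
merge_rule <- function(a, b) {
  if (a == 2 || b == 2) return(2L)
  if (a == 1 || b == 1) return(1L)
  0L
}
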