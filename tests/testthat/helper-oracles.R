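# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# all compositions of n into s positive parts, one per row
compositions <- function(n, s) {
  if (s == 1) return(matrix(n, 1, 1))
  do.call(rbind, lapply(seq_len(n - s + 1), function(k) {
    cbind(k, compositions(n - k, s - 1))
  }))
}

# Brillouin diversity straight from lgamma, no package code
brillouin_oracle <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  (lgamma(n + 1) - sum(lgamma(counts + 1))) / n
}

# a seeded random count vector with N <= n_max, S <= s_max
random_counts <- function(n_max = 200, s_max = 20) {
  s <- sample(s_max, 1)
  n <- sample(seq(s, n_max), 1)
  as.integer(tabulate(sample(s, n - s, replace = TRUE), nbins = s) + 1L)
}

# plant a point mutation at position i (to a different base)
mutate_at <- function(seq, i, to = NULL) {
  chars <- strsplit(seq, "")[[1]]
  if (is.null(to)) to <- setdiff(c("A", "C", "G", "T"), chars[i])[1]
  chars[i] <- to
  paste(chars, collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

study_counts_list <- function() {
  m <- copediv::study_count_matrix()
  lapply(setNames(seq_len(ncol(m)), colnames(m)), function(j) {
    v <- m[, j]
    as.integer(v[v > 0])
  })
}
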