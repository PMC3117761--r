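# Brute-force NODF oracle: literal pairwise definition with explicit loops,
# kept deliberately independent of the package's vectorised implementation.
nodf_bruteforce <- function(m) {
  b <- (m > 0) * 1
  b <- b[rowSums(b) > 0, colSums(b) > 0, drop = FALSE]
  paired <- function(rich, poor) {
    fill_rich <- sum(rich)
    fill_poor <- sum(poor)
    if (fill_rich == fill_poor || fill_poor == 0) return(0)
    if (fill_poor > fill_rich) return(paired(poor, rich))
    100 * sum(rich == 1 & poor == 1) / fill_poor
  }
  total <- 0
  for (i in seq_len(nrow(b) - 1)) {
    for (j in (i + 1):nrow(b)) total <- total + paired(b[i, ], b[j, ])
  }
  for (i in seq_len(ncol(b) - 1)) {
    for (j in (i + 1):ncol(b)) total <- total + paired(b[, i], b[, j])
  }
  n_pairs <- nrow(b) * (nrow(b) - 1) / 2 + ncol(b) * (ncol(b) - 1) / 2
  total / n_pairs
}

# random binary matrix with no empty rows or columns
random_binary_matrix <- function(nr, nc, p = 0.3) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1, p), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# perfectly nested stepped matrix: row i covers the first (n - i + 1) columns
stepped_matrix <- function(n) {
  m <- matrix(0, n, n)
  for (i in seq_len(n)) m[i, seq_len(n - i + 1)] <- 1
  m
}
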