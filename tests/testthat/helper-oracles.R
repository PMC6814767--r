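# Independent brute-force oracles used to check the implementation paths.

# textbook dynamic-programming Levenshtein distance
lev_dp <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  d <- matrix(0L, m + 1L, n + 1L)
  d[, 1] <- 0:m
  d[1, ] <- 0:n
  if (m && n) {
    for (i in 1:m) for (j in 1:n) {
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                               d[i, j] + as.integer(A[i] != B[j]))
    }
  }
  d[m + 1L, n + 1L]
}

# brute-force centered window means of rescaled residue values
window_means_bf <- function(seq, w, scale = "FaucherePliska") {
  v <- phasekit::scale_values(scale)[strsplit(seq, "")[[1]]]
  n <- length(v) - w + 1L
  vapply(seq_len(n), function(i) mean(v[i:(i + w - 1L)]), numeric(1))
}

# draw a random sequence over an alphabet
rand_seq <- function(len, alphabet = c("A", "C", "G", "S")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# filled disk mask helper for synthetic image tests
draw_disk <- function(img, r0, c0, radius, value) {
  idx <- (row(img) - r0)^2 + (col(img) - c0)^2 <= radius^2
  img[idx] <- value
  img
}
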