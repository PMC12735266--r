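# Independent brute-force oracles used across the suite.

# Naive per-pixel clipped window sum (double loop).
naive_box_sum <- function(m, r) {
  p <- (r - 1) %/% 2
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    rs <- max(1, i - p):min(H, i + p)
    cs <- max(1, j - p):min(W, j + p)
    out[i, j] <- sum(m[rs, cs])
  }
  out
}

# A tiny scene pair used by several modules: 5x5 map with one centered
# target, 3x3 kernel.
toy_delta <- function() {
  p <- matrix(0, 5, 5); p[3, 3] <- 1
  p
}

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
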