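# Independent oracles shared across test files.

# Brute-force anti-image oracle: partial correlation of (i, j) given all
# other variables, via explicit regression on the remaining variables --
# independent of the matrix-inverse shortcut used by kmo().
partial_cor_oracle <- function(R, i, j) {
  rest <- setdiff(seq_len(ncol(R)), c(i, j))
  if (length(rest) == 0) return(R[i, j])
  Rr <- R[rest, rest, drop = FALSE]
  bi <- solve(Rr, R[rest, i])
  bj <- solve(Rr, R[rest, j])
  num <- R[i, j] - sum(R[i, rest] * bj)
  di <- 1 - sum(R[i, rest] * bi)
  dj <- 1 - sum(R[j, rest] * bj)
  num / sqrt(di * dj)
}

kmo_oracle <- function(R) {
  p <- ncol(R)
  r2 <- 0; q2 <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    r2 <- r2 + R[i, j]^2
    q2 <- q2 + partial_cor_oracle(R, i, j)^2
  }
  r2 / (r2 + q2)
}

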