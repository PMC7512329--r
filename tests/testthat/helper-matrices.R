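# small fixture builders shared across test files

im <- function(..., nrow) {
  incidence_matrix(matrix(c(...), nrow = nrow, byrow = TRUE))
}

# staircase-nested matrix: row i holds links in columns 1..(M - i + 1)
staircase <- function(N, M) {
  b <- matrix(0L, N, M)
  for (i in seq_len(N)) b[i, seq_len(max(1L, M - i + 1L))] <- 1L
  incidence_matrix(b)
}

# independent straight-line reimplementation of the unexpectedness sum:
# classify every cell against the isocline, measure d by dense sampling
# along the slope -1 probe line, and add the (d/D)^2 terms by hand
brute_unexpectedness <- function(m, r, n_probe = 2e5) {
  N <- nrow(m); M <- ncol(m)
  iso <- solve_isocline(N, M, sum(m) / (N * M))
  ranked <- reorder(m, r)
  total <- 0
  for (i in seq_len(N)) {
    for (a in seq_len(M)) {
      x <- (a - 0.5) / M
      y <- (N - i + 0.5) / N
      f_here <- isocline_value(iso, x)
      expected_filled <- y >= f_here - 1e-9
      if (xor(ranked[i, a] == 1L, expected_filled)) {
        s <- x + y
        u <- seq(0, min(1, s), length.out = n_probe)
        gap <- abs(isocline_value(iso, u) - (s - u))
        u_star <- u[which.min(gap)]
        d <- sqrt(2) * abs(x - u_star)
        D <- sqrt(2) * s
        total <- total + (d / D)^2
      }
    }
  }
  total / (N * M)
}
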