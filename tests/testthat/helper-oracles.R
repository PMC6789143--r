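# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (dist(), explicit loops) so they cannot share a code
# path with the kernels they check.

# O(N^2) correlation sum via stats::dist, counting d <= r for each edge.
naive_corr_C <- function(X, edges) {
  d <- as.vector(stats::dist(X))
  vapply(edges, function(r) sum(d <= r), numeric(1)) / length(d)
}

naive_variogram <- function(S, tau_max) {
  N <- length(S)
  vapply(seq_len(tau_max), function(tt) {
    acc <- 0
    for (i in seq_len(N - tt)) acc <- acc + (S[i + tt] - S[i])^2
    acc / (2 * (N - tt))
  }, numeric(1))
}

# Band-limited random texture on which macroblocks are uniquely matchable.
textured_frame <- function(nr = 96, nc = 96, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  cardiodyn:::gaussian_blur_fft(m, sigma = 2)
}

# Circular shift of a matrix by (dy, dx); content moves down/right.
circshift <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

# AR(1) series with coefficient phi.
ar1 <- function(n, phi, seed) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n))
}

gauss_pulse_test <- function(t, center, amp, sigma)
  amp * exp(-(t - center)^2 / (2 * sigma^2))

# Exact integer pair counts (cumulative per edge) via an explicit pair loop.
# The squared distance is accumulated coordinate by coordinate in double
# precision (not via sum(), which uses extended precision) so that pairs
# sitting exactly on an edge bin identically to any double-precision
# implementation of the same formula.
naive_corr_count_exact <- function(X, edges) {
  n <- nrow(X); m <- ncol(X)
  counts <- numeric(length(edges))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- 0
      for (k in seq_len(m)) {
        dd <- X[i, k] - X[j, k]
        d2 <- d2 + dd * dd
      }
      counts <- counts + as.numeric(sqrt(d2) <= edges)
    }
  }
  counts
}
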