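#' Phase-space delay from the autocorrelation function
#'
#' Selects the delay tau for phase-space reconstruction as the first integer
#' lag at which the (biased, mean-removed) autocorrelation falls to 1/e of
#' its zero-lag value, modelling the ACF envelope as `C(tau) = C(0) e^(-k tau)`
#' with decay rate `k = 1/tau*`. No interpolation: the data are discrete.
#'
#' @param S numeric series or [motion_waveform()] (non-constant, N >= 16).
#' @return Object of class `acf_lag`: `C` (autocovariance from lag 0 up to
#'   at least the selected lag), `C0`, `tau_star` (samples), `k`, and
#'   `not_reached` (TRUE when the ACF never falls to `C0/e` within N/2 lags;
#'   `tau_star` is then N/2).
#' @examples
#' a <- acf_lag(sin(2 * pi * (1:4000) / 100))
#' a$tau_star  # ~ 0.188 * 100: where cos(2 pi tau / T) crosses 1/e
#' @export
acf_lag <- function(S) {
  if (inherits(S, "motion_waveform")) S <- S$S
  S <- as.numeric(S)
  N <- length(S)
  if (N < 16) stop("acf_lag needs at least 16 samples")
  if (stats::sd(S) == 0) stop("acf_lag is undefined for a constant signal")
  lag_max <- floor(N / 2)
  # stats::acf costs O(N * lag.max); search the 1/e crossing in doubling
  # windows instead of computing all N/2 lags up front
  lm <- min(64L, lag_max)
  repeat {
    C <- as.vector(stats::acf(S, lag.max = lm, type = "covariance",
                              demean = TRUE, plot = FALSE)$acf)
    C0 <- C[1]
    below <- which(C[-1] <= C0 / exp(1))
    if (length(below) || lm == lag_max) break
    lm <- min(2L * lm, lag_max)
  }
  not_reached <- length(below) == 0L
  tau_star <- if (not_reached) lag_max else below[1]
  if (not_reached)
    warning("ACF never fell to C(0)/e within N/2 lags; tau_star set to N/2")
  structure(list(C = C, C0 = C0, tau_star = as.integer(tau_star),
                 k = 1 / tau_star, not_reached = not_reached),
            class = "acf_lag")
}

#' @export
print.acf_lag <- function(x, ...) {
  cat(sprintf("<acf_lag> tau* = %d samples (k = %.4f)%s\n", x$tau_star, x$k,
              if (x$not_reached) " [1/e not reached]" else ""))
  invisible(x)
}

#' Takens delay embedding
#'
#' Builds the trajectory matrix whose row j is
#' `(S_j, S_{j+tau}, ..., S_{j+(m-1)tau})`, j = 1..N-(m-1)tau.
#'
#' @param S numeric series or [motion_waveform()].
#' @param m embedding dimension (>= 1).
#' @param tau delay in samples (>= 1).
#' @return Numeric matrix of class `embedding` with `N - (m-1) tau` rows and
#'   `m` columns; attributes `m` and `tau`.
#' @examples
#' embed_series(1:5, m = 2, tau = 1)
#' @export
embed_series <- function(S, m, tau) {
  if (inherits(S, "motion_waveform")) S <- S$S
  S <- as.numeric(S)
  N <- length(S)
  m <- as.integer(m); tau <- as.integer(tau)
  if (m < 1 || tau < 1) stop("'m' and 'tau' must be positive integers")
  n <- N - (m - 1) * tau
  if (n < 1)
    stop(sprintf("series too short: need N >= %d for m = %d, tau = %d",
                 (m - 1) * tau + 1, m, tau))
  X <- vapply(0:(m - 1), function(k) S[(1 + k * tau):(n + k * tau)],
              numeric(n))
  X <- matrix(X, nrow = n, ncol = m) # vapply drops dims when n = 1
  structure(X, m = m, tau = tau, class = c("embedding", "matrix", "array"))
}

#' Embedding dimension by false nearest neighbours
#'
#' Kennel-style FNN: for each m, every point's nearest neighbour in the
#' m-dimensional embedding is lifted to m+1 dimensions; the pair is "false"
#' when the extra coordinate moves it apart disproportionately
#' (`|extra| / R_m > rtol`) or the lifted distance is large relative to the
#' attractor size (`R_{m+1} / sd(S) > atol`, the criterion that keeps pure
#' noise from ever qualifying). The selected m is the smallest with a false
#' fraction below `fnn_frac_threshold`.
#'
#' @param S numeric series or [motion_waveform()].
#' @param tau delay in samples.
#' @param m_max largest dimension tried.
#' @param rtol distance-ratio threshold.
#' @param atol attractor-size threshold (in units of sd(S)).
#' @param fnn_frac_threshold acceptable false-neighbour fraction.
#' @return Integer m with attributes `fractions` (per m = 1..m_max) and
#'   `saturated` (TRUE when no m qualified and m_max was returned, e.g. for
#'   stochastic signals, which have no finite embedding).
#' @export
fnn_embedding_dim <- function(S, tau, m_max = 12L, rtol = 15, atol = 2,
                              fnn_frac_threshold = 0.01) {
  if (inherits(S, "motion_waveform")) S <- S$S
  S <- as.numeric(S)
  tau <- as.integer(tau); m_max <- as.integer(m_max)
  if (tau < 1) stop("'tau' must be >= 1")
  if (m_max < 2) stop("'m_max' must be >= 2")
  frac <- cpp_fnn_fractions(S, tau, m_max, rtol, atol)
  ok <- which(!is.na(frac) & frac < fnn_frac_threshold)
  saturated <- length(ok) == 0L
  m <- if (saturated) m_max else ok[1]
  if (saturated)
    warning("no m <= m_max reached the FNN threshold; returning m_max ",
            "(signal may be stochastic)")
  structure(as.integer(m), fractions = frac, saturated = saturated)
}
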