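#' Correlation integral of an embedded trajectory
#'
#' Grassberger-Procaccia correlation sum: for each of 32 bin edges r_n,
#' `C_m(r_n) = 2/(N'(N'-1)) * #\{(i, j), i > j : ||x_i - x_j|| <= r_n\}`,
#' with N' embedded points. Edges are uniform in log distance between the
#' smallest nonzero and the largest pairwise distance (default), or uniform
#' in distance with `log_bins = FALSE`. By construction the last edge has
#' `C_m = 1`.
#'
#' The log-span of the edges is floored at 4 decades
#' (`r_min >= 1e-4 r_max`): (near-)periodic signals produce numerically
#' duplicated embedded points whose ~1e-16 spacings would otherwise waste
#' most bins below the real geometry of the trajectory.
#'
#' @param X an [embed_series()] result (or any numeric matrix of points,
#'   >= 32 rows, not all identical).
#' @param bins number of bin edges.
#' @param log_bins logical; log-uniform (default) or linear-uniform edges.
#' @param min_span_decades resolution floor for the log span.
#' @return Object of class `correlation_integral`: `r` (edges), `C`
#'   (correlation sums in `[0, 1]`, non-decreasing), `counts` (cumulative
#'   pair counts), `n_points`, `n_pairs`, `log_bins`.
#' @export
correlation_integral <- function(X, bins = 32L, log_bins = TRUE,
                                 min_span_decades = 4) {
  X <- unclass(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 32) stop("correlation_integral needs at least 32 points")
  mm <- cpp_pair_minmax(X)
  r_min <- mm[1]; r_max <- mm[2]
  if (r_max <= 0) stop("degenerate input: all points identical")
  if (r_min <= 0) r_min <- r_max * 10^(-min_span_decades)
  r_min <- max(r_min, r_max * 10^(-min_span_decades))
  edges <- if (log_bins) {
    exp(seq(log(r_min), log(r_max), length.out = bins))
  } else {
    seq(r_min, r_max, length.out = bins)
  }
  # pin the endpoints: exp(log(r_max)) can round below r_max, silently
  # dropping the extremal pair from the last bin
  edges[1] <- r_min
  edges[bins] <- r_max
  counts <- cpp_pair_counts(X, edges)
  n_pairs <- n * (n - 1) / 2
  structure(list(r = edges, C = counts / n_pairs, counts = counts,
                 n_points = n, n_pairs = n_pairs, log_bins = log_bins),
            class = "correlation_integral")
}

# Scaling-region selection: among all contiguous windows of >= min_len bins
# with nonzero correlation sums, take the one maximizing the R^2 of the
# log C vs log r straight-line fit; ties (iteration order) resolve toward
# smaller r, then shorter windows. Saturated stretches (constant C) have
# zero variance and are skipped.
fit_scaling_region <- function(ci, min_len = 8L, window = NULL) {
  lr <- log(ci$r); lC <- suppressWarnings(log(ci$C))
  nb <- length(ci$r)
  if (!is.null(window)) {
    i <- window[1]:window[2]
    f <- stats::lm.fit(cbind(1, lr[i]), lC[i])
    ss <- sum((lC[i] - mean(lC[i]))^2)
    return(list(window = c(window[1], window[2]),
                slope = unname(f$coefficients[2]),
                intercept = unname(f$coefficients[1]),
                r_squared = if (ss > 0) 1 - sum(f$residuals^2) / ss else NA))
  }
  best <- NULL; best_r2 <- -Inf
  for (a in seq_len(nb - min_len + 1)) {
    if (ci$C[a] <= 0) next
    for (b in (a + min_len - 1):nb) {
      i <- a:b
      if (any(ci$C[i] <= 0)) break
      ss <- sum((lC[i] - mean(lC[i]))^2)
      if (ss < 1e-20) next
      f <- stats::lm.fit(cbind(1, lr[i]), lC[i])
      r2 <- 1 - sum(f$residuals^2) / ss
      if (is.finite(r2) && r2 > best_r2 + 1e-12) {
        best_r2 <- r2
        best <- list(window = c(a, b), slope = unname(f$coefficients[2]),
                     intercept = unname(f$coefficients[1]), r_squared = r2)
      }
    }
  }
  best
}

#' Correlation dimension by the Grassberger-Procaccia method
#'
#' For each embedding dimension m the series is delay-embedded
#' ([embed_series()]), its correlation integral computed
#' ([correlation_integral()]), and `D_correlation(m)` estimated as the slope
#' of `log C_m(r)` vs `log r` over an automatically selected scaling region
#' (the contiguous window of at least `min_region_len` bins with the best
#' straight-line fit; override with `fit_window`). The plateau of
#' `D_correlation(m)` over m is the steady correlation dimension
#' ([steady_value()]): saturation indicates deterministic dynamics, while for
#' stochastic signals D grows with m without bound and no plateau exists.
#'
#' @param S numeric series or [motion_waveform()].
#' @param tau delay in samples, or `"auto"` ([acf_lag()]).
#' @param m_values embedding dimensions to try.
#' @param bins,log_bins passed to [correlation_integral()].
#' @param min_region_len minimum scaling-region length in bins.
#' @param fit_window optional fixed bin window `c(first, last)` for all m.
#' @param theiler temporal exclusion window in samples: pairs closer in time
#'   are left out of the correlation sum. Default 0 (all i > j pairs, the
#'   classical form); set e.g. `tau` for methodological comparison.
#' @return Object of class `correlation_result`: `m_values`, `tau`,
#'   `integrals` (per-m `correlation_integral`), `slopes` (`D_correlation(m)`),
#'   `regions` (per-m bin windows), `r_squared`, `D_steady`, `plateau`
#'   (logical), `failed_m` (dimensions dropped with a warning).
#' @examples
#' S <- sin(2 * pi * (1:1500) / 83)
#' cr <- correlation_dimension(S, tau = "auto", m_values = 2:5)
#' round(cr$D_steady, 1)  # ~1: a limit cycle is one-dimensional
#' @export
correlation_dimension <- function(S, tau = "auto", m_values = 2:12,
                                  bins = 32L, log_bins = TRUE,
                                  min_region_len = 8L, fit_window = NULL,
                                  theiler = 0L) {
  if (inherits(S, "motion_waveform")) S <- S$S
  S <- as.numeric(S)
  if (identical(tau, "auto")) tau <- acf_lag(S)$tau_star
  tau <- as.integer(tau)
  slopes <- rep(NA_real_, length(m_values))
  r2 <- rep(NA_real_, length(m_values))
  regions <- vector("list", length(m_values))
  integrals <- vector("list", length(m_values))
  failed <- integer(0)
  for (i in seq_along(m_values)) {
    m <- m_values[i]
    res <- tryCatch({
      X <- embed_series(S, m = m, tau = tau)
      if (theiler > 0) {
        ci <- correlation_integral_theiler(X, bins = bins,
                                           log_bins = log_bins,
                                           theiler = theiler)
      } else {
        ci <- correlation_integral(X, bins = bins, log_bins = log_bins)
      }
      fit <- fit_scaling_region(ci, min_len = min_region_len,
                                window = fit_window)
      if (is.null(fit)) stop("no scaling region found")
      list(ci = ci, fit = fit)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("m = %d dropped: %s", m, conditionMessage(res)))
      failed <- c(failed, m)
      next
    }
    integrals[[i]] <- res$ci
    slopes[i] <- res$fit$slope
    r2[i] <- res$fit$r_squared
    regions[[i]] <- res$fit$window
  }
  ok <- !is.na(slopes)
  st <- if (sum(ok) >= 3) {
    steady_value(slopes[ok])
  } else { # too few dimensions for a plateau
    list(value = if (any(ok)) slopes[max(which(ok))] else NA_real_,
         plateau = FALSE)
  }
  structure(list(m_values = m_values, tau = tau, integrals = integrals,
                 slopes = slopes, regions = regions, r_squared = r2,
                 D_steady = st$value, plateau = st$plateau,
                 failed_m = failed,
                 params = list(bins = bins, log_bins = log_bins,
                               min_region_len = min_region_len,
                               theiler = theiler)),
            class = "correlation_result")
}

# Theiler-window variant computed in R (reference path for methodological
# comparison; the default pipeline uses the all-pairs C++ kernel).
correlation_integral_theiler <- function(X, bins = 32L, log_bins = TRUE,
                                         theiler = 0L,
                                         min_span_decades = 4) {
  X <- unclass(X)
  n <- nrow(X)
  if (n < 32) stop("correlation_integral needs at least 32 points")
  d <- as.matrix(stats::dist(X))
  keep <- abs(row(d) - col(d)) > theiler & upper.tri(d)
  dv <- d[keep]
  if (!length(dv) || max(dv) <= 0) stop("degenerate input after exclusion")
  r_max <- max(dv)
  r_min <- max(min(dv[dv > 0], r_max), r_max * 10^(-min_span_decades))
  edges <- if (log_bins) exp(seq(log(r_min), log(r_max), length.out = bins))
           else seq(r_min, r_max, length.out = bins)
  counts <- vapply(edges, function(r) sum(dv <= r), numeric(1))
  structure(list(r = edges, C = counts / length(dv), counts = counts,
                 n_points = n, n_pairs = length(dv), log_bins = log_bins),
            class = "correlation_integral")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> tau = %d, m = %s\n", x$tau,
              paste(range(x$m_values), collapse = "-")))
  cat("  D(m):", paste(sprintf("%.2f", x$slopes), collapse = " "), "\n")
  cat(sprintf("  D_steady = %.3f (plateau: %s)\n", x$D_steady, x$plateau))
  invisible(x)
}

#' @export
plot.correlation_result <- function(x, which = c("D", "C"), ...) {
  which <- match.arg(which)
  if (which == "D") {
    graphics::plot(x$m_values, x$slopes, type = "b", xlab = "m",
                   ylab = "D_correlation(m)", ...)
    if (x$plateau) graphics::abline(h = x$D_steady, lty = 2, col = 2)
  } else {
    ok <- which(!vapply(x$integrals, is.null, logical(1)))
    graphics::plot(NA, xlim = range(log(x$integrals[[ok[1]]]$r)),
                   ylim = c(min(vapply(x$integrals[ok], function(ci)
                     min(log(ci$C[ci$C > 0])), numeric(1))), 0),
                   xlab = "log r", ylab = "log C_m(r)", ...)
    for (i in ok)
      graphics::lines(log(x$integrals[[i]]$r), log(x$integrals[[i]]$C),
                      col = i)
  }
  invisible(x)
}

#' Steady (plateau) value of the correlation-dimension curve
#'
#' The steady correlation dimension is the mean of `D(m)` over the largest
#' contiguous run of embedding dimensions where successive values differ by
#' less than `tol`. When no such run exists (e.g. stochastic signals, where
#' D(m) keeps growing), the plateau flag is `FALSE` and the last D is
#' returned as the value.
#'
#' @param D_of_m numeric vector of `D(m)` (>= 3 values).
#' @param tol plateau tolerance on successive differences.
#' @return List: `value`, `plateau` (logical), `run` (indices used).
#' @export
steady_value <- function(D_of_m, tol = 0.1) {
  D <- as.numeric(D_of_m)
  if (length(D) < 3) stop("steady_value needs at least 3 D(m) values")
  dd <- abs(diff(D))
  r <- rle(dd < tol)
  if (!any(r$values))
    return(list(value = D[length(D)], plateau = FALSE, run = length(D)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  i <- which(r$values)
  j <- i[which.max(r$lengths[i])]
  run <- starts[j]:(ends[j] + 1) # a run of k small diffs spans k+1 values
  list(value = mean(D[run]), plateau = TRUE, run = run)
}
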