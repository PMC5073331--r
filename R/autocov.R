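#' Autocovariance of a single spike train
#'
#' The train is binned at `bin` seconds into counts `x_n`; for each lag
#' `tau = k * bin` (with `0 < |tau| < max_lag`) the autocovariance is the
#' sum of `(x_n - mu)(x_{n+k} - mu)` over the overlapping part of the
#' recording, divided by the recording length adjusted by the absolute lag,
#' `T - |tau|`.  The zero-lag bin is excluded.  The computation exploits the
#' sparsity of spike trains: the raw product sum at lag k equals the number
#' of spike pairs exactly k bins apart (a pairwise-lag histogram) and the
#' mean-correction terms follow from cumulative spike counts, so no dense
#' count vector is formed.
#'
#' @param train numeric vector of sorted spike times (seconds).
#' @param duration recording length in seconds.
#' @param max_lag maximum absolute lag in seconds (default 2).
#' @param bin lag bin width in seconds (default 0.001; well inside the 5 ms
#'   smoothing scale applied afterwards).
#'
#' @return list of class `autocov_result`: `lags` (symmetric, zero
#'   excluded), `values`, `bin`, `duration`, `half_width` (`NA` until
#'   [autocov_half_width()] is applied), `smoothed` flag.
#' @export
spike_autocov <- function(train, duration, max_lag = 2, bin = 0.001) {
  if (length(train) == 0) stop("empty spike train")
  stopifnot(bin > 0, max_lag > bin, duration > 0)
  n_bins <- as.integer(ceiling(duration / bin))
  b <- sort(pmin(as.integer(floor(train / bin)), n_bins - 1L))  # 0-based
  K <- as.integer(round(max_lag / bin)) - 1L       # lags strictly < max_lag
  n <- length(b)
  mu <- n / n_bins

  P <- as.numeric(pair_lag_counts(b, K))
  k <- seq_len(K)
  ## spikes in the first k bins (bins 0..k-1) and last k bins
  first_k <- findInterval(k - 0.5, b)              # count of b <= k-1
  last_k <- n - findInterval(n_bins - k - 0.5, b)  # count of b >= n_bins-k
  S1 <- n - last_k                                 # sum over n = 1..N-k
  S2 <- n - first_k                                # sum over n = k+1..N
  A <- P - mu * (S1 + S2) + (n_bins - k) * mu^2
  vals <- A / (duration - k * bin)

  structure(list(lags = c(-rev(k), k) * bin,
                 values = c(rev(vals), vals),
                 bin = bin, duration = duration, max_lag = max_lag,
                 smoothed = FALSE, half_width = NA_real_),
            class = "autocov_result")
}

#' @export
print.autocov_result <- function(x, ...) {
  cat("<autocov_result> lags in (", -x$max_lag, ", ", x$max_lag,
      ") s, bin = ", x$bin, " s",
      if (x$smoothed) ", smoothed", sep = "")
  if (!is.na(x$half_width))
    cat(", half-width = ", signif(x$half_width, 4), " s", sep = "")
  cat("\n")
  invisible(x)
}

#' Moving-average smoothing across lags
#'
#' Centered moving average of `window` seconds (default 5 ms) applied
#' across the lag axis; edge bins use the partial window.  The small gap at
#' the excluded zero lag is treated as contiguous.
#'
#' @param result an `autocov_result`.
#' @param window smoothing window in seconds.
#' @return smoothed `autocov_result`.
#' @export
smooth_autocov <- function(result, window = 0.005) {
  stopifnot(inherits(result, "autocov_result"), result$bin <= window)
  w <- max(1L, round(window / result$bin))
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  v <- result$values
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  result$values <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  result$smoothed <- TRUE
  result
}

#' Half-width of the autocovariance peak
#'
#' Full width at half maximum around the global peak: finds the maximum of
#' the curve over lags, then the first crossings below half that maximum
#' walking outward from the peak in both directions (linear interpolation
#' between lag bins).  When the curve never drops below half maximum within
#' the lag range, the full range (`2 * max_lag`) is returned with a
#' `saturated` attribute.
#'
#' @param result an `autocov_result` (normally smoothed first).
#' @return half-width in seconds (attribute `saturated` when the crossings
#'   lie outside the lag range); errors when the curve has no positive
#'   peak.
#' @export
autocov_half_width <- function(result) {
  stopifnot(inherits(result, "autocov_result"))
  v <- result$values
  lag <- result$lags
  pk <- which.max(v)
  if (v[pk] <= 0) stop("autocovariance has no positive peak")
  half <- v[pk] / 2

  cross_out <- function(dir) {
    ix <- if (dir > 0) seq(pk, length(v)) else seq(pk, 1)
    below <- which(v[ix] < half)
    if (length(below) == 0) return(NA_real_)
    j <- ix[below[1]]; jprev <- j - dir
    ## interpolate between the last point >= half and the first below
    lag[jprev] + (lag[j] - lag[jprev]) *
      (v[jprev] - half) / (v[jprev] - v[j])
  }
  right <- cross_out(+1)
  left <- cross_out(-1)
  sat <- is.na(right) || is.na(left)
  if (is.na(right)) right <- lag[length(lag)]
  if (is.na(left)) left <- lag[1]
  hw <- right - left
  attr(hw, "saturated") <- sat
  hw
}

#' Network autocovariance
#'
#' Computes the autocovariance per active electrode, smooths each curve
#' (5 ms moving average), averages the curves over electrodes, normalizes
#' the averaged curve so its peak equals 1, and extracts the half-width.
#' Electrodes with fewer than `min_spikes` spikes are skipped.
#'
#' @param spikes active-electrode [spike_train_set()].
#' @param max_lag,bin as in [spike_autocov()].
#' @param smooth_window moving-average width in seconds.
#' @param min_spikes minimum spikes per electrode to enter the average.
#' @return an `autocov_result` with peak value 1, `half_width` filled in,
#'   and the per-electrode smoothed curves in `$per_electrode` (matrix,
#'   lags x electrodes).
#' @export
network_autocov <- function(spikes, max_lag = 2, bin = 0.001,
                            smooth_window = 0.005, min_spikes = 2) {
  stopifnot(inherits(spikes, "spike_train_set"))
  use <- names(spikes$trains)[lengths(spikes$trains) >= min_spikes]
  if (length(use) == 0) stop("no active electrodes with enough spikes")
  curves <- vapply(use, function(id) {
    r <- spike_autocov(spikes$trains[[id]], spikes$duration, max_lag, bin)
    smooth_autocov(r, smooth_window)$values
  }, numeric(2L * (round(max_lag / bin) - 1L)))
  tmpl <- spike_autocov(spikes$trains[[use[1]]], spikes$duration,
                        max_lag, bin)
  avg <- rowMeans(curves)
  pk <- max(avg)
  if (pk <= 0) stop("network autocovariance has no positive peak")
  res <- structure(list(lags = tmpl$lags, values = avg / pk, bin = bin,
                        duration = spikes$duration, max_lag = max_lag,
                        smoothed = TRUE, half_width = NA_real_,
                        per_electrode = curves),
                   class = "autocov_result")
  res$half_width <- as.numeric(autocov_half_width(res))
  res
}
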