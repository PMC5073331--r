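#' Coefficient of variation of a set of intervals
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' The CV is dimensionless and invariant to uniform time rescaling.
#'
#' @param intervals numeric vector of intervals (seconds).
#' @return CV, or `NA` when fewer than 2 intervals are available.
#' @export
interval_cv <- function(intervals) {
  intervals <- intervals[!is.na(intervals)]
  if (length(intervals) < 2) return(NA_real_)
  m <- mean(intervals)
  if (m <= 0) stop("interval mean must be positive")
  sd(intervals) / m
}

#' CV of the interspike intervals, averaged over electrodes
#'
#' Computes the ISI CV per active electrode (electrodes with fewer than
#' 3 spikes, i.e. fewer than 2 ISIs, are skipped) and averages across
#' electrodes.
#'
#' @param spikes active-electrode [spike_train_set()].
#' @return network CV_ISI, or `NA` when no electrode has enough spikes.
#' @export
cv_isi <- function(spikes) {
  stopifnot(inherits(spikes, "spike_train_set"))
  cvs <- vapply(spikes$trains,
                function(t) if (length(t) >= 3) interval_cv(diff(t))
                            else NA_real_,
                numeric(1))
  if (all(is.na(cvs))) NA_real_ else mean(cvs, na.rm = TRUE)
}

#' Fano factor of windowed spike counts
#'
#' Spike counts are taken in sliding windows of `window` seconds advanced
#' by `step` seconds; the Fano factor of one electrode is the variance of
#' the counts divided by their mean, and the network value is the average
#' over active electrodes.  Electrodes with no spikes are excluded (their
#' mean count is zero, leaving the ratio undefined).  A Poisson train gives
#' FF near 1; a perfectly periodic train whose period divides the window
#' gives exactly 0.  Overlapping windows correlate neighbouring counts,
#' which widens the sampling variability of the estimate but not its
#' expectation.
#'
#' @param spikes active-electrode [spike_train_set()].
#' @param window window length in seconds (default 5).
#' @param step window slide in seconds (default 1).
#' @return network Fano factor (`NA` when no electrode has spikes).
#' @export
fano_factor <- function(spikes, window = 5, step = 1) {
  stopifnot(inherits(spikes, "spike_train_set"),
            spikes$duration >= window)
  starts <- seq(0, spikes$duration - window, by = step)
  ffs <- vapply(spikes$trains, function(t) {
    if (length(t) == 0) return(NA_real_)
    counts <- findInterval(starts + window, t) - findInterval(starts, t)
    m <- mean(counts)
    if (m == 0) return(NA_real_)
    var(counts) / m
  }, numeric(1))
  if (all(is.na(ffs))) NA_real_ else mean(ffs, na.rm = TRUE)
}

#' Rate-independent burst-irregularity metric (IR)
#'
#' Mean absolute natural-log ratio of consecutive interburst intervals:
#' `IR = 1/(N-1) * sum_i |ln(IBI[i+1] / IBI[i])|`.  Exactly 0 for periodic
#' bursting, invariant to multiplying all IBIs by a constant (hence
#' independent of the burst rate), and converging to `2 ln 2 ~ 1.386` for
#' i.i.d. exponential IBIs (the log-ratio of two i.i.d. exponentials is
#' standard logistic, whose mean absolute value is `2 ln 2`).
#'
#' @param ibis numeric vector of interburst intervals (seconds), all > 0.
#' @return IR, or `NA` when fewer than 2 IBIs are available.
#' @export
ir_metric <- function(ibis) {
  ibis <- ibis[!is.na(ibis)]
  if (length(ibis) < 2) return(NA_real_)
  if (any(ibis <= 0)) stop("all IBIs must be positive")
  mean(abs(diff(log(ibis))))
}

#' CV of the interburst intervals
#'
#' @param bursts a [burst_train()] (or a numeric vector of IBIs).
#' @return CV of the IBIs; `NA` with fewer than 3 bursts (2 IBIs).
#' @export
cv_ibi <- function(bursts) {
  ibis <- if (inherits(bursts, "burst_train")) bursts$ibis else bursts
  interval_cv(ibis)
}
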