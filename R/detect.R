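#' Spike-detection parameters
#'
#' Defaults follow the standard MEA preprocessing chain: 300 Hz 6th-order
#' Butterworth high-pass, per-channel offset correction, and a peak-to-peak
#' threshold `theta = f * median(|signal|) * multiplier` with gain factor
#' `f = 8` and multiplier 1.5.  The peak-to-peak window and dead time are
#' not dictated by the threshold formula; the defaults (1 ms window, 2 ms
#' dead time) match typical extracellular spike widths.
#'
#' @param highpass_cutoff high-pass cutoff in Hz.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective attenuation is doubled and the phase is zero).
#' @param gain_factor the gain factor `f` in the threshold formula.
#' @param threshold_multiplier the final multiplier (1.5).
#' @param peak_window width of the sliding peak-to-peak window (seconds).
#' @param dead_time minimum separation between detected spikes (seconds);
#'   closer detections are merged.
#' @param offset_operand what to subtract per channel for offset correction:
#'   `"median"` (centers the signal at zero) or `"median_abs"` (median of
#'   the absolute value; retained as an alternative convention).
#'
#' @return list of class `detection_params`.
#' @export
detection_params <- function(highpass_cutoff = 300, filter_order = 6,
                             gain_factor = 8, threshold_multiplier = 1.5,
                             peak_window = 0.001, dead_time = 0.002,
                             offset_operand = c("median", "median_abs")) {
  offset_operand <- match.arg(offset_operand)
  stopifnot(highpass_cutoff > 0, filter_order >= 1, gain_factor > 0,
            threshold_multiplier > 0, peak_window > 0, dead_time >= 0)
  structure(list(highpass_cutoff = highpass_cutoff,
                 filter_order = filter_order,
                 gain_factor = gain_factor,
                 threshold_multiplier = threshold_multiplier,
                 peak_window = peak_window, dead_time = dead_time,
                 offset_operand = offset_operand),
            class = "detection_params")
}

#' High-pass filter a raw recording
#'
#' Zero-phase (forward-backward) Butterworth high-pass per channel.
#' Zero-phase application avoids biasing spike times by the filter group
#' delay.
#'
#' @param rec a [raw_recording()].
#' @param params a [detection_params()].
#' @return filtered [raw_recording()].
#' @export
highpass_filter <- function(rec, params = detection_params()) {
  stopifnot(inherits(rec, "raw_recording"))
  nyq <- rec$sampling_rate / 2
  if (params$highpass_cutoff >= nyq)
    stop("high-pass cutoff must be below the Nyquist frequency (",
         nyq, " Hz)")
  bf <- signal::butter(params$filter_order,
                       params$highpass_cutoff / nyq, type = "high")
  v <- rec$voltage
  for (i in seq_len(nrow(v)))
    v[i, ] <- signal::filtfilt(bf, v[i, ])
  out <- raw_recording(v, rec$sampling_rate, rec$channel_ids)
  attr(out, "planted_spikes") <- attr(rec, "planted_spikes")
  out
}

#' Offset-correct a raw recording
#'
#' Subtracts, per channel, the median of the signal so each channel is
#' centered at zero.  The alternative operand `"median_abs"` subtracts the
#' median of the absolute value instead (does not center a symmetric
#' signal; kept as a switch because both conventions occur in MEA
#' pipelines).
#'
#' @param rec a [raw_recording()].
#' @param operand `"median"` or `"median_abs"`.
#' @return corrected [raw_recording()].
#' @export
offset_correct <- function(rec, operand = c("median", "median_abs")) {
  stopifnot(inherits(rec, "raw_recording"), nrow(rec$voltage) > 0)
  operand <- match.arg(operand)
  v <- rec$voltage
  off <- apply(v, 1, function(x)
    if (operand == "median") median(x) else median(abs(x)))
  v <- v - off
  out <- raw_recording(v, rec$sampling_rate, rec$channel_ids)
  attr(out, "planted_spikes") <- attr(rec, "planted_spikes")
  out
}

#' Peak-to-peak spike-detection threshold
#'
#' `theta = f * median(|signal|) * multiplier`, computed on the filtered,
#' offset-corrected channel.  For Gaussian noise `median(|x|) = 0.6745 sd`,
#' so with the defaults the threshold sits at about `8.1 sd` of the noise.
#'
#' @param channel_signal numeric vector (one channel, microvolts).
#' @param params a [detection_params()].
#' @return threshold in microvolts; attribute `dead_channel` is `TRUE` for
#'   an all-zero channel (threshold 0).
#' @export
compute_threshold <- function(channel_signal, params = detection_params()) {
  m <- median(abs(channel_signal))
  th <- params$gain_factor * m * params$threshold_multiplier
  attr(th, "dead_channel") <- (m == 0)
  th
}

## sliding peak-to-peak excursion: p2p[i] = max - min over x[i .. i+k-1]
rolling_p2p <- function(x, k) {
  if (k <= 1) return(rep(0, length(x)))
  mx <- zoo::rollmax(x, k, align = "left")
  mn <- -zoo::rollmax(-x, k, align = "left")
  mx - mn
}

#' Detect spikes from a raw recording
#'
#' Per channel: computes the peak-to-peak excursion in a sliding window of
#' `peak_window` seconds; wherever it exceeds the channel threshold a spike
#' is registered at the time of the negative peak; detections closer than
#' `dead_time` are merged into one.  The recording should already be
#' filtered and offset-corrected (see [highpass_filter()],
#' [offset_correct()]); [detect_spikes_pipeline()] chains all three.
#'
#' @param rec filtered, offset-corrected [raw_recording()].
#' @param params a [detection_params()].
#' @return a [spike_train_set()]; per-channel thresholds in
#'   `attr(, "thresholds")`.
#' @export
detect_spikes <- function(rec, params = detection_params()) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sampling_rate
  k <- max(2L, round(params$peak_window * fs))
  dead <- round(params$dead_time * fs)
  trains <- list()
  thresholds <- numeric(nrow(rec$voltage))
  for (i in seq_len(nrow(rec$voltage))) {
    x <- rec$voltage[i, ]
    th <- compute_threshold(x, params)
    thresholds[i] <- th
    if (isTRUE(attr(th, "dead_channel")) || length(x) < k) {
      trains[[rec$channel_ids[i]]] <- numeric(0)
      next
    }
    p2p <- rolling_p2p(x, k)
    cand <- which(p2p > th)           # window start indices
    if (length(cand) == 0) {
      trains[[rec$channel_ids[i]]] <- numeric(0)
      next
    }
    ## merge candidate windows whose starts are within dead_time
    grp <- cumsum(c(1L, diff(cand) > max(dead, k)))
    times <- vapply(split(cand, grp), function(ix) {
      lo <- ix[1]
      hi <- min(ix[length(ix)] + k - 1L, length(x))
      seg <- lo:hi
      (seg[which.min(x[seg])] - 1L) / fs   # time of the negative peak
    }, numeric(1))
    trains[[rec$channel_ids[i]]] <- unname(sort(times))
  }
  sts <- spike_train_set(trains, rec$duration)
  attr(sts, "thresholds") <- thresholds
  sts
}

#' Full spike-detection chain
#'
#' Convenience wrapper: high-pass filter, offset correction, threshold
#' detection.
#'
#' @inheritParams detect_spikes
#' @return a [spike_train_set()].
#' @export
detect_spikes_pipeline <- function(rec, params = detection_params()) {
  detect_spikes(offset_correct(highpass_filter(rec, params),
                               params$offset_operand), params)
}

#' Select active electrodes
#'
#' Keeps electrodes with firing rate strictly above `min_rate` (the
#' standard >0.1 spike/s activity criterion) and at most `max_rate`
#' (noisy channels with implausibly high rates are discarded).
#'
#' @param spikes a [spike_train_set()].
#' @param min_rate Hz; electrodes at or below this rate are dropped.
#' @param max_rate Hz; electrodes above this rate are dropped as noisy.
#' @return filtered [spike_train_set()]; dropped electrodes and the reason
#'   in `attr(, "dropped")`.
#' @export
select_active <- function(spikes, min_rate = 0.1, max_rate = 100) {
  stopifnot(inherits(spikes, "spike_train_set"))
  r <- firing_rates(spikes)
  keep <- r > min_rate & r <= max_rate
  dropped <- data.frame(electrode = names(r)[!keep],
                        rate = unname(r[!keep]),
                        reason = ifelse(r[!keep] <= min_rate,
                                        "inactive", "noisy"),
                        stringsAsFactors = FALSE)
  if (!any(keep))
    stop("no active electrodes left (", sum(r <= min_rate), " inactive, ",
         sum(r > max_rate), " noisy of ", length(r), ")")
  out <- spikes
  out$trains <- spikes$trains[keep]
  attr(out, "dropped") <- dropped
  out
}
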