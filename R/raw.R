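#' Biphasic extracellular spike template
#'
#' Negative-first biphasic waveform (sharp negativity followed by a slower
#' positive rebound), normalized so its minimum equals -1.  Total support is
#' about 1.6 ms, typical of an extracellular action potential.
#'
#' @param sampling_rate Hz.
#' @return list with `shape` (numeric vector) and `peak_index` (index of the
#'   negative peak within the template).
#' @keywords internal
spike_template <- function(sampling_rate) {
  t <- seq(0, 0.0016, by = 1 / sampling_rate)
  w <- -exp(-(t - 3e-4)^2 / (2 * (1e-4)^2)) +
    0.45 * exp(-(t - 8e-4)^2 / (2 * (2e-4)^2))
  w <- w / abs(min(w))
  list(shape = w, peak_index = which.min(w))
}

#' Render a spike-train set as a raw multichannel voltage recording
#'
#' Each spike is drawn as a biphasic template whose negative peak is placed
#' at the spike time, scaled to `waveform_amplitude`, on top of zero-mean
#' Gaussian noise and an optional DC offset.  Spikes that overlap within the
#' template width on the same channel add linearly.  Used to exercise the
#' spike-detection stage against planted ground truth.
#'
#' @param spikes a [spike_train_set()].
#' @param waveform_amplitude negative-peak amplitude in microvolts.
#' @param noise_sd Gaussian noise standard deviation in microvolts.
#' @param sampling_rate Hz (default 10000, the acquisition rate).
#' @param dc_offset constant offset added to every sample (microvolts).
#' @param seed optional seed for the noise.
#'
#' @return a [raw_recording()]; the input spike times are preserved in
#'   `attr(, "planted_spikes")`.
#' @export
synthesize_raw <- function(spikes, waveform_amplitude = 50, noise_sd = 2,
                           sampling_rate = 10000, dc_offset = 0,
                           seed = NULL) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_samp <- round(spikes$duration * sampling_rate)
  ne <- length(spikes$trains)
  tmpl <- spike_template(sampling_rate)
  w <- tmpl$shape * waveform_amplitude
  lw <- length(w)
  v <- matrix(if (noise_sd > 0) rnorm(ne * n_samp, 0, noise_sd) else 0,
              nrow = ne, ncol = n_samp)
  v <- v + dc_offset
  for (i in seq_len(ne)) {
    for (tt in spikes$trains[[i]]) {
      c0 <- round(tt * sampling_rate) + 1L           # sample of the neg peak
      i0 <- c0 - tmpl$peak_index + 1L
      sel <- seq.int(i0, i0 + lw - 1L)
      keep <- sel >= 1L & sel <= n_samp
      v[i, sel[keep]] <- v[i, sel[keep]] + w[keep]
    }
  }
  rec <- raw_recording(v, sampling_rate,
                       channel_ids = names(spikes$trains))
  attr(rec, "planted_spikes") <- spikes$trains
  rec
}
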