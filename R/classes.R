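#' Spike-train set container
#'
#' Bundles per-electrode spike timestamps with the recording metadata the
#' downstream metrics need.  Timestamps are in seconds from recording onset
#' and are kept sorted per electrode.
#'
#' @param trains named list of numeric vectors, one per electrode; names are
#'   electrode ids.  Each vector is sorted non-decreasing, within
#'   `[0, duration]`.
#' @param duration recording length in seconds.
#' @param metadata list with optional entries `culture`, `condition`, `div`.
#' @param n_active_final number of active electrodes at the final recording
#'   age of the same culture; used to normalize the mean firing rate across
#'   development.  `NULL` when unknown.
#' @param ground_truth for simulated sets, a list with the planted burst
#'   table and generator parameters (see [simulate_culture()]).
#'
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, duration,
                            metadata = list(),
                            n_active_final = NULL,
                            ground_truth = NULL) {
  stopifnot(is.list(trains), is.numeric(duration), length(duration) == 1L,
            duration > 0)
  if (length(trains) > 0 && is.null(names(trains)))
    names(trains) <- sprintf("e%02d", seq_along(trains))
  for (id in names(trains)) {
    t <- trains[[id]]
    if (length(t) == 0) next
    if (is.unsorted(t))
      stop("spike times on electrode ", id, " are not sorted")
    if (t[1] < 0 || t[length(t)] > duration + 1e-9)
      stop("spike times on electrode ", id, " outside [0, duration]")
  }
  structure(list(trains = trains, duration = duration,
                 metadata = metadata, n_active_final = n_active_final,
                 ground_truth = ground_truth),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  n_sp <- sum(lengths(x$trains))
  cat("<spike_train_set> ", length(x$trains), " electrodes, ",
      n_sp, " spikes, ", x$duration, " s\n", sep = "")
  md <- x$metadata
  if (length(md))
    cat("  ", paste(names(md), unlist(lapply(md, format)), sep = "=",
                    collapse = ", "), "\n", sep = "")
  if (!is.null(x$ground_truth))
    cat("  ground truth: ", nrow(x$ground_truth$bursts), " planted bursts\n",
        sep = "")
  invisible(x)
}

#' Total spike count of a spike-train set
#' @param x a `spike_train_set`.
#' @return integer spike count over all electrodes.
#' @export
n_spikes <- function(x) sum(lengths(x$trains))

#' Per-electrode firing rates
#' @param x a `spike_train_set`.
#' @return named numeric vector of rates in Hz.
#' @export
firing_rates <- function(x) lengths(x$trains) / x$duration

#' Raw multichannel recording container
#'
#' @param voltage numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate sampling frequency in Hz.
#' @param channel_ids character vector of channel names (defaults to rownames
#'   or `ch01`, `ch02`, ...).
#'
#' @return an object of class `raw_recording` with fields `voltage`,
#'   `sampling_rate`, `channel_ids` and `duration` (seconds).
#' @export
raw_recording <- function(voltage, sampling_rate, channel_ids = NULL) {
  stopifnot(is.matrix(voltage), sampling_rate > 0)
  if (is.null(channel_ids))
    channel_ids <- rownames(voltage)
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%02d", seq_len(nrow(voltage)))
  stopifnot(length(channel_ids) == nrow(voltage))
  rownames(voltage) <- channel_ids
  structure(list(voltage = voltage, sampling_rate = sampling_rate,
                 channel_ids = channel_ids,
                 duration = ncol(voltage) / sampling_rate),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording> ", nrow(x$voltage), " channels x ",
      ncol(x$voltage), " samples @ ", x$sampling_rate, " Hz (",
      signif(x$duration, 4), " s)\n", sep = "")
  invisible(x)
}

#' Network-burst train container
#'
#' @param bursts data.frame with columns `onset`, `offset`, `duration`,
#'   `size` (one row per detected network burst, ordered by onset).
#' @param ibis numeric vector of interburst intervals (seconds),
#'   `nrow(bursts) - 1` values (or length 0).
#' @param ibi_convention how the intervals were measured: `"gap"`
#'   (offset to next onset) or `"onset"` (onset to onset).
#'
#' @return an object of class `burst_train`.
#' @export
burst_train <- function(bursts, ibis, ibi_convention = "gap") {
  stopifnot(is.data.frame(bursts),
            all(c("onset", "offset", "duration", "size") %in% names(bursts)))
  if (nrow(bursts) > 1) {
    if (is.unsorted(bursts$onset)) stop("bursts must be ordered by onset")
    if (any(bursts$onset[-1] < bursts$offset[-nrow(bursts)]))
      stop("burst windows overlap")
  }
  stopifnot(length(ibis) == max(0L, nrow(bursts) - 1L))
  structure(list(bursts = bursts, ibis = as.numeric(ibis),
                 ibi_convention = ibi_convention),
            class = "burst_train")
}

#' @export
print.burst_train <- function(x, ...) {
  cat("<burst_train> ", nrow(x$bursts), " network bursts", sep = "")
  if (nrow(x$bursts) > 0)
    cat("; mean duration ", signif(mean(x$bursts$duration), 3),
        " s, mean size ", signif(mean(x$bursts$size), 3), sep = "")
  if (length(x$ibis) > 0)
    cat(", mean IBI ", signif(mean(x$ibis), 3), " s (", x$ibi_convention,
        ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of bursts in a burst train
#' @param x a `burst_train`.
#' @return integer count.
#' @export
n_bursts <- function(x) nrow(x$bursts)
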