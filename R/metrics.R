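#' All per-recording metrics from a spike-train set
#'
#' Runs the analysis chain on one recording: active-electrode selection,
#' two-step background labeling, Gaussian spike density, network-burst
#' detection, burst metrics, irregularity statistics and (optionally) the
#' network autocovariance half-width.  Returns a single metrics row ready
#' for [compare_study()].
#'
#' @param spikes a [spike_train_set()].
#' @param min_rate,max_rate active-electrode criteria, see
#'   [select_active()].
#' @param theta1,theta2 labeling thresholds, see [label_background()].
#' @param sigma,dt density kernel width and grid step, see
#'   [spike_density()].
#' @param threshold,reference_channels,scaling burst-detection settings,
#'   see [detect_network_bursts()].
#' @param ff_window,ff_step Fano-factor windowing, see [fano_factor()].
#' @param include_autocov compute the autocovariance half-width (the most
#'   expensive metric); set `FALSE` for large simulation sweeps that do not
#'   use it.
#' @param n_active_final active-electrode count at the final age of this
#'   culture (for MFR normalization); `NA` falls back to the current count.
#'
#' @return one-row data.frame: `culture`, `condition`, `div`, the columns
#'   of [culture_metrics()], plus `cv_isi`, `fano_factor`, `cv_ibi`, `ir`,
#'   and `autocov_half_width` (NA when not computed).
#' @export
recording_metrics <- function(spikes,
                              min_rate = 0.1, max_rate = 100,
                              theta1 = 0.100, theta2 = 0.005,
                              sigma = 0.050, dt = 0.001,
                              threshold = 10, reference_channels = 60,
                              scaling = "proportional",
                              ff_window = 5, ff_step = 1,
                              include_autocov = TRUE,
                              n_active_final = NULL) {
  active <- select_active(spikes, min_rate, max_rate)
  labeling <- label_background(active, theta1, theta2)
  dens <- spike_density(active, sigma = sigma, dt = dt)
  bursts <- detect_network_bursts(dens, threshold = threshold,
                                  n_active = length(active$trains),
                                  reference_channels = reference_channels,
                                  scaling = scaling)
  base <- culture_metrics(active, bursts, labeling,
                          n_active_final = if (is.null(n_active_final) ||
                                               is.na(n_active_final))
                            length(active$trains) else n_active_final)
  md <- spikes$metadata
  hw <- NA_real_
  if (include_autocov)
    hw <- tryCatch(network_autocov(active)$half_width,
                   error = function(e) NA_real_)
  cbind(data.frame(culture = md$culture %||% NA_character_,
                   condition = md$condition %||% NA_character_,
                   div = md$div %||% NA_real_,
                   stringsAsFactors = FALSE),
        base,
        data.frame(cv_isi = cv_isi(active),
                   fano_factor = fano_factor(active, ff_window, ff_step),
                   cv_ibi = cv_ibi(bursts),
                   ir = if (length(bursts$ibis) >= 2)
                     ir_metric(bursts$ibis) else NA_real_,
                   autocov_half_width = hw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Metrics table for a whole study
#'
#' Applies [recording_metrics()] to every recording of a simulated (or
#' loaded) study and fills in the MFR normalization: for each culture, the
#' active-electrode count at its final recorded age is used as the
#' denominator at every age.
#'
#' @param study list of [spike_train_set()] objects with `culture`,
#'   `condition` and `div` metadata (e.g. from [simulate_study()]).
#' @param ... further arguments passed to [recording_metrics()].
#' @return data.frame, one row per recording.
#' @export
study_metrics <- function(study, ...) {
  meta <- data.frame(
    culture = vapply(study, function(s) s$metadata$culture, character(1)),
    div = vapply(study, function(s) as.numeric(s$metadata$div), numeric(1)))
  ## active-electrode count at the final DIV, per culture
  final_active <- new.env()
  for (cult in unique(meta$culture)) {
    ix <- which(meta$culture == cult)
    i_final <- ix[which.max(meta$div[ix])]
    n_act <- tryCatch(
      length(select_active(study[[i_final]])$trains),
      error = function(e) NA_integer_)
    assign(cult, n_act, envir = final_active)
  }
  rows <- lapply(seq_along(study), function(i) {
    naf <- get(meta$culture[i], envir = final_active)
    tryCatch(
      recording_metrics(study[[i]], n_active_final = naf, ...),
      error = function(e) NULL)   # e.g. no active electrodes at all
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
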