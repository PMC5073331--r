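#' Run the end-to-end study pipeline
#'
#' Simulates the longitudinal two-condition study described by `config`,
#' computes per-recording metrics, compares the conditions per DIV, and
#' writes the artifacts (`metrics.csv`, `comparisons.csv`,
#' `fingerprint.txt`, `manifest.json`) into `outdir`.  Re-running with the
#' same configuration reproduces identical outputs.
#'
#' @param config a [study_config()].
#' @param outdir output directory (created when missing); `NULL` skips
#'   writing.
#' @param presets condition presets; defaults to [default_presets()] at the
#'   configured duration and electrode count.
#' @param quiet suppress per-stage progress messages.
#'
#' @return list with `metrics` (data.frame), `comparison`
#'   (`group_comparison`), `fingerprint` (character matrix) and
#'   `manifest` (list).
#' @export
run_study_pipeline <- function(config = study_config(), outdir = NULL,
                               presets = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (!quiet) message(...)
  if (is.null(presets))
    presets <- default_presets(duration = config$duration,
                               n_electrodes = config$n_electrodes)

  say("stage 1/3: simulating ", sum(config$n_cultures), " cultures x ",
      length(config$divs), " DIVs")
  study <- simulate_study(presets, n_cultures = config$n_cultures,
                          seed = config$seed, divs = config$divs,
                          heterogeneity_sd = config$heterogeneity_sd)

  say("stage 2/3: computing per-recording metrics (",
      length(study), " recordings)")
  b <- config$burst
  metrics <- study_metrics(study,
                           theta1 = b$theta1, theta2 = b$theta2,
                           sigma = b$sigma, dt = b$dt,
                           threshold = b$threshold,
                           reference_channels = b$reference_channels,
                           scaling = b$scaling,
                           ff_window = config$irregularity$ff_window,
                           ff_step = config$irregularity$ff_step,
                           include_autocov = isTRUE(config$autocov$include))

  say("stage 3/3: group comparison per DIV")
  comparison <- compare_study(metrics,
                              alpha = config$stats$alpha,
                              method = config$stats$method)
  fp <- fingerprint(comparison)
  manifest <- list(package_version = as.character(
                     utils::packageVersion("meaburst")),
                   seed = config$seed,
                   param_hash = config_hash(config),
                   n_recordings = length(study),
                   n_metric_rows = nrow(metrics),
                   n_comparisons = nrow(comparison))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_metrics(metrics, file.path(outdir, "metrics.csv"), config)
    write_metrics(as.data.frame(comparison),
                  file.path(outdir, "comparisons.csv"), config)
    writeLines(c(sprintf("# fingerprint (%s relative to %s), param_hash=%s",
                         attr(comparison, "conditions")[2],
                         attr(comparison, "conditions")[1],
                         config_hash(config)),
                 utils::capture.output(print(fp, quote = FALSE))),
               file.path(outdir, "fingerprint.txt"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(metrics = metrics, comparison = comparison, fingerprint = fp,
       manifest = manifest)
}

#' Basic raster plot of a spike-train set
#'
#' One row of tick marks per electrode; detected or planted burst windows
#' can be shaded for orientation.
#'
#' @param spikes a [spike_train_set()].
#' @param bursts optional [burst_train()] whose windows are shaded.
#' @param xlim time range to display (seconds).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_raster <- function(spikes, bursts = NULL,
                        xlim = c(0, min(spikes$duration, 120)), ...) {
  stopifnot(inherits(spikes, "spike_train_set"))
  ne <- length(spikes$trains)
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, ne + 0.5),
                 xlab = "time (s)", ylab = "electrode", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(ne), labels = names(spikes$trains),
                 las = 1, cex.axis = 0.5)
  if (!is.null(bursts) && nrow(bursts$bursts) > 0)
    graphics::rect(bursts$bursts$onset, 0.5, bursts$bursts$offset,
                   ne + 0.5, col = grDevices::adjustcolor("red", 0.15),
                   border = NA)
  for (i in seq_len(ne)) {
    t <- spikes$trains[[i]]
    t <- t[t >= xlim[1] & t <= xlim[2]]
    if (length(t) > 0)
      graphics::segments(t, i - 0.4, t, i + 0.4, lwd = 0.4)
  }
  invisible(NULL)
}
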