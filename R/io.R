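#' Write a spike-train set to CSV
#'
#' Two-column table (`electrode_id`, `timestamp_s`, timestamps printed with
#' 6 decimal places) preceded by `#key=value` header lines carrying the
#' recording metadata (duration, culture, condition, DIV).
#'
#' @param spikes a [spike_train_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  md <- spikes$metadata
  hdr <- c(sprintf("#duration_s=%.6f", spikes$duration),
           sprintf("#n_electrodes=%d", length(spikes$trains)))
  for (k in c("culture", "condition", "div"))
    if (!is.null(md[[k]])) hdr <- c(hdr, sprintf("#%s=%s", k, md[[k]]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("electrode_id,timestamp_s", con)
  for (id in names(spikes$trains)) {
    t <- spikes$trains[[id]]
    if (length(t) > 0)
      writeLines(sprintf("%s,%.6f", id, t), con)
  }
  invisible(path)
}

#' Read a spike-train set from CSV
#'
#' Counterpart of [write_spike_trains()].  Validates that timestamps are
#' non-negative, within the recorded duration and sorted per electrode;
#' the offending row is named on failure.
#'
#' @param path input file.
#' @return a [spike_train_set()].
#' @export
read_spike_trains <- function(path) {
  lines <- readLines(path)
  hdr_ix <- grep("^#", lines)
  hdr <- lines[hdr_ix]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  if (!"duration_s" %in% names(meta))
    stop("missing duration metadata in ", path)
  duration <- as.numeric(meta[["duration_s"]])
  body <- lines[-hdr_ix]
  stopifnot(body[1] == "electrode_id,timestamp_s")
  body <- body[-1]
  trains <- list()
  if (length(body) > 0) {
    parts <- strsplit(body, ",", fixed = TRUE)
    el <- vapply(parts, `[`, character(1), 1)
    ts <- as.numeric(vapply(parts, `[`, character(1), 2))
    bad <- which(is.na(ts) | ts < 0 | ts > duration + 1e-9)
    if (length(bad) > 0)
      stop("invalid timestamp at data row ", bad[1], " of ", path)
    for (id in unique(el)) {
      t <- ts[el == id]
      if (is.unsorted(t)) {
        row <- which(el == id)[which(diff(t) < 0)[1] + 1L]
        stop("unsorted timestamps for electrode ", id,
             " at data row ", row, " of ", path)
      }
      trains[[id]] <- t
    }
  }
  ne <- suppressWarnings(as.integer(meta["n_electrodes"]))
  if (!is.na(ne) && ne > length(trains)) {
    ## electrodes without spikes are absent from the body; restore them
    have <- names(trains)
    all_ids <- sprintf("e%02d", seq_len(ne))
    if (all(have %in% all_ids))
      for (id in setdiff(all_ids, have)) trains[[id]] <- numeric(0)
    trains <- trains[order(names(trains))]
  }
  md <- list()
  for (k in c("culture", "condition"))
    if (k %in% names(meta)) md[[k]] <- unname(meta[[k]])
  if ("div" %in% names(meta)) md$div <- as.numeric(meta[["div"]])
  spike_train_set(trains, duration, metadata = md)
}

## small FNV-1a hash over the serialized configuration; identifies the
## parameter set that produced an output file without external deps
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a metrics (or comparison) table to CSV
#'
#' Plain CSV with an optional leading `#param_hash=` comment line tying the
#' file to the configuration that produced it.
#'
#' @param table data.frame.
#' @param path output file.
#' @param config optional configuration list to hash into the header.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(table, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(sprintf("#param_hash=%s", config_hash(config)), con)
  write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read a metrics table written by [write_metrics()]
#' @param path input file.
#' @return data.frame; the parameter hash, when present, in
#'   `attr(, "param_hash")`.
#' @export
read_metrics <- function(path) {
  first <- readLines(path, n = 1)
  hash <- NULL
  skip <- 0
  if (grepl("^#param_hash=", first)) {
    hash <- sub("^#param_hash=", "", first)
    skip <- 1
  }
  out <- read.csv(path, skip = skip, stringsAsFactors = FALSE)
  attr(out, "param_hash") <- hash
  out
}

#' Write burst intervals as BED-like TSV
#'
#' Tab-separated `start_s`, `end_s`, `size` rows, one per network burst.
#'
#' @param bursts a [burst_train()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_burst_intervals <- function(bursts, path) {
  stopifnot(inherits(bursts, "burst_train"))
  df <- data.frame(start_s = sprintf("%.6f", bursts$bursts$onset),
                   end_s = sprintf("%.6f", bursts$bursts$offset),
                   size = sprintf("%.3f", bursts$bursts$size))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' Sidecar file with the planted burst table and generator configuration of
#' a simulated recording.
#'
#' @param spikes a simulated [spike_train_set()] with ground truth.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"),
            !is.null(spikes$ground_truth))
  gt <- spikes$ground_truth
  jsonlite::write_json(list(bursts = gt$bursts,
                            config = unclass(gt$config),
                            warning_flags = gt$warning_flags,
                            metadata = spikes$metadata),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Study configuration
#'
#' Single nested configuration for the end-to-end pipeline; every default
#' equals the corresponding stage's default.  Serializes losslessly to
#' YAML via [save_config()] / [load_config()].
#'
#' @param seed master seed.
#' @param n_cultures named vector of cultures per condition.
#' @param divs ages (DIV) to simulate.
#' @param duration recording length in seconds.
#' @param n_electrodes electrodes per array.
#' @param heterogeneity_sd between-culture lognormal multiplier SD.
#' @param detection list of [detection_params()] overrides.
#' @param burst list: `theta1`, `theta2`, `sigma`, `dt`, `threshold`,
#'   `reference_channels`, `scaling`.
#' @param irregularity list: `ff_window`, `ff_step`.
#' @param autocov list: `max_lag`, `bin`, `smooth_window`,
#'   `include` (logical).
#' @param stats list: `method` (FDR), `alpha`.
#' @return list of class `study_config`.
#' @export
study_config <- function(seed = 1,
                         n_cultures = c(control = 25, deficient = 19),
                         divs = c(10, 13, 15, 17),
                         duration = 1200, n_electrodes = 60,
                         heterogeneity_sd = 0.2,
                         detection = list(),
                         burst = list(theta1 = 0.100, theta2 = 0.005,
                                      sigma = 0.050, dt = 0.001,
                                      threshold = 10,
                                      reference_channels = 60,
                                      scaling = "proportional"),
                         irregularity = list(ff_window = 5, ff_step = 1),
                         autocov = list(max_lag = 2, bin = 0.001,
                                        smooth_window = 0.005,
                                        include = TRUE),
                         stats = list(method = "BY", alpha = 0.05)) {
  structure(list(seed = seed, n_cultures = n_cultures, divs = divs,
                 duration = duration, n_electrodes = n_electrodes,
                 heterogeneity_sd = heterogeneity_sd,
                 detection = detection, burst = burst,
                 irregularity = irregularity, autocov = autocov,
                 stats = stats),
            class = "study_config")
}

#' @rdname study_config
#' @param config a `study_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  x$n_cultures <- as.list(x$n_cultures)   # keep names through YAML
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname study_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- study_config()
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  ## yaml drops names of atomic vectors read back as lists; restore
  cfg$n_cultures <- unlist(cfg$n_cultures)
  cfg$divs <- unlist(cfg$divs)
  cfg
}
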