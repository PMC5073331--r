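#' Two-step background / burst-candidate labeling
#'
#' Separates temporally isolated (background) action potentials from
#' burst-candidate spikes in two steps: (1) per electrode, a spike is
#' background when both its pre- and post-interspike intervals exceed
#' `theta1` (100 ms); (2) the remaining spikes from all electrodes are
#' pooled into one train, and a spike is also background when both pooled
#' pre- and post-ISIs exceed `theta2` (5 ms).  A missing ISI (first or last
#' spike) counts as infinite.
#'
#' @param spikes a [spike_train_set()] (active electrodes).
#' @param theta1 per-electrode isolation threshold in seconds (default 0.1).
#' @param theta2 pooled-train isolation threshold in seconds (default 0.005).
#'
#' @return data.frame with one row per spike: `electrode`, `time`,
#'   `label` (`"background"` or `"burst"`), `stage` (1, 2, or 0 for
#'   burst candidates).
#' @export
label_background <- function(spikes, theta1 = 0.100, theta2 = 0.005) {
  stopifnot(inherits(spikes, "spike_train_set"))
  el <- rep(names(spikes$trains), lengths(spikes$trains))
  tt <- unlist(spikes$trains, use.names = FALSE)
  if (length(tt) == 0)
    return(data.frame(electrode = character(0), time = numeric(0),
                      label = character(0), stage = integer(0),
                      stringsAsFactors = FALSE))

  isolated <- function(t, theta) {
    ## pre/post ISIs with missing intervals treated as infinite
    pre <- c(Inf, diff(t))
    post <- c(diff(t), Inf)
    pre > theta & post > theta
  }

  ## stage 1: per electrode (trains are stored per electrode and sorted)
  stage <- unlist(lapply(spikes$trains, function(t)
    ifelse(isolated(t, theta1), 1L, 0L)), use.names = FALSE)

  ## stage 2: pooled train of the remaining spikes
  rem <- which(stage == 0L)
  if (length(rem) > 0) {
    o <- rem[order(tt[rem])]
    bg2 <- isolated(tt[o], theta2)
    stage[o[bg2]] <- 2L
  }
  lab <- data.frame(electrode = el, time = tt,
                    label = ifelse(stage > 0L, "background", "burst"),
                    stage = stage, stringsAsFactors = FALSE)
  lab[order(lab$time, lab$electrode), , drop = FALSE]
}

#' Gaussian spike-density trace
#'
#' Convolves the pooled spike train of all (active) electrodes with a unit
#' Gaussian kernel: `density(t) = sum_i A exp(-(t - tau_i)^2 / (2 sigma^2))`.
#' Spikes are binned at `dt` (1 ms by default, far below the 50 ms kernel
#' width) and the kernel is truncated at 5 sigma (relative mass error
#' < 1e-6).
#'
#' @param spikes a [spike_train_set()] or a numeric vector of spike times
#'   (then `duration` is required).
#' @param sigma Gaussian width in seconds (default 0.050).
#' @param amplitude kernel amplitude `A` (default 1).
#' @param dt grid step in seconds (default 0.001).
#' @param duration recording length; taken from the spike-train set when
#'   available.
#'
#' @return list of class `spike_density`: `time`, `density`, `sigma`,
#'   `amplitude`, `dt`, `kernel_area` (`A * sigma * sqrt(2 pi)`).
#' @export
spike_density <- function(spikes, sigma = 0.050, amplitude = 1, dt = 0.001,
                          duration = NULL) {
  if (inherits(spikes, "spike_train_set")) {
    duration <- spikes$duration
    tt <- unlist(spikes$trains, use.names = FALSE)
  } else {
    tt <- as.numeric(spikes)
    if (is.null(duration)) stop("duration required for a bare spike vector")
  }
  n_grid <- floor(duration / dt) + 1L
  grid <- (seq_len(n_grid) - 1L) * dt
  half <- ceiling(5 * sigma / dt)
  kernel <- amplitude * exp(-((-half:half) * dt)^2 / (2 * sigma^2))
  ## spikes sorted by bin: the C++ accumulation then walks the grid almost
  ## sequentially, which matters for long recordings
  dens <- if (length(tt) == 0) numeric(n_grid) else
    kernel_density_sum(sort.int(pmin(pmax(as.integer(round(tt / dt)) + 1L,
                                          1L), n_grid)),
                       kernel, n_grid)
  structure(list(time = grid, density = dens, sigma = sigma,
                 amplitude = amplitude, dt = dt,
                 kernel_area = amplitude * sigma * sqrt(2 * pi)),
            class = "spike_density")
}

#' @export
print.spike_density <- function(x, ...) {
  cat("<spike_density> ", length(x$time), " points, dt = ", x$dt,
      " s, sigma = ", x$sigma, " s, peak = ", signif(max(x$density), 4),
      "\n", sep = "")
  invisible(x)
}

#' Detect network bursts from a spike-density trace
#'
#' A network burst starts where the spike-density trace crosses the
#' detection threshold from below and ends where it falls back under it.
#' The nominal threshold (10 Hz) is referenced to a 60-electrode array; by
#' default it is scaled proportionally to the number of active electrodes
#' (`threshold * n_active / reference_channels`) so per-electrode
#' sensitivity is constant as cultures mature; `scaling = "fixed"` uses the
#' nominal value as is.  Burst size is the area under the density within
#' the burst window divided by the area of the spike kernel, i.e. a count
#' in spike equivalents.  Bursts already in progress at the start or still
#' in progress at the end of the recording are discarded.
#'
#' @param density a [spike_density()].
#' @param threshold nominal density threshold (default 10).
#' @param n_active number of active electrodes the density was built from.
#' @param reference_channels electrode count the nominal threshold refers
#'   to (default 60).
#' @param scaling `"proportional"` or `"fixed"`.
#' @param ibi_convention `"gap"` (offset to next onset, the quiescent
#'   interval; default) or `"onset"` (onset to onset).
#'
#' @return a [burst_train()]; the effective threshold in
#'   `attr(, "effective_threshold")`.
#' @export
detect_network_bursts <- function(density, threshold = 10,
                                  n_active = NULL,
                                  reference_channels = 60,
                                  scaling = c("proportional", "fixed"),
                                  ibi_convention = c("gap", "onset")) {
  stopifnot(inherits(density, "spike_density"))
  scaling <- match.arg(scaling)
  ibi_convention <- match.arg(ibi_convention)
  if (scaling == "proportional" && is.null(n_active))
    stop("n_active is required for proportional threshold scaling")
  eff <- if (scaling == "proportional")
    threshold * n_active / reference_channels else threshold
  d <- density$density
  above <- d >= eff
  up <- which(!above[-length(above)] & above[-1]) + 1L    # first index above
  down <- which(above[-length(above)] & !above[-1])       # last index above

  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0), size = numeric(0))
  if (length(up) == 0 || length(down) == 0) {
    bt <- burst_train(empty, numeric(0), ibi_convention)
    attr(bt, "effective_threshold") <- eff
    return(bt)
  }
  ## keep complete onset/offset pairs only
  down <- down[down >= up[1]]
  if (length(down) == 0) {
    bt <- burst_train(empty, numeric(0), ibi_convention)
    attr(bt, "effective_threshold") <- eff
    return(bt)
  }
  up <- up[seq_len(length(down))]

  dt <- density$dt
  interp_cross <- function(i0, i1) {
    ## linear interpolation of the threshold crossing between grid points
    t0 <- density$time[i0]
    if (d[i1] == d[i0]) return(density$time[i1])
    t0 + dt * (eff - d[i0]) / (d[i1] - d[i0])
  }
  onset <- vapply(up, function(i) interp_cross(i - 1L, i), numeric(1))
  offset <- vapply(down, function(i) interp_cross(i, i + 1L), numeric(1))
  size <- vapply(seq_along(up), function(b) {
    ix <- up[b]:down[b]
    sum(d[ix]) * dt / density$kernel_area
  }, numeric(1))
  bursts <- data.frame(onset = onset, offset = offset,
                       duration = offset - onset, size = size)
  ibis <- if (nrow(bursts) > 1) {
    if (ibi_convention == "gap")
      bursts$onset[-1] - bursts$offset[-nrow(bursts)]
    else diff(bursts$onset)
  } else numeric(0)
  bt <- burst_train(bursts, ibis, ibi_convention)
  attr(bt, "effective_threshold") <- eff
  bt
}

#' Per-recording activity metrics
#'
#' Assembles the basic activity statistics of one recording: mean firing
#' rate (MFR; spike count divided by duration and by the number of active
#' electrodes at the final recording age, so development is not confounded
#' with electrode recruitment), burst rate (per minute), percentage of
#' spikes inside burst windows (and, when a labeling is supplied, the
#' percentage labeled burst-candidate by the two-step rule), and means of
#' burst duration, size and interburst interval.
#'
#' @param spikes active-electrode [spike_train_set()].
#' @param bursts a [burst_train()].
#' @param labeling optional output of [label_background()].
#' @param n_active_final active-electrode count at the final age of the same
#'   culture; falls back (with a warning) to the current count when missing.
#'
#' @return one-row data.frame with columns `mfr`, `burst_rate`,
#'   `pct_spikes_in_bursts`, `pct_burst_labeled`, `mean_burst_duration`,
#'   `mean_burst_size`, `mean_ibi`, `n_active_electrodes`, `n_bursts`.
#'   Burst means are `NA` when no (or too few) bursts were detected.
#' @export
culture_metrics <- function(spikes, bursts, labeling = NULL,
                            n_active_final = spikes$n_active_final) {
  stopifnot(inherits(spikes, "spike_train_set"),
            inherits(bursts, "burst_train"))
  n_active <- length(spikes$trains)
  if (is.null(n_active_final)) {
    warning("n_active_final missing; normalizing MFR by the current ",
            "active-electrode count")
    n_active_final <- n_active
  }
  total <- n_spikes(spikes)
  tt <- unlist(spikes$trains, use.names = FALSE)
  nb <- n_bursts(bursts)
  in_burst <- if (nb > 0 && total > 0) {
    ## burst windows are disjoint and ordered: a spike is inside iff it
    ## lands in an odd interval of the interleaved onset/offset boundaries
    edges <- as.vector(rbind(bursts$bursts$onset, bursts$bursts$offset))
    idx <- findInterval(tt, edges, rightmost.closed = FALSE)
    sum(idx %% 2L == 1L | tt %in% bursts$bursts$offset)
  } else 0L
  pct_lab <- if (!is.null(labeling) && nrow(labeling) > 0)
    100 * mean(labeling$label == "burst") else NA_real_
  data.frame(
    mfr = total / spikes$duration / n_active_final,
    burst_rate = nb / spikes$duration * 60,
    pct_spikes_in_bursts = if (total > 0) 100 * in_burst / total else 0,
    pct_burst_labeled = pct_lab,
    mean_burst_duration = if (nb > 0) mean(bursts$bursts$duration) else NA_real_,
    mean_burst_size = if (nb > 0) mean(bursts$bursts$size) else NA_real_,
    mean_ibi = if (length(bursts$ibis) > 0) mean(bursts$ibis) else NA_real_,
    n_active_electrodes = n_active,
    n_bursts = nb)
}
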