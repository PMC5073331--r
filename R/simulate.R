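#' Configuration for the synthetic culture generator
#'
#' The generator is a doubly stochastic point-process model of a bursting
#' MEA culture: network bursts occur as a gamma renewal process, each burst
#' recruits a random subset of electrodes which fire Poisson numbers of
#' spikes positioned by a within-burst envelope, and every electrode adds
#' independent homogeneous Poisson background firing.
#'
#' @param n_electrodes number of electrodes (default 60, a standard MEA).
#' @param duration recording length in seconds (default 1200, i.e. 20 min).
#' @param background_rate homogeneous Poisson background rate per electrode
#'   (Hz).
#' @param burst_ibi_mean mean of the burst renewal intervals, onset to onset
#'   (seconds); `Inf` disables bursting.
#' @param burst_ibi_cv coefficient of variation of the renewal intervals.
#'   Intervals are gamma with shape `1/cv^2` and scale `mean * cv^2`, so the
#'   mean and CV are controlled independently.
#' @param burst_duration_mean mean burst duration (seconds).
#' @param burst_duration_cv CV of burst durations (0 gives fixed durations).
#' @param spikes_per_burst_per_electrode mean Poisson spike count a recruited
#'   electrode contributes to one burst.
#' @param participation_prob probability that an electrode is recruited into
#'   a given burst.
#' @param envelope within-burst spike-latency profile: `"gamma"` (rise-fall
#'   density, latencies gamma-distributed and truncated to the burst window)
#'   or `"uniform"`.
#' @param envelope_shape gamma shape of the latency distribution (rise
#'   steepness); ignored for the uniform envelope.
#' @param seed optional integer seed stored with the config.
#'
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_electrodes = 60,
                              duration = 1200,
                              background_rate = 0.3,
                              burst_ibi_mean = 10,
                              burst_ibi_cv = 0.3,
                              burst_duration_mean = 0.55,
                              burst_duration_cv = 0.2,
                              spikes_per_burst_per_electrode = 10,
                              participation_prob = 0.85,
                              envelope = c("gamma", "uniform"),
                              envelope_shape = 2,
                              seed = NULL) {
  envelope <- match.arg(envelope)
  cfg <- list(n_electrodes = n_electrodes, duration = duration,
              background_rate = background_rate,
              burst_ibi_mean = burst_ibi_mean, burst_ibi_cv = burst_ibi_cv,
              burst_duration_mean = burst_duration_mean,
              burst_duration_cv = burst_duration_cv,
              spikes_per_burst_per_electrode = spikes_per_burst_per_electrode,
              participation_prob = participation_prob,
              envelope = envelope, envelope_shape = envelope_shape,
              seed = seed)
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_electrodes >= 1, duration > 0,
              background_rate >= 0,
              burst_ibi_mean > 0, burst_ibi_cv >= 0,
              burst_duration_mean > 0, burst_duration_cv >= 0,
              spikes_per_burst_per_electrode >= 0,
              participation_prob >= 0, participation_prob <= 1,
              envelope_shape > 0)
    if (is.finite(burst_ibi_mean) && burst_ibi_mean <= burst_duration_mean)
      stop("burst_ibi_mean must exceed burst_duration_mean")
  })
  invisible(cfg)
}

## deterministic child seed: keeps every per-culture, per-DIV simulation
## reproducible in isolation from one master seed.  Arithmetic in double to
## stay inside 2^31 without integer overflow.
child_seed <- function(master, counter) {
  m <- as.numeric(master) %% 1000003
  as.integer((m * 20011 + as.numeric(counter) * 7919) %% 2147483629) + 1L
}

## gamma-renewal event times on [0, horizon); shape/scale from mean + CV.
## cv = 0 degenerates to a deterministic clock.
renewal_onsets <- function(mean_ibi, cv, horizon) {
  if (!is.finite(mean_ibi) || mean_ibi >= horizon * 100) return(numeric(0))
  n_guess <- ceiling(horizon / mean_ibi + 6 * sqrt(horizon / mean_ibi) + 10)
  draw <- function(n) {
    if (cv <= 0) rep(mean_ibi, n)
    else rgamma(n, shape = 1 / cv^2, scale = mean_ibi * cv^2)
  }
  iv <- draw(n_guess)
  on <- cumsum(iv)
  while (on[length(on)] < horizon) {
    iv2 <- draw(n_guess)
    on <- c(on, on[length(on)] + cumsum(iv2))
  }
  on[on < horizon]
}

#' Simulate one MEA culture recording
#'
#' Draws a spike-train set from the generative model described in
#' [simulation_config()]: gamma-renewal network bursts with per-electrode
#' recruitment and within-burst latency envelopes on top of homogeneous
#' Poisson background firing.  The planted burst table (onset, offset,
#' truncation flag, spike count) is attached as ground truth.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @param metadata list with `culture`, `condition`, `div` carried through to
#'   the returned set.
#'
#' @return a [spike_train_set()] whose `ground_truth` field holds
#'   `bursts` (data.frame: onset, offset, duration, truncated, n_spikes),
#'   `config`, and `warning_flags`.
#' @export
simulate_culture <- function(config, seed = config$seed, metadata = list()) {
  validate_simulation_config(config)
  if (is.null(seed)) stop("a seed is required for reproducible simulation")
  set.seed(as.integer(seed))
  ne <- config$n_electrodes
  Tdur <- config$duration
  flags <- character(0)

  ## --- planted network bursts -------------------------------------------
  onsets <- if (config$participation_prob > 0 &&
                config$spikes_per_burst_per_electrode > 0)
    renewal_onsets(config$burst_ibi_mean, config$burst_ibi_cv, Tdur)
  else numeric(0)
  nb <- length(onsets)
  if (is.finite(config$burst_ibi_mean) && Tdur < config$burst_ibi_mean)
    flags <- c(flags, "duration_shorter_than_expected_ibi")

  if (nb > 0) {
    dur <- if (config$burst_duration_cv <= 0)
      rep(config$burst_duration_mean, nb)
    else rgamma(nb, shape = 1 / config$burst_duration_cv^2,
                scale = config$burst_duration_mean * config$burst_duration_cv^2)
    truncated <- onsets + dur > Tdur
    offsets <- pmin(onsets + dur, Tdur)
    dur <- offsets - onsets
  } else {
    dur <- offsets <- numeric(0)
    truncated <- logical(0)
  }

  ## --- burst spikes ------------------------------------------------------
  sp_el <- integer(0); sp_t <- numeric(0); sp_burst <- integer(0)
  if (nb > 0) {
    recruit <- matrix(rbinom(nb * ne, 1L, config$participation_prob),
                      nrow = nb, ncol = ne)
    counts <- matrix(0L, nb, ne)
    idx <- which(recruit == 1L)
    counts[idx] <- rpois(length(idx),
                         config$spikes_per_burst_per_electrode)
    tot <- sum(counts)
    if (tot > 0) {
      pos <- which(counts > 0, arr.ind = TRUE)
      k <- counts[counts > 0]
      b_id <- rep(pos[, 1], k)
      sp_el <- rep(pos[, 2], k)
      d_b <- dur[b_id]
      if (config$envelope == "uniform") {
        lat <- runif(tot) * d_b
      } else {
        ## gamma latencies truncated to the burst window by inverse-CDF
        sh <- config$envelope_shape
        sc <- d_b / (3 * sh)   # mean latency ~ duration/3
        u <- runif(tot) * pgamma(d_b, shape = sh, scale = sc)
        lat <- qgamma(u, shape = sh, scale = sc)
      }
      sp_t <- onsets[b_id] + lat
      sp_burst <- b_id
    }
  }

  ## --- background spikes -------------------------------------------------
  if (config$background_rate > 0) {
    nbg <- rpois(ne, config$background_rate * Tdur)
    bg_el <- rep(seq_len(ne), nbg)
    bg_t <- runif(sum(nbg)) * Tdur
    sp_el <- c(sp_el, bg_el)
    sp_t <- c(sp_t, bg_t)
    sp_burst <- c(sp_burst, rep(0L, sum(nbg)))
  }

  ids <- sprintf("e%02d", seq_len(ne))
  trains <- rep(list(numeric(0)), ne)
  names(trains) <- ids
  if (length(sp_t) > 0) {
    o <- order(sp_el, sp_t)
    sp_el <- sp_el[o]; sp_t <- sp_t[o]
    split_t <- split(sp_t, factor(sp_el, levels = seq_len(ne)))
    trains <- lapply(split_t, as.numeric)
    names(trains) <- ids
  }

  gt_bursts <- data.frame(onset = onsets, offset = offsets, duration = dur,
                          truncated = truncated,
                          n_spikes = if (nb > 0)
                            tabulate(sp_burst[sp_burst > 0], nb) else integer(0))
  spike_train_set(trains, Tdur, metadata = metadata,
                  ground_truth = list(bursts = gt_bursts, config = config,
                                      warning_flags = flags))
}

#' Default developmental condition presets
#'
#' Generator configurations for the two experimental conditions (`control`
#' and `deficient`, i.e. EHMT1 knock-down) at each recording age
#' (DIV 10, 13, 15, 17).  Control presets follow the canonical maturation of
#' dissociated cortical cultures: sparse, weakly synchronized firing at
#' DIV 10 developing into regular network bursting that becomes stationary
#' by DIV 15.  The deficient presets encode the developmental fingerprint of
#' the phenotype: at DIV 13 a 40% lower burst rate, reduced background
#' firing and longer bursts; at DIV 17 matched rates but markedly more
#' irregular burst timing (higher IBI CV).
#'
#' @param duration recording length in seconds for every preset.
#' @param n_electrodes electrodes per array.
#'
#' @return nested named list: `presets[[condition]][[as.character(div)]]` is
#'   a [simulation_config()].
#' @export
default_presets <- function(duration = 1200, n_electrodes = 60) {
  base <- function(bg, ibi, cv, dur_b, spb, part)
    simulation_config(n_electrodes = n_electrodes, duration = duration,
                      background_rate = bg, burst_ibi_mean = ibi,
                      burst_ibi_cv = cv, burst_duration_mean = dur_b,
                      spikes_per_burst_per_electrode = spb,
                      participation_prob = part)
  control <- list(
    `10` = base(0.15, 45, 0.60, 0.40, 4, 0.45),
    `13` = base(0.25, 20, 0.40, 0.50, 8, 0.70),
    `15` = base(0.30, 12, 0.35, 0.55, 10, 0.80),
    `17` = base(0.30, 10, 0.30, 0.55, 10, 0.85))
  deficient <- list(
    ## DIV 10: mildly reduced activity
    `10` = base(0.135, 50, 0.60, 0.40, 4, 0.45),
    ## DIV 13: burst rate x0.6 (40% reduction), background x0.82,
    ## bursts 24% longer
    `13` = base(0.205, 20 / 0.6, 0.40, 0.62, 8, 0.70),
    ## DIV 15: partial catch-up
    `15` = base(0.285, 12 / 0.85, 0.40, 0.58, 10, 0.80),
    ## DIV 17: rates recovered, burst timing more irregular
    `17` = base(0.30, 10, 0.45, 0.55, 10, 0.85))
  list(control = control, deficient = deficient)
}

#' Simulate a longitudinal two-condition study
#'
#' Re-simulates each culture at every requested age (DIV) with the
#' age-specific preset, mimicking a longitudinal MEA experiment in which the
#' same arrays are recorded repeatedly during development.  Each culture
#' carries a persistent lognormal activity multiplier (applied to the
#' background rate and the burst rate) so that between-culture variability
#' is larger than within-recording sampling noise, as in real culture
#' batches.
#'
#' @param presets nested preset list as returned by [default_presets()].
#' @param n_cultures named vector, cultures per condition
#'   (default `c(control = 25, deficient = 19)`, the study design sizes).
#' @param seed master seed; per-culture, per-DIV child seeds are derived
#'   from it with a counter scheme.
#' @param divs ages to simulate; must be available in every preset.
#' @param heterogeneity_sd standard deviation of the log-normal
#'   between-culture activity multiplier (0 disables heterogeneity).
#'
#' @return list of [spike_train_set()] objects with metadata
#'   (`culture`, `condition`, `div`) filled in.
#' @export
simulate_study <- function(presets = default_presets(),
                           n_cultures = c(control = 25, deficient = 19),
                           seed = 1,
                           divs = c(10, 13, 15, 17),
                           heterogeneity_sd = 0.2) {
  conditions <- names(presets)
  if (is.null(names(n_cultures))) names(n_cultures) <- conditions
  if (any(n_cultures < 2))
    stop("need at least 2 cultures per condition for group statistics")
  for (cond in conditions)
    if (!all(as.character(divs) %in% names(presets[[cond]])))
      stop("presets must cover every requested DIV for condition ", cond)

  set.seed(as.integer(seed))
  mult <- lapply(conditions, function(cond)
    if (heterogeneity_sd > 0)
      rlnorm(n_cultures[[cond]], 0, heterogeneity_sd)
    else rep(1, n_cultures[[cond]]))
  names(mult) <- conditions

  out <- list()
  counter <- 0L
  for (cond in conditions) {
    for (ci in seq_len(n_cultures[[cond]])) {
      culture_id <- sprintf("%s_%02d", substr(cond, 1, 4), ci)
      for (div in divs) {
        counter <- counter + 1L
        cfg <- presets[[cond]][[as.character(div)]]
        m <- mult[[cond]][ci]
        cfg$background_rate <- cfg$background_rate * m
        cfg$burst_ibi_mean <- cfg$burst_ibi_mean / m
        sts <- simulate_culture(cfg, seed = child_seed(seed, counter),
                                metadata = list(culture = culture_id,
                                                condition = cond,
                                                div = div))
        out[[paste(culture_id, div, sep = "_div")]] <- sts
      }
    }
  }
  out
}
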