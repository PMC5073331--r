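# Shared fixtures and independent oracles for the test suite.

# small, fast generator config for tests that do not need the full array
quick_config <- function(...) {
  args <- list(...)
  base <- list(n_electrodes = 12, duration = 300, background_rate = 0.25,
               burst_ibi_mean = 20, burst_ibi_cv = 0.4,
               burst_duration_mean = 0.5,
               spikes_per_burst_per_electrode = 8,
               participation_prob = 0.7)
  base[names(args)] <- args
  do.call(simulation_config, base)
}

# spike-train set from a plain list of numeric vectors
sts <- function(trains, duration) {
  if (is.null(names(trains)))
    names(trains) <- sprintf("e%02d", seq_along(trains))
  spike_train_set(trains, duration)
}

# exhaustive rank-permutation Mann-Whitney oracle (no ties assumed):
# enumerates every assignment of pooled ranks to group a and computes the
# two-sided p exactly from the null U distribution
mw_enumeration_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  sets <- utils::combn(na + nb, na)
  u_all <- apply(sets, 2, function(ix) sum(ix) - na * (na + 1) / 2)
  # ranks of the pooled sample are 1..n, so subsets of indices = subsets of
  # ranks; U depends on ranks only
  pl <- mean(u_all <= u_obs)
  pg <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pg))
}

# dense binned-definition autocovariance oracle: builds the full count
# vector and evaluates sum((x_n - mu)(x_{n+k} - mu)) / (T - |tau|) lag by
# lag.  Independent of the sparse pair-histogram route in the package.
autocov_dense_oracle <- function(train, duration, max_lag = 2, bin = 0.001) {
  n_bins <- as.integer(ceiling(duration / bin))
  x <- tabulate(pmin(floor(train / bin), n_bins - 1) + 1, n_bins)
  mu <- mean(x)
  K <- as.integer(round(max_lag / bin)) - 1L
  vals <- vapply(seq_len(K), function(k) {
    sum((x[1:(n_bins - k)] - mu) * (x[(k + 1):n_bins] - mu)) /
      (duration - k * bin)
  }, numeric(1))
  list(lags = c(-rev(seq_len(K)), seq_len(K)) * bin,
       values = c(rev(vals), vals))
}

# brute-force two-step labeling oracle: literal per-spike scan, written
# independently of the vectorized implementation
label_oracle <- function(trains, theta1 = 0.1, theta2 = 0.005) {
  rows <- list()
  for (id in names(trains)) {
    t <- trains[[id]]
    for (i in seq_along(t)) {
      pre <- if (i == 1) Inf else t[i] - t[i - 1]
      post <- if (i == length(t)) Inf else t[i + 1] - t[i]
      rows[[length(rows) + 1]] <-
        data.frame(electrode = id, time = t[i],
                   bg1 = pre > theta1 && post > theta1)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$time, df$electrode), ]
  rem <- df[!df$bg1, , drop = FALSE]
  df$bg2 <- FALSE
  if (nrow(rem) > 0) {
    rem <- rem[order(rem$time), ]
    for (i in seq_len(nrow(rem))) {
      pre <- if (i == 1) Inf else rem$time[i] - rem$time[i - 1]
      post <- if (i == nrow(rem)) Inf else rem$time[i + 1] - rem$time[i]
      if (pre > theta2 && post > theta2) {
        hit <- which(df$electrode == rem$electrode[i] &
                       df$time == rem$time[i])
        df$bg2[hit] <- TRUE
      }
    }
  }
  df$label <- ifelse(df$bg1 | df$bg2, "background", "burst")
  df
}

# planted gap IBIs (offset to next onset) of the complete bursts of a
# simulated set
planted_gap_ibis <- function(s) {
  gt <- s$ground_truth$bursts
  gt <- gt[!gt$truncated, , drop = FALSE]
  if (nrow(gt) < 2) return(numeric(0))
  gt$onset[-1] - gt$offset[-nrow(gt)]
}
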