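test_that("two-step labeling follows the isolation rules", {
  # a single spike has infinite ISIs on both sides -> background at stage 1
  one <- sts(list(c(5)), duration = 10)
  lab <- label_background(one)
  expect_equal(lab$label, "background")
  expect_equal(lab$stage, 1L)

  # an electrode firing every 50 ms never passes the 100 ms criterion
  fast <- sts(list(seq(1, 3, by = 0.05)), duration = 10)
  lab2 <- label_background(fast)
  expect_false(any(lab2$stage == 1L))

  # three electrodes firing simultaneously every 10 s: per-electrode ISIs
  # (10 s) exceed theta1, so stage 1 labels everything background
  sim <- sts(rep(list(c(10, 20, 30)), 3), duration = 40)
  lab3 <- label_background(sim)
  expect_true(all(lab3$label == "background"))
  expect_true(all(lab3$stage == 1L))
})

test_that("labeling matches the brute-force oracle on random toy sets", {
  for (seed in 1:25) {
    set.seed(seed)
    ne <- sample(1:3, 1)
    trains <- lapply(seq_len(ne), function(i)
      sort(round(runif(sample(1:4, 1), 0, 2), 3)))
    names(trains) <- sprintf("e%02d", seq_len(ne))
    got <- label_background(spike_train_set(trains, 2))
    want <- label_oracle(trains)
    expect_equal(got$label, want$label,
                 info = paste("seed", seed))
  }
})

test_that("spike density has unit peaks and the Gaussian kernel area", {
  d <- spike_density(c(5), duration = 10, sigma = 0.05, dt = 0.001)
  expect_equal(max(d$density), 1, tolerance = 1e-4)
  expect_equal(d$time[which.max(d$density)], 5)
  # area under one kernel = A * sigma * sqrt(2 pi)
  expect_equal(sum(d$density) * d$dt, 0.05 * sqrt(2 * pi),
               tolerance = 1e-4)
  # superposition: coincident spikes double the peak
  d2 <- spike_density(c(5, 5), duration = 10)
  expect_equal(max(d2$density), 2, tolerance = 1e-3)
  # empty input gives a zero trace
  d0 <- spike_density(numeric(0), duration = 10)
  expect_true(all(d0$density == 0))
})

test_that("network-burst detection resolves planted volleys", {
  # two 60-electrode volleys of 10 spikes each, 10 s of quiescence between
  set.seed(8)
  mk_volley <- function(t0) sort(t0 + runif(600, 0, 0.3))
  tt <- c(mk_volley(5), mk_volley(15.3))
  d <- spike_density(tt, duration = 25)
  bt <- detect_network_bursts(d, n_active = 60)
  expect_equal(n_bursts(bt), 2L)
  expect_equal(bt$ibis, 10, tolerance = 0.05)
  # size tracks the spike count inside the detected window within 10%
  for (b in 1:2) {
    inside <- sum(tt >= bt$bursts$onset[b] & tt <= bt$bursts$offset[b])
    expect_equal(bt$bursts$size[b], inside, tolerance = 0.1)
  }
  # flat sub-threshold density yields no bursts
  flat <- spike_density(numeric(0), duration = 5)
  flat$density <- rep(4, length(flat$density))
  expect_equal(n_bursts(detect_network_bursts(flat, n_active = 60)), 0L)
})

test_that("burst windows are disjoint, ordered, with positive IBIs", {
  s <- simulate_culture(quick_config(n_electrodes = 60, duration = 600),
                        seed = 9)
  d <- spike_density(s)
  bt <- detect_network_bursts(d, n_active = 60)
  expect_gt(n_bursts(bt), 5)
  b <- bt$bursts
  expect_true(all(b$offset > b$onset))
  expect_true(!is.unsorted(b$onset))
  expect_true(all(b$onset[-1] >= b$offset[-nrow(b)]))
  expect_true(all(bt$ibis > 0))
  # onset-to-onset convention equals diff of onsets
  bt2 <- detect_network_bursts(d, n_active = 60, ibi_convention = "onset")
  expect_equal(bt2$ibis, diff(b$onset))
})

test_that("raising the threshold never increases the burst count and keeps containment", {
  s <- simulate_culture(quick_config(n_electrodes = 60, duration = 600,
                                     background_rate = 0.1), seed = 10)
  d <- spike_density(s)
  ths <- c(5, 10, 20, 40)
  bts <- lapply(ths, function(th)
    detect_network_bursts(d, threshold = th, n_active = 60))
  counts <- vapply(bts, n_bursts, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # every burst at a higher threshold lies inside one at a lower threshold
  for (i in 2:length(bts)) {
    hi <- bts[[i]]$bursts; lo <- bts[[i - 1]]$bursts
    if (nrow(hi) == 0) next
    contained <- vapply(seq_len(nrow(hi)), function(b)
      any(lo$onset <= hi$onset[b] & lo$offset >= hi$offset[b]), logical(1))
    expect_true(all(contained))
  }
})

test_that("burst sizes conserve density mass on well-separated bursts", {
  cfg <- quick_config(n_electrodes = 60, duration = 600,
                      background_rate = 0, burst_ibi_mean = 15,
                      burst_duration_mean = 0.4,
                      spikes_per_burst_per_electrode = 10,
                      participation_prob = 0.8)
  s <- simulate_culture(cfg, seed = 12)
  d <- spike_density(s)
  bt <- detect_network_bursts(d, n_active = 60)
  expect_equal(sum(bt$bursts$size), n_spikes(s), tolerance = 0.05)
  expect_lte(sum(bt$bursts$size), n_spikes(s) * 1.01)
})

test_that("threshold scaling follows the active-electrode count", {
  d <- spike_density(c(1), duration = 2)
  bt <- detect_network_bursts(d, threshold = 10, n_active = 30)
  expect_equal(attr(bt, "effective_threshold"), 5)
  btf <- detect_network_bursts(d, threshold = 10, n_active = 30,
                               scaling = "fixed")
  expect_equal(attr(btf, "effective_threshold"), 10)
})

test_that("culture metrics compute the normalized rates", {
  trains <- lapply(1:10, function(i) seq(0.05 * i, by = 1,
                                         length.out = 1200))
  s <- spike_train_set(trains, 1200)
  expect_equal(n_spikes(s), 12000)
  empty_bt <- burst_train(data.frame(onset = numeric(0), offset = numeric(0),
                                     duration = numeric(0),
                                     size = numeric(0)), numeric(0))
  m <- culture_metrics(s, empty_bt, n_active_final = 10)
  expect_equal(m$mfr, 1.0)
  expect_equal(m$burst_rate, 0)
  expect_equal(m$pct_spikes_in_bursts, 0)
  expect_true(is.na(m$mean_burst_duration))
  # all spikes inside one big window -> 100%
  big <- burst_train(data.frame(onset = 0, offset = 1200, duration = 1200,
                                size = 12000), numeric(0))
  expect_equal(culture_metrics(s, big, n_active_final = 10)$
                 pct_spikes_in_bursts, 100)
  # missing final-DIV electrode count falls back with a warning
  expect_warning(culture_metrics(s, empty_bt, n_active_final = NULL),
                 "n_active_final")
})
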