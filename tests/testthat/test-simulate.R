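test_that("no sources means no spikes", {
  cfg <- quick_config(background_rate = 0, participation_prob = 0)
  s <- simulate_culture(cfg, seed = 1)
  expect_equal(n_spikes(s), 0L)
  expect_length(s$trains, 12)
})

test_that("background-only spike count matches the Poisson oracle", {
  cfg <- simulation_config(n_electrodes = 60, duration = 1200,
                           background_rate = 5, participation_prob = 0)
  s <- simulate_culture(cfg, seed = 7)
  expected <- 5 * 1200 * 60
  expect_lt(abs(n_spikes(s) - expected), 3 * sqrt(expected))
  # timestamps live inside the recording and are sorted per electrode
  expect_true(all(vapply(s$trains, function(t)
    !is.unsorted(t) && all(t >= 0 & t <= 1200), logical(1))))
})

test_that("planted burst count follows the gamma renewal process", {
  cfg <- quick_config(duration = 1200, burst_ibi_mean = 10,
                      burst_ibi_cv = 0.4)
  s <- simulate_culture(cfg, seed = 11)
  # independent renewal-count oracle: Monte-Carlo over gamma interval sums
  set.seed(99)
  counts <- replicate(2000, {
    iv <- rgamma(200, shape = 1 / 0.4^2, scale = 10 * 0.4^2)
    sum(cumsum(iv) < 1200)
  })
  expect_lt(abs(nrow(s$ground_truth$bursts) - mean(counts)),
            3 * sd(counts))
})

test_that("planted statistics are recoverable from ground truth", {
  cfg <- quick_config(duration = 1200, background_rate = 0.5,
                      burst_ibi_mean = 12, burst_duration_mean = 0.5,
                      burst_duration_cv = 0.2)
  s <- simulate_culture(cfg, seed = 3)
  gt <- s$ground_truth$bursts
  # burst rate within 3 SE of the renewal rate
  n_exp <- 1200 / 12
  expect_lt(abs(nrow(gt) - n_exp), 3 * sqrt(n_exp))
  # mean burst duration within 3 SE
  expect_lt(abs(mean(gt$duration[!gt$truncated]) - 0.5),
            3 * 0.5 * 0.2 / sqrt(nrow(gt)))
  # background rate: spikes outside all burst windows, per electrode
  tt <- unlist(s$trains, use.names = FALSE)
  edges <- as.vector(rbind(gt$onset, gt$offset))
  outside <- sum(findInterval(tt, edges) %% 2 == 0)
  expected_bg <- 0.5 * 1200 * 12
  expect_lt(abs(outside - expected_bg), 4 * sqrt(expected_bg))
})

test_that("identical seed and config give bit-identical output", {
  cfg <- quick_config()
  a <- simulate_culture(cfg, seed = 5)
  b <- simulate_culture(cfg, seed = 5)
  expect_identical(a$trains, b$trains)
  expect_identical(a$ground_truth$bursts, b$ground_truth$bursts)
  d <- simulate_culture(cfg, seed = 6)
  expect_false(identical(a$trains, d$trains))
})

test_that("bursts reaching past the recording end are truncated and flagged", {
  cfg <- quick_config(duration = 30, burst_ibi_mean = 9.5,
                      burst_duration_mean = 2, burst_duration_cv = 0,
                      background_rate = 0)
  found <- FALSE
  for (seed in 1:30) {
    s <- simulate_culture(cfg, seed = seed)
    gt <- s$ground_truth$bursts
    expect_true(all(gt$offset <= 30 + 1e-9))
    if (any(gt$truncated)) found <- TRUE
  }
  expect_true(found)
  # too-short recording raises the warning flag, not an error
  s2 <- simulate_culture(quick_config(duration = 5, burst_ibi_mean = 20),
                         seed = 1)
  expect_true("duration_shorter_than_expected_ibi" %in%
                s2$ground_truth$warning_flags)
})

test_that("study simulation does the longitudinal bookkeeping", {
  study <- simulate_study(default_presets(duration = 60, n_electrodes = 6),
                          n_cultures = c(control = 3, deficient = 3),
                          seed = 2, heterogeneity_sd = 0)
  expect_length(study, 2 * 4 * 3)
  meta <- do.call(rbind, lapply(study, function(s)
    data.frame(culture = s$metadata$culture, cond = s$metadata$condition,
               div = s$metadata$div)))
  expect_equal(sort(unique(meta$div)), c(10, 13, 15, 17))
  expect_equal(length(unique(meta$culture)), 6)
  # same master seed reproduces the whole study; another seed does not
  study2 <- simulate_study(default_presets(duration = 60, n_electrodes = 6),
                           n_cultures = c(control = 3, deficient = 3),
                           seed = 2, heterogeneity_sd = 0)
  expect_identical(lapply(study, `[[`, "trains"),
                   lapply(study2, `[[`, "trains"))
  expect_error(simulate_study(n_cultures = c(control = 1, deficient = 5)),
               "at least 2")
})

test_that("condition presets are ordered as the phenotype requires", {
  p <- default_presets()
  # deficient at DIV 13: lower burst and background rates than control
  expect_lt(1 / p$deficient$`13`$burst_ibi_mean,
            1 / p$control$`13`$burst_ibi_mean)
  expect_lt(p$deficient$`13`$background_rate,
            p$control$`13`$background_rate)
  # deficient at DIV 17: strictly more irregular burst timing
  expect_gt(p$deficient$`17`$burst_ibi_cv, p$control$`17`$burst_ibi_cv)
  # planted ground truth reflects the burst-rate multiplier at DIV 13
  ctrl <- simulate_culture(p$control$`13`, seed = 21)
  defi <- simulate_culture(p$deficient$`13`, seed = 22)
  expect_lt(nrow(defi$ground_truth$bursts),
            nrow(ctrl$ground_truth$bursts))
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(participation_prob = 1.2))
  expect_error(simulation_config(burst_ibi_mean = 0.3,
                                 burst_duration_mean = 0.5),
               "must exceed")
  expect_error(simulation_config(duration = -1))
})

test_that("raw synthesis renders offset, noise and waveforms faithfully", {
  empty <- sts(rep(list(numeric(0)), 2), duration = 1)
  rec <- synthesize_raw(empty, noise_sd = 0, dc_offset = 3,
                        sampling_rate = 10000, seed = 1)
  expect_true(all(rec$voltage == 3))
  # Gaussian noise: median absolute value = 0.6745 * sd
  rec2 <- synthesize_raw(sts(rep(list(numeric(0)), 4), duration = 10),
                         noise_sd = 2, sampling_rate = 10000, seed = 2)
  expect_equal(median(abs(rec2$voltage)), 2 * 0.6745, tolerance = 0.02)
  # planted spikes survive the full detection chain
  set.seed(3)
  plant <- lapply(1:2, function(i) sort(runif(10, 0.5, 9.5)))
  rec3 <- synthesize_raw(sts(plant, duration = 10),
                         waveform_amplitude = 50, noise_sd = 2, seed = 3)
  det <- detect_spikes_pipeline(rec3)
  for (i in 1:2) {
    hits <- vapply(plant[[i]], function(t)
      any(abs(det$trains[[i]] - t) <= 0.001), logical(1))
    expect_gte(sum(hits), 9)
  }
})
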