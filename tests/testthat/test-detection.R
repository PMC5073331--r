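rms_amp <- function(x) sqrt(2 * mean(x^2))   # amplitude of a pure tone

test_that("high-pass filter removes DC and low frequencies, keeps spikes band", {
  fs <- 10000
  t <- (0:49999) / fs
  rec <- raw_recording(rbind(rep(10, length(t)),
                             sin(2 * pi * 10 * t),
                             sin(2 * pi * 1000 * t)), fs)
  f <- highpass_filter(rec)
  mid <- 10000:40000
  expect_lt(max(abs(f$voltage[1, mid])), 1e-6)            # DC gone
  expect_lt(rms_amp(f$voltage[2, mid]), 0.01)             # 10 Hz: > 99% out
  expect_equal(rms_amp(f$voltage[3, mid]), 1, tolerance = 0.01)  # 1 kHz kept
  expect_error(highpass_filter(rec, detection_params(highpass_cutoff = 6000)),
               "Nyquist")
})

test_that("offset correction centers each channel and is idempotent", {
  v <- rbind(rep(5, 1000), rnorm(1000) + 3)
  rec <- raw_recording(v, 1000)
  oc <- offset_correct(rec)
  expect_true(all(oc$voltage[1, ] == 0))
  expect_equal(median(oc$voltage[2, ]), 0)
  expect_equal(offset_correct(oc)$voltage, oc$voltage)
})

test_that("threshold formula is f * median(|signal|) * 1.5", {
  # median(|x|) = 2 exactly
  x <- c(-3, -2, -1, 1, 2, 3)
  expect_equal(as.numeric(compute_threshold(x)), 8 * 2 * 1.5)
  z <- compute_threshold(rep(0, 100))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "dead_channel"))
  # Gaussian noise: theta ~ 8 * 0.6745 * sd * 1.5
  set.seed(1)
  g <- rnorm(200000, sd = 2)
  expect_equal(as.numeric(compute_threshold(g)), 8 * 0.6745 * 2 * 1.5,
               tolerance = 0.01)
  # linearity: scaling the signal scales the threshold exactly
  expect_equal(as.numeric(compute_threshold(3.7 * x)),
               3.7 * as.numeric(compute_threshold(x)))
})

test_that("detection finds planted waveforms and rejects noise", {
  fs <- 10000
  noise <- sts(rep(list(numeric(0)), 2), duration = 10)
  rec <- synthesize_raw(noise, noise_sd = 2, sampling_rate = fs, seed = 4)
  det <- detect_spikes(offset_correct(rec))
  expect_equal(n_spikes(det), 0L)

  one <- sts(list(2.5, numeric(0)), duration = 10)
  rec1 <- synthesize_raw(one, waveform_amplitude = 50, noise_sd = 2,
                         sampling_rate = fs, seed = 5)
  det1 <- detect_spikes_pipeline(rec1)
  expect_length(det1$trains[[1]], 1)
  expect_lt(abs(det1$trains[[1]] - 2.5), 0.001)

  # 100 isolated planted spikes: >= 95 recovered, <= 2 false positives
  set.seed(6)
  t100 <- sort(runif(200, 1, 59))
  t100 <- t100[c(TRUE, diff(t100) > 0.010)][1:100]
  rec100 <- synthesize_raw(sts(list(t100), duration = 60),
                           waveform_amplitude = 60, noise_sd = 2,
                           sampling_rate = fs, seed = 6)
  det100 <- detect_spikes_pipeline(rec100)
  d <- det100$trains[[1]]
  hits <- vapply(t100, function(tt) any(abs(d - tt) <= 0.001), logical(1))
  matched <- vapply(d, function(tt) any(abs(t100 - tt) <= 0.001), logical(1))
  expect_gte(sum(hits), 95)
  expect_lte(sum(!matched), 2)
})

test_that("detection is translation-equivariant in time", {
  fs <- 10000
  carrier <- function(n) 2 * sin(2 * pi * 1000 * (0:(n - 1)) / fs)
  tmpl <- meaburst:::spike_template(fs)
  place <- function(x, t0) {
    c0 <- round(t0 * fs) + 1
    ix <- seq(c0 - tmpl$peak_index + 1, length.out = length(tmpl$shape))
    x[ix] <- x[ix] + 50 * tmpl$shape
    x
  }
  n <- 20000
  base_times <- c(0.5, 0.9, 1.4)
  shift <- 0.2   # whole number of 1 kHz carrier periods
  x1 <- Reduce(place, base_times, carrier(n))
  x2 <- Reduce(place, base_times + shift, carrier(n))
  d1 <- detect_spikes(raw_recording(matrix(x1, 1), fs))
  d2 <- detect_spikes(raw_recording(matrix(x2, 1), fs))
  expect_equal(d2$trains[[1]], d1$trains[[1]] + shift, tolerance = 1e-9)
})

test_that("lowering the gain factor never loses spikes", {
  rec <- synthesize_raw(sts(list(sort(runif(20, 1, 19))), duration = 20),
                        waveform_amplitude = 40, noise_sd = 2,
                        sampling_rate = 10000, seed = 7)
  rec <- offset_correct(highpass_filter(rec))
  counts <- vapply(c(8, 6, 4), function(f)
    n_spikes(detect_spikes(rec, detection_params(gain_factor = f))),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("active-electrode selection applies the rate criteria strictly", {
  trains <- list(low = seq(0, 1199, length.out = 50),        # 0.042 Hz
                 edge = seq(0, 1199, length.out = 121),      # 0.1008 Hz
                 noisy = seq(0, 1199.9, by = 1 / 300))       # 300 Hz
  s <- spike_train_set(trains, 1200)
  act <- select_active(s, min_rate = 0.1, max_rate = 100)
  expect_equal(names(act$trains), "edge")
  dropped <- attr(act, "dropped")
  expect_setequal(dropped$electrode, c("low", "noisy"))
  expect_equal(dropped$reason[dropped$electrode == "noisy"], "noisy")
  # exactly 0.1 Hz is not strictly above the criterion
  s2 <- spike_train_set(list(a = seq(0, 1199, length.out = 120),
                             b = seq(0, 1199, length.out = 200)), 1200)
  expect_equal(names(select_active(s2)$trains), "b")
  expect_error(select_active(spike_train_set(list(a = c(1, 2)), 1200)),
               "no active electrodes")
})
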