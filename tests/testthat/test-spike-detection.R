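fs <- 25000

# A biphasic event: a local extremum of height a at sample i and one of
# height b at sample j on a flat baseline.
pair_trace <- function(n, i, a, j, b) {
  x <- numeric(n)
  x[i] <- a
  x[j] <- b
  x
}

test_that("PTSD times a negative-first pair on its larger extremum", {
  x <- pair_trace(1000, 100, -10, 110, 8)
  sp <- detect_spikes_ptsd(x, fs, analysis_config(), noise_sd = 1)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$spike_time, 99 / fs)      # 0-based sample convention
  expect_equal(sp$amplitude, 18)            # peak-to-peak
})

test_that("PTSD is polarity-agnostic and follows the larger extremum", {
  x <- pair_trace(1000, 100, 8, 110, -10)   # positive-first
  sp <- detect_spikes_ptsd(x, fs, analysis_config(), noise_sd = 1)
  expect_equal(sp$spike_time, 109 / fs)     # larger |amplitude| is second
  expect_equal(sp$amplitude, 18)
})

test_that("sub-threshold pairs and same-sign pairs are rejected", {
  cfg <- analysis_config()   # k = 9
  x <- pair_trace(1000, 100, -5, 110, 3)    # ptp 8 < 9
  expect_equal(nrow(detect_spikes_ptsd(x, fs, cfg, noise_sd = 1)), 0)
  x2 <- pair_trace(1000, 100, 10, 110, 8)   # same sign
  expect_equal(nrow(detect_spikes_ptsd(x2, fs, cfg, noise_sd = 1)), 0)
})

test_that("extrema further apart than the peak lifetime are not paired", {
  # 1 ms at 25 kHz = 25 samples; separation 30 samples
  x <- pair_trace(1000, 100, -10, 130, 8)
  expect_equal(nrow(detect_spikes_ptsd(x, fs, analysis_config(), noise_sd = 1)), 0)
  # and exactly at the lifetime it is paired
  x2 <- pair_trace(1000, 100, -10, 125, 8)
  expect_equal(nrow(detect_spikes_ptsd(x2, fs, analysis_config(), noise_sd = 1)), 1)
})

test_that("the refractory period suppresses a second event within 1.6 ms", {
  # events at samples 100 and 120 (0.8 ms apart), a third at 200 (4 ms later)
  x <- numeric(1000)
  x[100] <- -10; x[105] <- 8
  x[120] <- -10; x[125] <- 8
  x[200] <- -10; x[205] <- 8
  sp <- detect_spikes_ptsd(x, fs, analysis_config(), noise_sd = 1)
  expect_equal(sp$spike_time, c(99, 199) / fs)
  expect_true(all(diff(sp$spike_time) >= analysis_config()$refractory))
})

test_that("events overlapping a masked interval are rejected", {
  x <- pair_trace(2000, 1000, -10, 1010, 8)  # ~40 ms
  mask <- data.frame(start = 0.039, end = 0.041)
  sp <- detect_spikes_ptsd(x, fs, analysis_config(), noise_sd = 1, masked = mask)
  expect_equal(nrow(sp), 0)
  far <- data.frame(start = 0.07, end = 0.08)
  expect_equal(nrow(detect_spikes_ptsd(x, fs, analysis_config(), noise_sd = 1,
                                       masked = far)), 1)
})

test_that("detection count is non-increasing in the threshold multiplier k", {
  set.seed(21)
  x <- rnorm(fs)  # 1 s of unit noise
  spikes_at <- seq(1000, 24000, by = 500)
  for (i in spikes_at) { x[i] <- x[i] - 6; x[i + 8] <- x[i + 8] + 5 }
  n_at <- vapply(c(5, 7.5, 9, 12), function(k)
    nrow(detect_spikes_ptsd(x, fs, analysis_config(threshold_k = k),
                            noise_sd = 1)), numeric(1))
  expect_true(all(diff(n_at) <= 0))
})

test_that("noise estimators behave: MAD ignores spikes, constant signal warns", {
  set.seed(5)
  x <- rnorm(50000)
  xs <- x; xs[seq(100, 49000, by = 300)] <- 40  # sparse large spikes
  expect_lt(abs(estimate_noise_sd(x) - 1), 0.03)
  expect_lt(abs(estimate_noise_sd(xs) - 1), 0.05)       # robust
  expect_gt(estimate_noise_sd(xs, "global_sd"), 1.5)    # inflated
  expect_warning(s0 <- estimate_noise_sd(rep(2, 100)), "constant")
  expect_equal(s0, 0)
})

test_that("detect_spikes skips reference electrodes and keeps the mask", {
  m <- electrode_map(c("C-01", "C-02"), c("C", "C"),
                     is_reference = c(FALSE, TRUE))
  sig <- matrix(rnorm(2 * fs / 5), 2)
  sig[, 1000] <- -10; sig[, 1010] <- 8
  rec <- raw_recording(sig, fs, m)
  attr(rec, "masked") <- data.frame(start = 0.1, end = 0.11)
  tab <- detect_spikes(rec, analysis_config())
  expect_true(all(tab$spikes$electrode_id == "C-01"))
  expect_equal(tab$masked, data.frame(start = 0.1, end = 0.11))
})

test_that("render -> filter -> detect recovers seeded ground truth", {
  sim <- simulate_spike_trains(network_sim_config(seed = 6), 5,
                               electrode_map = tiny_map(1))
  rec <- render_raw_signal(sim$table, noise_sd = 5, amplitude = 60, seed = 7)
  det <- detect_spikes(bandpass_notch_filter(rec))
  sc <- score_spike_detection(sim$truth$spikes,
                              split(det$spikes$spike_time, det$spikes$electrode_id))
  expect_gt(sc$recall, 0.9)
  expect_gt(sc$precision, 0.9)
  # refractory invariant per electrode
  for (id in unique(det$spikes$electrode_id))
    expect_true(all(diff(det$spikes$spike_time[det$spikes$electrode_id == id]) >=
                      analysis_config()$refractory - 1e-12))
})

test_that("score_spike_detection matches one-to-one", {
  sc <- score_spike_detection(c(1, 2, 3), c(1.0002, 1.0004, 2.5), tol = 1e-3)
  expect_equal(sc$n_matched, 1)  # both detections near t=1, only one credited
  expect_equal(sc$recall, 1 / 3)
  expect_equal(sc$precision, 1 / 3)
  sc2 <- score_spike_detection(numeric(0), numeric(0))
  expect_true(is.na(sc2$recall) && is.na(sc2$precision))
})
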