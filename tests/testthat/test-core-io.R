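test_that("electrode_map validates labels and uniqueness", {
  m <- electrode_map(c("a", "b"), c("C", "H1"))
  expect_s3_class(m, "electrode_map")
  expect_error(electrode_map(c("a", "a"), c("C", "C")), "duplicated")
  expect_error(electrode_map("a", "X9"), "unknown node label")
})

test_that("standard layout has 13/13/12/12 node electrodes plus 9 tunnel", {
  m <- standard_electrode_map()
  expect_equal(nrow(m), 59)
  expect_equal(as.vector(table(factor(m$node_label, levels = NODE_LEVELS))),
               c(13, 13, 12, 12, 9))
  expect_false(anyDuplicated(m$electrode_id) > 0)
})

test_that("raw_recording rejects shape mismatch and bad stimulation times", {
  m <- tiny_map(1)
  sig <- matrix(0, 4, 100)
  rec <- raw_recording(sig, 1000, m)
  expect_equal(recording_duration(rec), 0.1)
  expect_error(raw_recording(matrix(0, 3, 100), 1000, m), "shape mismatch")
  expect_error(raw_recording(sig, 1000, m, stimulation_times = c(0.05, 0.05)),
               "strictly increasing")
  expect_error(raw_recording(sig, 1000, m, stimulation_times = 0.5),
               "outside")
})

test_that("spike_table validates ordering and map membership", {
  m <- tiny_map(1)
  df <- data.frame(electrode_id = c("C-01", "C-01"), spike_time = c(0.2, 0.1))
  expect_error(spike_table(df, 1, electrode_map = m), "non-increasing.*C-01")
  df2 <- data.frame(electrode_id = "Z-99", spike_time = 0.1)
  expect_error(spike_table(df2, 1, electrode_map = m), "absent from the map")
  tab <- spike_table(data.frame(electrode_id = "C-01", spike_time = 0.5), 1,
                     electrode_map = m)
  expect_s3_class(tab, "spike_table")
})

test_that("unmasked_duration merges overlapping masked intervals", {
  tab <- spike_table(data.frame(electrode_id = character(0),
                                spike_time = numeric(0)), 10,
                     masked = data.frame(start = c(1, 1.5, 5), end = c(2, 3, 6)))
  # [1,3] merged (2 s) plus [5,6] (1 s) -> 10 - 3 = 7
  expect_equal(meacircuit:::unmasked_duration(tab), 7)
})

test_that("recording round-trips through the native container", {
  m <- tiny_map(1)
  sig <- matrix(rnorm(4 * 50), 4, 50)
  rec <- raw_recording(sig, 25000, m, stimulation_times = 1e-3,
                       metadata = list(div = 28, network_id = "n1"))
  p <- tempfile(fileext = ".rds")
  save_recording(rec, p)
  back <- load_recording(p)
  expect_equal(back$samples, rec$samples)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(back$stimulation_times, rec$stimulation_times)
  expect_equal(back$metadata$div, 28)
  unlink(p)
})

test_that("load_recording reports missing fields as format errors", {
  p <- tempfile(fileext = ".rds")
  saveRDS(list(signals = matrix(0, 1, 1)), p)
  expect_error(load_recording(p), "format error.*sampling_rate")
  unlink(p)
  expect_error(load_recording("/nonexistent/file.rds"), "not found")
})

test_that("spike table CSV round-trip preserves times, duration and mask", {
  m <- tiny_map(1)
  tab <- spike_table(
    data.frame(electrode_id = c("C-01", "H1-01"),
               spike_time = c(0.1 + 1e-12, 0.25), amplitude = c(-42.5, NA)),
    duration = 3.5, electrode_map = m,
    masked = data.frame(start = 1, end = 1.015))
  p <- tempfile(fileext = ".csv")
  save_spike_table(tab, p)
  back <- load_spike_table(p, electrode_map = m)
  expect_identical(back$spikes$spike_time, tab$spikes$spike_time)
  expect_identical(back$spikes$amplitude, tab$spikes$amplitude)
  expect_identical(back$duration, 3.5)
  expect_equal(back$masked, tab$masked)
  unlink(p)
})

test_that("analysis_config carries study defaults and rejects unknown keys", {
  cfg <- analysis_config()
  expect_equal(cfg$low_cut, 300)
  expect_equal(cfg$high_cut, 3000)
  expect_equal(cfg$threshold_k, 9)
  expect_equal(cfg$refractory, 0.0016)
  expect_equal(cfg$min_spikes, 4)
  expect_equal(cfg$max_isi, 0.1)
  expect_equal(cfg$nb_fraction, 0.1)
  expect_equal(cfg$edge_threshold, 0.1)
  expect_equal(cfg$min_diameter, 5)
  expect_error(analysis_config(bogus_param = 1), "unknown parameter")
  expect_error(analysis_config(low_cut = 5000), "low_cut < high_cut")
  expect_error(analysis_config(refractory = 1e-5), "refractory")
})

test_that("config YAML round-trip is lossless", {
  cfg <- analysis_config(threshold_k = 7.5, corr_bin = 0.025)
  p <- tempfile(fileext = ".yaml")
  write_config(cfg, p)
  back <- read_config(p)
  expect_equal(unclass(back), unclass(cfg))
  unlink(p)
})
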