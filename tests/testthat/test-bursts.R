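test_that("detect_bursts finds maximal runs of at least 4 close spikes", {
  times <- c(0, 0.01, 0.02, 0.03, 1, 1.01, 1.02, 2)
  b <- detect_bursts(times, threshold = 0.05)
  expect_equal(nrow(b), 1)            # second group has only 3 spikes
  expect_equal(b$start, 0)
  expect_equal(b$end, 0.03)
  expect_equal(b$n_spikes, 4L)
  # whole train one burst (exactly representable times)
  b2 <- detect_bursts((0:10) * 0.25, threshold = 0.25)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$n_spikes, 11L)
  # ISI exactly at the threshold counts as within the burst
  b3 <- detect_bursts(c(0, 0.25, 0.5, 0.75), threshold = 0.25)
  expect_equal(b3$n_spikes, 4L)
})

test_that("detect_bursts agrees with the brute-force oracle on random trains", {
  set.seed(31)
  for (r in 1:200) {
    n <- sample(0:20, 1)
    times <- sort(runif(n, 0, 2))
    times <- times[c(TRUE, diff(times) > 1e-9)]
    thr <- runif(1, 0.02, 0.3)
    got <- detect_bursts(times, thr)
    want <- brute_bursts(times, thr)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_spikes, want$n_spikes)
  }
})

test_that("logISI threshold separates a clearly bimodal ISI distribution", {
  set.seed(8)
  # 30 bursts of 8 spikes at ~5 ms ISI, separated by pauses of at least 0.5 s
  starts <- cumsum(c(1, 0.5 + rexp(29, 1 / 2)))
  times <- sort(unlist(lapply(starts, function(s)
    s + cumsum(c(0, 0.004 + runif(7, 0, 0.002))))))
  thr <- isi_threshold_logisi(times)
  expect_gt(thr, 0.006)        # above every intra-burst ISI
  expect_lte(thr, 0.1)         # at or below the cap
  b <- detect_bursts(times, thr)
  expect_equal(nrow(b), 30)
  expect_equal(sum(b$n_spikes), 240)
})

test_that("logISI threshold falls back to 100 ms for unimodal trains", {
  set.seed(9)
  pois <- cumsum(rexp(200, 5))
  expect_equal(isi_threshold_logisi(pois), 0.1)
  expect_true(is.na(isi_threshold_logisi(c(1))))
})

test_that("active electrode rule is >= 0.1 Hz over unmasked time", {
  m <- tiny_map(1)
  trains <- list("C-01" = seq(0.5, 99.5, by = 10),   # 10 spikes / 100 s = 0.1 Hz
                 "H1-01" = c(1, 2, 3),               # 0.03 Hz
                 "H2-01" = seq(0.5, 99.5, by = 1))   # 1 Hz
  tab <- table_from_lists(trains, 100, m)
  expect_setequal(active_electrodes(tab), c("C-01", "H2-01"))
})

test_that("network bursts honour the ceil(10% of active) rule inclusively", {
  m <- tiny_map(5)                     # 20 electrodes
  active <- m$electrode_id             # need = ceil(0.1 * 20) = 2
  mk <- function(ids, t0) data.frame(
    electrode_id = ids, start = t0 + seq(0, by = 0.01, length.out = length(ids)),
    end = t0 + 0.05 + seq(0, by = 0.01, length.out = length(ids)),
    n_spikes = 5L, stringsAsFactors = FALSE)
  bursts <- rbind(mk(c("C-01", "H1-01"), 0),   # 2 electrodes: qualifies
                  mk("C-02", 5))               # 1 electrode: rejected
  nbs <- detect_network_bursts(bursts, active, m)
  expect_equal(nrow(nbs), 1)
  expect_equal(nbs$n_electrodes, 2L)
  expect_equal(nbs$start, 0)
})

test_that("overlapping qualifying events are merged so NBs never overlap", {
  m <- tiny_map(5)
  active <- m$electrode_id
  bursts <- data.frame(
    electrode_id = c("C-01", "C-02", "H1-01", "H1-02"),
    start = c(0, 0.05, 0.30, 0.35),
    end = c(1.0, 0.10, 0.40, 0.45),   # first burst spans over the second group
    n_spikes = 5L, stringsAsFactors = FALSE)
  nbs <- detect_network_bursts(bursts, active, m)
  expect_equal(nrow(nbs), 1)
  expect_equal(nbs$start, 0)
  expect_equal(nbs$end, 1.0)
  expect_equal(nbs$n_electrodes, 4L)
  expect_equal(nbs$onset_C, 0)
  expect_equal(nbs$onset_H1, 0.30)
})

test_that("classify_propagation handles spans, ties and missing nodes", {
  cls <- function(v) classify_propagation(setNames(v, NODE_ORDER))
  full <- cls(c(0, 0.02, 0.04, 0.06))
  expect_equal(full$initiation_node, "C")
  expect_equal(full$span, 4L)
  expect_true(full$feedforward)
  # backward ordering: no downstream chain
  back <- cls(c(0.06, 0.04, 0.02, 0))
  expect_equal(back$initiation_node, "H3")
  expect_equal(back$span, 1L)
  expect_false(back$feedforward)
  # skipped node truncates the span
  skip <- cls(c(0, 0.02, NA, 0.05))
  expect_equal(skip$span, 2L)
  # tie within one sample resolves upstream and is flagged
  tie <- cls(c(0.01, 0.01 + 1e-6, NA, NA))
  expect_equal(tie$initiation_node, "C")
  expect_true(tie$tied)
  # mid-circuit initiation
  mid <- cls(c(NA, 0, 0.02, 0.04))
  expect_equal(mid$initiation_node, "H1")
  expect_equal(mid$span, 3L)
  expect_false(mid$feedforward)
  expect_error(cls(rep(NA_real_, 4)), "no per-node onsets")
})

test_that("propagation_summary percentages total 100 and rates include zeros", {
  m <- tiny_map(2)
  nbs <- data.frame(initiation_node = c("C", "C", "H1"), span = c(4L, 1L, 2L))
  bursts <- data.frame(electrode_id = c("C-01", "C-01", "H1-01"),
                       start = c(1, 10, 20), end = c(1.1, 10.1, 20.1),
                       n_spikes = 5L)
  ps <- propagation_summary(nbs, bursts, m, duration = 120)
  expect_equal(sum(ps$by_initiation_span$percent), 100)
  expect_equal(sum(ps$by_initiation_span$count), 3)
  # C-01 has 2 bursts in 2 min (1/min), C-02 none -> median 0.5
  expect_equal(unname(ps$node_burst_rate["C"]), 0.5)
  expect_equal(unname(ps$node_burst_rate["H2"]), 0)
})
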