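# Shared fixtures and independent oracles for the test suite.

# Small map: n electrodes per node, no tunnel electrodes.
tiny_map <- function(n = 2) standard_electrode_map(rep(n, 4), n_tunnel = 0)

# Independent brute-force burst oracle: enumerate every contiguous window of
# spikes, keep windows whose ISIs are all <= thr and that cannot be extended
# on either side (maximality), then apply the minimum-size rule. Quadratic,
# but algorithmically unrelated to the run-length implementation under test.
brute_bursts <- function(times, thr, min_spikes = 4) {
  n <- length(times)
  out <- NULL
  if (n >= min_spikes) for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1 < min_spikes) next
    if (any(diff(times[i:j]) > thr)) next
    left_ok <- i == 1 || times[i] - times[i - 1] > thr
    right_ok <- j == n || times[j + 1] - times[j] > thr
    if (left_ok && right_ok)
      out <- rbind(out, data.frame(start = times[i], end = times[j],
                                   n_spikes = j - i + 1L))
  }
  if (is.null(out))
    data.frame(start = numeric(0), end = numeric(0), n_spikes = integer(0))
  else out
}

# Spike table with given per-electrode spike-time lists on a tiny map.
table_from_lists <- function(trains, duration, map = NULL) {
  if (is.null(map)) {
    ids <- names(trains)
    map <- electrode_map(ids, sub("-.*", "", ids))
  }
  df <- do.call(rbind, lapply(names(trains), function(id)
    if (length(trains[[id]]))
      data.frame(electrode_id = id, spike_time = sort(trains[[id]]),
                 stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(electrode_id = character(0), spike_time = numeric(0))
  spike_table(df, duration, electrode_map = map)
}

# Calibration used throughout: 2046 px spanning 2803 um.
UM_PER_PX <- 2803 / 2046
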