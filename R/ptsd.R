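#' Robust noise-SD estimate for a filtered channel
#'
#' The detection threshold is a multiple of the channel noise SD. The
#' default estimator is the scaled median absolute deviation,
#' `median(|x - median(x)|) / 0.6745`, which is consistent for Gaussian noise
#' and nearly unaffected by the spikes themselves; `global_sd` (the plain
#' sample SD) is inflated by spikes and provided for comparison.
#'
#' @param x numeric signal (>= 1000 samples recommended).
#' @param method `"mad"` or `"global_sd"`.
#' @return Noise SD in the units of `x`; 0 (with a warning) for a constant
#'   signal, which disables detection on that channel.
#' @export
estimate_noise_sd <- function(x, method = c("mad", "global_sd")) {
  method <- match.arg(method)
  s <- switch(method, mad = stats::mad(x), global_sd = stats::sd(x))
  if (is.na(s)) s <- 0
  if (s == 0) warning("estimate_noise_sd: constant signal, returning 0")
  s
}

#' Precise timing spike detection (PTSD) on one channel
#'
#' Scans a band-pass filtered trace for pairs of opposite-sign local extrema
#' separated by at most the peak lifetime (1 ms) whose peak-to-peak
#' amplitude reaches `k` times the channel noise SD. The spike time is the
#' time of the extremum with the larger absolute amplitude, and after each
#' accepted spike no further spike is accepted within the refractory period
#' (1.6 ms). Both polarities (negative-first and positive-first) are
#' admitted. Events overlapping a masked interval are rejected entirely.
#'
#' @param x numeric filtered signal for one channel.
#' @param sampling_rate sampling rate in Hz.
#' @param config an [analysis_config] (`threshold_k`, `peak_lifetime`,
#'   `refractory`, `noise_sd_method`).
#' @param noise_sd optional precomputed noise SD.
#' @param masked optional data frame of masked intervals (`start`, `end`, s).
#' @return Data frame with `spike_time` (s, 0-based sample convention) and
#'   `amplitude` (peak-to-peak, same units as `x`).
#' @export
detect_spikes_ptsd <- function(x, sampling_rate, config = analysis_config(),
                               noise_sd = NULL, masked = NULL) {
  if (is.null(noise_sd))
    noise_sd <- suppressWarnings(estimate_noise_sd(x, config$noise_sd_method))
  empty <- data.frame(spike_time = numeric(0), amplitude = numeric(0))
  if (noise_sd == 0) return(empty)
  res <- ptsd_scan(as.numeric(x), config$threshold_k * noise_sd,
                   as.integer(round(config$peak_lifetime * sampling_rate)),
                   as.integer(round(config$refractory * sampling_rate)))
  if (!length(res$index)) return(empty)
  out <- data.frame(spike_time = (res$index - 1) / sampling_rate,
                    amplitude = res$amplitude)
  if (!is.null(masked) && nrow(masked)) {
    lf <- config$peak_lifetime
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(masked)))
      keep <- keep & !(out$spike_time + lf > masked$start[i] &
                         out$spike_time - lf < masked$end[i])
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Detect spikes on every channel of a recording
#'
#' Runs [detect_spikes_ptsd] per channel with a per-channel noise estimate
#' and assembles the results into a [spike_table].
#'
#' @param rec a band-pass filtered [raw_recording].
#' @param config an [analysis_config].
#' @return A [spike_table] carrying the recording's electrode map, metadata
#'   and any blanking mask.
#' @export
detect_spikes <- function(rec, config = analysis_config()) {
  validate_raw_recording(rec)
  mask <- attr(rec, "masked")
  ids <- rec$electrode_map$electrode_id
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    if (rec$electrode_map$is_reference[k]) next
    sp <- detect_spikes_ptsd(rec$samples[k, ], rec$sampling_rate, config,
                             masked = mask)
    if (nrow(sp))
      rows[[k]] <- data.frame(electrode_id = ids[k],
                              spike_time = sp$spike_time,
                              amplitude = sp$amplitude,
                              stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  spikes <- if (length(rows)) do.call(rbind, rows)
  else data.frame(electrode_id = character(0), spike_time = numeric(0),
                  amplitude = numeric(0))
  spike_table(spikes, recording_duration(rec), electrode_map = rec$electrode_map,
              metadata = rec$metadata,
              masked = mask %||% data.frame(start = numeric(0), end = numeric(0)))
}

#' Score detected spikes against ground truth
#'
#' Greedy one-to-one matching: true spikes are visited in time order and
#' matched to the nearest unused detection within the tolerance. Recall is
#' matched / true, precision matched / detected.
#'
#' @param truth,detected sorted spike-time vectors (s) for one channel, or
#'   named lists of them for many channels (pooled before scoring).
#' @param tol matching tolerance in seconds.
#' @return List with `recall`, `precision`, `n_true`, `n_detected`,
#'   `n_matched`.
#' @export
score_spike_detection <- function(truth, detected, tol = 1e-3) {
  score_one <- function(tr, det) {
    if (!length(tr) || !length(det)) return(0L)
    used <- rep(FALSE, length(det))
    m <- 0L
    for (t in tr) {
      d <- abs(det - t)
      d[used] <- Inf
      j <- which.min(d)
      if (d[j] <= tol) { used[j] <- TRUE; m <- m + 1L }
    }
    m
  }
  if (is.list(truth)) {
    chans <- union(names(truth), names(detected))
    n_true <- sum(lengths(truth))
    n_det <- sum(lengths(detected))
    n_m <- sum(vapply(chans, function(id)
      score_one(truth[[id]] %||% numeric(0), detected[[id]] %||% numeric(0)),
      integer(1)))
  } else {
    n_true <- length(truth); n_det <- length(detected)
    n_m <- score_one(truth, detected)
  }
  list(recall = if (n_true) n_m / n_true else NA_real_,
       precision = if (n_det) n_m / n_det else NA_real_,
       n_true = n_true, n_detected = n_det, n_matched = n_m)
}
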