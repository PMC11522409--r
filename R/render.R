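#' Default biphasic spike waveform template
#'
#' Negative-first biphasic waveform (the dominant extracellular spike shape
#' near the soma) with a 0.6 ms trough-to-peak interval, normalised to unit
#' peak-to-peak amplitude. The returned vector samples the template at the
#' recording rate; the attribute `trough_sample` marks the sample of the
#' trough so that rendered spikes can be aligned on their ground-truth time.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param trough_to_peak trough-to-peak interval (s).
#' @param duration total template duration (s), must be <= 2 ms.
#' @return Numeric vector with attribute `trough_sample`.
#' @export
spike_template <- function(sampling_rate = 25000, trough_to_peak = 6e-4,
                           duration = 1.6e-3) {
  if (duration > 2e-3) stop("spike_template: duration must be <= 2 ms")
  t <- seq(0, duration, by = 1 / sampling_rate)
  t_tr <- duration * 0.3
  t_pk <- t_tr + trough_to_peak
  w <- -exp(-((t - t_tr)^2) / (2 * (1.2e-4)^2)) +
    0.45 * exp(-((t - t_pk)^2) / (2 * (2.0e-4)^2))
  w <- w / (max(w) - min(w))
  structure(w, trough_sample = which.min(w))
}

#' Render a spike table into a raw voltage recording
#'
#' Each spike becomes a scaled copy of the waveform template (aligned so the
#' template trough falls on the spike time) added to white Gaussian noise at
#' the recording rate. Optional stimulation artifacts are added on every
#' channel as large exponential transients, emulating the slow saturating
#' tails that follow electrical stimulation.
#'
#' @param table a [spike_table] (its electrode map defines the channels).
#' @param noise_sd noise standard deviation in microvolts (> 0).
#' @param amplitude peak-to-peak spike amplitude in microvolts; used where
#'   the table has no per-spike amplitude.
#' @param template waveform from [spike_template].
#' @param sampling_rate sampling rate in Hz.
#' @param stim_spec optional list with `times` (s), `amplitude` (microvolts)
#'   and `tau` (decay time constant, s) describing stimulation artifacts.
#' @param seed RNG seed for the noise.
#' @return A [raw_recording] whose ground-truth spikes are recoverable.
#' @export
render_raw_signal <- function(table, noise_sd = 5, amplitude = 60,
                              template = NULL, sampling_rate = 25000,
                              stim_spec = NULL, seed = 1) {
  stopifnot(noise_sd > 0)
  if (is.null(template)) template <- spike_template(sampling_rate)
  map <- table$electrode_map
  if (is.null(map)) stop("render_raw_signal: spike table has no electrode map")
  n_samp <- round(table$duration * sampling_rate)
  ids <- map$electrode_id
  tl <- length(template)
  trough <- attr(template, "trough_sample")

  artifact <- NULL
  if (!is.null(stim_spec) && length(stim_spec$times)) {
    artifact <- numeric(n_samp)
    tt <- (seq_len(n_samp) - 1) / sampling_rate
    for (ts in stim_spec$times) {
      idx <- which(tt >= ts & tt < ts + 10 * stim_spec$tau)
      artifact[idx] <- artifact[idx] + stim_spec$amplitude *
        exp(-(tt[idx] - ts) / stim_spec$tau)
    }
  }

  sig <- with_local_seed(seed, {
    m <- matrix(0, nrow = length(ids), ncol = n_samp, dimnames = list(ids, NULL))
    truncated <- 0L
    for (k in seq_along(ids)) {
      ch <- rnorm(n_samp, 0, noise_sd)
      sel <- table$spikes$electrode_id == ids[k]
      st <- table$spikes$spike_time[sel]
      amp <- table$spikes$amplitude[sel]
      amp[is.na(amp)] <- amplitude
      for (j in seq_along(st)) {
        i0 <- round(st[j] * sampling_rate) + 1L - (trough - 1L)
        i1 <- i0 + tl - 1L
        s0 <- max(i0, 1L); s1 <- min(i1, n_samp)
        if (s1 < i1 || s0 > i0) truncated <- truncated + 1L
        if (s0 <= s1)
          ch[s0:s1] <- ch[s0:s1] + amp[j] * template[(s0 - i0 + 1L):(s1 - i0 + 1L)]
      }
      if (!is.null(artifact)) ch <- ch + artifact
      m[k, ] <- ch
    }
    if (truncated > 0)
      warning("render_raw_signal: ", truncated,
              " spike template(s) truncated at the recording edge")
    m
  })

  raw_recording(sig, sampling_rate, map,
                stimulation_times = if (is.null(stim_spec)) numeric(0)
                else stim_spec$times,
                metadata = table$metadata)
}
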