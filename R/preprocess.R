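#' Zero-phase band-pass and mains-notch filtering
#'
#' Applies a 4th-order Butterworth band-pass (300--3000 Hz by default) and a
#' second-order IIR notch at the mains frequency (50 Hz) to every channel,
#' each run forward-backward (zero-phase), so the filtered signal has no
#' group delay and spike times are not shifted. Band edges are the design
#' (single-pass) -3 dB points; the forward-backward pass squares the
#' magnitude response. Edge transients are controlled by odd-reflection
#' padding before each filter pass.
#'
#' @param rec a [raw_recording].
#' @param config an [analysis_config]; `filter_order`, `low_cut`, `high_cut`,
#'   `notch_freq` and `notch_q` are used.
#' @return The filtered [raw_recording] (same length and metadata).
#' @export
bandpass_notch_filter <- function(rec, config = analysis_config()) {
  validate_raw_recording(rec)
  fs <- rec$sampling_rate
  if (config$high_cut >= fs / 2)
    stop("bandpass_notch_filter: high_cut must be below the Nyquist frequency")
  bp <- signal::butter(config$filter_order,
                       c(config$low_cut, config$high_cut) / (fs / 2),
                       type = "pass")
  nt <- design_notch(config$notch_freq, fs, config$notch_q)
  out <- rec$samples
  for (k in seq_len(nrow(out))) {
    x <- filtfilt_reflect(bp$b, bp$a, out[k, ])
    out[k, ] <- filtfilt_reflect(nt$b, nt$a, x)
  }
  rec$samples <- out
  rec
}

# Second-order IIR notch (constrained-pole biquad). Quality factor Q sets
# the -3 dB bandwidth f0/Q.
design_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Forward-backward filtering with odd-reflection padding at both ends.
# Padding length is capped at n - 1; one second of samples is ample for the
# slowest (notch) transient at MEA sampling rates.
filtfilt_reflect <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1, 25000)
  if (pad > 0) {
    left <- 2 * x[1] - x[(pad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - pad)]
    xe <- c(left, x, right)
  } else xe <- x
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' SALPA: local-polynomial stimulation-artifact suppression
#'
#' Suppresses slow post-stimulus artifacts by fitting a local cubic
#' polynomial (a Savitzky-Golay fit of order `salpa_poly_order` over a
#' sliding window of half-width `salpa_halfwidth`) to each channel over the
#' post-stimulus epoch and subtracting it. Subtraction runs from the
#' stimulus until the fitted curve has stayed inside the noise band for a
#' full window (the fit-and-test rule); the signal outside artifact epochs
#' is untouched. Samples pegged against the amplifier rails are replaced by
#' linear interpolation before fitting so they cannot drag the fit.
#'
#' @param rec a [raw_recording] (typically band-pass filtered).
#' @param stim_times stimulation times (s); defaults to the recording's own.
#' @param config an [analysis_config].
#' @param noise_band residual tolerance in microvolts; by default 3 robust
#'   noise SDs estimated per channel from pre-stimulus data.
#' @param pegged_limit absolute voltage treated as railed (default `Inf`).
#' @return The corrected [raw_recording].
#' @export
salpa_subtract <- function(rec, stim_times = rec$stimulation_times,
                           config = analysis_config(), noise_band = NULL,
                           pegged_limit = Inf) {
  validate_raw_recording(rec)
  if (!length(stim_times)) return(rec)
  fs <- rec$sampling_rate
  hw <- round(config$salpa_halfwidth * fs)
  win <- 2 * hw + 1
  if (win < config$salpa_poly_order + 2)
    stop("salpa_subtract: fit window too short for polynomial order")
  n <- ncol(rec$samples)
  epoch <- round(config$salpa_epoch * fs)
  out <- rec$samples
  for (k in seq_len(nrow(out))) {
    x <- out[k, ]
    nb <- noise_band
    if (is.null(nb)) {
      pre <- x[seq_len(max(min(round(stim_times[1] * fs), n), win))]
      nb <- 3 * stats::mad(pre)
      if (nb == 0) nb <- 1e-9
    }
    for (ts in stim_times) {
      i0 <- floor(ts * fs) + 1L
      i1 <- min(i0 + epoch - 1L, n)
      if (i1 - i0 + 1 < win) next
      seg <- x[i0:i1]
      peg <- abs(seg) >= pegged_limit
      if (any(peg) && !all(peg)) {
        ok <- which(!peg)
        seg[peg] <- stats::approx(ok, seg[ok], xout = which(peg), rule = 2)$y
      }
      fit <- signal::sgolayfilt(seg, p = config$salpa_poly_order, n = win)
      # fit-and-test: subtract up to the end of the first full window over
      # which the fitted artifact stays inside the noise band
      inside <- abs(fit) <= nb
      run <- rle(inside)
      stop_at <- length(seg)
      pos <- cumsum(run$lengths)
      j <- which(run$values & run$lengths >= win)
      if (length(j)) stop_at <- pos[j[1]] - run$lengths[j[1]] + win - 1
      idx <- seq_len(stop_at)
      x[i0:i1][idx] <- seg[idx] - fit[idx]
    }
    out[k, ] <- x
  }
  rec$samples <- out
  rec
}

#' Blank data after each stimulus
#'
#' Removes the first `blank_after` seconds (15 ms by default) following every
#' stimulation time: spikes inside `[t, t + blank)` are dropped from spike
#' tables, samples are zeroed in raw recordings. The blanked intervals are
#' recorded as a mask so firing-rate denominators exclude them. The interval
#' is half-open: a spike at exactly `t + blank` is retained.
#'
#' @param x a [spike_table] or [raw_recording].
#' @param stim_times stimulation times (s).
#' @param blank blank duration in seconds.
#' @return Same class as `x`.
#' @export
blank_after_stimulus <- function(x, stim_times = NULL, blank = 0.015) {
  stopifnot(blank > 0)
  UseMethod("blank_after_stimulus")
}

#' @export
blank_after_stimulus.spike_table <- function(x, stim_times = NULL, blank = 0.015) {
  if (is.null(stim_times)) stim_times <- x$metadata$stimulation_times
  if (!length(stim_times)) return(x)
  t <- x$spikes$spike_time
  drop <- rep(FALSE, length(t))
  for (ts in stim_times) drop <- drop | (t >= ts & t < ts + blank)
  x$spikes <- x$spikes[!drop, , drop = FALSE]
  x$masked <- rbind(x$masked,
                    data.frame(start = stim_times, end = stim_times + blank))
  validate_spike_table(x)
  x
}

#' @export
blank_after_stimulus.raw_recording <- function(x, stim_times = NULL, blank = 0.015) {
  if (is.null(stim_times)) stim_times <- x$stimulation_times
  if (!length(stim_times)) return(x)
  fs <- x$sampling_rate; n <- ncol(x$samples)
  mask <- attr(x, "masked") %||% data.frame(start = numeric(0), end = numeric(0))
  for (ts in stim_times) {
    i0 <- floor(ts * fs) + 1L
    i1 <- min(ceiling((ts + blank) * fs), n)
    x$samples[, i0:i1] <- 0
  }
  attr(x, "masked") <- rbind(mask, data.frame(start = stim_times,
                                              end = stim_times + blank))
  x
}
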