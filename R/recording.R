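#' Raw multichannel MEA recording
#'
#' Container for a multichannel extracellular voltage recording sampled at a
#' fixed rate (25 kHz by default on the recording workstation used for these
#' cultures). Rows of `samples` are channels, in the order of the electrode
#' map; values are microvolts. Time is seconds throughout; sample indices are
#' 0-based, so sample `i` covers time `[i/fs, (i+1)/fs)`.
#'
#' @param samples numeric matrix, channels x time samples (microvolts).
#'   Row names, if present, must equal the electrode ids of the map.
#' @param sampling_rate sampling rate in Hz.
#' @param electrode_map an [electrode_map] with one row per channel.
#' @param stimulation_times numeric vector of stimulation times in seconds,
#'   strictly increasing, possibly empty.
#' @param metadata named list; conventional fields are `div` (days in vitro),
#'   `condition` (`"control"` or `"perturbed"`) and `network_id`.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, sampling_rate = 25000, electrode_map,
                          stimulation_times = numeric(0), metadata = list()) {
  rec <- structure(list(
    samples = samples,
    sampling_rate = as.numeric(sampling_rate),
    electrode_map = electrode_map,
    stimulation_times = as.numeric(stimulation_times),
    metadata = metadata
  ), class = "raw_recording")
  validate_raw_recording(rec)
  rec
}

#' @export
validate_raw_recording <- function(rec) {
  if (is.null(rec$sampling_rate) || is.na(rec$sampling_rate) || rec$sampling_rate <= 0)
    stop("raw_recording: field 'sampling_rate' missing or not positive")
  if (!is.matrix(rec$samples))
    stop("raw_recording: field 'samples' must be a channels x time matrix")
  validate_electrode_map(rec$electrode_map)
  if (nrow(rec$samples) != nrow(rec$electrode_map))
    stop("raw_recording: shape mismatch, ", nrow(rec$samples),
         " channel rows but ", nrow(rec$electrode_map), " electrode-map entries")
  if (!is.null(rownames(rec$samples)) &&
      !identical(rownames(rec$samples), rec$electrode_map$electrode_id))
    stop("raw_recording: row names of 'samples' do not match electrode_map ids")
  st <- rec$stimulation_times
  if (length(st)) {
    if (any(diff(st) <= 0))
      stop("raw_recording: field 'stimulation_times' must be strictly increasing")
    if (min(st) < 0 || max(st) > recording_duration(rec))
      stop("raw_recording: field 'stimulation_times' outside [0, duration]")
  }
  invisible(rec)
}

#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$sampling_rate

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d channels, %.1f s at %g Hz, %d stimulation times\n",
              nrow(x$samples), recording_duration(x), x$sampling_rate,
              length(x$stimulation_times)))
  invisible(x)
}

#' Spike-time table
#'
#' Tidy table of detected (or simulated) spikes: one row per spike with the
#' electrode id, the spike time in seconds and optionally the peak-to-peak
#' amplitude in microvolts. Times are strictly increasing within each
#' electrode. `masked` records intervals (e.g. post-stimulus blanks) that are
#' excluded from firing-rate denominators.
#'
#' @param spikes data frame with columns `electrode_id`, `spike_time` and
#'   optionally `amplitude`.
#' @param duration recording duration in seconds.
#' @param electrode_map an [electrode_map].
#' @param metadata named list, see [raw_recording].
#' @param masked data frame with columns `start`, `end` of masked intervals.
#' @return An object of class `spike_table`.
#' @export
spike_table <- function(spikes, duration, electrode_map = NULL,
                        metadata = list(),
                        masked = data.frame(start = numeric(0), end = numeric(0))) {
  if (!"amplitude" %in% names(spikes))
    spikes[["amplitude"]] <- rep(NA_real_, nrow(spikes))
  spikes <- spikes[, c("electrode_id", "spike_time", "amplitude")]
  spikes$electrode_id <- as.character(spikes$electrode_id)
  tab <- structure(list(
    spikes = spikes, duration = as.numeric(duration),
    electrode_map = electrode_map, metadata = metadata, masked = masked
  ), class = "spike_table")
  validate_spike_table(tab)
  tab
}

#' @export
validate_spike_table <- function(tab) {
  sp <- tab$spikes
  if (tab$duration <= 0) stop("spike_table: duration must be positive")
  if (nrow(sp)) {
    if (min(sp$spike_time) < 0 || max(sp$spike_time) > tab$duration)
      stop("spike_table: spike times outside [0, duration]")
    bad <- vapply(split(sp$spike_time, sp$electrode_id),
                  function(t) any(diff(t) <= 0), logical(1))
    if (any(bad))
      stop("spike_table: non-increasing spike times on electrode(s): ",
           paste(names(bad)[bad], collapse = ", "))
  }
  if (!is.null(tab$electrode_map)) {
    validate_electrode_map(tab$electrode_map)
    extra <- setdiff(unique(sp$electrode_id), tab$electrode_map$electrode_id)
    if (length(extra))
      stop("spike_table: spikes on electrodes absent from the map: ",
           paste(extra, collapse = ", "))
  }
  invisible(tab)
}

#' @export
print.spike_table <- function(x, ...) {
  cat(sprintf("spike_table: %d spikes on %d electrodes over %.1f s\n",
              nrow(x$spikes), length(unique(x$spikes$electrode_id)), x$duration))
  invisible(x)
}

# Total unmasked time of a spike table (masked intervals clipped to the
# recording and merged before summation).
unmasked_duration <- function(tab) {
  m <- tab$masked
  if (is.null(m) || nrow(m) == 0) return(tab$duration)
  m$start <- pmax(m$start, 0); m$end <- pmin(m$end, tab$duration)
  m <- m[m$end > m$start, , drop = FALSE]
  if (!nrow(m)) return(tab$duration)
  m <- m[order(m$start), , drop = FALSE]
  tot <- 0; cur_s <- m$start[1]; cur_e <- m$end[1]
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    if (m$start[i] <= cur_e) cur_e <- max(cur_e, m$end[i])
    else { tot <- tot + (cur_e - cur_s); cur_s <- m$start[i]; cur_e <- m$end[i] }
  }
  tot <- tot + (cur_e - cur_s)
  tab$duration - tot
}

# Spike times for one electrode, sorted.
electrode_spikes <- function(tab, id) {
  tab$spikes$spike_time[tab$spikes$electrode_id == id]
}
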