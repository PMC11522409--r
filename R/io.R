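#' Save / load a raw recording
#'
#' Raw recordings are stored in a single self-describing container holding
#' the signal matrix (channels x samples, microvolts), the sampling rate, the
#' stimulation times, the electrode map and the metadata. Vendor acquisition
#' formats are deliberately not parsed; conversion into this container is the
#' user's concern.
#'
#' @param rec a [raw_recording].
#' @param path file path (conventionally `.rds`).
#' @rdname recording_io
#' @export
save_recording <- function(rec, path) {
  validate_raw_recording(rec)
  obj <- list(
    signals = rec$samples,
    sampling_rate = rec$sampling_rate,
    stimulation_times = rec$stimulation_times,
    electrode_map = as.data.frame(rec$electrode_map),
    metadata = rec$metadata,
    format = "meacircuit-raw-v1"
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname recording_io
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) stop("load_recording: file not found: ", path)
  obj <- readRDS(path)
  for (f in c("signals", "sampling_rate", "electrode_map"))
    if (is.null(obj[[f]]))
      stop("load_recording: format error, missing field '", f, "'")
  map <- obj$electrode_map
  class(map) <- c("electrode_map", "data.frame")
  validate_electrode_map(map)
  raw_recording(obj$signals, obj$sampling_rate, map,
                stimulation_times = obj$stimulation_times %||% numeric(0),
                metadata = obj$metadata %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a spike table as CSV
#'
#' The CSV has a header `electrode_id,spike_time_s,amplitude_uv` preceded by
#' comment lines (`# key: value`) holding the duration and any masked
#' intervals, so the round trip preserves the full object.
#'
#' @param tab a [spike_table].
#' @param path file path.
#' @rdname spike_table_io
#' @export
save_spike_table <- function(tab, path) {
  validate_spike_table(tab)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# duration_s: %.17g", tab$duration), con)
  if (nrow(tab$masked))
    writeLines(sprintf("# masked: %s",
                       paste(sprintf("%.17g-%.17g", tab$masked$start, tab$masked$end),
                             collapse = ";")), con)
  sp <- tab$spikes
  out <- data.frame(electrode_id = sp$electrode_id,
                    spike_time_s = sprintf("%.17g", sp$spike_time),
                    amplitude_uv = ifelse(is.na(sp$amplitude), "",
                                          sprintf("%.17g", sp$amplitude)))
  writeLines("electrode_id,spike_time_s,amplitude_uv", con)
  if (nrow(out))
    writeLines(paste(out$electrode_id, out$spike_time_s, out$amplitude_uv, sep = ","), con)
  invisible(path)
}

#' @param duration,electrode_map optional overrides; by default the duration
#'   stored in the file header is used (falling back to the latest spike).
#' @rdname spike_table_io
#' @export
load_spike_table <- function(path, duration = NULL, electrode_map = NULL) {
  if (!file.exists(path)) stop("load_spike_table: file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (is.null(duration)) {
    d <- sub("^# duration_s:\\s*", "", grep("^# duration_s:", hdr, value = TRUE))
    if (length(d)) duration <- as.numeric(d[1])
  }
  masked <- data.frame(start = numeric(0), end = numeric(0))
  mline <- grep("^# masked:", hdr, value = TRUE)
  if (length(mline)) {
    iv <- strsplit(sub("^# masked:\\s*", "", mline[1]), ";")[[1]]
    se <- do.call(rbind, lapply(strsplit(iv, "-"), as.numeric))
    masked <- data.frame(start = se[, 1], end = se[, 2])
  }
  df <- read.csv(text = paste(body, collapse = "\n"), stringsAsFactors = FALSE)
  need <- c("electrode_id", "spike_time_s")
  if (!all(need %in% names(df)))
    stop("load_spike_table: format error, header must contain ",
         paste(need, collapse = ", "))
  spikes <- data.frame(electrode_id = as.character(df$electrode_id),
                       spike_time = as.numeric(df$spike_time_s),
                       amplitude = if ("amplitude_uv" %in% names(df))
                         as.numeric(df$amplitude_uv) else NA_real_)
  if (is.null(duration))
    duration <- if (nrow(spikes)) max(spikes$spike_time) else 1
  spike_table(spikes, duration, electrode_map = electrode_map, masked = masked)
}

#' Write a results bundle as JSON
#'
#' @param bundle a `results_bundle` from [run_pipeline].
#' @param path output path.
#' @export
write_results_bundle <- function(bundle, path) {
  json <- results_bundle_json(bundle)
  writeLines(json, path)
  invisible(path)
}

# Deterministic JSON rendering of a results bundle (used both for files and
# for the byte-identity determinism check).
results_bundle_json <- function(bundle) {
  jsonlite::toJSON(unclass(bundle), auto_unbox = TRUE, digits = NA,
                   null = "null", na = "null", pretty = TRUE)
}
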