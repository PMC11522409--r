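#' Instantaneous firing rate in fixed bins
#'
#' Spike counts per half-open bin `[t, t + bin)`, optionally pooled per node
#' or network-wide. Rates in Hz divide each bin's count by its unmasked
#' time, so post-stimulus blanks do not depress the rate.
#'
#' @param table a [spike_table].
#' @param bin_width bin width in seconds.
#' @param scope `"electrode"`, `"node"` or `"network"`.
#' @return List of class `rate_series` with `bin_width`, `counts` (matrix
#'   series x bins), `hz` and `bin_unmasked` (seconds of unmasked time per
#'   bin).
#' @export
instantaneous_firing_rate <- function(table, bin_width = 0.05,
                                      scope = c("network", "node", "electrode")) {
  stopifnot(bin_width > 0)
  scope <- match.arg(scope)
  n_bins <- ceiling(table$duration / bin_width)
  bin_of <- function(t) pmin(floor(t / bin_width) + 1L, n_bins)

  groups <- switch(scope,
    network = list(network = table$spikes$spike_time),
    node = {
      map <- table$electrode_map
      if (is.null(map)) stop("node scope requires an electrode map")
      node_of <- setNames(map$node_label, map$electrode_id)
      split(table$spikes$spike_time, factor(node_of[table$spikes$electrode_id],
                                            levels = NODE_ORDER))
    },
    electrode = split(table$spikes$spike_time, table$spikes$electrode_id))

  counts <- t(vapply(groups, function(t)
    tabulate(bin_of(t), nbins = n_bins), numeric(n_bins)))
  if (n_bins == 1) counts <- matrix(counts, nrow = length(groups),
                                    dimnames = list(names(groups), NULL))

  unm <- rep(bin_width, n_bins)
  last <- table$duration - (n_bins - 1) * bin_width
  unm[n_bins] <- last
  if (!is.null(table$masked) && nrow(table$masked)) {
    for (i in seq_len(nrow(table$masked))) {
      s <- table$masked$start[i]; e <- min(table$masked$end[i], table$duration)
      if (e <= s) next
      for (bidx in (floor(s / bin_width) + 1L):min(floor((e - 1e-12) / bin_width) + 1L, n_bins)) {
        b0 <- (bidx - 1) * bin_width; b1 <- b0 + bin_width
        unm[bidx] <- max(unm[bidx] - (min(e, b1) - max(s, b0)), 0)
      }
    }
  }
  hz <- sweep(counts, 2, ifelse(unm > 0, unm, NA), "/")
  structure(list(bin_width = bin_width, counts = counts, hz = hz,
                 bin_unmasked = unm), class = "rate_series")
}

#' Coherence index (network synchrony)
#'
#' The ratio of the standard deviation to the mean of the binned population
#' firing rate: large when spikes concentrate into network-wide bursts,
#' near zero for steady asynchronous firing. Scale-invariant, computed with
#' the sample (n - 1) SD.
#'
#' @param x a `rate_series` (its pooled counts are used) or a numeric vector
#'   of per-bin values.
#' @return Dimensionless scalar; `NA` (with attribute `reason`) when the
#'   mean rate is zero.
#' @export
coherence_index <- function(x) {
  v <- if (inherits(x, "rate_series")) colSums(x$counts) else as.numeric(x)
  m <- mean(v)
  if (!is.finite(m) || m == 0)
    return(structure(NA_real_, reason = "zero activity"))
  sd(v) / m
}

#' Median firing rate across electrodes
#'
#' Median over electrodes of spikes per second of unmasked time.
#'
#' @param table a [spike_table].
#' @param electrodes electrodes to include; defaults to those with at least
#'   one spike.
#' @return Rate in Hz.
#' @export
median_firing_rate <- function(table, electrodes = NULL) {
  dur <- unmasked_duration(table)
  if (is.null(electrodes)) electrodes <- unique(table$spikes$electrode_id)
  if (!length(electrodes)) return(NA_real_)
  counts <- table(factor(table$spikes$electrode_id, levels = electrodes))
  median(as.numeric(counts) / dur)
}

#' Peristimulus time histogram per node
#'
#' Bins the spikes of each node (electrodes pooled) in the 300 ms following
#' every stimulation into 20 ms bins, and reports for each bin the mean and
#' SD of the count across the stimulation trials. The table is expected to
#' have been artifact-suppressed and blanked for 15 ms after each stimulus,
#' so the first bin only reflects its unblanked tail.
#'
#' @param table a [spike_table] (after SALPA and blanking).
#' @param stim_times stimulation times in seconds (>= 1).
#' @param config an [analysis_config] (`psth_window`, `psth_bin`).
#' @return List of class `psth_result`: per node a list with `centers_ms`,
#'   `mean`, `sd`, plus `n_trials`, `bin_ms`, `window_ms`.
#' @export
compute_psth <- function(table, stim_times, config = analysis_config()) {
  stopifnot(length(stim_times) >= 1)
  window <- config$psth_window; bin <- config$psth_bin
  if (length(stim_times) > 1 && min(diff(stim_times)) < window)
    stop("compute_psth: stimulation interval shorter than the PSTH window")
  map <- table$electrode_map
  if (is.null(map)) stop("compute_psth: spike table has no electrode map")
  n_bins <- round(window / bin)
  node_of <- setNames(map$node_label, map$electrode_id)
  res <- list()
  for (nd in NODE_ORDER) {
    tt <- table$spikes$spike_time[node_of[table$spikes$electrode_id] == nd]
    trial <- matrix(0, nrow = length(stim_times), ncol = n_bins)
    for (i in seq_along(stim_times)) {
      rel <- tt - stim_times[i]
      rel <- rel[rel >= 0 & rel < window]
      if (length(rel)) trial[i, ] <- tabulate(floor(rel / bin) + 1L, nbins = n_bins)
    }
    res[[nd]] <- list(centers_ms = ((seq_len(n_bins) - 0.5) * bin) * 1000,
                      mean = colMeans(trial),
                      sd = apply(trial, 2, sd))
  }
  structure(c(res, list(n_trials = length(stim_times), bin_ms = bin * 1000,
                        window_ms = window * 1000)), class = "psth_result")
}
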