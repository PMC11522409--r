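#' logISI inter-spike-interval threshold for one spike train
#'
#' Builds the histogram of `log10(ISI)` (default 10 bins per decade,
#' smoothed by a centred moving average), locates the intra-burst peak (the
#' tallest peak below the 100 ms cap) and scans subsequent histogram minima
#' for the first one whose void parameter against a later peak,
#' `1 - h_min / sqrt(h_peak1 * h_peak2)`, reaches the void threshold (0.7).
#' The ISI at that minimum, capped at `max_isi`, is the burst threshold. A
#' unimodal histogram (no valid peak/void structure) falls back to
#' `max_isi`.
#'
#' @param times spike times (s) of one electrode, sorted.
#' @param config an [analysis_config].
#' @return ISI threshold in seconds, or `NA` for trains with < 2 spikes.
#' @export
isi_threshold_logisi <- function(times, config = analysis_config()) {
  if (length(times) < 2) return(NA_real_)
  isi <- diff(times)
  isi <- isi[isi > 0]
  if (!length(isi)) return(NA_real_)
  lg <- log10(isi)
  lo <- floor(min(lg) * config$bins_per_decade) / config$bins_per_decade
  hi <- ceiling(max(lg) * config$bins_per_decade) / config$bins_per_decade
  if (hi <= lo) hi <- lo + 1 / config$bins_per_decade
  breaks <- seq(lo, hi, by = 1 / config$bins_per_decade)
  h <- hist(lg, breaks = breaks, plot = FALSE)
  counts <- smooth_counts(h$counts, config$smooth_bins)
  centers <- h$mids

  pk <- local_maxima(counts)
  if (!length(pk)) return(config$max_isi)
  intra_ok <- pk[centers[pk] < log10(config$max_isi)]
  if (!length(intra_ok)) return(config$max_isi)
  p1 <- intra_ok[which.max(counts[intra_ok])]
  later <- pk[pk > p1]
  for (p2 in later) {
    seg <- (p1 + 1):(p2 - 1)
    if (!length(seg) || p2 - p1 < 2) next
    m <- seg[which.min(counts[seg])]
    denom <- sqrt(counts[p1] * counts[p2])
    if (denom == 0) next
    void <- 1 - counts[m] / denom
    if (void >= config$void_threshold)
      return(min(10^centers[m], config$max_isi))
  }
  config$max_isi
}

# Centred moving average with shrinking windows at the edges.
smooth_counts <- function(x, w) {
  if (w <= 1) return(x)
  half <- floor(w / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    j <- max(1, i - half):min(n, i + half)
    mean(x[j])
  }, numeric(1))
}

# Indices of strict local maxima; plateaus take their first bin.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2
  while (i <= n - 1) {
    j <- i
    while (j + 1 <= n && x[j + 1] == x[i]) j <- j + 1
    if (j <= n - 1 && x[i] > x[i - 1] && x[i] > x[j + 1]) out <- c(out, i)
    i <- j + 1
  }
  out
}

#' Detect bursts on one spike train
#'
#' A burst is a maximal run of consecutive spikes whose inter-spike
#' intervals are all at or below the threshold, with at least `min_spikes`
#' (4) spikes. Burst start and end are the first and last spike times of the
#' run.
#'
#' @param times sorted spike times (s).
#' @param threshold ISI threshold (s), e.g. from [isi_threshold_logisi].
#' @param config an [analysis_config].
#' @return Data frame with `start`, `end`, `n_spikes`.
#' @export
detect_bursts <- function(times, threshold, config = analysis_config()) {
  empty <- data.frame(start = numeric(0), end = numeric(0), n_spikes = integer(0))
  if (is.na(threshold) || length(times) < config$min_spikes) return(empty)
  stopifnot(threshold > 0)
  ok <- diff(times) <= threshold
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= (config$min_spikes - 1)
  if (!any(keep)) return(empty)
  data.frame(start = times[starts[keep]],
             end = times[ends[keep] + 1],
             n_spikes = r$lengths[keep] + 1L)
}

#' Per-electrode burst detection for a whole spike table
#'
#' Applies [isi_threshold_logisi] and [detect_bursts] to every electrode.
#'
#' @param table a [spike_table].
#' @param config an [analysis_config].
#' @return Data frame with `electrode_id`, `start`, `end`, `n_spikes`,
#'   `threshold`.
#' @export
detect_bursts_table <- function(table, config = analysis_config()) {
  out <- lapply(unique(table$spikes$electrode_id), function(id) {
    tt <- electrode_spikes(table, id)
    thr <- isi_threshold_logisi(tt, config)
    b <- detect_bursts(tt, thr, config)
    if (!nrow(b)) return(NULL)
    cbind(data.frame(electrode_id = id, stringsAsFactors = FALSE), b,
          threshold = thr)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(electrode_id = character(0), start = numeric(0),
                      end = numeric(0), n_spikes = integer(0),
                      threshold = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Active electrodes of a recording
#'
#' An electrode is active when its overall firing rate over unmasked time is
#' at least `active_rate_min` (0.1 Hz by default).
#'
#' @param table a [spike_table].
#' @param config an [analysis_config].
#' @return Character vector of electrode ids.
#' @export
active_electrodes <- function(table, config = analysis_config()) {
  dur <- unmasked_duration(table)
  if (dur <= 0) return(character(0))
  counts <- table(table$spikes$electrode_id)
  names(counts)[counts / dur >= config$active_rate_min]
}

#' Network-burst detection (logIBEI with the 10%-of-active-electrodes rule)
#'
#' Pools burst-onset events across all electrodes, derives a grouping
#' threshold for the inter-burst-event intervals with the same log-histogram
#' machinery as the single-electrode logISI step (falling back to the 100 ms
#' cap for unimodal interval distributions), and groups temporally
#' contiguous bursts into candidate network events. A candidate qualifies as
#' a network burst when it involves at least `ceil(nb_fraction * n_active)`
#' distinct bursting electrodes (the 10% rule, inclusive). Qualifying events
#' whose spans overlap are merged so network bursts never overlap.
#'
#' @param bursts data frame from [detect_bursts_table].
#' @param active character vector from [active_electrodes]; must be
#'   non-empty.
#' @param electrode_map an [electrode_map] used for per-node onsets and
#'   propagation classification.
#' @param config an [analysis_config].
#' @return Data frame with one row per network burst: `start`, `end`,
#'   `n_electrodes`, per-node onset columns `onset_C` ... `onset_H3`,
#'   `initiation_node`, `span`, `feedforward`, plus a list column
#'   `electrodes`.
#' @export
detect_network_bursts <- function(bursts, active, electrode_map,
                                  config = analysis_config()) {
  stopifnot(length(active) > 0)
  empty <- nb_empty()
  if (!nrow(bursts)) return(empty)
  b <- bursts[order(bursts$start), , drop = FALSE]
  thr <- isi_threshold_logisi(b$start, config)
  if (is.na(thr)) thr <- config$max_isi
  grp <- cumsum(c(1, as.integer(diff(b$start) > thr)))
  need <- ceiling(config$nb_fraction * length(active))

  cand <- lapply(split(seq_len(nrow(b)), grp), function(idx) {
    el <- unique(b$electrode_id[idx])
    if (length(el) < need) return(NULL)
    list(start = min(b$start[idx]), end = max(b$end[idx]),
         electrodes = el, idx = idx)
  })
  cand <- cand[!vapply(cand, is.null, logical(1))]
  if (!length(cand)) return(empty)

  # merge qualifying events with overlapping spans
  merged <- list(cand[[1]])
  if (length(cand) > 1) for (c2 in cand[-1]) {
    last <- merged[[length(merged)]]
    if (c2$start <= last$end) {
      last$end <- max(last$end, c2$end)
      last$electrodes <- unique(c(last$electrodes, c2$electrodes))
      last$idx <- c(last$idx, c2$idx)
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1]] <- c2
  }

  node_of <- setNames(electrode_map$node_label, electrode_map$electrode_id)
  rows <- lapply(merged, function(cc) {
    bb <- b[cc$idx, , drop = FALSE]
    onsets <- setNames(rep(NA_real_, 4), NODE_ORDER)
    for (nd in NODE_ORDER) {
      sel <- node_of[bb$electrode_id] == nd
      if (any(sel, na.rm = TRUE)) onsets[nd] <- min(bb$start[sel], na.rm = TRUE)
    }
    cls <- classify_propagation(onsets)
    d <- data.frame(start = cc$start, end = cc$end,
                    n_electrodes = length(cc$electrodes),
                    initiation_node = cls$initiation_node, span = cls$span,
                    feedforward = cls$feedforward, stringsAsFactors = FALSE)
    for (nd in NODE_ORDER) d[[paste0("onset_", nd)]] <- unname(onsets[nd])
    d$electrodes <- I(list(cc$electrodes))
    d
  })
  do.call(rbind, rows)
}

nb_empty <- function() {
  d <- data.frame(start = numeric(0), end = numeric(0),
                  n_electrodes = integer(0), initiation_node = character(0),
                  span = integer(0), feedforward = logical(0),
                  stringsAsFactors = FALSE)
  for (nd in NODE_ORDER) d[[paste0("onset_", nd)]] <- numeric(0)
  d$electrodes <- I(list())
  d
}

#' Classify feedforward propagation of one network burst
#'
#' The initiation node is the node with the earliest onset (ties within one
#' sample resolved toward the upstream node). The span is the length of the
#' maximal chain of consecutive downstream nodes, starting at the initiation
#' node, with strictly increasing onsets and no node skipped. A burst is
#' feedforward when it initiates in the cortical node and spans all four.
#'
#' @param onsets named numeric vector of per-node onsets (`C`, `H1`, `H2`,
#'   `H3`), `NA` where the node showed no bursting; at least one non-`NA`.
#' @param tie_tol onsets closer than this (s) count as tied (default one
#'   sample at 25 kHz).
#' @return List with `initiation_node`, `span`, `feedforward`, `tied`.
#' @export
classify_propagation <- function(onsets, tie_tol = 1 / 25000) {
  onsets <- onsets[NODE_ORDER]
  if (all(is.na(onsets))) stop("classify_propagation: no per-node onsets")
  tmin <- min(onsets, na.rm = TRUE)
  tied_set <- which(!is.na(onsets) & onsets - tmin < tie_tol)
  init <- tied_set[1]  # upstream-most among ties
  span <- 1L
  j <- init
  while (j < 4) {
    nxt <- onsets[j + 1]
    if (is.na(nxt) || nxt <= onsets[j]) break
    span <- span + 1L
    j <- j + 1L
  }
  list(initiation_node = NODE_ORDER[init], span = span,
       feedforward = (init == 1L && span == 4L),
       tied = length(tied_set) > 1)
}

#' Summarise network-burst propagation and per-node burst rates
#'
#' Tabulates network bursts by initiation node and span (counts and
#' percentages over all network bursts) and reports, per node, the median
#' across that node's electrodes of the single-electrode burst rate in
#' bursts per minute.
#'
#' @param nbs data frame from [detect_network_bursts].
#' @param bursts data frame from [detect_bursts_table].
#' @param electrode_map an [electrode_map].
#' @param duration recording duration in seconds.
#' @return List with `by_initiation_span` (data frame of counts and
#'   percentages) and `node_burst_rate` (named numeric, bursts/min).
#' @export
propagation_summary <- function(nbs, bursts, electrode_map, duration) {
  stopifnot(nrow(nbs) >= 1)
  tab <- aggregate(list(count = rep(1L, nrow(nbs))),
                   by = list(initiation_node = nbs$initiation_node,
                             span = nbs$span), FUN = sum)
  tab$percent <- 100 * tab$count / nrow(nbs)
  tab <- tab[order(match(tab$initiation_node, NODE_ORDER), tab$span), ]
  rownames(tab) <- NULL

  rate <- setNames(rep(NA_real_, 4), NODE_ORDER)
  counts <- table(bursts$electrode_id)
  for (nd in NODE_ORDER) {
    ids <- node_electrodes(electrode_map, nd)
    if (!length(ids)) next
    per <- as.numeric(counts[ids])
    per[is.na(per)] <- 0
    rate[nd] <- median(per / (duration / 60))
  }
  list(by_initiation_span = tab, node_burst_rate = rate,
       n_network_bursts = nrow(nbs))
}
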