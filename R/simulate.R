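#' Configuration of the feedforward network-burst simulator
#'
#' The simulator emulates the statistical structure of spontaneous activity
#' in a four-nodal feedforward culture: network-burst events arise as a
#' Poisson process in each initiating node, propagate node-to-node in the
#' feedforward direction (`C -> H1 -> H2 -> H3`) with a per-hop transmission
#' probability and a jittered hop delay, recruit a random subset of the
#' electrodes in each reached node into short spike bursts, and are
#' superposed on independent tonic background spiking. The `abeta`
#' perturbation mode reproduces the two effects reported for amyloid-beta
#' perturbed cultures -- a higher burst rate in the (perturbed) cortical node
#' and weaker transmission to downstream nodes -- by scaling only the
#' cortical initiation rate (up) and the hop transmission probability (down);
#' any synchrony change is emergent, not injected.
#'
#' @param n_electrodes_per_node electrodes per node (default 10).
#' @param nb_rate network-burst initiations per minute per initiating node.
#' @param p_tx per-hop transmission probability in `[0, 1]`. The default
#'   0.62 makes roughly a quarter of cortical-initiated events span all four
#'   nodes (`0.62^3 = 0.24`), the proportion typical of mature control
#'   cultures.
#' @param hop_delay mean node-to-node onset delay in seconds.
#' @param hop_jitter SD of the hop delay (truncated so delays stay >= 1 ms).
#' @param participation_prob probability an electrode of a reached node joins
#'   the event.
#' @param intra_burst_isi_mean mean intra-burst inter-spike interval (s).
#' @param intra_burst_isi_min hard floor on intra-burst ISIs (s); neurons are
#'   refractory, so intervals below ~2 ms do not occur.
#' @param spikes_per_burst_mean mean spikes per electrode burst (>= 4).
#' @param onset_jitter per-electrode burst-onset jitter within a node (s).
#' @param tonic_rate background Poisson rate per electrode (Hz).
#' @param init_nodes nodes allowed to initiate events (subset of
#'   `C`, `H1`, `H2`, `H3`). Restricting to `"C"` yields purely
#'   cortically initiated activity, convenient for propagation studies.
#' @param perturbation `"none"` or `"abeta"`.
#' @param abeta_rate_factor multiplier (>= 1) on the cortical initiation rate
#'   in `abeta` mode.
#' @param abeta_ptx_factor multiplier (<= 1) on `p_tx` in `abeta` mode.
#' @param seed RNG seed; identical config and seed give identical output.
#' @return A list of class `network_sim_config`.
#' @export
network_sim_config <- function(n_electrodes_per_node = 10, nb_rate = 6,
                               p_tx = 0.62, hop_delay = 0.020,
                               hop_jitter = 0.005, participation_prob = 0.75,
                               intra_burst_isi_mean = 0.010,
                               intra_burst_isi_min = 0.002,
                               spikes_per_burst_mean = 8, onset_jitter = 0.005,
                               tonic_rate = 1, init_nodes = NODE_ORDER,
                               perturbation = "none",
                               abeta_rate_factor = 2, abeta_ptx_factor = 0.6,
                               seed = 1) {
  cfg <- as.list(environment())
  probs <- c("p_tx", "participation_prob")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop("network_sim_config: '", p, "' must be in [0, 1]")
  if (cfg$nb_rate < 0 || cfg$tonic_rate < 0)
    stop("network_sim_config: rates must be >= 0")
  if (!length(init_nodes) || !all(init_nodes %in% NODE_ORDER))
    stop("network_sim_config: 'init_nodes' must be a non-empty subset of ",
         paste(NODE_ORDER, collapse = ", "))
  if (!perturbation %in% c("none", "abeta"))
    stop("network_sim_config: perturbation must be 'none' or 'abeta'")
  if (abeta_rate_factor < 1 || abeta_ptx_factor > 1 || abeta_ptx_factor < 0)
    stop("network_sim_config: abeta factors must satisfy rate >= 1, 0 <= p_tx factor <= 1")
  if (spikes_per_burst_mean < 4)
    stop("network_sim_config: 'spikes_per_burst_mean' must be >= 4")
  if (intra_burst_isi_min <= 0 || intra_burst_isi_mean <= intra_burst_isi_min)
    stop("network_sim_config: need 0 < intra_burst_isi_min < intra_burst_isi_mean")
  class(cfg) <- "network_sim_config"
  cfg
}

#' Simulate feedforward multinodal spike trains with ground truth
#'
#' Draws network-burst events per initiating node, propagates them downstream
#' hop-by-hop, emits per-electrode spike bursts and tonic background spikes,
#' and records complete ground truth (event records with per-node onsets,
#' burst intervals, and per-electrode spike times) so that every downstream
#' detection stage can be scored against a known answer.
#'
#' @param config a [network_sim_config].
#' @param duration simulated recording length in seconds.
#' @param electrode_map optional [electrode_map]; by default a map with
#'   `n_electrodes_per_node` electrodes per node and no tunnel electrodes.
#' @return A list with elements `table` (a [spike_table]) and `truth` (a list
#'   with `events`, `bursts` and `spikes`).
#' @export
simulate_spike_trains <- function(config, duration, electrode_map = NULL) {
  stopifnot(inherits(config, "network_sim_config"), duration > 0)
  if (is.null(electrode_map)) {
    n <- config$n_electrodes_per_node
    electrode_map <- standard_electrode_map(rep(n, 4), n_tunnel = 0)
  }
  with_local_seed(config$seed,
                  simulate_spike_trains_impl(config, duration, electrode_map))
}

simulate_spike_trains_impl <- function(config, duration, map) {
  p_tx <- config$p_tx
  rate <- rep(config$nb_rate, 4)
  if (config$perturbation == "abeta") {
    rate[1] <- rate[1] * config$abeta_rate_factor
    p_tx <- p_tx * config$abeta_ptx_factor
  }
  names(rate) <- NODE_ORDER

  events <- list(); bursts <- list(); ev_id <- 0L
  for (ni in seq_along(NODE_ORDER)) {
    if (!NODE_ORDER[ni] %in% config$init_nodes) next
    n_ev <- rpois(1, rate[ni] / 60 * duration)
    if (n_ev == 0) next
    t0 <- sort(runif(n_ev, 0, duration))
    for (t_init in t0) {
      ev_id <- ev_id + 1L
      onsets <- rep(NA_real_, 4); names(onsets) <- NODE_ORDER
      onsets[ni] <- t_init
      t_cur <- t_init
      for (nj in seq(ni + 1, 4)) {
        if (ni == 4 || nj > 4) break
        if (runif(1) > p_tx) break
        delay <- max(config$hop_delay + rnorm(1, 0, config$hop_jitter), 0.001)
        t_cur <- t_cur + delay
        onsets[nj] <- t_cur
      }
      reached <- NODE_ORDER[!is.na(onsets)]
      for (node in reached) {
        for (id in node_electrodes(map, node)) {
          if (runif(1) > config$participation_prob) next
          b_start <- onsets[node] + runif(1, 0, config$onset_jitter)
          n_sp <- config$min_spikes_internal %||% 4
          n_sp <- n_sp + rpois(1, config$spikes_per_burst_mean - n_sp)
          isis <- config$intra_burst_isi_min +
            rexp(n_sp - 1, 1 / (config$intra_burst_isi_mean - config$intra_burst_isi_min))
          times <- b_start + c(0, cumsum(isis))
          times <- times[times < duration]
          if (length(times) < 2) next
          bursts[[length(bursts) + 1L]] <- list(
            event_id = ev_id, electrode_id = id, node = node,
            start = times[1], end = times[length(times)],
            n_spikes = length(times), times = times)
        }
      }
      events[[ev_id]] <- list(event_id = ev_id, init_node = NODE_ORDER[ni],
                              onsets = onsets,
                              n_nodes_reached = length(reached))
    }
  }

  # ground-truth burst spikes per electrode
  spk <- list()
  for (b in bursts) spk[[b$electrode_id]] <- c(spk[[b$electrode_id]], b$times)

  # tonic background, thinned so it never lands on top of a burst spike
  all_ids <- map$electrode_id[!map$is_reference]
  rows <- vector("list", length(all_ids))
  truth_spikes <- list()
  for (k in seq_along(all_ids)) {
    id <- all_ids[k]
    burst_t <- sort(spk[[id]] %||% numeric(0))
    n_ton <- rpois(1, config$tonic_rate * duration)
    ton <- sort(runif(n_ton, 0, duration))
    if (length(burst_t) && length(ton)) {
      near <- vapply(ton, function(t) {
        i <- findInterval(t, burst_t)
        d <- Inf
        if (i >= 1) d <- min(d, t - burst_t[i])
        if (i < length(burst_t)) d <- min(d, burst_t[i + 1] - t)
        d
      }, numeric(1))
      ton <- ton[near > 5e-4]
    }
    tt <- sort(c(burst_t, ton))
    tt <- tt[c(TRUE, diff(tt) > 1e-6)]
    truth_spikes[[id]] <- tt
    if (length(tt))
      rows[[k]] <- data.frame(electrode_id = id, spike_time = tt,
                              stringsAsFactors = FALSE)
  }
  spikes_df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(spikes_df))
    spikes_df <- data.frame(electrode_id = character(0), spike_time = numeric(0))

  burst_df <- if (length(bursts)) do.call(rbind, lapply(bursts, function(b)
    data.frame(event_id = b$event_id, electrode_id = b$electrode_id,
               node = b$node, start = b$start, end = b$end,
               n_spikes = b$n_spikes, stringsAsFactors = FALSE)))
  else data.frame(event_id = integer(0), electrode_id = character(0),
                  node = character(0), start = numeric(0), end = numeric(0),
                  n_spikes = integer(0))

  event_df <- if (length(events)) do.call(rbind, lapply(events, function(e) {
    d <- data.frame(event_id = e$event_id, init_node = e$init_node,
                    n_nodes_reached = e$n_nodes_reached,
                    stringsAsFactors = FALSE)
    for (nd in NODE_ORDER) d[[paste0("onset_", nd)]] <- unname(e$onsets[nd])
    d
  })) else NULL

  tab <- spike_table(spikes_df, duration, electrode_map = map,
                     metadata = list(condition = if (config$perturbation == "none")
                       "control" else "perturbed"))
  list(table = tab,
       truth = list(events = event_df, bursts = burst_df, spikes = truth_spikes))
}
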