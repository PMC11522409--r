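#' Bin spike trains into fixed-width count series
#'
#' @param table a [spike_table].
#' @param bin_width bin width in seconds (50 ms by default).
#' @return List of class `binned_trains`: `counts` (electrodes x bins,
#'   non-negative integers; half-open bins), `bin_width`, `electrode_ids`.
#' @export
bin_trains <- function(table, bin_width = 0.05) {
  stopifnot(table$duration > 0, bin_width > 0)
  map <- table$electrode_map
  ids <- if (!is.null(map)) map$electrode_id[!map$is_reference]
  else sort(unique(table$spikes$electrode_id))
  n_bins <- ceiling(table$duration / bin_width)
  counts <- matrix(0L, nrow = length(ids), ncol = n_bins,
                   dimnames = list(ids, NULL))
  for (id in ids) {
    t <- electrode_spikes(table, id)
    if (length(t))
      counts[id, ] <- tabulate(pmin(floor(t / bin_width) + 1L, n_bins), n_bins)
  }
  structure(list(counts = counts, bin_width = bin_width, electrode_ids = ids),
            class = "binned_trains")
}

#' Maximum lagged cross-correlation of two binned spike trains
#'
#' Computes `r(l) = sum_t x_t y_(t+l) / sqrt(sum x^2 sum y^2)` for lags `l`
#' in `[-max_lag, max_lag]` bins and returns the maximum and its lag. The
#' normalisation makes each autocorrelation equal 1 at zero lag; no mean is
#' subtracted, so independent high-rate trains have a positive floor rather
#' than zero (a documented property of this estimator). Ties are broken
#' toward the smallest absolute lag, then the negative lag.
#'
#' @param x,y numeric count series of equal length (>= `2 * max_lag + 1`).
#' @param max_lag maximum lag in bins (10 bins = 500 ms at 50 ms bins).
#' @return List with `coef` in `[0, 1]` and `lag` (bins); `coef` is `NA`
#'   for an all-zero series.
#' @export
max_xcorr <- function(x, y, max_lag = 10) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2 * max_lag + 1)
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0) return(list(coef = NA_real_, lag = NA_integer_))
  lags <- order(abs(seq(-max_lag, max_lag)),
                seq(-max_lag, max_lag))  # 0, -1, 1, -2, 2, ...
  lags <- seq(-max_lag, max_lag)[lags]
  best <- -Inf; best_lag <- NA_integer_
  for (l in lags) {
    r <- if (l >= 0) sum(x[seq_len(n - l)] * y[seq_len(n - l) + l])
    else sum(x[seq_len(n + l) - l] * y[seq_len(n + l)])
    r <- r / denom
    if (r > best + 1e-12) { best <- r; best_lag <- l }
  }
  list(coef = best, lag = best_lag)
}

#' Electrode- and node-level correlation matrices
#'
#' The electrode-level matrix holds the maximum lagged cross-correlation for
#' every electrode pair (tunnel electrodes included). The node-level 4x4
#' matrix has, on the diagonal, the mean pairwise correlation between the
#' electrodes within each node (intranodal), and off the diagonal the
#' maximum lagged cross-correlation between the summed spike trains of each
#' node pair (internodal); tunnel electrodes are excluded from node
#' aggregates. Both matrices are symmetric under the max-over-both-lags
#' convention.
#'
#' @param binned a `binned_trains` from [bin_trains].
#' @param electrode_map an [electrode_map].
#' @param config an [analysis_config] (`max_lag_bins`).
#' @return List of class `connectivity_summary` with `electrode_matrix`,
#'   `lag_matrix`, `node_matrix` and `params`.
#' @export
correlation_matrices <- function(binned, electrode_map,
                                 config = analysis_config()) {
  X <- binned$counts
  L <- config$max_lag_bins
  E <- nrow(X); n <- ncol(X)
  norms <- sqrt(rowSums(X^2))
  # r_l[i, j] = sum_t x_i(t) x_j(t + l), l = 0..L; negative lags by symmetry
  R <- array(NA_real_, dim = c(L + 1, E, E))
  for (l in 0:L) {
    A <- X[, seq_len(n - l), drop = FALSE]
    B <- X[, seq_len(n - l) + l, drop = FALSE]
    R[l + 1, , ] <- tcrossprod(A, B)
  }
  coef <- matrix(NA_real_, E, E, dimnames = list(binned$electrode_ids,
                                                 binned$electrode_ids))
  lagm <- matrix(NA_integer_, E, E, dimnames = dimnames(coef))
  lag_order <- seq(-L, L)[order(abs(seq(-L, L)), seq(-L, L))]
  for (i in seq_len(E)) for (j in i:E) {
    if (norms[i] == 0 || norms[j] == 0) next
    rs <- vapply(lag_order, function(l)
      if (l >= 0) R[l + 1, i, j] else R[-l + 1, j, i], numeric(1))
    rs <- rs / (norms[i] * norms[j])
    k <- 1; for (q in seq_along(rs)) if (rs[q] > rs[k] + 1e-12) k <- q
    coef[i, j] <- coef[j, i] <- rs[k]
    lagm[i, j] <- lag_order[k]; lagm[j, i] <- -lag_order[k]
  }
  diag(coef)[norms > 0] <- 1

  node_mat <- matrix(NA_real_, 4, 4, dimnames = list(NODE_ORDER, NODE_ORDER))
  pooled <- matrix(0, 4, n)
  for (ni in seq_along(NODE_ORDER)) {
    ids <- intersect(node_electrodes(electrode_map, NODE_ORDER[ni]),
                     binned$electrode_ids)
    if (length(ids))
      pooled[ni, ] <- colSums(X[ids, , drop = FALSE])
    # intranodal mean of pairwise coefficients
    act <- ids[norms[match(ids, binned$electrode_ids)] > 0]
    if (length(act) >= 2) {
      pr <- combn(match(act, binned$electrode_ids), 2)
      node_mat[ni, ni] <- mean(coef[cbind(pr[1, ], pr[2, ])])
    }
  }
  for (ni in 1:3) for (nj in (ni + 1):4) {
    r <- max_xcorr(pooled[ni, ], pooled[nj, ], L)
    node_mat[ni, nj] <- node_mat[nj, ni] <- r$coef
  }
  structure(list(electrode_matrix = coef, lag_matrix = lagm,
                 node_matrix = node_mat,
                 params = list(max_lag_bins = L, bin_width = binned$bin_width)),
            class = "connectivity_summary")
}
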