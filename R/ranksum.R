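#' Exact two-sided Wilcoxon rank-sum comparison
#'
#' Computes the rank-sum statistic `W` (sum of the pooled ranks of the first
#' sample) and a two-sided p-value. Without ties and for small samples the
#' p-value is exact: the proportion of all `choose(na + nb, na)` rank
#' assignments whose statistic deviates from its null mean `na (N + 1) / 2`
#' at least as much as the observed one. With ties (midranks) or for large
#' samples, a normal approximation with tie correction and continuity
#' correction is used and flagged. Two identical samples give p = 1.
#'
#' @param a,b numeric samples, both non-empty.
#' @param max_enum largest number of rank assignments enumerated exactly.
#' @return List of class `group_comparison` with `statistic` (W),
#'   `p_two_sided`, `method` (`"exact"` or `"normal-approx"`), `ties`,
#'   `n_a`, `n_b`.
#' @export
exact_ranksum_p <- function(a, b, max_enum = 500000) {
  stopifnot(length(a) > 0, length(b) > 0)
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0
  rk <- rank(pooled)
  W <- sum(rk[seq_len(na)])
  mu <- na * (N + 1) / 2

  if (!ties && choose(N, na) <= max_enum) {
    dev <- abs(W - mu)
    # all assignments of na ranks out of 1..N
    sums <- colSums(combn(N, na))
    p <- mean(abs(sums - mu) >= dev - 1e-9)
    method <- "exact"
  } else {
    # normal approximation with tie correction and continuity correction
    tie_tab <- table(pooled)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
      p <- min(2 * pnorm(-max(z, 0)), 1)
    }
    method <- "normal-approx"
  }
  structure(list(statistic = W, p_two_sided = p, method = method,
                 ties = ties, n_a = na, n_b = nb),
            class = "group_comparison")
}

#' Grouped summary of a longitudinal metric table
#'
#' Summarises a tidy metric table (one row per network, time point and
#' condition) into per-DIV, per-condition mean, SD, median and n, the layout
#' used for plotting developmental trends. Groups with a single observation
#' get SD 0 and are flagged.
#'
#' @param df data frame with columns `network_id`, `div`, `condition`,
#'   `value`.
#' @return Data frame with one row per `div` x `condition`.
#' @export
group_summary <- function(df) {
  stopifnot(nrow(df) >= 1,
            all(c("div", "condition", "value") %in% names(df)))
  agg <- aggregate(value ~ div + condition, data = df, FUN = function(v)
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
      median = median(v), n = length(v)))
  out <- cbind(agg[, c("div", "condition")], as.data.frame(agg$value))
  out$single_n <- out$n == 1
  out[order(out$condition, out$div), ]
}
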