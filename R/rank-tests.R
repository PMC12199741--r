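# Two-sample rank-sum (Mann-Whitney/Wilcoxon) tests with exact enumeration
# at small n, and Bonferroni-corrected pairwise families.

#' Two-sided rank-sum test
#'
#' Two-sample Mann-Whitney/Wilcoxon rank-sum test. When both groups have at
#' most `exact_max` observations the two-sided p-value is computed by exact
#' enumeration of all C(n+m, n) group assignments of the pooled mid-ranks
#' (ties handled naturally); otherwise a tie-corrected normal approximation
#' (no continuity correction) is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest per-group size for exhaustive enumeration.
#' @return list with `statistic` (rank-sum W of `x`), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 8) {
  n <- length(x); m <- length(y)
  abort_if(n < 1 || m < 1, "both groups need at least one observation")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  if (n <= exact_max && m <= exact_max) {
    idx <- utils::combn(n + m, n)
    sums <- colSums(matrix(r[idx], nrow = n))
    # two-sided: arrangements at least as extreme in |W - E[W]|
    dev <- abs(sums - (n * (n + m + 1) / 2))
    p <- mean(dev >= abs(W - n * (n + m + 1) / 2) - 1e-9)
    list(statistic = W, p_value = p, method = "exact enumeration")
  } else {
    N <- n + m
    mu <- n * (N + 1) / 2
    ties <- table(r)
    sig2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    # all pooled observations tied: no evidence either way
    z <- if (sig2 <= 0) 0 else (W - mu) / sqrt(sig2)
    list(statistic = W, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal approximation (tie-corrected)")
  }
}

#' Pairwise rank-sum tests with Bonferroni correction
#'
#' Runs [rank_sum_test()] on every pair of groups and multiplies each raw
#' p-value by the number of comparisons, capping at 1.
#'
#' @param groups named list of numeric vectors, or a list plus `labels`.
#' @param labels optional group labels.
#' @param paired if `TRUE`, a Wilcoxon signed-rank test on observations
#'   paired by position (groups truncated to the shorter length) is used
#'   instead of the unpaired rank-sum; provided for designs with a natural
#'   pairing unit.
#' @return data.frame with `group1`, `group2`, `statistic`, `p_raw`,
#'   `p_adjusted`, `m_comparisons`.
#' @export
pairwise_rank_sum <- function(groups, labels = names(groups),
                              paired = FALSE) {
  k <- length(groups)
  abort_if(k < 2, "need at least two groups")
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- groups[[pairs[1, j]]]; b <- groups[[pairs[2, j]]]
    if (paired) {
      len <- min(length(a), length(b))
      ht <- suppressWarnings(stats::wilcox.test(a[seq_len(len)],
                                                b[seq_len(len)],
                                                paired = TRUE, exact = FALSE))
      stat <- unname(ht$statistic); p <- ht$p.value
    } else {
      ht <- rank_sum_test(a, b)
      stat <- ht$statistic; p <- ht$p_value
    }
    data.frame(group1 = labels[pairs[1, j]], group2 = labels[pairs[2, j]],
               statistic = stat, p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out$m_comparisons <- m
  out
}
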