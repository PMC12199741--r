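# Pooling calibration ensembles across drifters, as when several tagged
# objects escape the same origin and each seeds its own backtracking runs.

#' Pool calibration results across drifters
#'
#' Concatenates the per-K passing-distance ensembles of several
#' [calibrate_diffusivity()] results (one per drifter), recomputes the
#' summary statistics, pairwise rank-sum tests and smallest-mean selection
#' on the pooled samples.
#'
#' @param results list of `calibration_result` objects sharing the same
#'   candidate set.
#' @return a pooled `calibration_result`.
#' @export
pool_calibrations <- function(results) {
  abort_if(length(results) < 1, "nothing to pool")
  Ks <- sort(unique(results[[1]]$distances$K))
  for (r in results)
    abort_if(!identical(sort(unique(r$distances$K)), Ks),
             "calibration results use different candidate sets")
  dist_list <- lapply(Ks, function(K)
    unlist(lapply(results, function(r)
      r$distances$distance_km[r$distances$K == K])))
  distances <- data.frame(K = rep(Ks, vapply(dist_list, length, 1L)),
                          distance_km = unlist(dist_list))
  summ <- do.call(rbind, lapply(seq_along(Ks), function(i) {
    d <- dist_list[[i]]
    q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
    data.frame(K = Ks[i], n = length(d), mean_km = mean(d),
               median_km = stats::median(d), iqr_lo_km = q[1],
               iqr_hi_km = q[2])
  }))
  tests <- if (length(Ks) >= 2)
    pairwise_rank_sum(dist_list, labels = as.character(Ks)) else NULL
  sel <- summ$K[which.min(summ$mean_km)]
  indist <- sel
  if (!is.null(tests)) {
    lab <- as.character(sel)
    rel <- tests[tests$group1 == lab | tests$group2 == lab, ]
    other <- ifelse(rel$group1 == lab, rel$group2, rel$group1)
    indist <- sort(unique(c(sel, as.numeric(other[rel$p_adjusted >= 0.05]))))
  }
  structure(list(distances = distances, summary = summ, tests = tests,
                 selected_K = sel, indistinguishable = indist),
            class = "calibration_result")
}
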