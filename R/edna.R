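# Pooled-qPCR eDNA screening: Cq calling, standard-curve quantification,
# region decision rules, replicate reliability, synthetic curves.

#' Call the quantification cycle (Cq) of an amplification curve
#'
#' Finds the first crossing of the fluorescence threshold, linearly
#' interpolated between the bracketing cycles.
#'
#' @param cycles integer cycle numbers (consecutive from 1).
#' @param rfu fluorescence per cycle (relative fluorescence units).
#' @param threshold critical fluorescence threshold (> 0).
#' @return fractional cycle of first crossing, or `NA` if never crossed.
#' @export
call_cq <- function(cycles, rfu, threshold) {
  abort_if(threshold <= 0, "threshold must be positive")
  abort_if(length(cycles) != length(rfu), "cycles and rfu lengths differ")
  above <- rfu >= threshold
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(as.numeric(cycles[1]))
  frac <- (threshold - rfu[i - 1]) / (rfu[i] - rfu[i - 1])
  cycles[i - 1] + frac * (cycles[i] - cycles[i - 1])
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of Cq on log10 template copies over a dilution
#' series. Amplification efficiency derives from the slope as
#' `10^(-1/slope) - 1` (slope -3.3219 corresponds to perfect doubling,
#' 100% efficiency).
#'
#' @param log10_copies log10 known template copies per standard.
#' @param cq called Cq per standard.
#' @return a `standard_curve`: list with `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `n`.
#' @export
fit_standard_curve <- function(log10_copies, cq) {
  ok <- !is.na(cq)
  log10_copies <- log10_copies[ok]; cq <- cq[ok]
  abort_if(length(unique(log10_copies)) < 3,
           "need at least 3 distinct dilution levels")
  fit <- stats::lm(cq ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  # summary.lm warns on exact collinear fits; ideal dilution ladders are
  # exactly linear, so that case is expected here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 efficiency = 10^(-1 / slope) - 1,
                 r_squared = r2,
                 n = length(cq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Cq = %.3f %+.4f * log10(copies); eff = %.1f%%, r2 = %.4f\n",
    x$intercept, x$slope, 100 * x$efficiency, x$r_squared))
  invisible(x)
}

#' Quantify starting copies from a Cq
#'
#' Inverts the fitted standard curve: `copies = 10^((Cq - intercept) /
#' slope)`. An uncalled Cq (`NA`) maps to zero starting quantity.
#'
#' @param cq called Cq (vector; `NA` allowed).
#' @param fit a `standard_curve`.
#' @return starting copies (vector).
#' @export
quantify <- function(cq, fit) {
  abort_if(!inherits(fit, "standard_curve"), "fit must be a standard_curve")
  out <- 10^((cq - fit$intercept) / fit$slope)
  out[is.na(cq)] <- 0
  out
}

#' Fallback plate-threshold estimator
#'
#' When the instrument's auto-computed threshold is unavailable: baseline
#' mean plus 10 baseline standard deviations, pooled over cycles 3-15 of
#' the supplied (typically NTC and early-cycle) traces.
#'
#' @param rfu_matrix cycles x wells matrix of fluorescence.
#' @param cycles cycle numbers of the rows.
#' @param baseline_cycles which cycles form the baseline window.
#' @param n_sd number of standard deviations above the baseline mean.
#' @return threshold in RFU.
#' @export
estimate_threshold <- function(rfu_matrix, cycles = seq_len(nrow(rfu_matrix)),
                               baseline_cycles = 3:15, n_sd = 10) {
  base <- rfu_matrix[cycles %in% baseline_cycles, , drop = FALSE]
  mean(base) + n_sd * stats::sd(base)
}

#' Screen one region's pooled qPCR results
#'
#' Decision table for a region screened with a sample pool (the pooled
#' field replicates), a positive pool (the same pool spiked with eDNA from
#' a confirmed-positive site), and contamination controls:
#' any NTC or equipment-blank amplification -> `contaminated`;
#' else a positive pool with no amplifying replicate -> `invalid_spike_fail`
#' (pooling may have diluted the target below detection);
#' else a sample pool with >= 1 replicate of positive starting quantity ->
#' `detected` (with a re-screen recommendation);
#' else `presumed_negative`. "Positive starting quantity" means a called Cq
#' whose quantified copy number is positive.
#'
#' @param region region label.
#' @param sample_quantities per-replicate starting quantities of the sample
#'   pool (>= 3 technical replicates).
#' @param positive_quantities per-replicate starting quantities of the
#'   positive pool.
#' @param ntc_quantities,eb_quantities control starting quantities (NTC:
#'   no-template PCR controls; EB: filtration equipment blanks).
#' @return a `region_call`: list with `region`, `status`, the replicate
#'   quantities, and `rescreen_recommended`.
#' @export
call_region <- function(region, sample_quantities, positive_quantities,
                        ntc_quantities, eb_quantities) {
  abort_if(length(sample_quantities) < 3,
           "need >= 3 technical replicates of the sample pool")
  abort_if(length(positive_quantities) < 3,
           "need >= 3 technical replicates of the positive pool")
  abort_if(length(ntc_quantities) < 1 || length(eb_quantities) < 1,
           "missing NTC or equipment-blank controls")
  status <- if (any(ntc_quantities > 0) || any(eb_quantities > 0)) {
    "contaminated"
  } else if (!any(positive_quantities > 0)) {
    "invalid_spike_fail"
  } else if (any(sample_quantities > 0)) {
    "detected"
  } else {
    "presumed_negative"
  }
  structure(list(region = region, status = status,
                 sample_quantities = sample_quantities,
                 positive_quantities = positive_quantities,
                 rescreen_recommended = status == "detected"),
            class = "region_call")
}

#' @export
print.region_call <- function(x, ...) {
  cat(sprintf("<region_call> %s: %s%s\n", x$region, x$status,
              if (x$rescreen_recommended) " (re-screen recommended)" else ""))
  invisible(x)
}

#' Replicate-concordance reliability check
#'
#' A detection is flagged reliable when a smoothed consensus trace (the
#' per-cycle mean across replicates, smoothed with a centred moving
#' average) exceeds the mean fluorescence threshold — concordant
#' amplification across replicates, not a spike in a single well.
#'
#' @param rfu_matrix cycles x replicates fluorescence matrix (>= 2
#'   replicates).
#' @param threshold mean fluorescence threshold.
#' @param window moving-average window in cycles (odd; default 3).
#' @return logical: is the detection reliable?
#' @export
reliability_check <- function(rfu_matrix, threshold, window = 3) {
  abort_if(ncol(rfu_matrix) < 2, "need >= 2 replicates")
  abort_if(window %% 2 != 1, "window must be odd")
  consensus <- rowMeans(rfu_matrix)
  k <- rep(1 / window, window)
  sm <- stats::filter(consensus, k, sides = 2)
  any(sm >= threshold, na.rm = TRUE)
}

#' Generate a synthetic amplification curve
#'
#' A logistic sigmoid in cycle number whose threshold crossing solves, in
#' closed form, to the Cq the standard-curve line assigns to the given
#' copy number: `Cq = intercept + slope * log10(copies)`. Zero copies give
#' a flat baseline-noise trace.
#'
#' @param copies starting template copies.
#' @param slope,intercept standard-curve line parameters (defaults: perfect
#'   doubling, intercept 38).
#' @param threshold fluorescence threshold the crossing is anchored to.
#' @param plateau sigmoid plateau, RFU.
#' @param steepness logistic growth rate per cycle.
#' @param n_cycles number of cycles.
#' @param noise_sd Gaussian noise s.d., RFU.
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return data.frame with `cycle` and `rfu`; the target Cq (or `NA`) as
#'   attribute `cq_true`.
#' @export
make_qpcr <- function(copies, slope = -1 / log10(2),
                      intercept = 38, threshold = 100, plateau = 3000,
                      steepness = 0.8, n_cycles = 45, noise_sd = 0,
                      seed = 1L) {
  cycle <- seq_len(n_cycles)
  if (copies <= 0) {
    rfu <- rep(0, n_cycles)
    cq_true <- NA_real_
  } else {
    cq_true <- intercept + slope * log10(copies)
    # place the sigmoid midpoint so the curve crosses `threshold` at cq_true
    mid <- cq_true + log(plateau / threshold - 1) / steepness
    rfu <- plateau / (1 + exp(-steepness * (cycle - mid)))
  }
  if (noise_sd > 0) {
    rfu <- rfu + with_seed(seed, function() stats::rnorm(n_cycles, 0,
                                                         noise_sd))
  }
  structure(data.frame(cycle = cycle, rfu = rfu), cq_true = cq_true,
            class = c("amplification_curve", "data.frame"))
}

#' Read / write qPCR plate exports
#'
#' Long-format CSV with columns `plate_id`, `well`, `role` (one of
#' `sample_pool`, `positive_pool`, `field_positive`, `tissue`, `standard`,
#' `NTC`, `EB`), `region`, `cycle`, `rfu`, and `log10_copies` (standards
#' only; `NA` elsewhere).
#'
#' @param path file path.
#' @param plate long-format plate data.frame (writer).
#' @return plate data.frame (reader) / `path` (writer).
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("plate_id", "well", "role", "region", "cycle", "rfu")
  miss <- setdiff(need, names(df))
  abort_if(length(miss) > 0, "plate CSV lacks column(s): %s",
           paste(miss, collapse = ", "))
  roles <- c("sample_pool", "positive_pool", "field_positive", "tissue",
             "standard", "NTC", "EB")
  bad <- !df$role %in% roles
  abort_if(any(bad), "unknown well role(s): %s",
           paste(unique(df$role[bad]), collapse = ", "))
  if (!"log10_copies" %in% names(df)) df$log10_copies <- NA_real_
  df
}

#' @rdname read_plate_csv
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' Screen a whole plate export
#'
#' Calls Cq per well, fits the standard curve from the plate's standards,
#' quantifies every well, and issues a [call_region()] decision per region
#' present.
#'
#' @param plate long-format plate data (see [read_plate_csv()]).
#' @param threshold fluorescence threshold; if `NULL`, estimated from the
#'   plate's NTC/EB traces with [estimate_threshold()].
#' @return list with `threshold`, `fit` (the `standard_curve`), `wells`
#'   (per-well Cq and quantity), and `calls` (list of `region_call`s).
#' @export
screen_plate <- function(plate, threshold = NULL) {
  split_wells <- split(plate, plate$well)
  if (is.null(threshold)) {
    ctrl <- plate[plate$role %in% c("NTC", "EB"), ]
    abort_if(nrow(ctrl) == 0, "no controls available to estimate threshold")
    m <- do.call(cbind, lapply(split(ctrl, ctrl$well), function(w)
      w$rfu[order(w$cycle)]))
    threshold <- estimate_threshold(m, cycles = sort(unique(ctrl$cycle)))
  }
  wells <- do.call(rbind, lapply(split_wells, function(w) {
    w <- w[order(w$cycle), ]
    data.frame(well = w$well[1], role = w$role[1], region = w$region[1],
               log10_copies = w$log10_copies[1],
               cq = call_cq(w$cycle, w$rfu, threshold))
  }))
  std <- wells[wells$role == "standard", ]
  abort_if(nrow(std) < 3, "plate has fewer than 3 standards")
  fit <- fit_standard_curve(std$log10_copies, std$cq)
  wells$quantity <- quantify(wells$cq, fit)
  ntc <- wells$quantity[wells$role == "NTC"]
  eb <- wells$quantity[wells$role == "EB"]
  if (length(eb) == 0) eb <- 0  # plates without a filtration blank well
  regions <- unique(wells$region[wells$role %in%
                                   c("sample_pool", "positive_pool")])
  calls <- lapply(regions, function(rg) {
    call_region(rg,
                wells$quantity[wells$role == "sample_pool" &
                                 wells$region == rg],
                wells$quantity[wells$role == "positive_pool" &
                                 wells$region == rg],
                ntc, eb)
  })
  names(calls) <- regions
  rownames(wells) <- NULL
  list(threshold = threshold, fit = fit, wells = wells, calls = calls)
}

#' Plan a pooled screening design
#'
#' Pools at most `max_members` samples per region (the dilution bound for
#' reliable amplification of a single low-abundance positive), flagging the
#' spiked positive pool.
#'
#' @param sample_ids character vector of member sample ids.
#' @param region region label.
#' @param spike_source_id id of the confirmed-positive spike extract, or
#'   `NULL` for the unspiked sample pool.
#' @param max_members pooling cap (default 20).
#' @return a `pool_plan`.
#' @export
pool_plan <- function(sample_ids, region, spike_source_id = NULL,
                      max_members = 20) {
  abort_if(length(sample_ids) < 1, "a pool needs at least one member")
  abort_if(length(sample_ids) > max_members,
           "pool of %d exceeds the %d-member cap", length(sample_ids),
           max_members)
  structure(list(region = region, member_ids = sample_ids,
                 spiked = !is.null(spike_source_id),
                 spike_source_id = spike_source_id),
            class = "pool_plan")
}
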