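# Landing inference: per-cell tallies, region aggregation, drift-time
# statistics, density clouds, and ENSO/season covariate association.

#' Tally landings per settlement cell
#'
#' @param records landing records (data.frame with `cell_id`; typically the
#'   `landings` component of a [run_simulation()] result).
#' @param total_released total particles released by the schedule.
#' @return a `landing_table`: data.frame with one row per cell receiving at
#'   least one landing (`cell_id`, `count`, `percent`), `total_released`
#'   as an attribute. `percent` is exact; [format_percent()] renders it the
#'   way reports print it (half-up to one decimal).
#' @export
tally_landings <- function(records, total_released) {
  cnt <- table(records$cell_id)
  abort_if(total_released < sum(cnt),
           "total_released is smaller than the number of landings")
  out <- data.frame(cell_id = as.integer(names(cnt)),
                    count = as.integer(cnt))
  out <- out[order(-out$count, out$cell_id), , drop = FALSE]
  rownames(out) <- NULL
  out$percent <- 100 * out$count / total_released
  structure(out, total_released = total_released,
            class = c("landing_table", "data.frame"))
}

#' Landing percentage as printed in reports
#'
#' Percent of total released, rounded half-up to one decimal.
#'
#' @param count landing count (vector).
#' @param total_released schedule total.
#' @return numeric vector, one decimal place.
#' @export
format_percent <- function(count, total_released) {
  round_half_up(100 * count / total_released, 1)
}

#' Define a region-of-interest bounding box
#'
#' @param name region label.
#' @param lat `c(min, max)` latitude, degrees.
#' @param lon `c(min, max)` longitude, degrees; any convention; a pair whose
#'   wrapped min exceeds its wrapped max spans the 0/360 seam.
#' @return a `region_box`.
#' @export
region_box <- function(name, lat, lon) {
  abort_if(lat[1] >= lat[2], "degenerate latitude range")
  lon <- wrap_lon(lon)
  abort_if(lon[1] == lon[2], "degenerate longitude range")
  structure(list(name = name, lat = lat, lon = lon), class = "region_box")
}

in_box <- function(box, lon, lat) {
  lon <- wrap_lon(lon)
  lon_in <- if (box$lon[1] < box$lon[2])
    lon >= box$lon[1] & lon < box$lon[2]
  else
    lon >= box$lon[1] | lon < box$lon[2]
  lon_in & lat >= box$lat[1] & lat < box$lat[2]
}

validate_disjoint <- function(boxes) {
  if (length(boxes) < 2) return(invisible(NULL))
  # sample-free check: lat intervals and circular lon intervals must not
  # both overlap for any pair
  seg <- function(lon) if (lon[1] < lon[2]) list(lon) else
    list(c(lon[1], 360), c(0, lon[2]))
  for (i in seq_along(boxes)[-length(boxes)]) for (j in (i + 1):length(boxes)) {
    a <- boxes[[i]]; b <- boxes[[j]]
    lat_olap <- a$lat[1] < b$lat[2] && b$lat[1] < a$lat[2]
    lon_olap <- any(vapply(seg(a$lon), function(s1)
      any(vapply(seg(b$lon), function(s2)
        s1[1] < s2[2] && s2[1] < s1[2], TRUE)), TRUE))
    abort_if(lat_olap && lon_olap, "region boxes '%s' and '%s' overlap",
             a$name, b$name)
  }
  invisible(NULL)
}

#' Aggregate a landing table into regions of interest
#'
#' A cell contributes to the region whose box contains its centroid
#' (inclusive lower bounds, exclusive upper bounds); cells in no box form
#' the `"other"` residue. Boxes are validated pairwise disjoint.
#'
#' @param table a `landing_table` from [tally_landings()].
#' @param cells data.frame with `id`, `lon`, `lat` cell centroids (the
#'   `cells` component of a `hex_grid`), or a `hex_grid`.
#' @param boxes list of [region_box()] objects.
#' @return data.frame with `region`, `count`, `percent` (exact percent of
#'   total released), including the `"other"` row.
#' @export
aggregate_regions <- function(table, cells, boxes) {
  if (inherits(cells, "hex_grid")) cells <- cells$cells
  validate_disjoint(boxes)
  total <- attr(table, "total_released")
  m <- match(table$cell_id, cells$id)
  abort_if(anyNA(m), "landing table references unknown cell ids")
  clon <- cells$lon[m]; clat <- cells$lat[m]
  region <- rep("other", nrow(table))
  for (b in boxes) {
    hit <- in_box(b, clon, clat)
    region[hit] <- b$name
  }
  agg <- stats::aggregate(list(count = table$count),
                          by = list(region = region), FUN = sum)
  lv <- c(vapply(boxes, function(b) b$name, ""), "other")
  agg <- agg[match(lv[lv %in% agg$region], agg$region), , drop = FALSE]
  missing <- setdiff(lv, agg$region)
  if (length(missing))
    agg <- rbind(agg, data.frame(region = missing, count = 0L))
  agg$percent <- 100 * agg$count / total
  rownames(agg) <- NULL
  agg
}

#' Drift-time summary and pairwise tests by region
#'
#' @param records landing records with `drift_days` and `cell_id`.
#' @param grouping either a function mapping rows to group labels, or a
#'   character vector of labels aligned with `records` rows; `NA` labels are
#'   dropped.
#' @return list with `summary` (per-group n/mean/median days) and `tests`
#'   (pairwise rank-sum with Bonferroni, via [pairwise_rank_sum()]).
#' @export
drift_time_summary <- function(records, grouping) {
  labels <- if (is.function(grouping)) grouping(records) else grouping
  keep <- !is.na(labels)
  if (any(!keep)) labels <- labels[keep]
  rec <- records[keep, , drop = FALSE]
  groups <- split(rec$drift_days, labels)
  empty <- vapply(groups, length, 1L) == 0
  if (any(empty)) {
    warning("dropping empty groups: ", paste(names(groups)[empty],
                                             collapse = ", "))
    groups <- groups[!empty]
  }
  abort_if(length(groups) < 2, "need at least two non-empty groups")
  summ <- do.call(rbind, lapply(names(groups), function(g)
    data.frame(region = g, n = length(groups[[g]]),
               mean_days = mean(groups[[g]]),
               median_days = stats::median(groups[[g]]))))
  list(summary = summ, tests = pairwise_rank_sum(groups))
}

#' Density cloud of particle positions
#'
#' Bins every logged particle position into pixels of the given resolution
#' and reports the proportion of all position samples per pixel.
#'
#' @param trajectories trajectory log (data.frame with `lon`, `lat`).
#' @param resolution pixel size, degrees.
#' @return data.frame with `lon_bin`, `lat_bin` (pixel lower-left corners)
#'   and `proportion`; proportions sum to 1.
#' @export
density_cloud <- function(trajectories, resolution = 1) {
  abort_if(is.null(trajectories) || nrow(trajectories) == 0,
           "empty trajectory log")
  lon_bin <- floor(wrap_lon(trajectories$lon) / resolution) * resolution
  lat_bin <- floor(trajectories$lat / resolution) * resolution
  tab <- stats::aggregate(list(n = rep(1L, length(lon_bin))),
                          by = list(lon_bin = lon_bin, lat_bin = lat_bin),
                          FUN = sum)
  tab$proportion <- tab$n / sum(tab$n)
  tab$n <- NULL
  tab
}

#' Associate landings with ENSO phase and season
#'
#' Bins landings by landing month, labels each month with its ENSO phase
#' (from the supplied series) and climatological season (DJF, MAM, JJA,
#' SON), and, per region, runs pairwise rank-sum tests on the monthly
#' landing counts between phases and between seasons, Bonferroni-corrected
#' within each family. Months inside the series but with zero landings
#' count as zeros.
#'
#' @param records landing records with `landing_date` and `cell_id`.
#' @param enso an `enso_series` (see [make_enso()] / [read_enso_csv()]).
#' @param cells cell centroids (`hex_grid` or its `cells` data.frame).
#' @param boxes list of [region_box()]; landings outside all boxes are
#'   grouped as `"other"`.
#' @param paired use the paired test variant (see [pairwise_rank_sum()]).
#' @return list with `monthly` (month x region counts with phase and season
#'   labels), `phase_tests` and `season_tests` (one data.frame each, tested
#'   per region).
#' @export
covariate_association <- function(records, enso, cells, boxes,
                                  paired = FALSE) {
  if (inherits(cells, "hex_grid")) cells <- cells$cells
  validate_disjoint(boxes)
  ym <- format(as.Date(records$landing_date), "%Y-%m")
  abort_if(!all(ym %in% enso$month),
           "ENSO series does not cover all landing months")
  m <- match(records$cell_id, cells$id)
  clon <- cells$lon[m]; clat <- cells$lat[m]
  region <- rep("other", nrow(records))
  for (b in boxes) region[in_box(b, clon, clat)] <- b$name
  months <- enso$month
  regions <- unique(c(vapply(boxes, function(b) b$name, ""),
                      unique(region)))
  monthly <- expand.grid(month = months, region = regions,
                         stringsAsFactors = FALSE)
  key <- paste(ym, region)
  cnt <- table(key)
  monthly$count <- as.integer(cnt[paste(monthly$month, monthly$region)])
  monthly$count[is.na(monthly$count)] <- 0L
  monthly$phase <- enso$phase[match(monthly$month, enso$month)]
  mnum <- as.integer(substr(monthly$month, 6, 7))
  monthly$season <- season_of_month(mnum)

  family <- function(label_col) {
    do.call(rbind, lapply(regions, function(rg) {
      sub <- monthly[monthly$region == rg, ]
      groups <- split(sub$count, sub[[label_col]])
      groups <- groups[vapply(groups, length, 1L) > 0]
      if (length(groups) < 2) return(NULL)
      out <- pairwise_rank_sum(groups, paired = paired)
      cbind(region = rg, out)
    }))
  }
  list(monthly = monthly,
       phase_tests = family("phase"),
       season_tests = family("season"))
}

#' Climatological season of a month number
#'
#' December-January-February (DJF), March-April-May (MAM),
#' June-July-August (JJA), September-October-November (SON).
#'
#' @param month integer month(s), 1-12.
#' @return character vector of season codes.
#' @export
season_of_month <- function(month) {
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[month]
}
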