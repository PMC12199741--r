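# Drifter-based horizontal-diffusivity calibration by minimum passing
# distance: backtrack an ensemble from a drifter's final fix and score each
# candidate K by how close the ensemble members pass to the known origin.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6,371 km. Vectorised;
#' symmetric; zero iff the points coincide.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  R <- 6371
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dp <- p2 - p1
  dl <- deg2rad(lon2 - lon1)
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

#' Minimum passing distance of a trajectory to a reference point
#'
#' @param lon,lat logged trajectory positions, degrees.
#' @param reference `c(lon, lat)` of the reference point.
#' @return minimum haversine distance in km over all logged positions.
#' @export
min_passing_distance <- function(lon, lat, reference) {
  abort_if(length(lon) == 0, "empty trajectory")
  min(haversine_km(lon, lat, reference[1], reference[2]))
}

#' Simulate a drifter track with known diffusivity
#'
#' Forward-simulates a surface drifter with the transport integrator and
#' observes its position at a fixed cadence (default every 4 hours) with
#' optional Gaussian position noise, mimicking a satellite-tracked buoy.
#' The generating diffusivity is recorded as ground truth.
#'
#' @param field a [velocity_field].
#' @param start `c(lon, lat)` release point, degrees.
#' @param start_time release time.
#' @param K_true generating horizontal diffusivity, m^2/s.
#' @param duration_days track length in days.
#' @param cadence_hours observation cadence (default 4 h).
#' @param noise_sd_deg s.d. of Gaussian observation noise per axis, degrees.
#' @param seed RNG seed.
#' @return a `drifter_track`: data.frame of fixes (`time`, `lon`, `lat`)
#'   with the origin, final fix and `K_true` as attributes.
#' @export
make_drifter <- function(field, start, start_time, K_true = 10,
                         duration_days = 30, cadence_hours = 4,
                         noise_sd_deg = 0, seed = 1L) {
  t0 <- as_utc(start_time)
  dt <- 3600
  n_steps <- as.integer(duration_days * 24)
  abort_if(as.numeric(t0) + n_steps * dt > as.numeric(max(field$time)),
           "duration extends past the field's time range")
  lon <- numeric(n_steps + 1); lat <- numeric(n_steps + 1)
  lon[1] <- wrap_lon(start[1]); lat[1] <- start[2]
  kick_sd <- if (K_true > 0) sqrt(2 * K_true * dt) else 0
  z <- with_seed(substream_seed(seed, 7L),
                 function() matrix(stats::rnorm(2 * n_steps), n_steps, 2))
  t_cur <- t0
  for (s in seq_len(n_steps)) {
    adv <- advect_rk4(field, lon[s], lat[s], t_cur, dt, "forward")
    if (K_true > 0) {
      dif <- diffuse(adv$lon, adv$lat, dt, K_true,
                     z = matrix(z[s, ], 1, 2))
    } else dif <- adv
    lon[s + 1] <- dif$lon; lat[s + 1] <- dif$lat
    t_cur <- t_cur + dt
  }
  keep <- seq(1, n_steps + 1, by = cadence_hours)
  fixes <- data.frame(
    time = t0 + (keep - 1) * dt,
    lon = lon[keep], lat = lat[keep])
  if (noise_sd_deg > 0) {
    zn <- with_seed(substream_seed(seed, 11L),
                    function() matrix(stats::rnorm(2 * nrow(fixes)),
                                      ncol = 2))
    fixes$lon <- wrap_lon(fixes$lon + zn[, 1] * noise_sd_deg)
    fixes$lat <- fixes$lat + zn[, 2] * noise_sd_deg
  }
  structure(fixes, class = c("drifter_track", "data.frame"),
            origin = c(lon[1], lat[1]), K_true = K_true)
}

#' Write / read drifter tracks as CSV
#'
#' CSV columns: `timestamp` (ISO-8601), `lon`, `lat`, `drifter_id`.
#'
#' @param track a `drifter_track` (or data.frame of fixes).
#' @param path file path.
#' @param drifter_id identifier stored in the CSV.
#' @return `path` (writer) / data.frame of fixes (reader).
#' @export
write_drifter_csv <- function(track, path, drifter_id = "drifter-1") {
  utils::write.csv(data.frame(
    timestamp = format(track$time, "%Y-%m-%dT%H:%M:%SZ"),
    lon = track$lon, lat = track$lat, drifter_id = drifter_id),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drifter_csv
#' @export
read_drifter_csv <- function(path) {
  df <- utils::read.csv(path)
  abort_if(!all(c("timestamp", "lon", "lat") %in% names(df)),
           "drifter CSV needs timestamp, lon, lat columns")
  out <- data.frame(time = as_utc(sub("T", " ", sub("Z$", "", df$timestamp))),
                    lon = df$lon, lat = df$lat,
                    drifter_id = if ("drifter_id" %in% names(df))
                      df$drifter_id else NA)
  abort_if(any(diff(as.numeric(out$time)) <= 0),
           "drifter timestamps must be strictly increasing")
  out
}

# Backtrack an ensemble from an endpoint and return each member's minimum
# passing distance (km) to the origin over daily logged positions.
backtrack_passing_distances <- function(field, endpoint, end_time, origin,
                                        K, n, seed, max_days) {
  schedule <- release_schedule(site = endpoint, particles_per_day = n,
                               start_date = as.Date(as_utc(end_time)),
                               end_date = as.Date(as_utc(end_time)))
  config <- transport_config(K = K, direction = "backward", seed = seed,
                             max_duration = max_days)
  grid <- build_hex_grid(c(0, 2, 0, 2))  # placeholder; no active cells
  run <- run_simulation(field, schedule, empty_settlement(grid), config,
                        save_trajectories = TRUE)
  tr <- run$trajectories
  dist <- haversine_km(tr$lon, tr$lat, origin[1], origin[2])
  out <- tapply(dist, tr$particle_id, min)
  as.numeric(out[order(as.integer(names(out)))])
}

#' Calibrate horizontal diffusivity against a known origin
#'
#' For each candidate diffusivity, backtracks `n` particles from the
#' endpoint (a drifter's final fix) and scores each particle by its minimum
#' passing distance to the known origin. Reports per-K summary statistics,
#' all pairwise rank-sum tests with Bonferroni correction, the selected K
#' (smallest mean passing distance), and the set of candidates statistically
#' indistinguishable from it (adjusted p >= 0.05).
#'
#' @param field a [velocity_field].
#' @param endpoint `c(lon, lat)` of the final fix.
#' @param end_time time of the final fix.
#' @param origin `c(lon, lat)` of the true release location.
#' @param K_candidates candidate diffusivities, m^2/s.
#' @param n ensemble size per candidate (>= 2).
#' @param seed master RNG seed; each candidate gets its own substream.
#' @param max_days maximum backtracking duration, days.
#' @return a `calibration_result`: list with `distances` (long data.frame of
#'   per-particle km), `summary` (per-K mean/median/IQR), `tests` (pairwise
#'   rank-sum report), `selected_K`, `indistinguishable`.
#' @export
calibrate_diffusivity <- function(field, endpoint, end_time, origin,
                                  K_candidates = c(0.5, 5, 10, 20, 50),
                                  n = 1000, seed = 1L, max_days = Inf) {
  abort_if(n < 2, "ensemble size n must be >= 2")
  abort_if(length(K_candidates) < 1, "need at least one candidate K")
  dist_list <- lapply(seq_along(K_candidates), function(i)
    backtrack_passing_distances(field, endpoint, end_time, origin,
                                K_candidates[i], n,
                                substream_seed(seed, i), max_days))
  distances <- data.frame(
    K = rep(K_candidates, vapply(dist_list, length, 1L)),
    distance_km = unlist(dist_list))
  summ <- do.call(rbind, lapply(seq_along(K_candidates), function(i) {
    d <- dist_list[[i]]
    q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
    data.frame(K = K_candidates[i], n = length(d), mean_km = mean(d),
               median_km = stats::median(d), iqr_lo_km = q[1],
               iqr_hi_km = q[2])
  }))
  tests <- if (length(K_candidates) >= 2) {
    pairwise_rank_sum(dist_list, labels = as.character(K_candidates))
  } else NULL
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

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("selected K = %g m^2/s (indistinguishable: %s)\n",
              x$selected_K, paste(x$indistinguishable, collapse = ", ")))
  invisible(x)
}
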