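# Lagrangian surface transport: RK4 advection + random-walk diffusion,
# forward or backward in time, with daily output and settlement checks.

#' Daily release schedule
#'
#' @param site release point `c(lon, lat)`, degrees. Default is the Manawai
#'   (Pearl and Hermes Atoll) release point used throughout: 27.8333 N,
#'   175.8333 W.
#' @param particles_per_day particles released each calendar day.
#' @param start_date,end_date first and last release day (inclusive).
#' @return a `release_schedule`.
#' @export
release_schedule <- function(site = c(wrap_lon(-175.8333), 27.8333),
                             particles_per_day = 100,
                             start_date = "2000-01-01",
                             end_date = "2015-12-30") {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  abort_if(end_date < start_date, "end_date before start_date")
  abort_if(particles_per_day < 1, "particles_per_day must be >= 1")
  structure(list(site = c(wrap_lon(site[1]), site[2]),
                 particles_per_day = as.integer(particles_per_day),
                 start_date = start_date, end_date = end_date),
            class = "release_schedule")
}

#' Total particles a schedule releases
#'
#' Releases happen on every calendar day from `start_date` through
#' `end_date` inclusive, `particles_per_day` at a time.
#'
#' @param schedule a [release_schedule()].
#' @return integer count.
#' @export
n_released <- function(schedule) {
  days <- as.integer(schedule$end_date - schedule$start_date) + 1L
  days * schedule$particles_per_day
}

#' Transport configuration
#'
#' @param K horizontal diffusivity, m^2/s (default 10, the drifter-calibrated
#'   value).
#' @param internal_step integrator sub-step, seconds; must divide
#'   `output_interval`.
#' @param output_interval interval between logged positions and settlement
#'   checks, seconds (default one day).
#' @param direction `"forward"` or `"backward"` in time.
#' @param seed master RNG seed; each particle draws its diffusion kicks from
#'   an independent substream keyed by particle id, so results do not depend
#'   on execution order or batching.
#' @param max_duration maximum tracking duration in days (default: until the
#'   velocity field's time boundary; particles still adrift there expire).
#' @return a `transport_config`.
#' @export
transport_config <- function(K = 10, internal_step = 3600,
                             output_interval = 86400,
                             direction = c("forward", "backward"),
                             seed = 1L, max_duration = Inf) {
  direction <- match.arg(direction)
  abort_if(K < 0, "K must be non-negative")
  abort_if(output_interval %% internal_step != 0,
           "internal_step must divide output_interval")
  structure(list(K = K, internal_step = internal_step,
                 output_interval = output_interval, direction = direction,
                 seed = as.integer(seed), max_duration = max_duration),
            class = "transport_config")
}

# Velocity in degrees/s at particle positions, clamped for sampling;
# out-of-range positions are flagged.
deg_velocity <- function(field, lon, lat, t) {
  latr <- range(field$lat)
  esc <- lat < latr[1] - 1e-9 | lat > latr[2] + 1e-9
  if (!field$periodic) {
    lonr <- range(field$lon)
    q <- wrap_lon(lon)
    esc <- esc | q < lonr[1] - 1e-9 | q > lonr[2] + 1e-9
    lon <- pmin(pmax(q, lonr[1]), lonr[2])
  }
  lat_c <- pmin(pmax(lat, latr[1]), latr[2])
  vel <- sample_velocity(field, lon, lat_c, t)
  list(dlon = vel$u / (M_PER_DEG * cos(deg2rad(lat_c))),
       dlat = vel$v / M_PER_DEG,
       escaped = esc)
}

#' One Runge-Kutta advection step
#'
#' Classical 4-stage Runge-Kutta over the interpolated velocity field.
#' Backward steps integrate the time-reversed dynamics (negated velocities,
#' decreasing clock). Meters convert to degrees with 111,195 m per degree
#' latitude and a cos(latitude) factor for longitude. Vectorised over
#' particles.
#'
#' @param field a [velocity_field].
#' @param lon,lat particle positions, degrees.
#' @param t current clock (shared by all particles).
#' @param dt step length, seconds (positive).
#' @param direction `"forward"` or `"backward"`.
#' @return list of `lon` (wrapped to `[0, 360)`), `lat`, and logical
#'   `escaped` flagging particles that left the grid during the step.
#' @export
advect_rk4 <- function(field, lon, lat, t, dt,
                       direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  sgn <- if (direction == "forward") 1 else -1
  t <- as.numeric(as_utc(t))
  h <- sgn * dt

  k1 <- deg_velocity(field, lon, lat, t)
  k2 <- deg_velocity(field, lon + h / 2 * k1$dlon, lat + h / 2 * k1$dlat,
                     t + h / 2)
  k3 <- deg_velocity(field, lon + h / 2 * k2$dlon, lat + h / 2 * k2$dlat,
                     t + h / 2)
  k4 <- deg_velocity(field, lon + h * k3$dlon, lat + h * k3$dlat, t + h)

  nlon <- lon + h / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
  nlat <- lat + h / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
  esc <- k1$escaped | k2$escaped | k3$escaped | k4$escaped
  latr <- range(field$lat)
  esc <- esc | nlat < latr[1] | nlat > latr[2]
  if (!field$periodic) {
    lonr <- range(field$lon)
    q <- wrap_lon(nlon)
    esc <- esc | q < lonr[1] | q > lonr[2]
  }
  list(lon = wrap_lon(nlon), lat = nlat, escaped = esc)
}

#' One random-walk diffusion step
#'
#' Independent zero-mean Gaussian displacements per horizontal axis with
#' variance `2 K dt` in meters squared, converted to degrees at the
#' particle's latitude. `K = 0` is the identity. Supplying `z` (an `n x 2`
#' matrix of standard normals) makes the kick a pure function of its inputs;
#' otherwise draws come from the current RNG stream.
#'
#' @param lon,lat particle positions, degrees.
#' @param dt step length, seconds.
#' @param K horizontal diffusivity, m^2/s.
#' @param z optional `n x 2` matrix of standard normal draws.
#' @return list of displaced `lon` (wrapped) and `lat`.
#' @export
diffuse <- function(lon, lat, dt, K, z = NULL) {
  abort_if(K < 0, "K must be non-negative")
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  if (K == 0) return(list(lon = wrap_lon(lon), lat = lat))
  if (is.null(z)) z <- matrix(stats::rnorm(2 * n), n, 2)
  sd_m <- sqrt(2 * K * dt)
  list(lon = wrap_lon(lon + z[, 1] * sd_m / (M_PER_DEG * cos(deg2rad(lat)))),
       lat = lat + z[, 2] * sd_m / M_PER_DEG)
}

# Pre-draw a particle-day's diffusion kicks from its substream.
# Row s of the matrix is the (lon, lat) standard-normal pair for sub-step s;
# rows beyond nsub are consumed, in order, by coast-resampling.
day_kicks <- function(seed, id, day_index, nsub, slack = 10) {
  with_seed(substream_seed(substream_seed(seed, id), day_index),
            function() matrix(stats::rnorm(2 * nsub * (1 + slack)),
                              ncol = 2, byrow = TRUE))
}

#' Run a dispersal simulation
#'
#' Releases `particles_per_day` particles on each calendar day of the
#' schedule (inclusive), integrates each with alternating RK4 advection
#' sub-steps and diffusion kicks, logs positions at every output interval,
#' and tests active particles against the active settlement cells at each
#' output interval; first containment lands the particle and removes it.
#' Particles leaving the grid become `escaped_domain`; particles still
#' adrift at the field's time boundary (or past `max_duration`) expire.
#'
#' A sub-step that would put a particle on a land node has its diffusion
#' kick resampled up to 10 times, after which the particle stays put for
#' that sub-step.
#'
#' @param field a [velocity_field].
#' @param schedule a [release_schedule()].
#' @param settlement a `settlement_set` (possibly [empty_settlement()]).
#' @param config a [transport_config()].
#' @param save_trajectories log positions at every output interval.
#' @return a `dispersal_run`: list with `particles` (final status of every
#'   particle), `landings` (one row per landed particle: `particle_id`,
#'   `release_date`, `landing_date`, `drift_days`, `cell_id`, `lon`, `lat`),
#'   `trajectories` (if requested), and `total_released`.
#' @export
run_simulation <- function(field, schedule, settlement, config,
                           save_trajectories = FALSE) {
  abort_if(!inherits(settlement, "settlement_set"),
           "settlement must be a settlement_set")
  t_field <- as.numeric(range(field$time))
  rel_days <- seq(schedule$start_date, schedule$end_date, by = "day")
  rel_times <- as.numeric(as_utc(rel_days))
  abort_if(min(rel_times) < t_field[1] || max(rel_times) > t_field[2],
           "release schedule is outside the field's time range")

  fwd <- config$direction == "forward"
  sgn <- if (fwd) 1 else -1
  out_dt <- config$output_interval
  nsub <- as.integer(out_dt / config$internal_step)
  dt <- config$internal_step
  n_per <- schedule$particles_per_day
  n_days <- length(rel_days)
  total <- n_per * n_days

  # particle state
  id <- integer(0); lon <- numeric(0); lat <- numeric(0)
  released_t <- numeric(0); age_days <- integer(0)
  ret_id <- integer(0); ret_status <- character(0)
  ret_lon <- numeric(0); ret_lat <- numeric(0)
  ret_cell <- integer(0); ret_time <- numeric(0); ret_release <- numeric(0)
  traj <- if (save_trajectories) vector("list", 0) else NULL

  retire <- function(sel, why, cell = NA_integer_, when = NA_real_) {
    # appends to the retired pools in the enclosing frame
    ret_id <<- c(ret_id, id[sel])
    ret_status <<- c(ret_status, rep(why, sum(sel)))
    ret_lon <<- c(ret_lon, lon[sel]); ret_lat <<- c(ret_lat, lat[sel])
    ret_cell <<- c(ret_cell, if (length(cell) == 1) rep(cell, sum(sel)) else cell)
    ret_time <<- c(ret_time, if (length(when) == 1) rep(when, sum(sel)) else when)
    ret_release <<- c(ret_release, released_t[sel])
    keep <- !sel
    id <<- id[keep]; lon <<- lon[keep]; lat <<- lat[keep]
    released_t <<- released_t[keep]; age_days <<- age_days[keep]
  }

  check_settlement <- function(t_now) {
    if (!any(set_active) || length(id) == 0) return(invisible(NULL))
    cells <- locate_cell(settlement, lon, lat)
    landed <- !is.na(cells)
    if (any(landed)) {
      retire(landed, "landed", cell = cells[landed], when = t_now)
    }
    invisible(NULL)
  }
  set_active <- any(settlement$active)

  # walk absolute time through the release days (down them when backward)
  day_order <- if (fwd) seq_len(n_days) else rev(seq_len(n_days))
  t_now <- rel_times[day_order[1]]
  t_stop <- if (fwd) t_field[2] else t_field[1]
  next_rel <- 1L  # pointer into day_order

  repeat {
    # release any batches whose time the clock has reached or passed
    while (next_rel <= n_days &&
           (if (fwd) rel_times[day_order[next_rel]] <= t_now
            else rel_times[day_order[next_rel]] >= t_now)) {
      d <- day_order[next_rel]
      new_ids <- (d - 1L) * n_per + seq_len(n_per)
      id <- c(id, new_ids)
      lon <- c(lon, rep(schedule$site[1], n_per))
      lat <- c(lat, rep(schedule$site[2], n_per))
      released_t <- c(released_t, rep(rel_times[d], n_per))
      age_days <- c(age_days, rep(0L, n_per))
      next_rel <- next_rel + 1L
    }
    check_settlement(t_now)
    if (save_trajectories && length(id)) {
      traj[[length(traj) + 1]] <- data.frame(
        particle_id = id, time = t_now, lon = lon, lat = lat)
    }
    done <- next_rel > n_days && length(id) == 0
    out_of_time <- if (fwd) t_now + out_dt > t_stop else t_now - out_dt < t_stop
    if (done || out_of_time) break

    if (length(id)) {
      # pre-draw each active particle's kicks for this day
      day_idx <- age_days + 1L
      if (config$K > 0) {
        kicks <- lapply(seq_along(id), function(k)
          day_kicks(config$seed, id[k], day_idx[k], nsub))
        # (particle, sub-step, axis) array for the regular kicks
        zarr <- vapply(kicks, function(m) m[seq_len(nsub), , drop = FALSE],
                       matrix(0, nsub, 2))
        cursor <- rep(nsub, length(id))  # last consumed row per particle
      }
      t_sub <- t_now
      for (s in seq_len(nsub)) {
        prev_lon <- lon; prev_lat <- lat
        adv <- advect_rk4(field, lon, lat, t_sub, dt, config$direction)
        if (config$K > 0) {
          z <- cbind(zarr[s, 1, ], zarr[s, 2, ])
          dif <- diffuse(adv$lon, adv$lat, dt, config$K, z = z)
        } else {
          dif <- adv
        }
        nlon <- dif$lon; nlat <- dif$lat
        grounded <- !adv$escaped & is_land(field, nlon, nlat)
        if (any(grounded) && config$K > 0) {
          for (k in which(grounded)) {
            ok <- FALSE
            for (try in 1:10) {
              cursor[k] <- cursor[k] + 1L
              if (cursor[k] > nrow(kicks[[k]])) break
              z1 <- kicks[[k]][cursor[k], ]
              cand <- diffuse(adv$lon[k], adv$lat[k], dt, config$K,
                              z = matrix(z1, 1, 2))
              if (!is_land(field, cand$lon, cand$lat)) {
                nlon[k] <- cand$lon; nlat[k] <- cand$lat; ok <- TRUE
                break
              }
            }
            if (!ok) { nlon[k] <- prev_lon[k]; nlat[k] <- prev_lat[k] }
          }
        } else if (any(grounded)) {
          nlon[grounded] <- prev_lon[grounded]
          nlat[grounded] <- prev_lat[grounded]
        }
        lon <- nlon; lat <- nlat
        if (any(adv$escaped)) retire(adv$escaped, "escaped_domain")
        if (config$K > 0) {
          # keep auxiliary structures aligned after retirement
          keep <- !adv$escaped
          if (!all(keep)) {
            kicks <- kicks[keep]; cursor <- cursor[keep]
            zarr <- zarr[, , keep, drop = FALSE]
          }
        }
        t_sub <- t_sub + sgn * dt
      }
      age_days <- age_days + 1L
      # expiry past max duration
      if (is.finite(config$max_duration) && length(id)) {
        old <- age_days >= config$max_duration
        if (any(old)) {
          # they still get this day's settlement check first
          t_next <- t_now + sgn * out_dt
          cells <- locate_cell(settlement, lon, lat)
          land_now <- old & !is.na(cells)
          if (any(land_now))
            retire(land_now, "landed", cell = cells[land_now], when = t_next)
          old <- age_days >= config$max_duration
          if (any(old)) retire(old, "expired")
        }
      }
    }
    t_now <- t_now + sgn * out_dt
  }
  # survivors at the field's time boundary expire
  if (length(id)) retire(rep(TRUE, length(id)), "expired")

  particles <- data.frame(
    particle_id = ret_id, status = ret_status,
    release_date = as.Date(as_utc(ret_release)),
    lon = ret_lon, lat = ret_lat,
    landing_cell = ret_cell,
    landing_time = as_utc(ret_time))
  particles <- particles[order(particles$particle_id), ]
  rownames(particles) <- NULL
  is_l <- particles$status == "landed"
  landings <- data.frame(
    particle_id = particles$particle_id[is_l],
    release_date = particles$release_date[is_l],
    landing_date = as.Date(particles$landing_time[is_l]),
    drift_days = as.integer(round(abs(
      as.numeric(particles$landing_time[is_l]) -
        as.numeric(as_utc(particles$release_date[is_l]))) / 86400)),
    cell_id = particles$landing_cell[is_l],
    lon = particles$lon[is_l], lat = particles$lat[is_l])
  structure(list(particles = particles, landings = landings,
                 trajectories = if (save_trajectories)
                   do.call(rbind, traj) else NULL,
                 total_released = total, config = config),
            class = "dispersal_run")
}

#' @export
print.dispersal_run <- function(x, ...) {
  tab <- table(factor(x$particles$status,
                      levels = c("active", "landed", "escaped_domain",
                                 "expired")))
  cat(sprintf("<dispersal_run> %d released (%s)\n", x$total_released,
              x$config$direction))
  for (nm in names(tab)) cat(sprintf("  %-15s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Write landing records to CSV
#'
#' @param run a `dispersal_run` (or its `landings` data.frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landings_csv <- function(run, path) {
  df <- if (inherits(run, "dispersal_run")) run$landings else run
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
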