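# Analytic velocity fields and island coastlines with known ground truth.
#
# All analytic fields are defined by closed-form motion in *degree space*:
# a rate (dlon/dt, dlat/dt) in degrees/s is prescribed and converted to
# physical m/s with the same per-latitude metric the integrator uses
# (M_PER_DEG and cos(lat)). This makes the degree-space trajectories exact
# closed forms (lines, circles, exponential spirals), which is what the
# oracle tests need; physical speeds remain realistic (order 0.1-1 m/s).

#' Specify an analytic velocity field
#'
#' @param kind one of `"uniform"`, `"solid_body"`, `"double_gyre"`,
#'   `"convergent_sink"`.
#' @param bbox numeric `c(lon_min, lon_max, lat_min, lat_max)`; `lon_max`
#'   may exceed 360 for domains spanning the antimeridian.
#' @param res grid spacing, degrees.
#' @param start,end first and last daily snapshot (dates).
#' @param u0,v0 uniform flow, m/s (`uniform`).
#' @param omega angular rate of the degree-space rotation, rad/s
#'   (`solid_body`).
#' @param shear_scale radial e-folding scale (degrees) of differential
#'   rotation for `solid_body`: the local angular rate is
#'   `omega * exp(-r / shear_scale)`. `Inf` (default) is rigid rotation;
#'   finite values make the vortex sheared, so neighbouring radii drift
#'   apart azimuthally — the mechanism that amplifies diffusive spread in
#'   real gyres. Orbits remain exact circles at every radius.
#' @param center rotation / sink centre `c(lon, lat)` (`solid_body`,
#'   `convergent_sink`).
#' @param rate inward contraction rate, 1/s (`convergent_sink`); positions
#'   decay toward the centre as `exp(-rate * t)` in degree space.
#' @param outward if `TRUE` the sink becomes a source (flow radially
#'   outward); backtracking a source funnels particles into the centre.
#' @param amplitude gyre streamfunction amplitude, degree^2/s
#'   (`double_gyre`).
#' @param epsilon separatrix oscillation amplitude of the double gyre in
#'   `[0, 0.5]`; 0 gives the steady (integrable) gyre, positive values give
#'   the classic time-periodic form whose advection is chaotic.
#' @param period_days oscillation period of the separatrix, days.
#' @param islands optional list of `list(center = c(lon, lat), radius)`
#'   discs masked as land.
#' @return a `field_spec` object accepted by [make_field()].
#' @export
field_spec <- function(kind = c("uniform", "solid_body", "double_gyre",
                                "convergent_sink"),
                       bbox = c(180, 220, 10, 40), res = 0.5,
                       start = "2020-01-01", end = "2020-03-31",
                       u0 = 0.1, v0 = 0, omega = 2.42e-6,
                       shear_scale = Inf,
                       center = NULL, rate = 1.5e-6, outward = FALSE,
                       amplitude = 4e-5, epsilon = 0, period_days = 20,
                       islands = NULL) {
  kind <- match.arg(kind)
  abort_if(length(bbox) != 4 || bbox[2] <= bbox[1] || bbox[4] <= bbox[3],
           "bbox must be c(lon_min, lon_max, lat_min, lat_max)")
  if (is.null(center)) center <- c(mean(bbox[1:2]), mean(bbox[3:4]))
  abort_if(epsilon < 0 || epsilon > 0.5, "epsilon must be in [0, 0.5]")
  structure(list(kind = kind, bbox = bbox, res = res,
                 start = start, end = end, u0 = u0, v0 = v0, omega = omega,
                 shear_scale = shear_scale,
                 center = center, rate = rate, outward = outward,
                 amplitude = amplitude, epsilon = epsilon,
                 period_days = period_days, islands = islands),
            class = "field_spec")
}

# Degree-space rates (dlon/dt, dlat/dt) for a spec at given coordinates;
# t is seconds since the field's first snapshot (used by the time-periodic
# double gyre only).
deg_rates <- function(spec, lon, lat, t = 0) {
  # work in the spec's own (possibly unwrapped past 360) frame
  x <- spec$bbox[1] + (lon - spec$bbox[1]) %% 360
  switch(spec$kind,
    uniform = list(dlon = rep_len(spec$u0 / (M_PER_DEG * cos(deg2rad(lat))),
                                  length(x)),
                   dlat = rep_len(spec$v0 / M_PER_DEG, length(x))),
    solid_body = {
      dx <- x - (spec$bbox[1] + (spec$center[1] - spec$bbox[1]) %% 360)
      dy <- lat - spec$center[2]
      w <- if (is.finite(spec$shear_scale)) {
        spec$omega * exp(-sqrt(dx^2 + dy^2) / spec$shear_scale)
      } else spec$omega
      list(dlon = -w * dy, dlat = w * dx)
    },
    convergent_sink = {
      s <- if (spec$outward) spec$rate else -spec$rate
      dx <- x - (spec$bbox[1] + (spec$center[1] - spec$bbox[1]) %% 360)
      dy <- lat - spec$center[2]
      list(dlon = s * dx, dlat = s * dy)
    },
    double_gyre = {
      # psi = A sin(pi f(sx, t)) sin(pi sy) on the unit-scaled bbox; two
      # counter-rotating cells, divergence-free in degree space. With
      # epsilon > 0 the separatrix oscillates (f quadratic in sx) and the
      # advection is chaotic; epsilon = 0 recovers the steady gyre.
      w <- spec$bbox[2] - spec$bbox[1]; h <- spec$bbox[4] - spec$bbox[3]
      sx <- (x - spec$bbox[1]) / w * 2
      sy <- (lat - spec$bbox[3]) / h
      A <- spec$amplitude
      e <- spec$epsilon
      ph <- if (e > 0) sin(2 * pi * t / (spec$period_days * 86400)) else 0
      a_t <- e * ph; b_t <- 1 - 2 * e * ph
      fx <- a_t * sx^2 + b_t * sx
      dfx <- 2 * a_t * sx + b_t
      list(dlon = -A * pi / h * sin(pi * fx) * cos(pi * sy),
           dlat =  A * pi * 2 / w * cos(pi * fx) * sin(pi * sy) * dfx)
    },
    stop(sprintf("unsupported field kind '%s'", spec$kind), call. = FALSE))
}

# Physical (u, v) in m/s for a spec, used to fill grids.
spec_velocity <- function(spec, lon, lat, t = 0) {
  r <- deg_rates(spec, lon, lat, t)
  list(u = r$dlon * M_PER_DEG * cos(deg2rad(lat)),
       v = r$dlat * M_PER_DEG)
}

#' Materialise an analytic field on a grid
#'
#' Samples the closed-form velocity of a [field_spec()] onto a regular grid
#' with daily snapshots, producing a [velocity_field] interchangeable with
#' one read from NetCDF. The uniform, solid-body and convergent-sink rates
#' are linear in lon/lat, so bilinear re-interpolation of the gridded field
#' reproduces the analytic motion to high accuracy.
#'
#' @param spec a [field_spec()].
#' @return a [velocity_field].
#' @export
make_field <- function(spec) {
  abort_if(!inherits(spec, "field_spec"), "spec must be a field_spec")
  lon <- seq(spec$bbox[1], spec$bbox[2], by = spec$res)
  lat <- seq(spec$bbox[3], spec$bbox[4], by = spec$res)
  t0 <- as_utc(spec$start); t1 <- as_utc(spec$end)
  abort_if(t1 <= t0, "end must be after start")
  time <- seq(t0, t1, by = 86400)
  g <- expand.grid(lon = lon, lat = lat)
  steady <- !(spec$kind == "double_gyre" && spec$epsilon > 0)
  dims <- c(length(lon), length(lat), length(time))
  if (steady) {
    vel <- spec_velocity(spec, g$lon, g$lat)
    u <- array(rep(matrix(vel$u, dims[1], dims[2]), dims[3]), dims)
    v <- array(rep(matrix(vel$v, dims[1], dims[2]), dims[3]), dims)
  } else {
    u <- array(0, dims); v <- array(0, dims)
    for (k in seq_along(time)) {
      vel <- spec_velocity(spec, g$lon, g$lat,
                           as.numeric(time[k]) - as.numeric(t0))
      u[, , k] <- vel$u
      v[, , k] <- vel$v
    }
  }
  mask <- matrix(FALSE, length(lon), length(lat))
  for (isl in spec$islands) {
    dx <- (g$lon - isl$center[1] + 180) %% 360 - 180
    dy <- g$lat - isl$center[2]
    mask <- mask | matrix(dx^2 + dy^2 <= isl$radius^2,
                          length(lon), length(lat))
  }
  velocity_field(wrap_lon(lon), lat, time, u, v, mask)
}

#' Build circular island coastlines
#'
#' Returns one closed 64-gon ring per island, in continuous (unwrapped)
#' longitudes so islands straddling the 0/360 seam stay single polygons.
#'
#' @param islands list of `list(center = c(lon, lat), radius)` with radius
#'   in degrees.
#' @return list of closed rings; each ring is a matrix with columns
#'   `lon`, `lat` whose first and last rows coincide.
#' @export
make_coastline <- function(islands) {
  lapply(islands, function(isl) {
    abort_if(isl$radius <= 0, "island radius must be positive")
    th <- seq(0, 2 * pi, length.out = 65)
    cbind(lon = isl$center[1] + isl$radius * cos(th),
          lat = isl$center[2] + isl$radius * sin(th))
  })
}

#' Write polygons as GeoJSON
#'
#' @param polys list of closed ring matrices (columns lon, lat).
#' @param path output path.
#' @param properties optional data.frame of per-polygon properties.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polys, path, properties = NULL) {
  feats <- lapply(seq_along(polys), function(i) {
    ring <- polys[[i]]
    props <- if (is.null(properties)) stats::setNames(list(), character(0))
             else as.list(properties[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(k) c(ring[k, 1], ring[k, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features; only exterior rings are kept.
#'
#' @param path GeoJSON file path.
#' @return list of closed ring matrices (columns lon, lat).
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  abort_if(is.null(gj$features), "not a GeoJSON FeatureCollection: %s", path)
  out <- list()
  for (f in gj$features) {
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
      stop(sprintf("unsupported geometry type '%s'", geom$type),
           call. = FALSE))
    for (r in rings) {
      m <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
      colnames(m) <- c("lon", "lat")
      out[[length(out) + 1]] <- m
    }
  }
  out
}
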