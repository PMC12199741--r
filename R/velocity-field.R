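# Gridded surface-velocity fields: container, NetCDF IO, interpolation.

#' Construct a gridded surface-velocity field
#'
#' A `velocity_field` holds eastward (`u`) and northward (`v`) surface
#' velocity in m/s on a regular lon/lat grid with daily (or other constant)
#' time snapshots, plus a land mask. Longitudes are normalised to the
#' package-wide `[0, 360)` convention; a grid whose nodes span the full
#' circle is treated as periodic in longitude.
#'
#' Velocities at masked (land) nodes are stored as 0 so that interpolation
#' near coasts never propagates missing values; the land mask itself is kept
#' separately and consulted by [is_land()] and the transport code.
#'
#' @param lon longitudes of grid nodes, degrees east (any convention;
#'   normalised to `[0, 360)` and reordered ascending, with `u`, `v` and the
#'   mask permuted to match).
#' @param lat latitudes of grid nodes, degrees north, strictly ascending.
#' @param time time of each snapshot (`POSIXct`, `Date` or ISO strings),
#'   strictly ascending.
#' @param u,v numeric arrays of dimension `(lon, lat, time)`, m/s.
#' @param land_mask logical matrix `(lon, lat)`; `TRUE` marks land nodes.
#'   Defaults to all sea. Nodes where `u` or `v` is non-finite at any time
#'   are added to the mask.
#' @return an object of class `velocity_field`.
#' @export
velocity_field <- function(lon, lat, time, u, v, land_mask = NULL) {
  time <- as_utc(time)
  abort_if(length(lat) < 2 || any(diff(lat) <= 0),
           "lat nodes must be strictly ascending")
  abort_if(length(time) < 2 || any(diff(as.numeric(time)) <= 0),
           "time nodes must be strictly ascending")
  dims <- c(length(lon), length(lat), length(time))
  abort_if(!identical(dim(u), as.integer(dims)),
           "u has dimensions (%s); expected (%s)",
           paste(dim(u), collapse = ","), paste(dims, collapse = ","))
  abort_if(!identical(dim(v), as.integer(dims)),
           "v has dimensions (%s); expected (%s)",
           paste(dim(v), collapse = ","), paste(dims, collapse = ","))

  lon <- wrap_lon(lon)
  ord <- order(lon)
  lon <- lon[ord]
  abort_if(anyDuplicated(lon) > 0, "lon nodes must be distinct after wrapping")
  u <- u[ord, , , drop = FALSE]
  v <- v[ord, , , drop = FALSE]

  if (is.null(land_mask)) {
    land_mask <- matrix(FALSE, dims[1], dims[2])
  } else {
    abort_if(!identical(dim(land_mask), as.integer(dims[1:2])),
             "land_mask must be (lon, lat)")
    land_mask <- land_mask[ord, , drop = FALSE]
  }
  bad <- apply(!is.finite(u) | !is.finite(v), c(1, 2), any)
  land_mask <- land_mask | bad
  if (any(land_mask)) {
    idx <- which(land_mask, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      u[idx[k, 1], idx[k, 2], ] <- 0
      v[idx[k, 1], idx[k, 2], ] <- 0
    }
  }
  abort_if(any(!is.finite(u)) || any(!is.finite(v)),
           "u and v must be finite at all sea nodes")

  # periodic iff the node spacing closes the circle
  dlon <- diff(lon)
  periodic <- length(lon) >= 4 &&
    abs((360 - (lon[length(lon)] - lon[1])) - stats::median(dlon)) < 1e-6

  structure(
    list(lon = lon, lat = lat, time = time, u = u, v = v,
         land_mask = land_mask, periodic = periodic),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf(
    "<velocity_field> %d x %d nodes, %d snapshots (%s .. %s)\n",
    length(x$lon), length(x$lat), length(x$time),
    format(x$time[1]), format(x$time[length(x$time)])))
  cat(sprintf("  lon [%g, %g]%s  lat [%g, %g]  land %.1f%%\n",
              min(x$lon), max(x$lon), if (x$periodic) " (periodic)" else "",
              min(x$lat), max(x$lat), 100 * mean(x$land_mask)))
  invisible(x)
}

#' Read a velocity field from NetCDF
#'
#' Reads CF-style gridded currents (default variable names `water_u` /
#' `water_v` on `lon`/`lat`/`time` axes). Longitudes in either the
#' `[0, 360)` or signed `[-180, 180]` convention are accepted and normalised
#' to `[0, 360)`. The land mask is derived from the variables' fill values.
#'
#' @param path NetCDF file path.
#' @param var_names named character vector mapping `u` and `v` to variable
#'   names in the file.
#' @param axis_names named character vector mapping `lon`, `lat`, `time` to
#'   dimension variable names.
#' @return a [velocity_field].
#' @export
read_velocity_field <- function(path,
                                var_names = c(u = "water_u", v = "water_v"),
                                axis_names = c(lon = "lon", lat = "lat",
                                               time = "time")) {
  abort_if(!file.exists(path), "no such file: %s", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  for (nm in var_names) {
    abort_if(!nm %in% names(nc$var),
             "variable '%s' not found in %s", nm, path)
  }
  lon <- as.numeric(ncdf4::ncvar_get(nc, axis_names[["lon"]]))
  lat <- as.numeric(ncdf4::ncvar_get(nc, axis_names[["lat"]]))
  abort_if(any(diff(lat) <= 0), "latitude axis is not strictly ascending")
  tdim <- nc$dim[[axis_names[["time"]]]]
  abort_if(is.null(tdim), "time axis '%s' not found", axis_names[["time"]])
  tvals <- as.numeric(tdim$vals)
  abort_if(any(diff(tvals) <= 0), "time axis is not strictly ascending")
  units <- tdim$units
  time <- parse_time_units(tvals, units)
  u <- ncdf4::ncvar_get(nc, var_names[["u"]], collapse_degen = FALSE)
  v <- ncdf4::ncvar_get(nc, var_names[["v"]], collapse_degen = FALSE)
  dims <- c(length(lon), length(lat), length(time))
  u <- array(u, dims)
  v <- array(v, dims)
  mask <- apply(is.na(u) | is.na(v), c(1, 2), any)
  u[is.na(u)] <- 0
  v[is.na(v)] <- 0
  velocity_field(lon, lat, time, u, v, mask)
}

parse_time_units <- function(vals, units) {
  m <- regmatches(units, regexec(
    "^(seconds|hours|days) since ([0-9]{4}-[0-9]{2}-[0-9]{2})[ T]?([0-9:]*)",
    units))[[1]]
  abort_if(length(m) == 0, "unsupported time units: %s", units)
  mult <- c(seconds = 1, hours = 3600, days = 86400)[[m[2]]]
  origin <- as_utc(paste(m[3], ifelse(nzchar(m[4]), m[4], "00:00:00")))
  origin + vals * mult
}

#' Write a velocity field to NetCDF
#'
#' Emits the same dialect [read_velocity_field()] consumes (variables
#' `water_u`/`water_v`, axes `lon`/`lat`/`time`, days since the first
#' snapshot; land nodes as fill values), so synthetic fields round-trip.
#'
#' @param field a [velocity_field].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_velocity_field <- function(field, path) {
  fill <- -30000
  t0 <- field$time[1]
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
  dtim <- ncdf4::ncdim_def(
    "time", sprintf("days since %s", format(t0, "%Y-%m-%d %H:%M:%S")),
    as.numeric(field$time - t0, units = "days"), unlim = TRUE)
  vu <- ncdf4::ncvar_def("water_u", "m s-1", list(dlon, dlat, dtim), fill,
                         prec = "double")
  vv <- ncdf4::ncvar_def("water_v", "m s-1", list(dlon, dlat, dtim), fill,
                         prec = "double")
  nc <- ncdf4::nc_create(path, list(vu, vv))
  on.exit(ncdf4::nc_close(nc))
  u <- field$u; v <- field$v
  if (any(field$land_mask)) {
    idx <- which(field$land_mask, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      u[idx[k, 1], idx[k, 2], ] <- NA
      v[idx[k, 1], idx[k, 2], ] <- NA
    }
  }
  ncdf4::ncvar_put(nc, vu, u)
  ncdf4::ncvar_put(nc, vv, v)
  invisible(path)
}

# Locate lon query columns: returns list(i0, i1, w) where the value is
# (1-w)*col[i0] + w*col[i1], wrap-aware when the grid is periodic.
lon_bracket <- function(field, lon) {
  q <- wrap_lon(lon)
  nodes <- field$lon
  n <- length(nodes)
  i0 <- findInterval(q, nodes)
  if (field$periodic) {
    seam <- i0 == 0L | i0 == n
    i0[i0 == 0L] <- n
    i1 <- i0 %% n + 1L
    span <- ifelse(seam, nodes[1] + 360 - nodes[n],
                   nodes[pmin(i0 + 1L, n)] - nodes[i0])
    dist <- ifelse(seam, (q - nodes[n]) %% 360, q - nodes[i0])
    w <- ifelse(span > 0, dist / span, 0)
  } else {
    abort_if(any(q < nodes[1] - 1e-9 | q > nodes[n] + 1e-9),
             "longitude outside grid range")
    i0 <- pmin(pmax(i0, 1L), n - 1L)
    i1 <- i0 + 1L
    w <- (q - nodes[i0]) / (nodes[i1] - nodes[i0])
    w <- pmin(pmax(w, 0), 1)
  }
  list(i0 = i0, i1 = i1, w = w)
}

axis_bracket <- function(nodes, x, what) {
  n <- length(nodes)
  abort_if(any(x < nodes[1] - 1e-9 | x > nodes[n] + 1e-9),
           "%s outside grid range", what)
  i0 <- pmin(pmax(findInterval(x, nodes), 1L), n - 1L)
  w <- (x - nodes[i0]) / (nodes[i0 + 1L] - nodes[i0])
  list(i0 = i0, i1 = i0 + 1L, w = pmin(pmax(w, 0), 1))
}

#' Sample interpolated velocity
#'
#' Bilinear interpolation in lon/lat (wrapping across the 0/360 seam on
#' periodic grids) and linear interpolation in time. Land nodes contribute
#' velocity 0, so a query exactly on a masked node returns `(0, 0)`.
#'
#' @param field a [velocity_field].
#' @param lon,lat query coordinates (vectors of equal length), degrees.
#' @param t query time (scalar or vector), within the field's time range.
#' @return list with numeric vectors `u` and `v` (m/s).
#' @export
sample_velocity <- function(field, lon, lat, t) {
  t <- as.numeric(as_utc(t))
  n <- max(length(lon), length(lat), length(t))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); t <- rep_len(t, n)
  lb <- lon_bracket(field, lon)
  yb <- axis_bracket(field$lat, lat, "latitude")
  tb <- axis_bracket(as.numeric(field$time), t, "time")

  interp_one <- function(arr) {
    acc <- numeric(n)
    for (ti in c("i0", "i1")) {
      tw <- if (ti == "i0") 1 - tb$w else tb$w
      sl <- tw *
        ((1 - lb$w) * (1 - yb$w) * arr[cbind(lb$i0, yb$i0, tb[[ti]])] +
         lb$w       * (1 - yb$w) * arr[cbind(lb$i1, yb$i0, tb[[ti]])] +
         (1 - lb$w) * yb$w       * arr[cbind(lb$i0, yb$i1, tb[[ti]])] +
         lb$w       * yb$w       * arr[cbind(lb$i1, yb$i1, tb[[ti]])])
      acc <- acc + sl
    }
    acc
  }
  list(u = interp_one(field$u), v = interp_one(field$v))
}

#' Is a point on land?
#'
#' Nearest-node lookup in the land mask, wrap-aware in longitude. A point
#' exactly midway between nodes is treated as land if any of the equidistant
#' nearest nodes is land.
#'
#' @param field a [velocity_field].
#' @param lon,lat query coordinates, degrees.
#' @return logical vector.
#' @export
is_land <- function(field, lon, lat) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  lb <- lon_bracket(field, lon)
  yb <- axis_bracket(field$lat, pmin(pmax(lat, min(field$lat)),
                                     max(field$lat)), "latitude")
  eps <- 1e-9
  near <- function(b) {
    lo <- b$w <= 0.5 + eps   # candidate i0
    hi <- b$w >= 0.5 - eps   # candidate i1
    list(lo = lo, hi = hi)
  }
  cx <- near(lb); cy <- near(yb)
  out <- logical(n)
  for (xi in c("lo", "hi")) for (yi in c("lo", "hi")) {
    sel <- cx[[xi]] & cy[[yi]]
    if (!any(sel)) next
    ii <- if (xi == "lo") lb$i0[sel] else lb$i1[sel]
    jj <- if (yi == "lo") yb$i0[sel] else yb$i1[sel]
    out[sel] <- out[sel] | field$land_mask[cbind(ii, jj)]
  }
  out
}
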