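# 1-degree hexagonal settlement grid: tessellation, activation, location.
#
# Pointy-top hexagons in planar lon/lat coordinates. The configured cell
# size is the horizontal edge-to-edge width w; the circumradius is
# s = w / sqrt(3). Axial coordinates (q, r) follow the standard layout:
#   x = s * sqrt(3) * (q + r/2),  y = s * 1.5 * r
# relative to the grid origin, with x measured in continuous (unwrapped)
# longitude so grids may span the 0/360 seam.

#' Build a hexagonal tessellation over a bounding box
#'
#' @param bbox `c(lon_min, lon_max, lat_min, lat_max)`; `lon_max` may exceed
#'   360 for boxes spanning the antimeridian, but the box may not span more
#'   than 360 degrees of longitude.
#' @param cell_size horizontal edge-to-edge hexagon width, degrees.
#' @return a `hex_grid` object with a `cells` data.frame
#'   (`id`, `q`, `r`, `lon`, `lat` of centres).
#' @export
build_hex_grid <- function(bbox, cell_size = 1) {
  abort_if(length(bbox) != 4 || bbox[2] <= bbox[1] || bbox[4] <= bbox[3],
           "bbox must be c(lon_min, lon_max, lat_min, lat_max)")
  abort_if(bbox[2] - bbox[1] > 360, "bbox spans more than 360 degrees")
  abort_if(cell_size <= 0, "cell_size must be positive")
  s <- cell_size / sqrt(3)
  x_max <- bbox[2] - bbox[1]
  y_max <- bbox[4] - bbox[3]
  r_range <- seq(floor((-s) / (1.5 * s)) - 1,
                 ceiling((y_max + s) / (1.5 * s)) + 1)
  rows <- list()
  for (r in r_range) {
    # q range so centre x covers [-w, x_max + w]
    q_lo <- floor((-cell_size) / cell_size - r / 2) - 1
    q_hi <- ceiling((x_max + cell_size) / cell_size - r / 2) + 1
    q <- seq(q_lo, q_hi)
    rows[[length(rows) + 1]] <- data.frame(q = q, r = r)
  }
  cells <- do.call(rbind, rows)
  cells$lon <- bbox[1] + s * sqrt(3) * (cells$q + cells$r / 2)
  cells$lat <- bbox[3] + s * 1.5 * cells$r
  # keep cells that could touch the bbox
  keep <- cells$lon >= bbox[1] - cell_size & cells$lon <= bbox[2] + cell_size &
          cells$lat >= bbox[3] - cell_size & cells$lat <= bbox[4] + cell_size
  cells <- cells[keep, , drop = FALSE]
  cells <- cells[order(cells$r, cells$q), , drop = FALSE]
  cells$id <- seq_len(nrow(cells))
  rownames(cells) <- NULL
  key <- paste(cells$q, cells$r)
  structure(list(cells = cells[, c("id", "q", "r", "lon", "lat")],
                 s = s, cell_size = cell_size, bbox = bbox,
                 index = stats::setNames(cells$id, key)),
            class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %d cells, width %g deg, bbox [%g, %g] x [%g, %g]\n",
              nrow(x$cells), x$cell_size, x$bbox[1], x$bbox[2],
              x$bbox[3], x$bbox[4]))
  invisible(x)
}

#' Vertices of a hexagonal cell
#'
#' @param grid a `hex_grid`.
#' @param id cell id.
#' @return closed 7 x 2 matrix of (lon, lat) vertices (pointy-top order).
#' @export
hex_vertices <- function(grid, id) {
  cell <- grid$cells[match(id, grid$cells$id), ]
  abort_if(anyNA(cell$id), "unknown cell id")
  th <- deg2rad(30 + 60 * (0:5))
  ring <- cbind(lon = cell$lon + grid$s * cos(th),
                lat = cell$lat + grid$s * sin(th))
  rbind(ring, ring[1, , drop = FALSE])
}

# Map points to cell (q, r) by cube rounding; x, y relative to grid origin.
axial_round <- function(grid, x, y) {
  s <- grid$s
  q <- (sqrt(3) / 3 * x - 1 / 3 * y) / s
  r <- (2 / 3 * y) / s
  cz <- -q - r
  rq <- round(q); rr <- round(r); rz <- round(cz)
  dq <- abs(rq - q); dr <- abs(rr - r); dz <- abs(rz - cz)
  fix_q <- dq > dr & dq > dz
  fix_r <- !fix_q & dr > dz
  rq[fix_q] <- -rr[fix_q] - rz[fix_q]
  rr[fix_r] <- -rq[fix_r] - rz[fix_r]
  list(q = rq, r = rr)
}

# Point in (closed) convex hexagon centred at (cx, cy): all cross products
# non-negative (CCW vertices), with tolerance so boundary points are
# inclusive. Vectorised over (point, centre) pairs.
in_hex <- function(grid, cx, cy, px, py, tol = 1e-9) {
  th <- deg2rad(30 + 60 * (0:5))
  vx <- outer(cx, grid$s * cos(th), "+")
  vy <- outer(cy, grid$s * sin(th), "+")
  ok <- rep(TRUE, length(px))
  for (k in 1:6) {
    k2 <- k %% 6 + 1
    cr <- (vx[, k2] - vx[, k]) * (py - vy[, k]) -
          (vy[, k2] - vy[, k]) * (px - vx[, k])
    ok <- ok & (cr >= -tol)
  }
  ok
}

# Resolve points to cell ids. Points on shared edges resolve to the lowest
# id among the cells whose closed hexagon contains them.
hex_locate_ids <- function(grid, lon, lat) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  x <- (lon - grid$bbox[1]) %% 360
  x[x > 360 - grid$cell_size & grid$bbox[2] - grid$bbox[1] < 359] <-
    x[x > 360 - grid$cell_size & grid$bbox[2] - grid$bbox[1] < 359] - 360
  y <- lat - grid$bbox[3]
  ax <- axial_round(grid, x, y)
  # candidate cell + 6 neighbours, pick lowest containing id
  nbr <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1),
               c(-1, 1))
  best <- rep(NA_integer_, n)
  s <- grid$s
  for (k in seq_len(nrow(nbr))) {
    q <- ax$q + nbr[k, 1]; r <- ax$r + nbr[k, 2]
    id <- unname(grid$index[paste(q, r)])
    has <- !is.na(id)
    if (!any(has)) next
    cx <- s * sqrt(3) * (q[has] + r[has] / 2)
    cy <- s * 1.5 * r[has]
    cont <- in_hex(grid, cx, cy, x[has], y[has])
    cand <- ifelse(cont, id[has], NA_integer_)
    cur <- best[has]
    best[has] <- ifelse(!is.na(cand) & (is.na(cur) | cand < cur), cand, cur)
  }
  best
}

# ---- polygon geometry (planar lon/lat) ------------------------------------

# Even-odd ray-casting containment; ring is a closed matrix, points vectors.
point_in_ring <- function(ring, px, py) {
  nv <- nrow(ring) - 1
  inside <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

segments_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
                         (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
   ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) |
    (d1 == 0 & on_seg(q1, q2, p1)) | (d2 == 0 & on_seg(q1, q2, p2)) |
    (d3 == 0 & on_seg(p1, p2, q1)) | (d4 == 0 & on_seg(p1, p2, q2))
}

on_seg <- function(a, b, c) {
  min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
  min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
}

validate_ring <- function(ring, idx) {
  abort_if(!is.matrix(ring) || ncol(ring) < 2 || nrow(ring) < 4,
           "polygon %d is not a ring matrix with >= 3 vertices", idx)
  abort_if(any(abs(ring[1, 1:2] - ring[nrow(ring), 1:2]) > 1e-9),
           "polygon %d ring is not closed", idx)
  invisible(NULL)
}

# Does a closed convex hex ring intersect a polygon ring (boundaries count)?
hex_ring_intersects <- function(hex, ring) {
  if (any(point_in_ring(ring, hex[1:6, 1], hex[1:6, 2]))) return(TRUE)
  nv <- nrow(ring) - 1
  if (any(point_in_ring(hex, ring[1:nv, 1], ring[1:nv, 2]))) return(TRUE)
  for (i in 1:6) for (j in seq_len(nv)) {
    if (segments_intersect(hex[i, 1:2], hex[i + 1, 1:2],
                           ring[j, 1:2], ring[j + 1, 1:2])) return(TRUE)
  }
  FALSE
}

#' Activate settlement cells from habitat and exclusion polygons
#'
#' A cell is active iff its hexagon intersects at least one habitat polygon
#' and intersects no exclusion polygon. Polygons are tested in the grid's
#' longitude frame with copies shifted by ±360, so coastlines given in
#' either longitude convention, including seam-straddling ones, match.
#'
#' @param grid a `hex_grid` from [build_hex_grid()].
#' @param habitat list of closed ring matrices (columns lon, lat).
#' @param exclusions optional list of closed ring matrices.
#' @return a `settlement_set`: the grid plus `active` flags and excluded ids.
#' @export
activate_cells <- function(grid, habitat, exclusions = list()) {
  for (i in seq_along(habitat)) validate_ring(habitat[[i]], i)
  for (i in seq_along(exclusions)) validate_ring(exclusions[[i]], i)

  frame_copies <- function(ring) {
    # shift the whole ring coherently (never vertex-by-vertex, which would
    # tear rings crossing the frame origin), then try +-360 copies
    x <- ring[, 1] - grid$bbox[1]
    base <- x - 360 * floor(mean(x[-length(x)]) / 360)
    lapply(c(-360, 0, 360), function(sh) {
      out <- ring
      out[, 1] <- base + sh
      out
    })
  }
  cell_hits <- function(polys) {
    hit <- rep(FALSE, nrow(grid$cells))
    for (p in polys) {
      copies <- frame_copies(p)
      # prefilter by bbox overlap per copy
      for (cp in copies) {
        xr <- range(cp[, 1]); yr <- range(cp[, 2])
        x <- grid$cells$lon - grid$bbox[1]
        cand <- which(!hit &
          x >= xr[1] - grid$cell_size & x <= xr[2] + grid$cell_size &
          grid$cells$lat >= yr[1] - grid$cell_size &
          grid$cells$lat <= yr[2] + grid$cell_size)
        for (ci in cand) {
          hex <- hex_vertices(grid, grid$cells$id[ci])
          hex[, 1] <- hex[, 1] - grid$bbox[1]
          hex[, 2] <- hex[, 2] - 0 # already absolute lat
          if (hex_ring_intersects(
                cbind(hex[, 1], hex[, 2] ),
                cbind(cp[, 1], cp[, 2]))) hit[ci] <- TRUE
        }
      }
    }
    hit
  }
  hab_hit <- cell_hits(habitat)
  exc_hit <- if (length(exclusions)) cell_hits(exclusions)
             else rep(FALSE, nrow(grid$cells))
  active <- hab_hit & !exc_hit
  structure(list(grid = grid, active = active,
                 excluded_ids = grid$cells$id[exc_hit],
                 n_habitat = length(habitat)),
            class = "settlement_set")
}

#' An empty settlement set (no active cells)
#'
#' @param grid a `hex_grid`.
#' @return a `settlement_set` with every cell inactive.
#' @export
empty_settlement <- function(grid) {
  structure(list(grid = grid, active = rep(FALSE, nrow(grid$cells)),
                 excluded_ids = integer(0), n_habitat = 0),
            class = "settlement_set")
}

#' @export
print.settlement_set <- function(x, ...) {
  cat(sprintf("<settlement_set> %d cells, %d active, %d excluded\n",
              nrow(x$grid$cells), sum(x$active), length(x$excluded_ids)))
  invisible(x)
}

#' Locate points in active settlement cells
#'
#' @param set a `settlement_set`.
#' @param lon,lat point coordinates, degrees.
#' @return integer vector of active cell ids, `NA` where the point falls in
#'   no active cell. Points on shared edges resolve to the lowest cell id.
#' @export
locate_cell <- function(set, lon, lat) {
  ids <- hex_locate_ids(set$grid, lon, lat)
  act <- set$active[match(ids, set$grid$cells$id)]
  ids[is.na(act) | !act] <- NA_integer_
  ids
}

#' Export a settlement grid (optionally with landing counts) as GeoJSON
#'
#' @param set a `settlement_set`.
#' @param path output path.
#' @param counts optional data.frame with columns `cell_id`, `count`.
#' @param active_only write only active cells (default TRUE).
#' @return `path`, invisibly.
#' @export
write_settlement_geojson <- function(set, path, counts = NULL,
                                     active_only = TRUE) {
  ids <- set$grid$cells$id[if (active_only) set$active else TRUE]
  polys <- lapply(ids, function(id) {
    ring <- hex_vertices(set$grid, id)
    ring[, 1] <- wrap_lon(ring[, 1])
    ring
  })
  cnt <- rep(0L, length(ids))
  if (!is.null(counts)) {
    m <- match(ids, counts$cell_id)
    cnt[!is.na(m)] <- counts$count[m[!is.na(m)]]
  }
  write_polygons_geojson(polys, path,
                         properties = data.frame(cell_id = ids, count = cnt))
}
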