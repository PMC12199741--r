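# Hexagonal tessellation, habitat activation and point location.

test_that("hexagons have the configured width and tile without gaps", {
  g <- build_hex_grid(c(10, 20, 0, 10), cell_size = 1)
  ring <- hex_vertices(g, g$cells$id[50])
  expect_equal(diff(range(ring[, 1])), 1.0)          # edge-to-edge width
  expect_equal(diff(range(ring[, 2])), 2 / sqrt(3))  # point-to-point height

  set.seed(42)
  lon <- stats::runif(1000, 10.2, 19.8)
  lat <- stats::runif(1000, 0.2, 9.8)
  ids <- driftback:::hex_locate_ids(g, lon, lat)
  expect_false(anyNA(ids))
  # partition: brute-force strict containment finds exactly one cell
  for (k in seq(1, 1000, by = 20)) {
    cont <- driftback:::in_hex(g, g$cells$lon, g$cells$lat,
                               rep(lon[k], nrow(g$cells)),
                               rep(lat[k], nrow(g$cells)), tol = 0)
    expect_identical(sum(cont), 1L)
    expect_identical(g$cells$id[which(cont)], ids[k])
  }
})

test_that("cell count matches a brute-force row/column enumeration", {
  g <- build_hex_grid(c(100, 110, 20, 30), cell_size = 1)
  s <- 1 / sqrt(3)
  # independent layout oracle: rows at lat = 20 + 1.5*s*r, centres at
  # lon = 100 + (q + r/2); count centres within one cell width of the box
  oracle <- 0
  for (r in -3:16) {
    clat <- 20 + 1.5 * s * r
    if (clat < 20 - 1 || clat > 30 + 1) next
    for (q in -25:25) {
      clon <- 100 + (q + r / 2)
      if (clon >= 100 - 1 && clon <= 110 + 1) oracle <- oracle + 1
    }
  }
  expect_identical(nrow(g$cells), as.integer(oracle))
})

test_that("a degenerate or over-wide bbox is rejected", {
  expect_error(build_hex_grid(c(10, 10, 0, 5)), "bbox")
  expect_error(build_hex_grid(c(0, 400, 0, 5)), "360")
})

test_that("activation matches a dense point-sampling oracle", {
  g <- build_hex_grid(c(195, 205, 20, 30), cell_size = 1)
  island <- list(center = c(200, 25), radius = 0.4)
  habitat <- make_coastline(list(island))
  set_ <- activate_cells(g, habitat)
  # oracle: a cell overlaps the disc iff some densely-sampled disc point
  # falls in the cell or some dense cell-boundary point falls in the disc
  th <- seq(0, 2 * pi, length.out = 720)
  rr <- seq(0, island$radius, length.out = 40)
  disc <- cbind(lon = island$center[1] + as.vector(outer(rr, cos(th))),
                lat = island$center[2] + as.vector(outer(rr, sin(th))))
  disc_ids <- unique(driftback:::hex_locate_ids(g, disc[, 1], disc[, 2]))
  active_ids <- g$cells$id[set_$active]
  expect_setequal(active_ids, disc_ids)

  # exclusion box covering the island kills every cell
  box <- cbind(lon = c(198, 202, 202, 198, 198),
               lat = c(23, 23, 27, 27, 23))
  set2 <- activate_cells(g, habitat, exclusions = list(box))
  expect_identical(sum(set2$active), 0L)

  # empty habitat means nothing is active
  set3 <- activate_cells(g, list())
  expect_identical(sum(set3$active), 0L)
})

test_that("activation is monotone in habitat and antitone in exclusions", {
  g <- build_hex_grid(c(195, 205, 20, 30), cell_size = 1)
  isl1 <- make_coastline(list(list(center = c(198, 23), radius = 0.5)))
  isl2 <- make_coastline(list(list(center = c(202, 27), radius = 0.5)))
  a1 <- activate_cells(g, isl1)
  a12 <- activate_cells(g, c(isl1, isl2))
  expect_true(all(which(a1$active) %in% which(a12$active)))
  excl <- list(cbind(lon = c(201, 203, 203, 201, 201),
                     lat = c(26, 26, 28, 28, 26)))
  a12e <- activate_cells(g, c(isl1, isl2), exclusions = excl)
  expect_true(all(which(a12e$active) %in% which(a12$active)))
  expect_lt(sum(a12e$active), sum(a12$active))
})

test_that("an unclosed polygon ring is a geometry error naming its index", {
  g <- build_hex_grid(c(195, 205, 20, 30), cell_size = 1)
  bad <- cbind(lon = c(198, 202, 202, 198), lat = c(23, 23, 27, 27))
  expect_error(activate_cells(g, list(bad)), "polygon 1")
})

test_that("locate honours activation, exclusion and the low-id tie rule", {
  g <- build_hex_grid(c(195, 205, 20, 30), cell_size = 1)
  island <- list(center = c(200, 25), radius = 0.4)
  set_ <- activate_cells(g, make_coastline(list(island)))
  active_ids <- g$cells$id[set_$active]
  # the centre of an active cell locates to that cell
  for (id in active_ids) {
    ctr <- g$cells[g$cells$id == id, ]
    expect_identical(locate_cell(set_, ctr$lon, ctr$lat), id)
  }
  # a point in an inactive cell locates to none
  expect_true(is.na(locate_cell(set_, 196, 29)))
  # excluded cell -> none even though it intersects habitat
  excl <- activate_cells(g, make_coastline(list(island)),
                         exclusions = make_coastline(list(island)))
  expect_true(is.na(locate_cell(excl, island$center[1], island$center[2])))
  # shared-edge points resolve to the lowest containing id
  c1 <- g$cells[g$cells$id == active_ids[1], ]
  ring <- hex_vertices(g, c1$id)
  edge_mid <- c(mean(ring[1:2, 1]), mean(ring[1:2, 2]))
  got <- driftback:::hex_locate_ids(g, edge_mid[1], edge_mid[2])
  cont <- driftback:::in_hex(g, g$cells$lon, g$cells$lat,
                             rep(edge_mid[1], nrow(g$cells)),
                             rep(edge_mid[2], nrow(g$cells)))
  expect_identical(got, min(g$cells$id[cont]))
})

test_that("locate agrees with brute-force containment on random points", {
  g <- build_hex_grid(c(195, 205, 20, 30), cell_size = 1)
  set_ <- activate_cells(g, make_coastline(list(
    list(center = c(200, 25), radius = 2))))
  set.seed(9)
  lon <- stats::runif(400, 195.5, 204.5)
  lat <- stats::runif(400, 20.5, 29.5)
  got <- locate_cell(set_, lon, lat)
  for (k in seq_len(400)) {
    cont <- which(driftback:::in_hex(g, g$cells$lon, g$cells$lat,
                                     rep(lon[k], nrow(g$cells)),
                                     rep(lat[k], nrow(g$cells)), tol = 0))
    truth <- g$cells$id[cont]
    truth <- truth[truth %in% g$cells$id[set_$active]]
    if (length(truth) == 0) expect_true(is.na(got[k]))
    else expect_identical(got[k], truth[1])
  }
})

test_that("grids and coastlines work across the 0/360 seam", {
  g <- build_hex_grid(c(350, 370, -5, 5), cell_size = 1)
  island <- list(center = c(360, 0), radius = 0.6)   # on the seam
  set_ <- activate_cells(g, make_coastline(list(island)))
  expect_gt(sum(set_$active), 0)
  # the island centre, expressed either side of the seam, lands in a cell
  expect_false(is.na(locate_cell(set_, 0, 0)))
  expect_false(is.na(locate_cell(set_, 359.9999, 0)))
  expect_identical(locate_cell(set_, 0.3, 0.1),
                   locate_cell(set_, 360.3, 0.1))
})
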