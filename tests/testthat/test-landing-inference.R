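# Landing tallies, region aggregation, drift times, density clouds and
# covariate association.

test_that("tallies recompute the printed worked-example percentages", {
  total <- n_released(release_schedule())
  expect_equal(format_percent(44336, total), 7.6)
  expect_equal(format_percent(43248, total), 7.4)
  expect_equal(format_percent(32133, total), 5.5)
  expect_equal(format_percent(24415, total), 4.2)
  expect_equal(format_percent(28405, total), 4.9)
  expect_equal(format_percent(23149, total), 4.0)
})

test_that("percent rounding is half-up, not banker's", {
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(0.15, 1), 0.2)   # round() would give 0.2 too
  expect_equal(round_half_up(0.25, 1), 0.3)   # round() gives 0.2
  expect_equal(round_half_up(98.97 + 0.005, 2), 98.98)
})

test_that("landing tables conserve counts and order by frequency", {
  rec <- data.frame(cell_id = c(3, 1, 3, 3, 7, 1))
  tab <- tally_landings(rec, total_released = 100)
  expect_identical(tab$cell_id, c(3L, 1L, 7L))
  expect_identical(tab$count, c(3L, 2L, 1L))
  expect_equal(tab$percent, 100 * tab$count / 100)
  expect_lte(sum(tab$percent), 100)
  empty <- tally_landings(data.frame(cell_id = integer(0)), 100)
  expect_identical(nrow(empty), 0L)
  expect_error(tally_landings(rec, total_released = 2), "smaller")
})

test_that("region aggregation assigns by centroid with half-open bounds", {
  cells <- data.frame(id = 1:4,
                      lon = c(140, 190, 270, 100),
                      lat = c(35, 10, 5, -20))
  tab <- tally_landings(data.frame(cell_id = rep(1:4, c(5, 3, 2, 1))), 20)
  boxes <- list(
    region_box("japan", lat = c(29, 43.5), lon = c(135, 150)),
    region_box("central_pacific", lat = c(0.5, 18), lon = c(-172, -155)),
    region_box("etp", lat = c(-2.5, 12), lon = c(-110, -88.5)))
  agg <- aggregate_regions(tab, cells, boxes)
  expect_identical(agg$count[agg$region == "japan"], 5L)
  expect_identical(agg$count[agg$region == "central_pacific"], 3L)
  expect_identical(agg$count[agg$region == "etp"], 2L)
  expect_identical(agg$count[agg$region == "other"], 1L)
  expect_identical(sum(agg$count), 11L)       # conservation incl. residue
  expect_equal(agg$percent, 100 * agg$count / 20)

  # a centroid exactly on the lower bound is included
  cells2 <- data.frame(id = 1, lon = 135, lat = 29)
  tab2 <- tally_landings(data.frame(cell_id = 1), 1)
  agg2 <- aggregate_regions(tab2, cells2, boxes)
  expect_identical(agg2$count[agg2$region == "japan"], 1L)
  # and exactly on the upper bound is excluded
  cells3 <- data.frame(id = 1, lon = 150, lat = 35)
  agg3 <- aggregate_regions(tab2, cells3, boxes)
  expect_identical(agg3$count[agg3$region == "japan"], 0L)

  # one box over everything reduces to the total landing percent
  all_box <- list(region_box("all", lat = c(-90, 90), lon = c(0, 359.999)))
  agg4 <- aggregate_regions(tab, cells, all_box)
  expect_equal(agg4$percent[agg4$region == "all"], 100 * 11 / 20)

  # overlapping boxes are rejected up front
  expect_error(aggregate_regions(tab, cells, list(
    region_box("a", c(0, 10), c(100, 120)),
    region_box("b", c(5, 15), c(110, 130)))), "overlap")
})

test_that("drift-time summaries test all pairs with Bonferroni", {
  rec <- data.frame(drift_days = c(1, 2, 3, 4, 5, 6, 2, 3, 4),
                    cell_id = 1:9)
  lab <- rep(c("a", "b", "c"), each = 3)
  out <- drift_time_summary(rec, lab)
  expect_identical(nrow(out$summary), 3L)
  expect_identical(nrow(out$tests), 3L)
  expect_equal(out$summary$mean_days, c(2, 5, 3))
  expect_equal(out$tests$p_adjusted, pmin(1, out$tests$p_raw * 3))
  # {1,2,3} vs {4,5,6} appears as the a-b pair with exact p = 0.1
  ab <- out$tests[out$tests$group1 == "a" & out$tests$group2 == "b", ]
  expect_equal(ab$p_raw, 0.1)
  # groups with no observations are dropped with a warning
  expect_warning(
    drift_time_summary(rec, factor(lab, levels = c("a", "b", "c", "d"))),
    "empty")
})

test_that("density clouds are normalised occupancy histograms", {
  # one stationary particle -> a single pixel holds everything
  tr <- data.frame(lon = rep(200.2, 5), lat = rep(25.3, 5))
  dc <- density_cloud(tr, resolution = 1)
  expect_identical(nrow(dc), 1L)
  expect_equal(dc$proportion, 1)
  expect_equal(dc$lon_bin, 200)

  set.seed(11)
  tr2 <- data.frame(lon = stats::runif(20000, 200, 210),
                    lat = stats::runif(20000, 20, 30))
  dc2 <- density_cloud(tr2, resolution = 1)
  expect_equal(sum(dc2$proportion), 1, tolerance = 1e-12)
  # uniform positions: max pixel within 3 sigma of the multinomial bound
  p0 <- 1 / 100
  sigma <- sqrt(p0 * (1 - p0) / 20000)
  expect_lt(max(dc2$proportion), p0 + 3 * sigma + 1e-12)
})

test_that("month labelling follows the stated season definition", {
  expect_identical(season_of_month(c(9, 10, 11)), c("SON", "SON", "SON"))
  expect_identical(season_of_month(c(12, 1, 2)), c("DJF", "DJF", "DJF"))
  expect_identical(season_of_month(3), "MAM")
  expect_identical(season_of_month(6), "JJA")
})

test_that("a doubled Neutral landing rate is detected against both phases", {
  # synthetic monthly series: 100 months, Neutral months draw double-rate
  # landing counts
  months <- format(seq(as.Date("2000-01-01"), by = "month",
                       length.out = 100), "%Y-%m")
  set.seed(21)
  phase <- sample(c("El Nino", "La Nina", "Neutral"), 100, replace = TRUE)
  enso <- structure(data.frame(month = months, phase = phase),
                    class = c("enso_series", "data.frame"))
  lam <- ifelse(phase == "Neutral", 20, 10)
  n_m <- stats::rpois(100, lam)
  rec <- data.frame(
    landing_date = rep(as.Date(paste0(months, "-15")), n_m),
    cell_id = 1L)
  cells <- data.frame(id = 1L, lon = 140, lat = 35)
  boxes <- list(region_box("japan", lat = c(29, 43.5), lon = c(135, 150)))
  out <- covariate_association(rec, enso, cells, boxes)
  jp <- out$phase_tests[out$phase_tests$region == "japan", ]
  nen <- jp[(jp$group1 == "Neutral" | jp$group2 == "Neutral") &
              (jp$group1 == "El Nino" | jp$group2 == "El Nino"), ]
  nln <- jp[(jp$group1 == "Neutral" | jp$group2 == "Neutral") &
              (jp$group1 == "La Nina" | jp$group2 == "La Nina"), ]
  expect_lt(nen$p_adjusted, 0.05)
  expect_lt(nln$p_adjusted, 0.05)
  # seasons carry no signal here
  expect_true(all(out$season_tests$p_adjusted >
                    out$phase_tests$p_adjusted[
                      out$phase_tests$region == "japan" &
                        out$phase_tests$p_adjusted < 0.05][1]))
})

test_that("phase tests match a permutation oracle on a 12-month toy case", {
  months <- format(seq(as.Date("2001-01-01"), by = "month",
                       length.out = 12), "%Y-%m")
  set.seed(3)
  phase <- sample(rep(c("El Nino", "Neutral"), each = 6))
  enso <- structure(data.frame(month = months, phase = phase),
                    class = c("enso_series", "data.frame"))
  n_m <- c(4, 1, 3, 2, 7, 0, 5, 2, 2, 6, 1, 3)
  rec <- data.frame(
    landing_date = rep(as.Date(paste0(months, "-10")), n_m),
    cell_id = 1L)
  cells <- data.frame(id = 1L, lon = 140, lat = 35)
  boxes <- list(region_box("japan", lat = c(29, 43.5), lon = c(135, 150)))
  out <- covariate_association(rec, enso, cells, boxes)
  got <- out$phase_tests[out$phase_tests$region == "japan", ]

  # oracle: exhaustive enumeration over all C(12,6) label assignments of
  # the observed monthly counts
  counts <- n_m
  obs <- sum(rank(counts)[phase == "El Nino"])
  idx <- utils::combn(12, 6)
  sums <- colSums(matrix(rank(counts)[idx], nrow = 6))
  p_perm <- mean(abs(sums - 6 * 13 / 2) >= abs(obs - 6 * 13 / 2) - 1e-9)
  expect_equal(got$p_raw, p_perm)

  # an unlabeled landing month is a validation error
  bad <- rbind(rec, data.frame(landing_date = as.Date("2005-06-01"),
                               cell_id = 1L))
  expect_error(covariate_association(bad, enso, cells, boxes), "cover")
})
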