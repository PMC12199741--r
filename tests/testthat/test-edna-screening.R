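# qPCR Cq calling, standard curves, quantification and screening decisions.

test_that("Cq calling interpolates the first threshold crossing", {
  expect_true(is.na(call_cq(1:40, rep(5, 40), threshold = 100)))
  rfu <- rep(0, 40); rfu[20] <- 80; rfu[21] <- 180; rfu[22:40] <- 500
  expect_equal(call_cq(1:40, rfu, threshold = 100), 20.2)
  expect_error(call_cq(1:40, rfu, threshold = 0), "positive")
})

test_that("synthetic sigmoids cross at their closed-form Cq", {
  for (copies in c(10, 1000, 1e5)) {
    curve <- make_qpcr(copies, threshold = 100)
    got <- call_cq(curve$cycle, curve$rfu, threshold = 100)
    expect_equal(got, attr(curve, "cq_true"), tolerance = 0.05)
  }
  # the generator's line itself: 1,000 copies at slope -3.3219, intercept 38
  curve <- make_qpcr(1000, slope = -3.321928, intercept = 38)
  expect_equal(attr(curve, "cq_true"), 38 - 3 * 3.321928)
})

test_that("standard-curve fits recover slope, efficiency and r-squared", {
  # perfect doubling chemistry
  lg <- 5:1
  cq <- 38 - 3.321928 * lg
  fit <- fit_standard_curve(lg, cq)
  expect_equal(fit$slope, -3.321928, tolerance = 1e-6)
  expect_equal(fit$efficiency, 1.0, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1.0)
  expect_error(fit_standard_curve(c(1, 2), c(30, 27)), "3 distinct")

  # noisy series: slope recovered within 2 SE
  set.seed(8)
  lgn <- rep(5:1, each = 3)
  cqn <- 37.5 - 3.1 * lgn + stats::rnorm(15, 0, 0.2)
  fitn <- fit_standard_curve(lgn, cqn)
  se <- summary(stats::lm(cqn ~ lgn))$coefficients[2, 2]
  expect_lt(abs(fitn$slope - (-3.1)), 2 * se)
})

test_that("quantification inverts the fitted line exactly", {
  fit <- fit_standard_curve(5:1, 38 - 3.321928 * (5:1))
  expect_equal(quantify(fit$intercept, fit), 1)
  expect_equal(quantify(fit$intercept + 3 * fit$slope, fit), 1000)
  expect_equal(quantify(NA_real_, fit), 0)
  # round-trip through the synthetic generator within 10%
  for (c0 in 10^(1:6)) {
    curve <- make_qpcr(c0, threshold = 100)
    cq <- call_cq(curve$cycle, curve$rfu, threshold = 100)
    expect_equal(quantify(cq, fit), c0, tolerance = 0.1)
  }
})

test_that("region decisions follow the screening decision table", {
  # all-negative samples, amplifying spike, clean controls
  neg <- call_region("okinawa", c(0, 0, 0), c(4, 6, 5), c(0, 0, 0), 0)
  expect_identical(neg$status, "presumed_negative")
  expect_false(neg$rescreen_recommended)
  # any single positive replicate is a detection
  det <- call_region("johnston", c(0, 0, 12), c(4, 6, 5), c(0, 0, 0), 0)
  expect_identical(det$status, "detected")
  expect_true(det$rescreen_recommended)
  # the decision is invariant to replicate order
  det2 <- call_region("johnston", c(12, 0, 0), c(5, 4, 6), c(0, 0, 0), 0)
  expect_identical(det2$status, det$status)
  # spike failure invalidates the pool
  sf <- call_region("kiritimati", c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), 0)
  expect_identical(sf$status, "invalid_spike_fail")
  # control contamination trumps everything
  ct <- call_region("okinawa", c(0, 0, 9), c(4, 6, 5), c(0, 2, 0), 0)
  expect_identical(ct$status, "contaminated")
  expect_error(call_region("x", c(0, 0), c(1, 1, 1), 0, 0), "replicates")
})

test_that("whole-plate screening reproduces an all-negative survey", {
  plate <- fixture_plate(sample_copies = c(kiritimati = 0, johnston = 0,
                                           okinawa = 0), spike_copies = 8)
  out <- screen_plate(plate, threshold = 100)
  expect_equal(out$fit$efficiency, 1.0, tolerance = 1e-4)
  statuses <- vapply(out$calls, function(x) x$status, "")
  expect_true(all(statuses == "presumed_negative"))
  # spiked pools quantify near the spike level (below 10 copies)
  pos <- out$wells[out$wells$role == "positive_pool", ]
  expect_true(all(pos$quantity > 0 & pos$quantity < 10))
  # with a locally-present target the sample pool flips to detected
  plate2 <- fixture_plate(sample_copies = c(okinawa = 50), spike_copies = 8)
  out2 <- screen_plate(plate2, threshold = 100)
  expect_identical(out2$calls$okinawa$status, "detected")
})

test_that("pooling dilutes but preserves detection above the LOD", {
  # one positive of c copies among m members behaves like c/m copies
  fit <- fit_standard_curve(5:1, 38 - 3.321928 * (5:1))
  c0 <- 400; m <- 20
  curve <- make_qpcr(c0 / m, threshold = 100)
  cq <- call_cq(curve$cycle, curve$rfu, threshold = 100)
  q <- quantify(cq, fit)
  expect_gt(q, 0)
  expect_equal(q, c0 / m, tolerance = 0.1)
  call <- call_region("pooled", c(0, 0, q), c(3, 3, 3), c(0, 0, 0), 0)
  expect_identical(call$status, "detected")
})

test_that("reliability requires concordant smoothed amplification", {
  good <- vapply(1:3, function(i)
    make_qpcr(1000, threshold = 100)$rfu, numeric(45))
  expect_true(reliability_check(good, threshold = 100))
  flat <- matrix(1, 45, 3)
  expect_false(reliability_check(flat, threshold = 100))
  # one single-cycle spike among flat replicates is smoothed away
  spiky <- matrix(1, 45, 3)
  spiky[25, 1] <- 250
  expect_false(reliability_check(spiky, threshold = 100))
  expect_error(reliability_check(flat[, 1, drop = FALSE], 100), "replicates")
})

test_that("fallback thresholds sit well above baseline noise", {
  set.seed(2)
  base <- matrix(stats::rnorm(45 * 4, 10, 2), 45, 4)
  thr <- estimate_threshold(base)
  expect_gt(thr, 10 + 5 * 2)
  expect_lt(thr, 10 + 15 * 2)
})

test_that("plate CSVs round-trip and validate roles", {
  plate <- fixture_plate()
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(plate, path)
  back <- read_plate_csv(path)
  expect_equal(back$rfu, plate$rfu)
  expect_identical(back$role, plate$role)
  bad <- plate; bad$role[1] <- "mystery"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(bad, path2)
  expect_error(read_plate_csv(path2), "mystery")
})

test_that("pool plans enforce the 20-member cap", {
  expect_error(pool_plan(character(0), "r"), "at least one")
  expect_error(pool_plan(paste0("s", 1:21), "r"), "cap")
  p <- pool_plan(paste0("s", 1:20), "r", spike_source_id = "fp1")
  expect_true(p$spiked)
})
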