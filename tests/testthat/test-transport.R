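# RK4 advection, random-walk diffusion, and full simulation bookkeeping.

test_that("uniform-flow advection matches the analytic displacement", {
  f <- fixture_uniform_field(u0 = 0.1, v0 = 0)
  step <- advect_rk4(f, 200, 0, "2020-01-10", 86400, "forward")
  # 0.1 m/s for a day = 8,640 m; at the equator that is 8640/111195 deg
  expect_equal(step$lat, 0)
  expect_equal(step$lon - 200, 8640 / 111195, tolerance = 1e-10)
  expect_false(step$escaped)

  # backward step exactly reverses the forward step
  back <- advect_rk4(f, step$lon, step$lat, "2020-01-11", 86400, "backward")
  expect_equal(back$lon, 200, tolerance = 1e-12)
  expect_equal(back$lat, 0, tolerance = 1e-12)
})

test_that("solid-body rotation conserves radius over a revolution", {
  f <- fixture_rotation_field(period_days = 30)
  lon <- 204; lat <- 25
  t <- as.POSIXct("2020-01-01", tz = "UTC")
  n_steps <- 100
  dt <- 30 * 86400 / n_steps
  for (i in seq_len(n_steps)) {
    p <- advect_rk4(f, lon, lat, t, dt, "forward")
    lon <- p$lon; lat <- p$lat; t <- t + dt
  }
  r0 <- 4
  r1 <- sqrt((lon - 200)^2 + (lat - 25)^2)
  expect_lt(abs(r1 - r0) / r0, 0.001)   # < 0.1% per revolution
  # and it comes back to the start after a full period
  expect_lt(sqrt((lon - 204)^2 + (lat - 25)^2), 0.01)
})

test_that("deterministic forward-backward round trip closes within 1 km", {
  f <- make_field(field_spec("double_gyre", bbox = c(180, 220, 10, 40),
                             res = 0.5, start = "2020-01-01",
                             end = "2020-03-31"))
  lon <- 190; lat <- 20
  t <- as.POSIXct("2020-01-01", tz = "UTC")
  for (i in seq_len(30 * 24)) {
    p <- advect_rk4(f, lon, lat, t, 3600, "forward")
    lon <- p$lon; lat <- p$lat; t <- t + 3600
  }
  expect_gt(haversine_km(lon, lat, 190, 20), 10)  # it actually went somewhere
  for (i in seq_len(30 * 24)) {
    p <- advect_rk4(f, lon, lat, t, 3600, "backward")
    lon <- p$lon; lat <- p$lat; t <- t - 3600
  }
  expect_lt(haversine_km(lon, lat, 190, 20), 1)
})

test_that("diffusion is the identity at K = 0 and reproducible by seed", {
  p <- diffuse(200, 25, 86400, K = 0)
  expect_equal(p, list(lon = 200, lat = 25))
  set.seed(5); a <- diffuse(rep(200, 10), rep(25, 10), 3600, K = 10)
  set.seed(5); b <- diffuse(rep(200, 10), rep(25, 10), 3600, K = 10)
  expect_identical(a, b)
})

test_that("diffusion displacement variance matches 2*K*dt per axis", {
  n <- 10000; K <- 10; dt <- 86400
  set.seed(1234)
  p <- diffuse(rep(0, n), rep(0, n), dt, K)
  dx_m <- ifelse(p$lon > 180, p$lon - 360, p$lon) * 111195  # at the equator
  dy_m <- p$lat * 111195
  target <- 2 * K * dt   # 1.728e6 m^2
  expect_equal(stats::var(dx_m), target, tolerance = 0.05)
  expect_equal(stats::var(dy_m), target, tolerance = 0.05)
  # ensemble centroid stays at the release point within 3 standard errors
  se <- sqrt(target / n)
  expect_lt(abs(mean(dx_m)), 3 * se)
  expect_lt(abs(mean(dy_m)), 3 * se)
})

test_that("release accounting is calendar-inclusive", {
  sched <- release_schedule()  # the default monitoring schedule
  expect_identical(n_released(sched), 584300L)
  one_day <- release_schedule(particles_per_day = 7,
                              start_date = "2020-01-01",
                              end_date = "2020-01-01")
  expect_identical(n_released(one_day), 7L)
})

test_that("simulation conserves particles and lands everything in a sink", {
  fx <- fixture_sink()
  sched <- release_schedule(site = c(205, 29), particles_per_day = 50,
                            start_date = "2020-02-08",
                            end_date = "2020-02-10")
  cfg <- transport_config(K = 0, direction = "backward", seed = 2)
  run <- run_simulation(fx$field, sched, fx$settlement, cfg,
                        save_trajectories = TRUE)
  expect_identical(run$total_released, 150L)
  expect_identical(nrow(run$particles), 150L)
  counts <- table(run$particles$status)
  expect_identical(sum(counts), 150L)
  # convergent flow in backtracking: every particle reaches the island
  expect_identical(unname(counts[["landed"]]), 150L)
  # landed cells really are active island cells
  expect_true(all(run$landings$cell_id %in%
                    fx$grid$cells$id[fx$settlement$active]))
  # drift duration equals |landing - release| in whole days
  dd <- as.integer(abs(as.numeric(run$landings$landing_date -
                                    run$landings$release_date)))
  expect_identical(run$landings$drift_days, dd)
  # trajectory log covers every particle from release to landing
  expect_true(all(run$particles$particle_id %in%
                    run$trajectories$particle_id))
})

test_that("an empty settlement set yields no landings", {
  fx <- fixture_sink()
  sched <- release_schedule(site = c(205, 29), particles_per_day = 20,
                            start_date = "2020-02-10",
                            end_date = "2020-02-10")
  cfg <- transport_config(K = 0, direction = "backward", seed = 2)
  run <- run_simulation(fx$field, sched, empty_settlement(fx$grid), cfg)
  expect_identical(nrow(run$landings), 0L)
  expect_true(all(run$particles$status %in%
                    c("active", "escaped_domain", "expired")))
})

test_that("a schedule outside the field's span fails before integrating", {
  fx <- fixture_sink()
  sched <- release_schedule(site = c(205, 29), particles_per_day = 1,
                            start_date = "2021-01-01",
                            end_date = "2021-01-02")
  cfg <- transport_config(K = 0, direction = "backward", seed = 2)
  expect_error(run_simulation(fx$field, sched, fx$settlement, cfg),
               "time range")
})

test_that("stochastic runs are seed-reproducible", {
  fx <- fixture_sink()
  cfg <- transport_config(K = 10, direction = "backward", seed = 42,
                          max_duration = 20)
  sched <- release_schedule(site = c(204, 28), particles_per_day = 10,
                            start_date = "2020-02-09",
                            end_date = "2020-02-10")
  run_a <- run_simulation(fx$field, sched, fx$settlement, cfg)
  run_b <- run_simulation(fx$field, sched, fx$settlement, cfg)
  expect_identical(run_a$particles, run_b$particles)
  cfg2 <- transport_config(K = 10, direction = "backward", seed = 43,
                           max_duration = 20)
  run_c <- run_simulation(fx$field, sched, fx$settlement, cfg2)
  expect_false(identical(run_a$particles$lon, run_c$particles$lon))
})
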