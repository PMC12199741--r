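# Shared fixtures, built in code at test time.

# small uniform eastward field over the central North Pacific
fixture_uniform_field <- function(u0 = 0.1, v0 = 0, ...) {
  make_field(field_spec("uniform", u0 = u0, v0 = v0,
                        bbox = c(180, 220, -10, 40), res = 1,
                        start = "2020-01-01", end = "2020-03-31", ...))
}

# solid-body rotation: one revolution per 30 days in degree space
fixture_rotation_field <- function(period_days = 30) {
  make_field(field_spec("solid_body", omega = 2 * pi / (period_days * 86400),
                        center = c(200, 25), bbox = c(180, 220, 10, 40),
                        res = 0.5, start = "2020-01-01", end = "2020-05-01"))
}

# a source island whose backtracked flow funnels everything to one atoll
fixture_sink <- function() {
  island <- list(center = c(200, 25), radius = 0.4)
  field <- make_field(field_spec(
    "convergent_sink", center = c(200, 25), rate = 2e-6, outward = TRUE,
    islands = list(island), bbox = c(185, 215, 12, 38), res = 0.5,
    start = "2020-01-01", end = "2020-02-15"))
  grid <- build_hex_grid(c(185, 215, 12, 38), 1)
  settlement <- activate_cells(grid, make_coastline(list(island)))
  list(island = island, field = field, grid = grid,
       settlement = settlement)
}

# tiny plate export: standards ladder + pooled wells for two regions
fixture_plate <- function(sample_copies = c(A = 0, B = 50),
                          spike_copies = 8, threshold = 100,
                          intercept = 38, slope = -1 / log10(2)) {
  rows <- list()
  add_well <- function(well, role, region, copies, log10_copies = NA) {
    curve <- make_qpcr(copies, slope = slope, intercept = intercept,
                       threshold = threshold)
    rows[[length(rows) + 1]] <<- data.frame(
      plate_id = "P1", well = well, role = role, region = region,
      cycle = curve$cycle, rfu = curve$rfu, log10_copies = log10_copies)
  }
  wi <- 0
  nw <- function() { wi <<- wi + 1; sprintf("W%02d", wi) }
  for (lg in 5:1) add_well(nw(), "standard", "std", 10^lg, lg)
  for (rg in names(sample_copies)) {
    for (r in 1:3) add_well(nw(), "sample_pool", rg, sample_copies[[rg]])
    for (r in 1:3) add_well(nw(), "positive_pool", rg,
                            sample_copies[[rg]] + spike_copies)
  }
  for (r in 1:3) add_well(nw(), "NTC", "ctrl", 0)
  add_well(nw(), "EB", "ctrl", 0)
  do.call(rbind, rows)
}
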