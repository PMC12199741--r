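# Shared construction helpers for the analysis scripts.

# A plate export for three screened regions: every sample pool truly
# negative, every positive pool spiked to a low copy number, clean
# controls, and a five-point tenfold standards ladder.
synth_plate <- function(seed, regions = c("region-A", "region-B", "region-C"),
                        spike_copies = 8, threshold = 100) {
  rows <- list()
  wi <- 0
  add_well <- function(role, region, copies, log10_copies = NA) {
    wi <<- wi + 1
    curve <- make_qpcr(copies, threshold = threshold, noise_sd = 1.5,
                       seed = seed + wi)
    rows[[length(rows) + 1]] <<- data.frame(
      plate_id = "SYN1", well = sprintf("W%02d", wi), role = role,
      region = region, cycle = curve$cycle, rfu = curve$rfu,
      log10_copies = log10_copies)
  }
  for (lg in 5:1) add_well("standard", "std", 10^lg, lg)
  for (rg in regions) {
    for (r in 1:3) add_well("sample_pool", rg, 0)
    for (r in 1:3) add_well("positive_pool", rg, spike_copies)
  }
  for (r in 1:3) add_well("NTC", "ctrl", 0)
  add_well("EB", "ctrl", 0)
  do.call(rbind, rows)
}
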