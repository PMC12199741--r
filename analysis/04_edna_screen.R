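#!/usr/bin/env Rscript
# Screen the pooled qPCR plate: call Cq values, fit the standard curve,
# quantify starting copies, and issue per-region detection decisions.

library(driftback)

in_dir <- file.path("results", "inputs")
out_dir <- file.path("results", "edna")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

plate <- read_plate_csv(file.path(in_dir, "plate.csv"))
screen <- screen_plate(plate, threshold = 100)

print(screen$fit)
utils::write.csv(screen$wells, file.path(out_dir, "well_quantities.csv"),
                 row.names = FALSE)
calls <- data.frame(
  region = names(screen$calls),
  status = vapply(screen$calls, function(x) x$status, ""),
  rescreen = vapply(screen$calls, function(x) x$rescreen_recommended, TRUE),
  max_sample_quantity = vapply(screen$calls, function(x)
    max(x$sample_quantities), 1),
  min_positive_quantity = vapply(screen$calls, function(x)
    min(x$positive_quantities), 1))
utils::write.csv(calls, file.path(out_dir, "region_calls.csv"),
                 row.names = FALSE)
print(calls, row.names = FALSE)

# reliability of the spiked-pool detections: smoothed replicate consensus
# must clear the threshold
for (rg in names(screen$calls)) {
  sub <- plate[plate$role == "positive_pool" & plate$region == rg, ]
  m <- do.call(cbind, lapply(split(sub, sub$well), function(w)
    w$rfu[order(w$cycle)]))
  cat(sprintf("positive pool %s reliable: %s\n", rg,
              reliability_check(m, threshold = 100)))
}
cat("eDNA outputs written to", out_dir, "\n")
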