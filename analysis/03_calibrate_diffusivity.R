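#!/usr/bin/env Rscript
# Calibrate the horizontal diffusivity against synthetic tagged debris:
# three tags escape the monitored atoll inside a rotating gyre, drift with
# the true K = 10 m^2/s, and their backtracked candidate ensembles are
# pooled and compared by minimum passing distance.

library(driftback)

out_dir <- file.path("results", "calibration")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cal <- calibration_study(seed = 1L, n = 1000)
print(cal)

utils::write.csv(cal$distances,
                 file.path(out_dir, "passing_distances.csv"),
                 row.names = FALSE)
utils::write.csv(cal$summary, file.path(out_dir, "summary.csv"),
                 row.names = FALSE)
utils::write.csv(cal$tests, file.path(out_dir, "pairwise_tests.csv"),
                 row.names = FALSE)

sel <- as.character(cal$selected_K)
p05 <- cal$tests[(cal$tests$group1 == "0.5" | cal$tests$group2 == "0.5") &
                   (cal$tests$group1 == sel | cal$tests$group2 == sel), ]
cat(sprintf(
  "selected K = %s m^2/s; indistinguishable set {%s}; 0.5 vs %s adj p = %.2g\n",
  sel, paste(cal$indistinguishable, collapse = ", "), sel,
  p05$p_adjusted))
cat("calibration outputs written to", out_dir, "\n")
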