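#!/usr/bin/env Rscript
# Build the synthetic study world: an analytic velocity field written as
# NetCDF, an island coastline as GeoJSON, a monthly ENSO phase series, a
# pooled qPCR plate export, and a synthetic barcode family as FASTA.
# Everything downstream (02-05) reads only these files plus the package.

library(driftback)

out_dir <- file.path("results", "inputs")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20160115

# -- velocity field: a source island whose outward surface flow, run in
#    backtracking mode, funnels particles to the island -------------------
island <- list(center = c(200, 25), radius = 0.4)
spec <- field_spec("convergent_sink", center = island$center, rate = 2e-6,
                   outward = TRUE, islands = list(island),
                   bbox = c(185, 215, 12, 38), res = 0.5,
                   start = "2020-01-01", end = "2020-02-15")
field <- make_field(spec)
write_velocity_field(field, file.path(out_dir, "field_sink.nc"))
write_polygons_geojson(make_coastline(list(island)),
                       file.path(out_dir, "coastline.geojson"),
                       properties = data.frame(name = "source-island"))

# -- ENSO phase series covering the simulated period ----------------------
enso <- make_enso("2020-01", "2020-12", probs = c(0.25, 0.25, 0.5),
                  seed = seed)
write_enso_csv(enso, file.path(out_dir, "enso.csv"))

# -- qPCR plate: three regional sample/positive pools, standards, controls;
#    the synthetic truth is an all-negative survey with low-copy spikes ----
source(file.path("analysis", "helpers.R"))
plate <- synth_plate(seed)
write_plate_csv(plate, file.path(out_dir, "plate.csv"))

# -- barcode family: a 389-nt reference, a conspecific-grade near match
#    (0.5% divergence), and more distant congeners (3%) ------------------
set.seed(seed)
reference <- paste(sample(c("A", "C", "G", "T"), 389, replace = TRUE),
                   collapse = "")
congeners <- make_markers(reference, n = 11, d = 0.03, seed = seed)
near <- make_markers(reference, n = 1, d = 0.005, seed = seed + 1)
family <- c(reference = reference,
            stats::setNames(near, "near_match"), congeners)
write_fasta(family, file.path(out_dir, "upa_family_synthetic.fasta"))

manifest <- list(seed = seed, island = island,
                 field = unclass(spec)[c("kind", "bbox", "res", "start",
                                         "end", "rate", "outward")],
                 note = "synthetic inputs; all ground truth known by construction")
jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                     auto_unbox = TRUE, pretty = TRUE)
cat("synthetic inputs written to", out_dir, "\n")
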