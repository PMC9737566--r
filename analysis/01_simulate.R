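#!/usr/bin/env Rscript

# Stage 1: simulate the synthetic seed study.
#
# Builds the default four-group world (smooth, rugose, echinate,
# papillose; 4 species per group, 20 seeds per species, two views each)
# and writes every seed as a calibrated mask PNG plus the dataset
# manifest.  Masks are bulky, so they go under scratch/; everything the
# later stages need is reachable through the manifest path printed below.

suppressMessages(library(seedshape))

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
study_dir <- "scratch/study"

specs <- default_study_specs(species_per_group = 4L, n_seeds = 20L,
                             seed = seed)
manifest <- generate_study(specs, study_dir, raster_px = 512L)

cat(sprintf("simulated %d species (%d groups), %d seed-view masks\n",
            length(specs), length(unique(manifest$group)), nrow(manifest)))
cat(sprintf("manifest: %s\n", file.path(study_dir, "manifest.csv")))
cat(sprintf("regeneration specs: %s\n", file.path(study_dir, "specs.json")))
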