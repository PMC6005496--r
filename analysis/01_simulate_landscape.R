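#!/usr/bin/env Rscript
# Simulate the virtual study landscape and species.
#
# Generates the default 80 x 80 km landscape (terrain, monthly climate
# normals, 250 m land cover, two years of 16-day EVI/LST/albedo composites),
# defines the cool-wet virtual species on the climate predictors, samples
# presence-only records, and writes every raster plus the occurrence table
# under results/landscape/.

library(efasdm)

seed <- 1
outdir <- "results/landscape"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- landscape_config(seed = derive_seed(seed, "landscape"))
bundle <- generate_landscape(cfg)
write_landscape(bundle, outdir)

efa <- compute_efa_stack(bundle$satellite)
stack <- derive_predictors(bundle, cfg$fine_cell_km, NULL, efa)
species <- define_virtual_species(stack, c("TmDQ", "PpWM"), c(-2, 2),
                                  prevalence_target = 0.15)
write_ascii_grid(species$truth_map, file.path(outdir, "truth_suitability.asc"))

recs <- sample_occurrences(species, 91, seed = derive_seed(seed, "occ"))
write.csv(recs[, c("species", "x", "y", "grid_id", "year")],
          file.path(outdir, "occurrences.csv"), row.names = FALSE)

cat(sprintf(
  "Landscape: %d x %d km, elevation %.0f-%.0f m, land cover %s\n",
  cfg$nrow, cfg$ncol, min(bundle$elevation$values),
  max(bundle$elevation$values),
  paste(cfg$landcover_classes, collapse = "/")))
cat(sprintf("Virtual species: prevalence %.3f (target 0.15), %d records\n",
            species$prevalence, nrow(recs)))
cat("Wrote rasters and occurrences to", outdir, "\n")
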