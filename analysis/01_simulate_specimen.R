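#!/usr/bin/env Rscript
# Simulate one peri-implantitis-like phantom specimen and write its survey
# and high-statistics titanium maps, sulfur map, geometry and ground truth.
# Downstream scripts (02, 03) consume these artefacts.

suppressPackageStartupMessages(library(tipix))
out <- "results/specimen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- phantom_spec(specimen_width_mm = 4, specimen_depth_mm = 3,
                     thickness_um = 21, pixel_size_um = 2.5, seed = 42)
geom <- phantom_geometry(spec, inflamed_fraction = 0.59)
truth <- sample_particle_field(spec, geom)
survey <- render_maps(truth, spec, geom, 200)
high <- render_maps(truth, spec, geom, 20000, elements = "ti")

write_elemental_map(survey$ti, file.path(out, "ti_survey.tif"))
write_elemental_map(survey$s, file.path(out, "s_survey.tif"))
write_elemental_map(high$ti, file.path(out, "ti_high_stat.tif"))
write_geometry(geom, file.path(out, "geometry.geojson"))
write.table(truth$particles, file.path(out, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "Simulated a %g x %g mm specimen at %g um/px: %d true particles (%s per zone),\n%d confuser sources; maps written to %s\n",
  spec$specimen_width_mm, spec$specimen_depth_mm, spec$pixel_size_um,
  nrow(truth$particles), paste(tabulate(truth$particles$zone, 3), collapse = "/"),
  nrow(truth$confusers), out))
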