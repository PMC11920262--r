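#!/usr/bin/env Rscript
# Full paired-cohort run: six patients, one peri-implantitis and one
# reference specimen each, simulated and pushed through the entire pipeline.
# Emits the study-style tables (cohort, per-ROI paired comparisons,
# inflamed/non-inflamed, particle morphometry, heatmaps) under results/cohort.

suppressPackageStartupMessages(library(tipix))
cfg <- run_config(n_pairs = 6, seed = 1)
summ <- suppressMessages(run_pipeline(cfg, out_dir = "results/cohort"))

roi <- summ$roi
ent <- function(cond, m) mean(roi[roi$roi_name == "entire" &
                                    roi$site_condition == cond, m])
cat(sprintf(
  "Cohort of %d pairs.\nEntire-specimen volumetric density: peri %.0f vs reference %.0f particles/mm^3 (paired Wilcoxon p = %.3f).\nSpecimen area: peri %.1f vs reference %.1f mm^2 (p = %.4f).\nTi-high group: %d of %d peri samples above the mean inflamed-zone density (%.0f/mm^3).\nTables written to results/cohort.\n",
  cfg$n_pairs,
  ent("peri-implantitis", "volumetric_density"), ent("reference", "volumetric_density"),
  summ$tests[["entire.volumetric_density"]],
  ent("peri-implantitis", "area_mm2"), ent("reference", "area_mm2"),
  summ$tests[["entire.area_mm2"]],
  sum(summ$ti_groups$label == "Ti-high"), nrow(summ$ti_groups),
  summ$ti_groups$threshold[1]))
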