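#!/usr/bin/env Rscript
# Validation campaign: does the full pipeline recover the zone densities the
# generator was configured with, and does a configured decreasing gradient
# survive detection and quantification? 30 replicate phantoms.

suppressPackageStartupMessages(library(tipix))
dir.create("results", showWarnings = FALSE)

spec <- phantom_spec(specimen_width_mm = 3, specimen_depth_mm = 2,
                     thickness_um = 30, pixel_size_um = 2.5,
                     zone_densities = c(500, 200, 50), false_source_rate = 1,
                     seed = 1)
rec <- suppressMessages(zone_recovery_experiment(spec, n_reps = 30, seed = 202))
write.csv(rec, "results/zone_recovery.csv", row.names = FALSE)

for (z in 1:3) {
  sub <- rec[rec$zone == z, ]
  pooled <- sum(sub$n_detected) / sum(sub$volume_mm3)
  se <- sqrt(sub$true_density[1] / sum(sub$volume_mm3))
  cat(sprintf("zone %d: configured %3g, recovered %6.1f particles/mm^3 (%.1f SE off)\n",
              z, sub$true_density[1], pooled,
              (pooled - sub$true_density[1]) / se))
}
mono <- vapply(split(rec, rec$rep), function(r) {
  d <- r$density[order(r$zone)]; d[1] > d[2] && d[2] > d[3]
}, TRUE)
cat(sprintf("monotone zone1 > zone2 > zone3 gradient in %d/%d replicates (%.0f%%)\n",
            sum(mono), length(mono), 100 * mean(mono)))
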