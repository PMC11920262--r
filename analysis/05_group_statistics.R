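#!/usr/bin/env Rscript
# Group-level statistics on the cohort run from 03: linear regression of
# volumetric density on implant covariates (with the three-category implant
# system grouping) and a Mann-Whitney comparison between the Ti-high and
# Ti-low sample groups.

suppressPackageStartupMessages(library(tipix))
src <- "results/cohort"
if (!file.exists(file.path(src, "roi_metrics.tsv")))
  stop("run analysis/03_cohort_pipeline.R first")

roi <- read.delim(file.path(src, "roi_metrics.tsv"))
samples <- read.csv(file.path(src, "samples.csv"))
ent <- roi[roi$roi_name == "entire", ]
d <- merge(ent, samples, by = c("patient_id", "site_condition"))
d$implant_system_grouped <- recode_implant_system(d$implant_system)

fit <- tryCatch(
  density_regression(d, volumetric_density ~ implant_system_grouped +
                       probing_pocket_depth_mm),
  error = function(e) e)
if (inherits(fit, "error")) {
  cat("regression not estimable on this draw:", conditionMessage(fit), "\n")
} else {
  print(fit)
  write.csv(fit$coefficients, "results/density_regression.csv",
            row.names = FALSE)
}

infl <- roi[roi$roi_name == "inflamed" &
              roi$site_condition == "peri-implantitis", ]
groups <- split_ti_groups(setNames(infl$volumetric_density, infl$sample_id))
hi <- groups$density[groups$label == "Ti-high"]
lo <- groups$density[groups$label == "Ti-low"]
cat(sprintf("Ti-high n = %d (mean %.0f/mm^3), Ti-low n = %d (mean %.0f/mm^3)\n",
            length(hi), mean(hi), length(lo), mean(lo)))
if (length(hi) >= 1 && length(lo) >= 1) {
  mw <- mann_whitney_u(hi, lo)
  print(mw)
}
write.csv(groups, "results/ti_groups.csv", row.names = FALSE)
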