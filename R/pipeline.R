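# Orchestration: simulate a paired cohort of phantom specimens, run the
# detection -> morphometry -> zoning -> quantification chain on each, compute
# the paired statistics, and emit study-style tables. Deterministic for a
# given configuration and seed.

#' Pipeline run configuration
#'
#' Defaults follow the study conditions wherever those are stated: 15 um
#' small/large split, 1 and 2 mm zone band edges, 1.5 um detectability floor,
#' survey fluence 200 and confirmation fluence 20,000 nC/mm^2. Cohort sizes
#' and raster pitch are the package's own choices (see the methods vignette).
#'
#' @param n_pairs number of patients (each contributes one peri-implantitis
#'   and one reference specimen).
#' @param seed master seed; every stage derives its randomness from it.
#' @param pixel_size_um raster pitch of the simulated maps.
#' @param survey_fluence_nc_mm2,high_fluence_nc_mm2 the two pass fluences.
#' @param size_threshold_um small/large split.
#' @param band_edges_mm zone band edges.
#' @param min_diameter_um segmentation floor.
#' @param sensitivity,min_snr detector and confirmation parameters.
#' @param peri,reference per-condition generator settings: lists with
#'   `width_range_mm`, `depth_range_mm`, `zone_densities`,
#'   `inflamed_fraction`.
#' @param thickness_range_um per-sample section thickness range.
#' @return object of class `run_config`.
#' @export
run_config <- function(n_pairs = 6, seed = 1L, pixel_size_um = 2.5,
                       survey_fluence_nc_mm2 = 200,
                       high_fluence_nc_mm2 = 20000,
                       size_threshold_um = 15, band_edges_mm = c(1, 2),
                       min_diameter_um = 1.5, sensitivity = 0.995,
                       min_snr = 5,
                       peri = list(width_range_mm = c(3.6, 4.6),
                                   depth_range_mm = c(2.6, 3.4),
                                   zone_densities = c(260, 159, 152),
                                   inflamed_fraction = 0.59),
                       reference = list(width_range_mm = c(2.4, 3.2),
                                        depth_range_mm = c(1.9, 2.5),
                                        zone_densities = c(260, 229, 116),
                                        inflamed_fraction = 0.45),
                       thickness_range_um = c(15, 27)) {
  cfg <- structure(as.list(environment()), class = "run_config")
  cfg$seed <- as.integer(seed)
  cfg$version <- as.character(utils::packageVersion("tipix"))
  cfg
}

# Small deterministic sub-seed derivation (kept below 2^31).
derive_seed <- function(seed, k) as.integer((as.double(seed) * 97 + k * 131) %% 2147483000)

# Deterministic digest of a configuration, for run provenance.
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[order(names(config))]), f)
  unname(tools::md5sum(f))
}

#' Process one specimen: detection through ROI metrics
#'
#' The full single-specimen analysis chain: outline extraction from the
#' sulfur map, candidate detection on the survey Ti map, high-statistics
#' confirmation, threshold calibration from the false detections,
#' segmentation, morphometry, position assignment and per-ROI metrics.
#'
#' @param survey list with `ti` and `s` survey `elemental_map`s.
#' @param high_ti confirmation-pass Ti `elemental_map`.
#' @param geometry the `specimen_geometry` (reference lines, inflammation
#'   polygons, thickness).
#' @param config a `run_config`.
#' @param use_extracted_outline use the sulfur-derived outline for ROI
#'   building (as the study did); otherwise use `geometry$outline`.
#' @return list: `particles` (measured + positioned data.frame), `rois`
#'   (`roi_set`), `roi_metrics` (data.frame over the six ROIs), `threshold`,
#'   `candidates`, `confirmation`, `outline`.
#' @export
process_specimen <- function(survey, high_ti, geometry, config = run_config(),
                             use_extracted_outline = TRUE) {
  outline <- if (use_extracted_outline) extract_outline(survey$s)
             else geometry$outline
  cands <- detect_candidates(survey$ti, sensitivity = config$sensitivity)
  if (nrow(cands) > 0) {
    conf <- confirm_candidates(cands, high_ti, min_snr = config$min_snr)
    thr <- calibrate_threshold(conf, cands)
  } else {
    conf <- confirm_candidates(cands, high_ti, min_snr = config$min_snr)
    thr <- structure(list(value = 0, provenance = numeric(0)),
                     class = "detection_threshold")
  }
  seg <- segment_particles(survey$ti, thr, config$min_diameter_um)
  particles <- measure_particles(seg, config$size_threshold_um)
  particles <- assign_positions(particles, geometry,
                                band_edges_mm = config$band_edges_mm,
                                outline = outline)
  rois <- build_zones(outline, geometry$interface_line,
                      survey$ti$pixel_size_um, dim(survey$ti$counts),
                      origin_um = survey$ti$origin_um,
                      band_edges_mm = config$band_edges_mm,
                      inflammation_zones = geometry$inflammation_zones)
  inp <- particles[particles$in_outline, , drop = FALSE]
  sel <- list(entire = rep(TRUE, nrow(inp)),
              zone1 = inp$zone == 1L, zone2 = inp$zone == 2L,
              zone3 = inp$zone == 3L,
              inflamed = inp$inflamed, non_inflamed = !inp$inflamed)
  rm_list <- lapply(names(sel), function(nm)
    roi_metrics(inp[sel[[nm]], , drop = FALSE], nm, rois$areas_mm2[[nm]],
                geometry$thickness_um))
  list(particles = particles, rois = rois,
       roi_metrics = do.call(rbind, rm_list), threshold = thr,
       candidates = cands, confirmation = conf, outline = outline)
}

# Simulate per-sample metadata mirroring the cohort table fields; implant
# system frequencies follow the study cohort.
simulate_cohort_metadata <- function(n_pairs, seed) {
  systems <- c("Ankylos/Friadent Plus", "Astra Tech/Osseospeed",
               "Astra Tech/TioBlast", "Branemark/Turned", "Nobel/TiUnite",
               "Straumann/SLA")
  sys_p <- c(1, 5, 2, 2, 7, 1) / 18
  with_seed(derive_seed(seed, 7), {
    rows <- list()
    for (i in seq_len(n_pairs)) {
      for (cond in c("peri-implantitis", "reference")) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = sprintf("P%02d", i), site_condition = cond,
          implant_system = sample(systems, 1, prob = sys_p),
          years_in_function = round(max(1, stats::rnorm(1, 12.6, 5.5)), 1),
          implant_length_mm = round(stats::rnorm(1, 13, 3), 1),
          implant_diameter_mm = round(stats::rnorm(1, 4, 0.7), 1),
          jaw = sample(c("mandible", "maxilla"), 1, prob = c(1, 2)),
          location = sample(c("anterior", "posterior"), 1, prob = c(1, 2)),
          reconstruction_type = sample(c("single crown", "bridge", "overdenture"),
                                       1, prob = c(3, 12, 3)),
          probing_pocket_depth_mm =
            round(stats::rnorm(1, if (cond == "peri-implantitis") 7.6 else 4.1,
                               if (cond == "peri-implantitis") 0.78 else 1.08), 1),
          bone_level_mm =
            round(stats::rnorm(1, if (cond == "peri-implantitis") 4.7 else 1.6,
                               if (cond == "peri-implantitis") 0.96 else 0.77), 1))
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate one cohort specimen (maps + geometry + truth)
#'
#' @param config a `run_config`.
#' @param pair_index patient index.
#' @param condition `"peri-implantitis"` or `"reference"`.
#' @return list: `spec`, `geometry`, `truth`, `survey` (ti + s), `high_ti`.
#' @export
simulate_specimen <- function(config, pair_index, condition) {
  grp <- if (condition == "peri-implantitis") config$peri else config$reference
  k <- pair_index * 2L + (condition == "peri-implantitis")
  sseed <- derive_seed(config$seed, k)
  dims <- with_seed(sseed, c(stats::runif(1, grp$width_range_mm[1], grp$width_range_mm[2]),
                             stats::runif(1, grp$depth_range_mm[1], grp$depth_range_mm[2]),
                             stats::runif(1, config$thickness_range_um[1],
                                          config$thickness_range_um[2])))
  spec <- phantom_spec(specimen_width_mm = dims[1], specimen_depth_mm = dims[2],
                       thickness_um = dims[3],
                       pixel_size_um = config$pixel_size_um,
                       zone_densities = grp$zone_densities,
                       seed = derive_seed(config$seed, k + 5000L))
  geometry <- phantom_geometry(spec, inflamed_fraction = grp$inflamed_fraction)
  truth <- sample_particle_field(spec, geometry)
  survey <- render_maps(truth, spec, geometry, config$survey_fluence_nc_mm2)
  high <- render_maps(truth, spec, geometry, config$high_fluence_nc_mm2,
                      elements = "ti")
  list(spec = spec, geometry = geometry, truth = truth, survey = survey,
       high_ti = high$ti)
}

#' Run the full pipeline on a simulated paired cohort
#'
#' Simulates `n_pairs` patients (one peri-implantitis and one reference
#' specimen each), runs [process_specimen()] on every specimen, computes the
#' paired comparisons and the Ti-high/Ti-low split, and (optionally) writes
#' every artefact to a run directory. Identical config + seed gives identical
#' outputs.
#'
#' @param config a `run_config`.
#' @param out_dir output directory; `NULL` to skip writing.
#' @return summary list: `samples` (metadata), `roi` (per-sample ROI
#'   metrics), `particles`, `tests` (paired Wilcoxon per ROI and metric),
#'   `ti_groups`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
    invisible(NULL)
  }
  samples <- simulate_cohort_metadata(config$n_pairs, config$seed)
  roi_all <- list(); part_all <- list()
  for (i in seq_len(config$n_pairs)) {
    for (cond in c("peri-implantitis", "reference")) {
      sid <- sprintf("P%02d_%s", i,
                     if (cond == "peri-implantitis") "peri" else "ref")
      stage <- "simulate"
      res <- tryCatch({
        sim <- simulate_specimen(config, i, cond)
        stage <- "process"
        pr <- process_specimen(sim$survey, sim$high_ti, sim$geometry, config)
        list(sim = sim, pr = pr)
      }, error = function(e)
        stop(sprintf("stage '%s' failed for sample %s: %s", stage, sid,
                     conditionMessage(e)), call. = FALSE))
      pr <- res$pr
      rm_df <- pr$roi_metrics
      rm_df$sample_id <- sid
      rm_df$patient_id <- sprintf("P%02d", i)
      rm_df$site_condition <- cond
      rm_df$thickness_um <- res$sim$geometry$thickness_um
      roi_all[[sid]] <- rm_df
      p_df <- pr$particles
      if (nrow(p_df)) {
        p_df$sample_id <- sid
        p_df$patient_id <- sprintf("P%02d", i)
        p_df$site_condition <- cond
        part_all[[sid]] <- p_df
      }
      say("sample %s: %d particles, threshold %g counts", sid,
          nrow(pr$particles), pr$threshold$value)
    }
  }
  roi <- do.call(rbind, roi_all); rownames(roi) <- NULL
  particles <- if (length(part_all)) do.call(rbind, part_all) else NULL
  if (!is.null(particles)) rownames(particles) <- NULL

  tests <- paired_roi_tests(roi)
  infl <- roi[roi$roi_name == "inflamed" & roi$site_condition == "peri-implantitis", ]
  dens <- stats::setNames(infl$volumetric_density, infl$sample_id)
  ti_groups <- split_ti_groups(dens)
  summary <- list(samples = samples, roi = roi, particles = particles,
                  tests = tests, ti_groups = ti_groups, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ptab <- particles
    if (is.null(ptab)) ptab <- data.frame()
    ptab$particle_id <- if (nrow(ptab)) seq_len(nrow(ptab)) else integer(0)
    write_particle_table(ptab, file.path(out_dir, "particles.tsv"))
    utils::write.table(roi, file.path(out_dir, "roi_metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.csv(samples, file.path(out_dir, "samples.csv"), row.names = FALSE)
    jsonlite::write_json(list(tests = tests, ti_groups = ti_groups,
                              provenance = list(seed = config$seed,
                                                version = config$version,
                                                config_hash = config_hash(config))),
                         file.path(out_dir, "tests.json"),
                         auto_unbox = TRUE, digits = NA)
    build_study_tables(summary, out_dir)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  summary
}

#' Zone-density recovery experiment on replicate phantoms
#'
#' Renders `n_reps` independent phantoms from one spec, runs the full
#' detection-to-quantification chain on each, and returns per-replicate,
#' per-zone particle counts, volumes and volumetric densities together with
#' the ground-truth counts. Used to verify that the pipeline recovers the
#' configured zone densities and reproduces a configured density gradient.
#'
#' @param spec a `phantom_spec`; its `zone_densities` are the configured
#'   truth.
#' @param n_reps number of replicate phantoms.
#' @param seed experiment seed (each replicate derives its own).
#' @param config a `run_config` supplying the detection parameters.
#' @return data.frame with one row per replicate and zone: `rep`, `zone`,
#'   `n_detected`, `n_true`, `volume_mm3`, `density`, `true_density`.
#' @export
zone_recovery_experiment <- function(spec, n_reps = 30, seed = 1,
                                     config = run_config()) {
  rows <- list()
  for (r in seq_len(n_reps)) {
    sp <- spec
    sp$seed <- derive_seed(seed, r)
    geom <- phantom_geometry(sp)
    truth <- sample_particle_field(sp, geom)
    survey <- render_maps(truth, sp, geom, config$survey_fluence_nc_mm2)
    high <- render_maps(truth, sp, geom, config$high_fluence_nc_mm2,
                        elements = "ti")
    pr <- suppressWarnings(
      process_specimen(survey, high$ti, geom, config))
    rm <- pr$roi_metrics
    for (z in 1:3) {
      zn <- paste0("zone", z)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, zone = z,
        n_detected = rm$n_particles[rm$roi_name == zn],
        n_true = sum(truth$particles$zone == z),
        volume_mm3 = rm$volume_mm3[rm$roi_name == zn],
        density = rm$volumetric_density[rm$roi_name == zn],
        true_density = sp$zone_densities[z])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Paired Wilcoxon tests per ROI and metric across conditions.
paired_roi_tests <- function(roi) {
  out <- list()
  metrics <- c("area_mm2", "volume_mm3", "n_particles", "pct_area_particles",
               "volumetric_density")
  for (nm in c("entire", "zone1", "zone2", "zone3")) {
    sub <- roi[roi$roi_name == nm, ]
    peri <- sub[sub$site_condition == "peri-implantitis", ]
    ref <- sub[sub$site_condition == "reference", ]
    common <- intersect(peri$patient_id, ref$patient_id)
    peri <- peri[match(common, peri$patient_id), ]
    ref <- ref[match(common, ref$patient_id), ]
    for (m in metrics) {
      p <- tryCatch(wilcoxon_signed_rank(peri[[m]], ref[[m]])$p_value,
                    error = function(e) NA_real_)
      out[[paste(nm, m, sep = ".")]] <- p
    }
  }
  out
}

#' Percentage formatting of cohort-table entries
#'
#' Whole percentages print without decimals (`"0%"`, `"100%"`); otherwise the
#' value is rounded to one decimal and displayed with two, e.g. 7 of 18 gives
#' `"38.90%"`.
#'
#' @param count,total non-negative integers, `total > 0`.
#' @return character scalar.
#' @export
format_percent <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  pct <- 100 * count / total
  if (isTRUE(all.equal(pct, round(pct)))) paste0(round(pct), "%")
  else sprintf("%.2f%%", round(pct, 1))
}

# mean/sd/median/IQR summary used by the study-style tables; quartiles by
# linear interpolation.
summary_row <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(mean = mean(x), sd = stats::sd(x), median = q[2],
             q25 = q[1], q75 = q[3])
}

#' Emit study-style summary tables
#'
#' Writes a cohort table (counts with formatted percentages, means and sds),
#' a per-ROI paired-comparison table, an inflamed/non-inflamed table, a
#' per-particle morphometry table and heatmap matrices.
#'
#' @param summary output of [run_pipeline()].
#' @param out_dir directory to write into.
#' @return `out_dir`, invisibly.
#' @export
build_study_tables <- function(summary, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- summary$samples
  roi <- summary$roi
  # paired design is required for the comparison tables
  tab <- table(samples$patient_id)
  if (any(tab != 2))
    stop("unpaired sample(s) in a paired table: ",
         paste(names(tab)[tab != 2], collapse = ", "))

  # cohort table
  rows <- list()
  for (cond in c("peri-implantitis", "reference")) {
    s <- samples[samples$site_condition == cond, ]
    n <- nrow(s)
    for (v in c("implant_system", "jaw", "location", "reconstruction_type")) {
      for (lv in sort(unique(samples[[v]]))) {
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, variable = v, level = lv,
          n = sum(s[[v]] == lv),
          value = format_percent(sum(s[[v]] == lv), n))
      }
    }
    for (v in c("years_in_function", "implant_length_mm", "implant_diameter_mm",
                "probing_pocket_depth_mm", "bone_level_mm")) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, variable = v, level = "mean (sd)", n = n,
        value = sprintf("%.1f (%.2f)", mean(s[[v]]), stats::sd(s[[v]])))
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "cohort_table.csv"),
                   row.names = FALSE)

  # per-ROI table in the paired-comparison arrangement
  rows <- list()
  for (nm in c("entire", "zone1", "zone2", "zone3")) {
    for (m in c("area_mm2", "volume_mm3", "n_particles", "pct_area_particles",
                "volumetric_density")) {
      peri <- roi[roi$roi_name == nm & roi$site_condition == "peri-implantitis", m]
      ref <- roi[roi$roi_name == nm & roi$site_condition == "reference", m]
      sp <- summary_row(peri); sr <- summary_row(ref)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = nm, metric = m,
        peri_mean = sp$mean, peri_sd = sp$sd, peri_median = sp$median,
        peri_iqr = sprintf("%.3g-%.3g", sp$q25, sp$q75),
        ref_mean = sr$mean, ref_sd = sr$sd, ref_median = sr$median,
        ref_iqr = sprintf("%.3g-%.3g", sr$q25, sr$q75),
        p = summary$tests[[paste(nm, m, sep = ".")]] %||% NA_real_)
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "roi_table.csv"),
                   row.names = FALSE)

  # inflamed vs non-inflamed within condition
  rows <- list()
  for (cond in c("peri-implantitis", "reference")) {
    for (m in c("area_mm2", "volume_mm3", "n_particles", "pct_area_particles",
                "volumetric_density")) {
      a <- roi[roi$roi_name == "inflamed" & roi$site_condition == cond, m]
      b <- roi[roi$roi_name == "non_inflamed" & roi$site_condition == cond, m]
      p <- tryCatch(wilcoxon_signed_rank(a, b)$p_value,
                    error = function(e) NA_real_)
      sa <- summary_row(a); sb <- summary_row(b)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, metric = m,
        inflamed_mean = sa$mean, inflamed_sd = sa$sd,
        non_inflamed_mean = sb$mean, non_inflamed_sd = sb$sd, p = p)
    }
  }
  utils::write.csv(do.call(rbind, rows),
                   file.path(out_dir, "inflammation_table.csv"),
                   row.names = FALSE)

  # particle morphometry table
  if (!is.null(summary$particles) && nrow(summary$particles)) {
    rows <- list()
    for (cond in c("peri-implantitis", "reference")) {
      p <- summary$particles[summary$particles$site_condition == cond &
                               summary$particles$in_outline, ]
      if (!nrow(p)) next
      for (m in c("area_um2", "equivalent_diameter_um", "circularity",
                  "feret_mean_um", "feret_max_um", "feret_min_um")) {
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, metric = m, n = nrow(p),
          mean = mean(p[[m]]), sd = stats::sd(p[[m]]))
      }
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(out_dir, "particle_summary_table.csv"),
                     row.names = FALSE)
    for (cond in c("peri", "ref")) {
      long <- if (cond == "peri") "peri-implantitis" else "reference"
      p <- summary$particles[summary$particles$site_condition == long &
                               summary$particles$in_outline, ]
      if (!nrow(p)) next
      hm <- heatmap_bins(p, bin_mm = 0.5)
      utils::write.table(hm, file.path(out_dir, sprintf("heatmap_%s.tsv", cond)),
                         sep = "\t", quote = FALSE)
    }
  }
  invisible(out_dir)
}
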