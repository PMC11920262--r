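# Shared phantom fixtures, built in code at test time.

# Standard small noisy phantom with confusers: low enough particle density
# that footprints essentially never overlap after beam blur, so detected
# region counts are comparable to truth counts.
std_noisy_spec <- function(seed) {
  phantom_spec(specimen_width_mm = 2.4, specimen_depth_mm = 2,
               thickness_um = 25, pixel_size_um = 2,
               zone_densities = c(70, 30, 10), false_source_rate = 2,
               seed = seed)
}

# Recovery/gradient phantom: configured decreasing densities, enough
# particles per zone for stable per-replicate estimates.
recovery_spec <- function(seed = 1) {
  phantom_spec(specimen_width_mm = 3, specimen_depth_mm = 2,
               thickness_um = 30, pixel_size_um = 2.5,
               zone_densities = c(500, 200, 50), false_source_rate = 1,
               seed = seed)
}

# Ground truth holding n ideal disks at given centres/diameters (um).
disk_truth <- function(cx, cy, dia) {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  foot <- lapply(seq_along(cx), function(i)
    cbind(cx[i] + dia[i] / 2 * cos(th), cy[i] + dia[i] / 2 * sin(th)))
  structure(list(
    particles = data.frame(id = seq_along(cx), x_um = cx, y_um = cy,
                           diameter_um = dia, area_um2 = pi * (dia / 2)^2,
                           circularity = 1, zone = 1L),
    footprints = foot,
    confusers = data.frame(id = integer(0), x_um = numeric(0),
                           y_um = numeric(0), peak = numeric(0))),
    class = "ground_truth")
}

# Full two-pass detection chain on one phantom.
run_detection_chain <- function(spec, geom = phantom_geometry(spec)) {
  truth <- sample_particle_field(spec, geom)
  survey <- render_maps(truth, spec, geom, 200)
  high <- render_maps(truth, spec, geom, 20000, elements = "ti")
  cands <- detect_candidates(survey$ti, sensitivity = 0.995)
  conf <- confirm_candidates(cands, high$ti)
  thr <- suppressWarnings(calibrate_threshold(conf, cands))
  seg <- segment_particles(survey$ti, thr)
  list(truth = truth, geom = geom, survey = survey, high = high,
       cands = cands, conf = conf, thr = thr, seg = seg)
}

# Rasterized ellipse mask (semi-axes in pixels, rotation in radians).
ellipse_mask <- function(n, a, b, theta) {
  cc <- (n + 1) / 2
  xy <- expand.grid(x = 1:n, y = 1:n)
  xr <- (xy$x - cc) * cos(theta) + (xy$y - cc) * sin(theta)
  yr <- -(xy$x - cc) * sin(theta) + (xy$y - cc) * cos(theta)
  matrix((xr / a)^2 + (yr / b)^2 <= 1, n, n)
}
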