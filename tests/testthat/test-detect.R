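test_that("a blank map yields no candidates and no regions", {
  blank <- elemental_map(matrix(0, 120, 120), "Ti", 2, 200)
  expect_equal(nrow(detect_candidates(blank)), 0)
  seg <- segment_particles(blank, 0)
  expect_length(seg$regions, 0)
})

test_that("noise-free disks are found exactly, centres within one pixel", {
  spec <- phantom_spec(specimen_width_mm = 2, specimen_depth_mm = 2,
                       pixel_size_um = 2, zone_densities = c(0, 0, 0),
                       background_rate = 0, false_source_rate = 0, seed = 5)
  geom <- phantom_geometry(spec)
  cx <- rep(seq(200, 1800, length.out = 5), 4)
  cy <- rep(seq(200, 1800, length.out = 4), each = 5)
  dia <- seq(3, 40, length.out = 20)
  ch <- disk_truth(cx, cy, dia)
  maps <- render_maps(ch, spec, geom, 200, noise = FALSE, elements = "ti")
  cands <- detect_candidates(maps$ti, sensitivity = 0.995)
  expect_equal(nrow(cands), 20)
  derr <- vapply(1:20, function(i)
    min(sqrt((cands$x_um - cx[i])^2 + (cands$y_um - cy[i])^2)), 0)
  expect_true(all(derr <= spec$pixel_size_um))
  # candidates are sorted by descending peak intensity
  expect_true(all(diff(cands$peak_intensity) <= 0))
  # end-to-end on the noise-free map: count exact, centroids within a pixel
  seg <- segment_particles(maps$ti, 0.5)
  expect_equal(length(seg$regions), 20)
  m <- measure_particles(seg)
  cerr <- vapply(1:20, function(i)
    min(sqrt((m$centroid_x_um - cx[i])^2 + (m$centroid_y_um - cy[i])^2)), 0)
  expect_true(all(cerr <= spec$pixel_size_um))
})

test_that("survey-pass detection recalls every true particle >= 1.5 um", {
  for (sd in 1:5) {
    ch <- run_detection_chain(std_noisy_spec(sd))
    p <- ch$truth$particles[ch$truth$particles$diameter_um >= 1.5, ]
    if (!nrow(p)) next
    hit <- vapply(seq_len(nrow(p)), function(i)
      min(sqrt((ch$cands$x_um - p$x_um[i])^2 +
                 (ch$cands$y_um - p$y_um[i])^2)) <= p$diameter_um[i] / 2 + 5,
      TRUE)
    expect_true(all(hit), label = sprintf("recall at seed %d", sd))
  }
})

test_that("confirmation separates particles from fluence-non-scaling confusers", {
  # noise-free: any candidate with true signal is confirmed
  spec <- phantom_spec(specimen_width_mm = 1, specimen_depth_mm = 1,
                       pixel_size_um = 2, zone_densities = c(0, 0, 0),
                       background_rate = 0, false_source_rate = 0, seed = 2)
  geom <- phantom_geometry(spec)
  ch <- disk_truth(c(300, 700), c(400, 600), c(10, 20))
  sv <- render_maps(ch, spec, geom, 200, noise = FALSE, elements = "ti")
  hs <- render_maps(ch, spec, geom, 20000, noise = FALSE, elements = "ti")
  cands <- detect_candidates(sv$ti)
  conf <- confirm_candidates(cands, hs$ti)
  expect_true(all(conf$confirmed))

  # empty candidate list -> empty result
  expect_equal(nrow(confirm_candidates(cands[0, ], hs$ti)), 0)

  # noisy phantoms: confusers overwhelmingly rejected
  rejected <- 0; total <- 0
  for (sd in 1:5) {
    ch <- run_detection_chain(std_noisy_spec(sd))
    cf <- ch$truth$confusers
    if (!nrow(cf)) next
    for (i in seq_len(nrow(cf))) {
      j <- which.min((ch$cands$x_um - cf$x_um[i])^2 +
                       (ch$cands$y_um - cf$y_um[i])^2)
      dist <- sqrt((ch$cands$x_um[j] - cf$x_um[i])^2 +
                     (ch$cands$y_um[j] - cf$y_um[i])^2)
      if (dist < 10) {
        total <- total + 1
        if (!ch$conf$confirmed[ch$conf$candidate_id == ch$cands$candidate_id[j]])
          rejected <- rejected + 1
      }
    }
  }
  expect_gt(total, 10)
  expect_gte(rejected / total, 0.95)
})

test_that("candidates outside the confirmation map are reported by id", {
  big <- elemental_map(matrix(5, 200, 200), "Ti", 2, 200)
  small <- elemental_map(matrix(5, 50, 50), "Ti", 2, 20000)
  cands <- data.frame(candidate_id = 1:2, peak_intensity = c(9, 9))
  cands$support <- list(1:10, 39000:39010)
  expect_error(confirm_candidates(cands, small), "2")
})

test_that("threshold calibration follows the false-detection maximum", {
  cands <- data.frame(candidate_id = 1:4, peak_intensity = c(3, 5, 9, 12))
  cands$support <- list(1L, 2L, 3L, 4L)
  res <- data.frame(candidate_id = 1:4,
                    confirmed = c(FALSE, FALSE, TRUE, TRUE),
                    high_stat_intensity = c(3, 5, 900, 1200))
  thr <- calibrate_threshold(res, cands)
  expect_equal(thr$value, 6)
  expect_setequal(thr$provenance, c(3, 5))
  # both confirmed peaks survive the threshold
  expect_true(all(c(9, 12) > thr$value))

  # no false candidates -> threshold 0
  res2 <- res; res2$confirmed <- TRUE
  expect_equal(calibrate_threshold(res2, cands)$value, 0)

  # all false -> max + 1, nothing survives
  res3 <- res; res3$confirmed <- FALSE
  expect_equal(calibrate_threshold(res3, cands)$value, 13)

  # a confirmed particle below the threshold triggers the conflict warning
  res4 <- data.frame(candidate_id = 1:4,
                     confirmed = c(FALSE, TRUE, FALSE, TRUE),
                     high_stat_intensity = c(3, 500, 9, 1200))
  expect_warning(calibrate_threshold(res4, cands), "below the calibrated")

  expect_error(calibrate_threshold(res[0, ], cands[0, ]), "no candidates")
})

test_that("segmentation uses strict thresholding and 8-connectivity", {
  m <- matrix(0, 10, 10)
  m[3, 3] <- 5; m[4, 4] <- 5   # touching diagonally
  m[8, 8] <- 5                 # separated by > 1 background pixel
  map <- elemental_map(m, "Ti", 2, 200)
  seg <- segment_particles(map, 1, min_diameter_um = 0)
  expect_length(seg$regions, 2)
  # ties at the threshold are background
  seg2 <- segment_particles(map, 5, min_diameter_um = 0)
  expect_length(seg2$regions, 0)
  # everything at or below the threshold -> zero regions
  expect_length(segment_particles(map, 10)$regions, 0)
  # minimum equivalent diameter filter: a single 2 um pixel (eq diam 2.26)
  # is dropped at 3 um, the two-pixel region (eq diam 3.19) survives
  seg3 <- segment_particles(map, 1, min_diameter_um = 3)
  expect_length(seg3$regions, 1)
  expect_length(segment_particles(map, 1, min_diameter_um = 4)$regions, 0)
})

test_that("raising the threshold never increases the particle count", {
  ch <- run_detection_chain(std_noisy_spec(4))
  counts <- vapply(c(0, 2, 5, 8, 12, 20, 50),
                   function(t) length(segment_particles(ch$survey$ti, t)$regions),
                   0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("the background-free map never gains intensity", {
  ch <- run_detection_chain(std_noisy_spec(6))
  bf <- background_free_map(ch$survey$ti, ch$seg)
  expect_lte(sum(bf$counts), sum(ch$survey$ti$counts))
  expect_true(all(bf$counts[ch$seg$labels == 0L] == 0))
})
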