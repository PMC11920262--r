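test_that("zero densities give an empty ground truth", {
  spec <- phantom_spec(specimen_width_mm = 1, specimen_depth_mm = 1,
                       zone_densities = c(0, 0, 0), false_source_rate = 0,
                       seed = 1)
  ch <- sample_particle_field(spec)
  expect_equal(nrow(ch$particles), 0)
  expect_equal(nrow(ch$confusers), 0)
})

test_that("per-zone particle counts are Poisson with the configured mean", {
  # density 200/mm^3 over a 1 mm^2 zone-1 slab of 100 um thickness:
  # zone volume 0.1 mm^3, expected count 20
  counts <- vapply(1:500, function(sd) {
    spec <- phantom_spec(specimen_width_mm = 1, specimen_depth_mm = 1,
                         thickness_um = 100, zone_densities = c(200, 0, 0),
                         false_source_rate = 0, seed = sd)
    nrow(sample_particle_field(spec)$particles)
  }, 0)
  se <- sqrt(20 / 500)
  expect_lt(abs(mean(counts) - 20), 3 * se)
  # and dispersion compatible with Poisson
  expect_gt(var(counts), 20 * 0.7)
  expect_lt(var(counts), 20 * 1.4)
})

test_that("all density in the first band keeps every particle within 1 mm", {
  spec <- phantom_spec(specimen_width_mm = 3, specimen_depth_mm = 1.5,
                       zone_densities = c(300, 0, 0), false_source_rate = 0,
                       seed = 3)
  geom <- phantom_geometry(spec)
  ch <- sample_particle_field(spec, geom)
  d <- min_distance_to_polyline(ch$particles$x_um, ch$particles$y_um,
                                geom$interface_line) / 1000
  expect_true(all(d < 1))
  expect_true(all(ch$particles$zone == 1L))
})

test_that("a zero-area band with positive density warns and yields nothing", {
  # 1.5 mm wide specimen has no band-3 territory
  spec <- phantom_spec(specimen_width_mm = 1.5, specimen_depth_mm = 1,
                       zone_densities = c(0, 0, 500), false_source_rate = 0,
                       seed = 2)
  expect_warning(ch <- sample_particle_field(spec), "zero area")
  expect_equal(nrow(ch$particles), 0)
})

test_that("generator size distribution matches its analytic small fraction", {
  spec <- phantom_spec(specimen_width_mm = 2, specimen_depth_mm = 2,
                       thickness_um = 50, zone_densities = c(6000, 6000, 0),
                       false_source_rate = 0, seed = 11)
  ch <- sample_particle_field(spec)
  expect_gt(nrow(ch$particles), 1000)
  frac <- mean(ch$particles$diameter_um <= 15)
  expect_lt(abs(frac - small_fraction_analytic(spec)), 0.05)
  # moment-matched defaults put the analytic small fraction near 60%
  expect_gt(small_fraction_analytic(spec), 0.54)
  expect_lt(small_fraction_analytic(spec), 0.64)
})

test_that("true footprint circularity matches the calibrated shape model", {
  spec <- phantom_spec(specimen_width_mm = 2, specimen_depth_mm = 2,
                       thickness_um = 50, zone_densities = c(3000, 3000, 0),
                       false_source_rate = 0, seed = 12)
  ch <- sample_particle_field(spec)
  expect_gt(nrow(ch$particles), 400)
  expect_lt(abs(mean(ch$particles$circularity) - 0.72), 0.05)
  expect_lt(abs(sd(ch$particles$circularity) - 0.16), 0.05)
})

test_that("rendering is deterministic and linear in fluence", {
  spec <- std_noisy_spec(5)
  geom <- phantom_geometry(spec)
  ch <- sample_particle_field(spec, geom)
  ch2 <- sample_particle_field(spec, geom)
  expect_identical(ch, ch2)
  m1 <- render_maps(ch, spec, geom, 200)
  m2 <- render_maps(ch, spec, geom, 200)
  expect_identical(m1$ti$counts, m2$ti$counts)
  expect_identical(m1$s$counts, m2$s$counts)

  # expectation maps scale exactly with fluence over particle interiors
  e1 <- render_maps(ch, spec, geom, 200, noise = FALSE, elements = "ti")
  e2 <- render_maps(ch, spec, geom, 20000, noise = FALSE, elements = "ti")
  interior <- e1$ti$counts > 0.5 * max(e1$ti$counts)
  expect_equal(e2$ti$counts[interior] / e1$ti$counts[interior],
               rep(100, sum(interior)), tolerance = 1e-9)
})

test_that("zero particles and zero background render an identically zero map", {
  spec <- phantom_spec(specimen_width_mm = 1, specimen_depth_mm = 1,
                       zone_densities = c(0, 0, 0), background_rate = 0,
                       false_source_rate = 0, seed = 1)
  maps <- render_maps(sample_particle_field(spec), spec,
                      phantom_geometry(spec), 200, elements = "ti")
  expect_true(all(maps$ti$counts == 0))
})

test_that("beam blur conserves the integrated particle signal", {
  spec <- phantom_spec(specimen_width_mm = 1, specimen_depth_mm = 1,
                       zone_densities = c(0, 0, 0), background_rate = 0,
                       false_source_rate = 0, seed = 1)
  geom <- phantom_geometry(spec)
  ch <- disk_truth(500, 500, 20)
  m <- render_maps(ch, spec, geom, 200, noise = FALSE, elements = "ti")
  expected <- polygon_area(ch$footprints[[1]]) * spec$particle_intensity
  expect_lt(abs(sum(m$ti$counts) - expected) / expected, 0.005)
})

test_that("confuser expectation does not scale with fluence", {
  spec <- phantom_spec(specimen_width_mm = 1, specimen_depth_mm = 1,
                       zone_densities = c(0, 0, 0), background_rate = 0,
                       false_source_rate = 30, seed = 9)
  geom <- phantom_geometry(spec)
  ch <- sample_particle_field(spec, geom)
  expect_gt(nrow(ch$confusers), 0)
  e1 <- render_maps(ch, spec, geom, 200, noise = FALSE, elements = "ti")
  e2 <- render_maps(ch, spec, geom, 20000, noise = FALSE, elements = "ti")
  expect_equal(e1$ti$counts, e2$ti$counts, tolerance = 1e-9)
})

test_that("mosaic tiles stitch back to the full frame exactly", {
  spec <- std_noisy_spec(8)
  geom <- phantom_geometry(spec)
  ch <- sample_particle_field(spec, geom)
  full <- render_maps(ch, spec, geom, 200)
  tiles <- render_mosaic(ch, spec, geom, 200)
  # 2.6 x 2.2 mm frame (specimen + margins) at 1 mm tiles: 3 x 3 grid with
  # partial edge tiles whose union covers the frame
  expect_equal(length(tiles), 9)
  st <- stitch_mosaic(tiles)
  expect_false(anyNA(st$ti))
  expect_identical(st$ti, full$ti$counts)
  expect_identical(st$s, full$s$counts)

  # tile equal to the full frame: single tile identical to render_maps
  spec1 <- spec; spec1$tile_size_um <- 2600
  t1 <- render_mosaic(ch, spec1, geom, 200)
  expect_equal(length(t1), 1)
  expect_identical(t1[[1]]$ti$counts, full$ti$counts)
})

test_that("a pixel grid smaller than the specimen is rejected", {
  spec <- phantom_spec(specimen_width_mm = 1, specimen_depth_mm = 1,
                       zone_densities = c(100, 0, 0), seed = 1)
  geom <- phantom_geometry(spec)
  ch <- sample_particle_field(spec, geom)
  expect_error(render_maps(ch, spec, geom, 200, dim = c(100, 100)),
               "smaller than specimen")
})
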