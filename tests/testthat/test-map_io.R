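test_that("elemental map TIFF round trip is the identity for integer counts", {
  m <- elemental_map(matrix(c(0, 1, 2, 3), 2, 2), "Ti", 5, 200)
  f <- withr::local_tempfile(fileext = ".tif")
  write_elemental_map(m, f)
  m2 <- read_elemental_map(f)
  expect_identical(m2$counts, m$counts)
  expect_equal(m2$pixel_size_um, 5)
  expect_equal(m2$element, "Ti")

  # large random 16-bit range
  set.seed(1)
  big <- elemental_map(matrix(sample(0:65535, 400, TRUE), 20, 20), "Ti", 2, 200)
  write_elemental_map(big, f)
  expect_identical(read_elemental_map(f)$counts, big$counts)

  # counts beyond 16 bits take the 32-bit fallback, still exact
  huge <- elemental_map(matrix(c(0, 70000, 123456, 3), 2, 2), "Ti", 2, 20000)
  write_elemental_map(huge, f)
  expect_identical(read_elemental_map(f)$counts, huge$counts)
})

test_that("phantom-rendered map conserves count totals through I/O", {
  spec <- phantom_spec(specimen_width_mm = 1, specimen_depth_mm = 0.8,
                       zone_densities = c(150, 0, 0), seed = 4)
  ch <- sample_particle_field(spec)
  maps <- render_maps(ch, spec, phantom_geometry(spec), 200)
  f <- withr::local_tempfile(fileext = ".tif")
  write_elemental_map(maps$ti, f)
  expect_identical(sum(read_elemental_map(f)$counts), sum(maps$ti$counts))
})

test_that("invalid maps and metadata are rejected", {
  expect_error(elemental_map(matrix(c(-1, 0, 1, 2), 2, 2), "Ti", 2, 200),
               "non-negative")
  expect_error(elemental_map(matrix(1, 2, 2), "Ti", 0, 200), "pixel_size")
  expect_error(elemental_map(matrix(1, 2, 2), "Ti", 2, -5), "fluence")
  f <- withr::local_tempfile(fileext = ".tif")
  write_elemental_map(elemental_map(matrix(1, 2, 2), "Ti", 2, 200), f)
  expect_error(read_elemental_map(f, metadata_path = "/nonexistent.json"),
               "sidecar")
})

test_that("geometry GeoJSON round trip preserves vertices and roles", {
  geom <- specimen_geometry(
    outline = rbind(c(0, 0), c(2000, 0), c(2100, 1500), c(-50, 1400)),
    interface_line = rbind(c(0, 0), c(-50, 1400)),
    margin_line = rbind(c(0, 0), c(2000, 0)),
    inflammation_zones = list(rbind(c(100, 100), c(900, 120), c(500, 900))),
    thickness_um = 25)
  f <- withr::local_tempfile(fileext = ".geojson")
  write_geometry(geom, f)
  g2 <- read_geometry(f)
  expect_equal(g2$outline, geom$outline, tolerance = 1e-9)
  expect_equal(g2$interface_line, geom$interface_line, tolerance = 1e-9)
  expect_equal(g2$margin_line, geom$margin_line, tolerance = 1e-9)
  expect_length(g2$inflammation_zones, 1)
  expect_equal(g2$inflammation_zones[[1]], geom$inflammation_zones[[1]],
               tolerance = 1e-9)
  expect_equal(g2$thickness_um, 25)
})

test_that("degenerate geometry is rejected", {
  # bow-tie self-intersection
  expect_error(specimen_geometry(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)),
                                 rbind(c(0, 0), c(0, 1)),
                                 rbind(c(0, 0), c(1, 0)), thickness_um = 25),
               "self-intersecting")
  # implausible thickness
  expect_error(specimen_geometry(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)),
                                 rbind(c(0, 0), c(0, 100)),
                                 rbind(c(0, 0), c(100, 0)), thickness_um = 2),
               "plausible band")
  # a unit square with a left-edge interface is fine
  expect_s3_class(specimen_geometry(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)),
                                    rbind(c(0, 0), c(0, 1000)),
                                    rbind(c(0, 0), c(1000, 0)), thickness_um = 25),
                  "specimen_geometry")
})

test_that("particle table round trip reproduces all fields", {
  # empty table: header only
  f <- withr::local_tempfile(fileext = ".tsv")
  write_particle_table(data.frame(), f)
  expect_length(readLines(f), 1)
  expect_equal(nrow(read_particle_table(f)), 0)

  set.seed(7)
  n <- 50
  tab <- data.frame(particle_id = 1:n,
                    centroid_x_um = runif(n, 0, 4000),
                    centroid_y_um = runif(n, 0, 3000),
                    area_um2 = rlnorm(n, 5, 1),
                    equivalent_diameter_um = rlnorm(n, 2.5, 0.6),
                    perimeter_um = rlnorm(n, 4, 0.5),
                    circularity = runif(n), feret_min_um = runif(n, 2, 30),
                    feret_mean_um = runif(n, 10, 40),
                    feret_max_um = runif(n, 20, 60),
                    horizontal_distance_mm = runif(n, 0, 4),
                    vertical_distance_mm = runif(n, 0, 3),
                    zone = sample(1:3, n, TRUE),
                    inflamed = sample(c(TRUE, FALSE), n, TRUE),
                    size_class = sample(c("small", "large"), n, TRUE))
  write_particle_table(tab, f)
  back <- read_particle_table(f)
  expect_equal(nrow(back), n)
  for (cl in particle_table_columns()) {
    if (is.numeric(tab[[cl]]))
      expect_equal(back[[cl]], tab[[cl]], tolerance = 1e-9)
    else expect_equal(as.character(back[[cl]]), as.character(tab[[cl]]))
  }

  # one particle -> exactly 2 lines
  write_particle_table(tab[1, ], f)
  expect_length(readLines(f), 2)

  # missing field named in the error
  expect_error(write_particle_table(tab[, -4], f), "area_um2")
  bad <- tab; bad$circularity[3] <- NA
  expect_error(write_particle_table(bad, f), "circularity")
})

test_that("sample table enforces the paired design", {
  f <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(patient_id = c("P1", "P1", "P2"),
                  site_condition = c("peri-implantitis", "reference",
                                     "peri-implantitis"))
  write.csv(d, f, row.names = FALSE)
  expect_equal(nrow(read_sample_table(f)), 3)
  d2 <- rbind(d, d[1, ])
  write.csv(d2, f, row.names = FALSE)
  expect_error(read_sample_table(f), "more than one sample")
})
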