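test_that("outline extracted from the sulfur map overlaps the true outline", {
  spec <- std_noisy_spec(3)
  geom <- phantom_geometry(spec)
  ch <- sample_particle_field(spec, geom)
  maps <- render_maps(ch, spec, geom, 200)
  out <- extract_outline(maps$s)
  jac <- polygon_jaccard(out, geom$outline, spec$pixel_size_um,
                         nrow(maps$s$counts), ncol(maps$s$counts))
  expect_gte(jac, 0.95)
  # extracted area within 5% of truth
  expect_lt(abs(polygon_area(out) - polygon_area(geom$outline)) /
              polygon_area(geom$outline), 0.05)
})

test_that("an empty sulfur map cannot produce an outline", {
  zero <- elemental_map(matrix(0, 50, 50), "S", 2, 200)
  expect_error(extract_outline(zero), "no foreground")
})

test_that("closing removes hole artefacts smaller than its radius", {
  m <- matrix(0, 60, 60)
  m[10:50, 10:50] <- 40
  m[30:31, 30:31] <- 0   # small interior hole
  s <- elemental_map(m, "S", 2, 200)
  out <- extract_outline(s, smoothing_um = 0.1, closing_radius_um = 6)
  # polygon area matches the filled square, i.e. hole is gone
  expect_lt(abs(polygon_area(out) - 41 * 41 * 4) / (41 * 41 * 4), 0.1)
})

test_that("point-to-polyline distance has exact closed-form cases", {
  seg <- rbind(c(0, 0), c(10000, 0))
  expect_equal(min_distance_to_polyline(0, 5000, seg), 5000)
  expect_equal(min_distance_to_polyline(4000, 0, seg), 0)
  expect_equal(min_distance_to_polyline(12000, 3000, seg),
               sqrt(2000^2 + 3000^2))
  # degenerate single-vertex polyline behaves as a point
  expect_equal(min_distance_to_polyline(3, 4, rbind(c(0, 0))), 5)
})

test_that("distance agrees with the dense-sampling oracle on random cases", {
  set.seed(17)
  worst <- 0
  for (k in 1:100) {
    nv <- sample(2:6, 1)
    pl <- cbind(runif(nv, 0, 3000), runif(nv, 0, 3000))
    px <- runif(1, -500, 3500); py <- runif(1, -500, 3500)
    d1 <- min_distance_to_polyline(px, py, pl)
    d2 <- oracle_polyline_distance(px, py, pl)
    worst <- max(worst, abs(d1 - d2))
  }
  expect_lte(worst, 0.5)
})

test_that("distances are invariant under rigid motions", {
  set.seed(18)
  pl <- cbind(runif(5, 0, 2000), runif(5, 0, 2000))
  pts <- cbind(runif(40, -200, 2200), runif(40, -200, 2200))
  d0 <- min_distance_to_polyline(pts[, 1], pts[, 2], pl)
  for (th in c(0.3, 1.2, 2.8)) {
    shift <- c(123.4, -456.7)
    plr <- tipix:::rigid_transform(pl, th, shift)
    ptr <- tipix:::rigid_transform(pts, th, shift)
    expect_equal(min_distance_to_polyline(ptr[, 1], ptr[, 2], plr), d0,
                 tolerance = 1e-6)
  }
})

test_that("a 3 x 1 mm rectangle splits into three equal 1 mm zones", {
  outline <- rbind(c(0, 0), c(3000, 0), c(3000, 1000), c(0, 1000))
  iface <- rbind(c(0, 0), c(0, 1000))
  rois <- build_zones(outline, iface, pixel_size_um = 10, dim = c(100, 300))
  px_row_mm2 <- 100 * (10 / 1000)^2  # one pixel column of the band boundary
  for (z in c("zone1", "zone2", "zone3"))
    expect_lt(abs(rois$areas_mm2[[z]] - 1), px_row_mm2 + 1e-9)
  # exact partition, pixelwise
  expect_equal(rois$zone1 | rois$zone2 | rois$zone3, rois$entire)
  expect_false(any(rois$zone1 & rois$zone2))
  expect_false(any(rois$zone2 & rois$zone3))
  expect_false(any(rois$zone1 & rois$zone3))
  expect_equal(rois$areas_mm2[["zone1"]] + rois$areas_mm2[["zone2"]] +
                 rois$areas_mm2[["zone3"]], rois$areas_mm2[["entire"]])
})

test_that("a specimen within 2 mm of the interface has an empty zone 3", {
  outline <- rbind(c(0, 0), c(1800, 0), c(1800, 1000), c(0, 1000))
  iface <- rbind(c(0, 0), c(0, 1000))
  rois <- build_zones(outline, iface, pixel_size_um = 10, dim = c(100, 180))
  expect_equal(rois$areas_mm2[["zone3"]], 0)
})

test_that("inflamed and non-inflamed masks partition the specimen", {
  outline <- rbind(c(0, 0), c(2000, 0), c(2000, 1000), c(0, 1000))
  iface <- rbind(c(0, 0), c(0, 1000))
  infl <- list(rbind(c(0, 0), c(900, 0), c(900, 1000), c(0, 1000)))
  rois <- build_zones(outline, iface, 10, c(100, 200),
                      inflammation_zones = infl)
  expect_equal(rois$inflamed | rois$non_inflamed, rois$entire)
  expect_false(any(rois$inflamed & rois$non_inflamed))
  expect_lt(abs(rois$areas_mm2[["inflamed"]] - 0.9), 0.02)
})

test_that("particle positions follow the half-open band convention", {
  geom <- specimen_geometry(
    outline = rbind(c(0, 0), c(3000, 0), c(3000, 1000), c(0, 1000)),
    interface_line = rbind(c(0, 0), c(0, 1000)),
    margin_line = rbind(c(0, 0), c(3000, 0)),
    thickness_um = 25)
  p <- data.frame(centroid_x_um = c(500, 1000, 1500, 2500),
                  centroid_y_um = rep(300, 4))
  pos <- assign_positions(p, geom)
  expect_equal(pos$zone, c(1L, 2L, 2L, 3L))  # exactly 1.000 mm -> zone 2
  expect_equal(pos$horizontal_distance_mm, c(0.5, 1, 1.5, 2.5))
  expect_equal(pos$vertical_distance_mm, rep(0.3, 4))
  expect_true(all(pos$in_outline))
  # outside-centroid particles are flagged
  p2 <- rbind(p, data.frame(centroid_x_um = 5000, centroid_y_um = 300))
  expect_message(pos2 <- assign_positions(p2, geom), "outside the outline")
  expect_false(pos2$in_outline[5])
})

test_that("zone particle counts pool exactly to the specimen count", {
  for (sd in c(2, 7)) {
    ch <- run_detection_chain(std_noisy_spec(sd))
    m <- measure_particles(ch$seg)
    pos <- suppressMessages(assign_positions(m, ch$geom))
    inp <- pos[pos$in_outline, ]
    expect_equal(sum(inp$zone == 1) + sum(inp$zone == 2) + sum(inp$zone == 3),
                 nrow(inp))
    hm <- heatmap_bins(inp, bin_mm = 0.5)
    expect_equal(sum(hm), nrow(inp))
    sp <- heatmap_bins(inp, bin_mm = 0.5, split_by_size = TRUE)
    expect_equal(sum(sp$small) + sum(sp$large), nrow(inp))
  }
})

test_that("heatmap binning handles degenerate inputs", {
  none <- data.frame(horizontal_distance_mm = numeric(0),
                     vertical_distance_mm = numeric(0))
  expect_true(all(heatmap_bins(none) == 0))
  one_cell <- data.frame(horizontal_distance_mm = rep(0.2, 7),
                         vertical_distance_mm = rep(0.3, 7))
  hm <- heatmap_bins(one_cell, bin_mm = 0.5)
  expect_equal(sum(hm != 0), 1)
  expect_equal(max(hm), 7)
  expect_error(heatmap_bins(one_cell, bin_mm = 0), "bin_mm > 0")
})

test_that("uniform positions pass a chi-square uniformity check", {
  ok <- 0
  for (sd in 1:20) {
    set.seed(400 + sd)
    pos <- data.frame(horizontal_distance_mm = runif(320, 0, 2),
                      vertical_distance_mm = runif(320, 0, 2))
    hm <- heatmap_bins(pos, bin_mm = 0.5)
    p <- suppressWarnings(chisq.test(as.vector(hm))$p.value)
    if (p > 0.01) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.95)
})
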