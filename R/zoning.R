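# Regions of interest and particle positions relative to the implant/tissue
# interface and the mucosal margin: specimen outline from the sulfur map,
# distance bands ("zones") from the interface, inflamed/non-inflamed masks,
# per-particle distances and heatmap binning.

#' Extract the specimen outline from a sulfur map
#'
#' Sulfur is present throughout soft tissue, so its map delineates the
#' specimen: Otsu threshold, largest 8-connected component, morphological
#' closing (removing small hole artefacts), traced boundary polygon.
#'
#' @param s_map an `elemental_map` of element S.
#' @param smoothing_um Gaussian smoothing applied before thresholding, so the
#'   Otsu split separates tissue from background rather than chasing
#'   per-pixel counting noise.
#' @param closing_radius_um radius of the closing structuring element.
#' @param dp_tol_px simplification tolerance of the traced polygon (pixels).
#' @return outline polygon (n x 2 matrix, um, counter-clockwise).
#' @export
extract_outline <- function(s_map, smoothing_um = 10, closing_radius_um = 10,
                            dp_tol_px = 1) {
  validate_elemental_map(s_map)
  counts <- gaussian_blur(s_map$counts, smoothing_um / s_map$pixel_size_um)
  mx <- max(counts)
  if (mx <= 0) stop("no foreground after threshold: sulfur map is empty")
  img <- EBImage::Image(t(counts / mx))  # EBImage is x-major
  thr <- EBImage::otsu(img, range = c(0, 1))
  mask <- counts / mx > thr
  if (!any(mask)) stop("no foreground after threshold")
  lab <- label_components_8(mask)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  br_px <- max(1L, round(closing_radius_um / s_map$pixel_size_um))
  brush <- EBImage::makeBrush(2L * br_px + 1L, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(t(mask)), brush)
  mask <- t(as.matrix(closed)) > 0.5
  loops <- trace_crack_boundary(mask)
  outer_i <- which.max(vapply(loops, function(l) abs(polygon_signed_area(l)), 0))
  ring <- dp_simplify_ring(drop_collinear(loops[[outer_i]]), dp_tol_px)
  poly <- sweep(ring * s_map$pixel_size_um, 2, s_map$origin_um, "+")
  ensure_ccw(poly)
}

#' Build the zonal region-of-interest set on a raster grid
#'
#' Each in-outline pixel is assigned by its centre's minimum distance `d` to
#' the interface polyline: zone 1 for `d < band_edges_mm[1]`, zone 2 for
#' distances up to `band_edges_mm[2]`, zone 3 beyond (half-open bands).
#' Inflamed/non-inflamed masks come from the inflammation polygons.
#'
#' @param outline specimen outline polygon (um).
#' @param interface_line interface polyline (um).
#' @param pixel_size_um raster pitch.
#' @param dim `c(nrow, ncol)` of the raster.
#' @param origin_um raster offset in the specimen frame.
#' @param band_edges_mm inner band edges, default `c(1, 2)`.
#' @param inflammation_zones list of polygons (um).
#' @return object of class `roi_set`: logical masks `entire`, `zone1`,
#'   `zone2`, `zone3`, `inflamed`, `non_inflamed`; `areas_mm2` (named);
#'   `band_edges_mm`; `pixel_size_um`.
#' @export
build_zones <- function(outline, interface_line, pixel_size_um, dim,
                        origin_um = c(0, 0), band_edges_mm = c(1, 2),
                        inflammation_zones = list()) {
  nr <- dim[1]; nc <- dim[2]
  entire <- rasterize_polygon(outline, nr, nc, pixel_size_um, origin_um)
  idx <- which(entire)
  px_x <- origin_um[1] + (((idx - 1L) %/% nr) + 0.5) * pixel_size_um
  px_y <- origin_um[2] + (((idx - 1L) %% nr) + 0.5) * pixel_size_um
  d_mm <- min_distance_to_polyline(px_x, px_y, interface_line) / 1000
  z <- zone_from_distance(d_mm, band_edges_mm)
  zone1 <- zone2 <- zone3 <- matrix(FALSE, nr, nc)
  zone1[idx[z == 1L]] <- TRUE
  zone2[idx[z == 2L]] <- TRUE
  zone3[idx[z == 3L]] <- TRUE
  inflamed <- matrix(FALSE, nr, nc)
  for (p in inflammation_zones) {
    inflamed <- inflamed |
      (rasterize_polygon(p, nr, nc, pixel_size_um, origin_um) & entire)
  }
  non_inflamed <- entire & !inflamed
  px_mm2 <- (pixel_size_um / 1000)^2
  areas <- c(entire = sum(entire), zone1 = sum(zone1), zone2 = sum(zone2),
             zone3 = sum(zone3), inflamed = sum(inflamed),
             non_inflamed = sum(non_inflamed)) * px_mm2
  structure(list(entire = entire, zone1 = zone1, zone2 = zone2, zone3 = zone3,
                 inflamed = inflamed, non_inflamed = non_inflamed,
                 areas_mm2 = areas, band_edges_mm = band_edges_mm,
                 pixel_size_um = pixel_size_um),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set> areas (mm2):\n")
  print(round(x$areas_mm2, 3))
  invisible(x)
}

#' Per-particle positions relative to the reference lines
#'
#' Adds the horizontal distance to the interface, the vertical distance to
#' the mucosal margin (both in mm, measured from the particle centroid), the
#' zone label under the half-open band convention, the inflammation flag
#' (centroid inside any inflammation polygon) and an `in_outline` flag.
#' Particles outside the outline are flagged, not dropped; ROI counting
#' excludes them.
#'
#' @param particles data.frame with `centroid_x_um`, `centroid_y_um`.
#' @param geometry a `specimen_geometry` (or a list with `outline`,
#'   `interface_line`, `margin_line`, `inflammation_zones`).
#' @param band_edges_mm inner band edges.
#' @param outline optional outline polygon overriding `geometry$outline`
#'   (e.g. one extracted from the sulfur map).
#' @return `particles` with columns `horizontal_distance_mm`,
#'   `vertical_distance_mm`, `zone`, `inflamed`, `in_outline` appended.
#' @export
assign_positions <- function(particles, geometry, band_edges_mm = c(1, 2),
                             outline = NULL) {
  if (is.null(outline)) outline <- geometry$outline
  x <- particles$centroid_x_um; y <- particles$centroid_y_um
  particles$horizontal_distance_mm <-
    min_distance_to_polyline(x, y, geometry$interface_line) / 1000
  particles$vertical_distance_mm <-
    min_distance_to_polyline(x, y, geometry$margin_line) / 1000
  particles$zone <- zone_from_distance(particles$horizontal_distance_mm,
                                       band_edges_mm)
  infl <- rep(FALSE, nrow(particles))
  for (p in geometry$inflammation_zones) {
    infl <- infl | points_in_polygon(x, y, p)
  }
  particles$inflamed <- infl
  particles$in_outline <- points_in_polygon(x, y, outline)
  if (nrow(particles) && any(!particles$in_outline))
    message(sum(!particles$in_outline),
            " particle centroid(s) outside the outline; flagged and excluded from ROI counts")
  particles
}

#' Spatial heatmap of particle positions
#'
#' 2-D histogram over (horizontal, vertical) distance; the total count is
#' conserved. With `split_by_size = TRUE`, one matrix per size class.
#'
#' @param positions data.frame with `horizontal_distance_mm`,
#'   `vertical_distance_mm` and (for the split) `size_class`.
#' @param bin_mm bin edge length (> 0).
#' @param split_by_size stratify into small/large.
#' @return matrix of counts (rows = vertical bins, cols = horizontal bins),
#'   or a list `small`/`large` of such matrices.
#' @export
heatmap_bins <- function(positions, bin_mm = 0.5, split_by_size = FALSE) {
  stopifnot(bin_mm > 0)
  h <- positions$horizontal_distance_mm
  v <- positions$vertical_distance_mm
  n_h <- max(1, ceiling(max(h, 0, na.rm = TRUE) / bin_mm + 1e-12))
  n_v <- max(1, ceiling(max(v, 0, na.rm = TRUE) / bin_mm + 1e-12))
  bin_of <- function(x, n) pmin(n, floor(x / bin_mm) + 1L)
  tab <- function(sel) {
    m <- matrix(0L, n_v, n_h)
    if (any(sel)) {
      t2 <- table(factor(bin_of(v[sel], n_v), levels = 1:n_v),
                  factor(bin_of(h[sel], n_h), levels = 1:n_h))
      m <- matrix(as.integer(t2), n_v, n_h)
    }
    dimnames(m) <- list(vertical_mm = sprintf("[%g,%g)", bin_mm * (0:(n_v - 1)), bin_mm * (1:n_v)),
                        horizontal_mm = sprintf("[%g,%g)", bin_mm * (0:(n_h - 1)), bin_mm * (1:n_h)))
    m
  }
  if (!split_by_size) return(tab(rep(TRUE, length(h))))
  list(small = tab(positions$size_class == "small"),
       large = tab(positions$size_class == "large"))
}
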