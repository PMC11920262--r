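# I/O for elemental maps, specimen geometry, particle tables and sample
# metadata. Maps are single-channel TIFF rasters with a JSON sidecar; geometry
# is GeoJSON with per-feature roles; particle tables are TSV.

#' Construct an elemental count map
#'
#' A single-element raster of X-ray counts from a micro-PIXE scan, together
#' with the acquisition metadata needed to interpret it: pixel pitch, proton
#' fluence and the offset of the raster in the specimen coordinate frame.
#' The frame has x increasing away from the implant/tissue interface and y
#' increasing apically from the mucosal margin; the centre of pixel
#' `[i, j]` (row i, column j) lies at `origin_um + (j - 0.5, i - 0.5) *
#' pixel_size_um`.
#'
#' @param counts numeric matrix of non-negative counts (rows = y, cols = x).
#'   Integer-valued for measured maps; expectation maps (noise switched off in
#'   the generator) may carry fractional values.
#' @param element chemical symbol, e.g. `"Ti"` or `"S"`.
#' @param pixel_size_um pixel pitch in micrometres (square pixels).
#' @param fluence_nc_mm2 proton fluence of the scan in nC/mm^2.
#' @param origin_um numeric length-2, specimen-frame offset of the raster.
#' @return an object of class `elemental_map`.
#' @export
elemental_map <- function(counts, element, pixel_size_um, fluence_nc_mm2,
                          origin_um = c(0, 0)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  x <- structure(
    list(counts = counts, element = as.character(element),
         pixel_size_um = as.numeric(pixel_size_um),
         fluence_nc_mm2 = as.numeric(fluence_nc_mm2),
         origin_um = as.numeric(origin_um)),
    class = "elemental_map")
  validate_elemental_map(x)
  x
}

#' Validate an elemental map
#' @param x an `elemental_map`.
#' @return `x`, invisibly; stops on invariant violation.
#' @export
validate_elemental_map <- function(x) {
  stopifnot(inherits(x, "elemental_map"))
  if (!is.matrix(x$counts) || length(x$counts) == 0)
    stop("counts must be a non-empty rectangular matrix")
  if (anyNA(x$counts) || any(x$counts < 0))
    stop("validation error: counts must be non-negative and finite")
  if (!is.character(x$element) || length(x$element) != 1 || !nzchar(x$element))
    stop("element must be a single chemical symbol string")
  if (length(x$pixel_size_um) != 1 || !is.finite(x$pixel_size_um) || x$pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  if (length(x$fluence_nc_mm2) != 1 || !is.finite(x$fluence_nc_mm2) || x$fluence_nc_mm2 <= 0)
    stop("fluence_nc_mm2 must be a positive scalar")
  if (length(x$origin_um) != 2 || anyNA(x$origin_um))
    stop("origin_um must be a length-2 numeric")
  invisible(x)
}

#' @export
print.elemental_map <- function(x, ...) {
  cat(sprintf("<elemental_map> %s  %d x %d px @ %.3g um/px, fluence %.6g nC/mm2, total counts %.6g\n",
              x$element, nrow(x$counts), ncol(x$counts), x$pixel_size_um,
              x$fluence_nc_mm2, sum(x$counts)))
  invisible(x)
}

# x coordinates (um) of pixel-column centres / y of pixel-row centres.
map_pixel_x <- function(map) map$origin_um[1] + (seq_len(ncol(map$counts)) - 0.5) * map$pixel_size_um
map_pixel_y <- function(map) map$origin_um[2] + (seq_len(nrow(map$counts)) - 0.5) * map$pixel_size_um

#' Write an elemental map as TIFF + JSON sidecar
#'
#' Counts with maximum <= 65535 and integer values are stored as 16-bit
#' grayscale (bit-exact round trip); larger or fractional counts fall back to
#' 32-bit storage of `counts / 2^24` (quantisation about 0.004 counts, which
#' rounding on read removes exactly for integer counts below 2^24).
#'
#' @param map an `elemental_map`.
#' @param path output TIFF path; sidecar written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_elemental_map <- function(map, path) {
  validate_elemental_map(map)
  mx <- max(map$counts)
  integral <- all(map$counts == round(map$counts))
  if (integral && mx <= 65535) {
    tiff::writeTIFF(map$counts / 65535, path, bits.per.sample = 16L)
    encoding <- list(bits = 16L, scale = 65535, integral = TRUE)
  } else {
    if (mx >= 2^24)
      stop("counts exceed the representable range of the 32-bit fallback")
    tiff::writeTIFF(map$counts / 2^24, path, bits.per.sample = 32L)
    encoding <- list(bits = 32L, scale = 2^24, integral = integral)
  }
  meta <- list(element = map$element, pixel_size_um = map$pixel_size_um,
               fluence_nc_mm2 = map$fluence_nc_mm2, origin_um = map$origin_um,
               encoding = encoding)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an elemental map written by [write_elemental_map()]
#'
#' @param path TIFF path.
#' @param metadata_path JSON sidecar path; defaults to `paste0(path, ".json")`.
#' @return an `elemental_map`.
#' @export
read_elemental_map <- function(path, metadata_path = paste0(path, ".json")) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  if (!file.exists(metadata_path)) stop("format error: missing sidecar metadata ", metadata_path)
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  req <- c("element", "pixel_size_um", "fluence_nc_mm2", "encoding")
  if (!all(req %in% names(meta)))
    stop("format error: sidecar lacks fields ", paste(setdiff(req, names(meta)), collapse = ", "))
  raw <- tiff::readTIFF(path)
  counts <- raw * meta$encoding$scale
  if (meta$encoding$bits == 16L || isTRUE(meta$encoding$integral))
    counts <- round(counts)
  elemental_map(counts, meta$element, meta$pixel_size_um, meta$fluence_nc_mm2,
                if (!is.null(meta$origin_um)) meta$origin_um else c(0, 0))
}

#' Construct specimen geometry
#'
#' The specimen outline, the two reference polylines (implant/tissue interface,
#' mucosal margin), optional inflammation polygons traced from stained serial
#' sections, and the section thickness. All coordinates in micrometres.
#'
#' @param outline simple polygon (n x 2 matrix, open ring) with positive area.
#' @param interface_line polyline (>= 1 vertex) marking the lateral border that
#'   faced the implant surface; origin of horizontal distances.
#' @param margin_line polyline marking the mucosal margin; origin of vertical
#'   distances.
#' @param inflammation_zones list of simple polygons (possibly empty).
#' @param thickness_um section thickness; plausibility band configurable.
#' @param thickness_band_um allowed `[min, max]` for `thickness_um`.
#' @return an object of class `specimen_geometry`.
#' @export
specimen_geometry <- function(outline, interface_line, margin_line,
                              inflammation_zones = list(), thickness_um,
                              thickness_band_um = c(5, 100)) {
  outline <- ensure_ccw(as_coord_matrix(outline))
  interface_line <- as_coord_matrix(interface_line)
  margin_line <- as_coord_matrix(margin_line)
  inflammation_zones <- lapply(inflammation_zones, function(p) ensure_ccw(as_coord_matrix(p)))
  if (!polygon_is_simple(outline))
    stop("validation error: outline polygon is self-intersecting")
  if (polygon_area(outline) <= 0) stop("validation error: outline has zero area")
  if (length(thickness_um) != 1 || !is.finite(thickness_um) ||
      thickness_um < thickness_band_um[1] || thickness_um > thickness_band_um[2])
    stop(sprintf("validation error: thickness_um outside plausible band [%g, %g]",
                 thickness_band_um[1], thickness_band_um[2]))
  structure(list(outline = outline, interface_line = interface_line,
                 margin_line = margin_line,
                 inflammation_zones = inflammation_zones,
                 thickness_um = as.numeric(thickness_um)),
            class = "specimen_geometry")
}

#' @export
print.specimen_geometry <- function(x, ...) {
  cat(sprintf("<specimen_geometry> outline %d vertices, area %.3g mm2, thickness %.3g um, %d inflammation zone(s)\n",
              nrow(x$outline), polygon_area(x$outline) / 1e6, x$thickness_um,
              length(x$inflammation_zones)))
  invisible(x)
}

geojson_feature <- function(role, coords, geomtype) {
  list(type = "Feature", properties = list(role = role),
       geometry = list(type = geomtype, coordinates = coords))
}

#' Write specimen geometry as GeoJSON
#'
#' One FeatureCollection; each feature carries `properties$role` in
#' `outline | interface | margin | inflammation`. Coordinates in micrometres;
#' section thickness stored as a foreign top-level member `thickness_um`.
#'
#' @param geom a `specimen_geometry`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geom, path) {
  ring <- function(p) list(lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2])))
  line <- function(p) lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2]))
  feats <- c(
    list(geojson_feature("outline",
                         list(c(ring(rbind(geom$outline, geom$outline[1, ])))[[1]]),
                         "Polygon")),
    list(geojson_feature("interface", line(geom$interface_line), "LineString")),
    list(geojson_feature("margin", line(geom$margin_line), "LineString")),
    lapply(geom$inflammation_zones, function(p)
      geojson_feature("inflammation", list(ring(rbind(p, p[1, ]))[[1]]), "Polygon"))
  )
  obj <- list(type = "FeatureCollection", thickness_um = geom$thickness_um,
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read specimen geometry from GeoJSON
#'
#' @param path GeoJSON file written by [write_geometry()] or an equivalent
#'   FeatureCollection with role-tagged features.
#' @param thickness_um section thickness override; required when the file has
#'   no `thickness_um` member.
#' @return a `specimen_geometry`.
#' @export
read_geometry <- function(path, thickness_um = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$features)) stop("format error: not a FeatureCollection")
  roles <- vapply(obj$features, function(f) f$properties$role %||% "", "")
  grab <- function(f) {
    g <- f$geometry
    cc <- if (g$type == "Polygon") g$coordinates[[1]] else g$coordinates
    m <- do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
    if (g$type == "Polygon" && nrow(m) > 1 && all(m[1, ] == m[nrow(m), ]))
      m <- m[-nrow(m), , drop = FALSE]
    m
  }
  if (!any(roles == "outline")) stop("format error: no outline feature")
  if (!any(roles == "interface")) stop("missing interface_line: zoning impossible")
  if (!any(roles == "margin")) stop("format error: no margin feature")
  th <- thickness_um %||% obj$thickness_um
  if (is.null(th)) stop("format error: no thickness_um in file and none supplied")
  specimen_geometry(
    outline = grab(obj$features[[which(roles == "outline")[1]]]),
    interface_line = grab(obj$features[[which(roles == "interface")[1]]]),
    margin_line = grab(obj$features[[which(roles == "margin")[1]]]),
    inflammation_zones = lapply(which(roles == "inflammation"),
                                function(i) grab(obj$features[[i]])),
    thickness_um = th)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Column set of the per-particle table
#'
#' Stable, documented order used by [write_particle_table()].
#' @return character vector of column names.
#' @export
particle_table_columns <- function() {
  c("particle_id", "centroid_x_um", "centroid_y_um", "area_um2",
    "equivalent_diameter_um", "perimeter_um", "circularity",
    "feret_min_um", "feret_mean_um", "feret_max_um",
    "horizontal_distance_mm", "vertical_distance_mm", "zone", "inflamed",
    "size_class")
}

#' Write the per-particle table as TSV
#'
#' One row per particle with the full documented column set (ids, centroid,
#' morphometrics, distances, zone, inflammation flag, size class). Numbers are
#' serialised at 15 significant digits so a read-back agrees within 1e-9.
#'
#' @param particles data.frame containing at least [particle_table_columns()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(particles, path) {
  cols <- particle_table_columns()
  if (nrow(particles) > 0) {
    missing_cols <- setdiff(cols, names(particles))
    if (length(missing_cols))
      stop("incomplete particle record: missing field(s) ",
           paste(missing_cols, collapse = ", "))
    for (cl in cols) {
      if (anyNA(particles[[cl]]))
        stop("incomplete particle record: NA in field ", cl)
    }
  } else {
    particles <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  }
  out <- particles[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-particle TSV
#' @param path TSV path written by [write_particle_table()].
#' @return data.frame with the documented column set.
#' @export
read_particle_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read per-sample metadata
#'
#' CSV mirroring the cohort table: one row per specimen with patient id, site
#' condition (`peri-implantitis` or `reference`), implant covariates and
#' clinical measurements. Enforces the paired design: at most one sample per
#' patient and condition.
#'
#' @param path CSV path.
#' @return data.frame of sample records.
#' @export
read_sample_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "site_condition") %in% names(d)))
    stop("format error: sample table needs patient_id and site_condition")
  bad <- !d$site_condition %in% c("peri-implantitis", "reference")
  if (any(bad)) stop("validation error: unknown site_condition value(s)")
  if (anyDuplicated(d[, c("patient_id", "site_condition")]))
    stop("validation error: more than one sample per patient and condition")
  d
}
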