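# Per-particle shape descriptors. The boundary is traced along pixel edges
# (the "crack" contour), simplified with Douglas-Peucker before the perimeter
# is measured (exact for axis-aligned rectangles, ~1% for rasterised disks);
# Feret calipers are projections of the convex hull of the boundary corner
# points over 180 directions.

# Trace the crack boundary of a logical mask. Returns a list of closed rings
# (n x 2 matrices of lattice-corner coordinates in pixel units; pixel [i, j]
# spans x in [j-1, j], y in [i-1, i]). Directed edges keep the region on the
# left; at pinch vertices (diagonally touching pixels) the most-clockwise
# turn is taken so an 8-connected region yields a single outer ring.
trace_crack_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) return(list())
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  bg <- function(r, c) r < 1L | r > nr | c < 1L | c > nc | !mask[pmin(pmax(r, 1L), nr) + (pmin(pmax(c, 1L), nc) - 1L) * nr]
  # directed edges: from-vertex (x0,y0) -> to-vertex (x1,y1)
  e <- list()
  up <- bg(rows - 1L, cols)     # side at smaller y
  dn <- bg(rows + 1L, cols)     # side at larger y
  lf <- bg(rows, cols - 1L)
  rt <- bg(rows, cols + 1L)
  x0 <- c((cols - 1L)[up], cols[rt],       cols[dn],       (cols - 1L)[lf])
  y0 <- c((rows - 1L)[up], (rows - 1L)[rt], rows[dn],      rows[lf])
  x1 <- c(cols[up],        cols[rt],       (cols - 1L)[dn], (cols - 1L)[lf])
  y1 <- c((rows - 1L)[up], rows[rt],       rows[dn],       (rows - 1L)[lf])
  n_e <- length(x0)
  if (!n_e) return(list())
  key <- function(x, y) x * (nr + 2L) + y  # unique vertex key
  from_key <- key(x0, y0)
  ord <- order(from_key)
  from_sorted <- from_key[ord]
  used <- logical(n_e)
  # index lookup: for each vertex key, edge ids starting there
  starts <- split(seq_len(n_e), from_key)
  loops <- list()
  for (e0 in seq_len(n_e)) {
    if (used[e0]) next
    verts_x <- x0[e0]; verts_y <- y0[e0]
    cur <- e0
    repeat {
      used[cur] <- TRUE
      vx <- x1[cur]; vy <- y1[cur]
      verts_x <- c(verts_x, vx); verts_y <- c(verts_y, vy)
      cand <- starts[[as.character(key(vx, vy))]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) == 1L) {
        cur <- cand
      } else {
        # pinch vertex: pick the most-clockwise turn w.r.t. incoming direction
        dx_in <- x1[cur] - x0[cur]; dy_in <- y1[cur] - y0[cur]
        cross <- dx_in * (y1[cand] - y0[cand]) - dy_in * (x1[cand] - x0[cand])
        cur <- cand[which.min(cross)]
      }
    }
    # drop duplicated closing vertex
    npts <- length(verts_x)
    if (verts_x[1] == verts_x[npts] && verts_y[1] == verts_y[npts]) npts <- npts - 1L
    loops[[length(loops) + 1L]] <- cbind(verts_x[1:npts], verts_y[1:npts])
  }
  loops
}

# Remove collinear intermediate vertices from a ring.
drop_collinear <- function(ring) {
  n <- nrow(ring)
  if (n <= 3) return(ring)
  prv <- rbind(ring[n, ], ring[-n, ])
  nxt <- rbind(ring[-1, ], ring[1, ])
  cross <- (ring[, 1] - prv[, 1]) * (nxt[, 2] - ring[, 2]) -
    (ring[, 2] - prv[, 2]) * (nxt[, 1] - ring[, 1])
  ring[cross != 0, , drop = FALSE]
}

# Caliper (Feret) widths of a point set over n_dir uniformly spaced
# directions, from the convex hull.
feret_widths <- function(pts, n_dir = 180) {
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  ang <- (seq_len(n_dir) - 1) * pi / n_dir
  proj <- hull %*% rbind(cos(ang), sin(ang))
  apply(proj, 2, max) - apply(proj, 2, min)
}

#' Measure one particle region
#'
#' Area is the pixel count times the pixel area; the equivalent diameter is
#' that of the circle of equal area; the perimeter comes from the traced
#' sub-pixel boundary contour (outer ring); circularity is the isoperimetric
#' shape factor `4*pi*A / P^2` clamped to `[0, 1]`; Feret calipers are
#' min/mean/max projections of the region's convex hull over 180 directions;
#' the centroid is the mean of pixel centres.
#'
#' @param mask logical matrix with the region's pixels `TRUE` (non-empty).
#' @param pixel_size_um pixel pitch in micrometres.
#' @param origin_um specimen-frame offset of the mask's pixel `[1, 1]` corner.
#' @param dp_tol_px Douglas-Peucker tolerance for the perimeter contour, in
#'   pixel units.
#' @return one-row data.frame: `area_um2`, `equivalent_diameter_um`,
#'   `perimeter_um`, `circularity`, `feret_min_um`, `feret_mean_um`,
#'   `feret_max_um`, `centroid_x_um`, `centroid_y_um`,
#'   `circularity_clamped` (logical: isoperimetric bound hit by
#'   discretisation).
#' @export
measure_region <- function(mask, pixel_size_um, origin_um = c(0, 0),
                           dp_tol_px = 1) {
  if (!any(mask)) stop("empty region")
  px <- pixel_size_um
  idx <- which(mask)
  nr <- nrow(mask)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  area <- length(idx) * px^2
  eq_d <- 2 * sqrt(area / pi)
  loops <- trace_crack_boundary(mask)
  outer_i <- which.max(vapply(loops, function(l) abs(polygon_signed_area(l)), 0))
  ring <- drop_collinear(loops[[outer_i]])
  ring_s <- dp_simplify_ring(ring, dp_tol_px)
  perimeter <- ring_perimeter(ring_s) * px
  raw_circ <- if (perimeter > 0) 4 * pi * area / perimeter^2 else 1
  circ <- min(1, raw_circ)
  # Feret on the corner points of all boundary loops
  corners <- unique(do.call(rbind, loops))
  fw <- feret_widths(corners) * px
  data.frame(area_um2 = area,
             equivalent_diameter_um = eq_d,
             perimeter_um = perimeter,
             circularity = circ,
             feret_min_um = min(fw), feret_mean_um = mean(fw),
             feret_max_um = max(fw),
             centroid_x_um = origin_um[1] + mean(cols - 0.5) * px,
             centroid_y_um = origin_um[2] + mean(rows - 0.5) * px,
             circularity_clamped = raw_circ > 1)
}

#' Measure all regions of a segmentation
#'
#' Applies [measure_region()] to each labelled region (cropped to its
#' bounding box) and appends the size class.
#'
#' @param seg a `particle_segmentation`.
#' @param size_threshold_um small/large split on the equivalent diameter.
#' @return data.frame, one row per particle, with `particle_id`, the
#'   [measure_region()] columns and `size_class`.
#' @export
measure_particles <- function(seg, size_threshold_um = 15) {
  n <- length(seg$regions)
  if (n == 0) {
    out <- measure_region(matrix(TRUE, 1, 1), seg$pixel_size_um)[0, ]
    out$particle_id <- integer(0); out$size_class <- character(0)
    return(out)
  }
  nr <- nrow(seg$labels)
  px <- seg$pixel_size_um
  res <- vector("list", n)
  for (k in seq_len(n)) {
    reg <- seg$regions[[k]]
    rows <- (reg - 1L) %% nr + 1L
    cols <- (reg - 1L) %/% nr + 1L
    r0 <- min(rows); c0 <- min(cols)
    sub <- matrix(FALSE, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
    sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
    m <- measure_region(sub, px,
                        origin_um = seg$origin_um + c(c0 - 1L, r0 - 1L) * px)
    m$particle_id <- k
    res[[k]] <- m
  }
  out <- do.call(rbind, res)
  out$size_class <- classify_size(out$equivalent_diameter_um, size_threshold_um)
  out[, c("particle_id", setdiff(names(out), "particle_id"))]
}

#' Small/large size classification
#'
#' `small` for equivalent diameter at or below the threshold (boundary
#' inclusive on small), `large` above it.
#'
#' @param diameter_um equivalent-circle diameter(s).
#' @param threshold_um split point, default 15 um.
#' @return character vector of `"small"` / `"large"`.
#' @export
classify_size <- function(diameter_um, threshold_um = 15) {
  ifelse(diameter_um <= threshold_um, "small", "large")
}
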