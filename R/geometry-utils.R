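# Low-level computational geometry on bare coordinate matrices.
# All coordinates are in micrometres; polygons are n x 2 matrices (open ring:
# the closing edge from the last to the first vertex is implicit).

#' Signed area of a simple polygon
#'
#' Shoelace formula; positive for counter-clockwise vertex order in a
#' y-up frame.
#'
#' @param poly numeric matrix with columns x, y (one ring, not closed).
#' @return signed area in squared input units.
#' @keywords internal
polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Unsigned polygon area
#' @inheritParams polygon_signed_area
#' @return area in squared input units.
#' @export
polygon_area <- function(poly) abs(polygon_signed_area(poly))

# Orientation normalisation: counter-clockwise (positive signed area).
ensure_ccw <- function(poly) {
  if (polygon_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

# Proper segment intersection test used by the simplicity check.
# Segments p1-p2 and p3-p4; shared endpoints of adjacent edges do not count.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Test whether a polygon ring is simple (non-self-intersecting)
#'
#' Pairwise proper-crossing test over non-adjacent edges; O(n^2), adequate for
#' specimen outlines with at most a few hundred vertices.
#'
#' @inheritParams polygon_signed_area
#' @return TRUE if no two non-adjacent edges properly cross.
#' @export
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  idx <- rbind(cbind(seq_len(n), c(seq_len(n)[-1], 1)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # adjacent edges (share a vertex) are skipped
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(poly[idx[i, 1], ], poly[idx[i, 2], ],
                         poly[idx[j, 1], ], poly[idx[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Vectorised point-in-polygon test
#'
#' Crossing-number (even-odd) rule, vectorised over points; points exactly on
#' an edge may fall on either side at floating-point resolution.
#'
#' @param px,py point coordinates.
#' @inheritParams polygon_signed_area
#' @return logical vector, TRUE for points inside the ring.
#' @export
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  xj <- poly[n, 1]; yj <- poly[n, 2]
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    xj <- xi; yj <- yi
  }
  inside
}

#' Rasterize a polygon onto a pixel grid
#'
#' Scanline fill: a pixel is set when its centre lies inside the ring (even-odd
#' rule), matching [points_in_polygon()] on pixel centres but in
#' O(vertices x rows) rather than O(vertices x pixels).
#'
#' @param poly polygon ring (n x 2 matrix, um).
#' @param nr,nc raster dimensions (rows, cols).
#' @param pixel_size_um pixel pitch.
#' @param origin_um offset of the pixel [1,1] corner in the polygon's frame.
#' @return logical `nr x nc` matrix.
#' @export
rasterize_polygon <- function(poly, nr, nc, pixel_size_um, origin_um = c(0, 0)) {
  mask <- matrix(FALSE, nr, nc)
  xi <- poly[, 1]; yi <- poly[, 2]
  xj <- c(xi[-1], xi[1]); yj <- c(yi[-1], yi[1])
  xc <- origin_um[1] + (seq_len(nc) - 0.5) * pixel_size_um
  for (i in seq_len(nr)) {
    y <- origin_um[2] + (i - 0.5) * pixel_size_um
    cross <- (yi > y) != (yj > y)
    if (!any(cross)) next
    xs <- sort(xi[cross] + (y - yi[cross]) * (xj[cross] - xi[cross]) /
                 (yj[cross] - yi[cross]))
    for (m in seq_len(length(xs) %/% 2)) {
      j <- which(xc > xs[2 * m - 1] & xc < xs[2 * m])
      if (length(j)) mask[i, j] <- TRUE
    }
  }
  mask
}

#' Minimum distance from points to a polyline
#'
#' Exact Euclidean point-to-segment minimum over all segments, with the
#' perpendicular foot clamped to segment ends. A single-vertex (degenerate)
#' polyline is treated as a point.
#'
#' @param px,py point coordinates (vectors of equal length).
#' @param polyline numeric matrix with columns x, y (>= 1 vertex).
#' @return numeric vector of distances in input units.
#' @export
min_distance_to_polyline <- function(px, py, polyline) {
  polyline <- as_coord_matrix(polyline)
  stopifnot(length(px) == length(py), nrow(polyline) >= 1)
  best <- rep(Inf, length(px))
  if (nrow(polyline) == 1) {
    return(sqrt((px - polyline[1, 1])^2 + (py - polyline[1, 2])^2))
  }
  for (i in seq_len(nrow(polyline) - 1)) {
    x1 <- polyline[i, 1]; y1 <- polyline[i, 2]
    x2 <- polyline[i + 1, 1]; y2 <- polyline[i + 1, 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d <- sqrt((px - x1)^2 + (py - y1)^2)
    } else {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
      d <- sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
    }
    best <- pmin(best, d)
  }
  best
}

# Coerce list / data.frame / vector input to an n x 2 numeric matrix.
as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"  # preserves dim even for a single row
    return(x)
  }
  if (is.data.frame(x)) return(cbind(as.numeric(x[[1]]), as.numeric(x[[2]])))
  if (is.numeric(x) && length(x) == 2) return(matrix(x, 1, 2))
  stop("cannot interpret coordinates; supply an n x 2 matrix")
}

#' Douglas-Peucker polyline simplification
#'
#' @param pts n x 2 matrix of ordered vertices (open path).
#' @param tol maximum allowed perpendicular deviation of removed points.
#' @return subset of rows of `pts`, first and last always kept.
#' @keywords internal
dp_simplify <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2) return(pts)
  keep <- logical(n); keep[1] <- keep[n] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    seg <- b - a; len <- sqrt(sum(seg^2))
    mid <- (i + 1):(j - 1)
    if (len == 0) {
      d <- sqrt((pts[mid, 1] - a[1])^2 + (pts[mid, 2] - a[2])^2)
    } else {
      d <- abs(seg[1] * (a[2] - pts[mid, 2]) - seg[2] * (a[1] - pts[mid, 1])) / len
    }
    k <- which.max(d)
    if (d[k] > tol) {
      km <- mid[k]
      keep[km] <- TRUE
      stack <- c(stack, list(c(i, km)), list(c(km, j)))
    }
  }
  pts[keep, , drop = FALSE]
}

# Closed-ring Douglas-Peucker: anchor at the two mutually most distant of a
# small set of extreme vertices, simplify the two arcs separately.
dp_simplify_ring <- function(ring, tol) {
  n <- nrow(ring)
  if (n <= 4) return(ring)
  i1 <- which.max(ring[, 1] + ring[, 2] * 1e-9)  # deterministic extreme
  d2 <- (ring[, 1] - ring[i1, 1])^2 + (ring[, 2] - ring[i1, 2])^2
  i2 <- which.max(d2)
  lo <- min(i1, i2); hi <- max(i1, i2)
  arc1 <- ring[lo:hi, , drop = FALSE]
  arc2 <- ring[c(hi:n, 1:lo), , drop = FALSE]
  s1 <- dp_simplify(arc1, tol)
  s2 <- dp_simplify(arc2, tol)
  out <- rbind(s1, s2[-1, , drop = FALSE])
  # drop duplicated closing vertex
  if (all(out[1, ] == out[nrow(out), ])) out <- out[-nrow(out), , drop = FALSE]
  out
}

# Path length of an open polyline.
path_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
}

# Ring perimeter (closing edge included).
ring_perimeter <- function(ring) {
  path_length(rbind(ring, ring[1, , drop = FALSE]))
}

# Apply a rigid motion (rotation by theta, then translation) to coordinates.
rigid_transform <- function(pts, theta = 0, shift = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(pts %*% t(R), 2, shift, "+")
}
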