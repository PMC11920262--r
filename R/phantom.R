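# Synthetic micro-PIXE specimen generator: titanium particle fields with a
# zonal density gradient, sulfur tissue background, Gaussian beam blur and
# fluence-scaled Poisson counting noise, plus fluence-non-scaling "confuser"
# sources that mimic false detections of the survey pass.

#' Phantom generator parameters
#'
#' Defaults describe a peri-implant soft-tissue section as characterised in
#' the study conditions this package emulates: a specimen a few millimetres
#' wide, sectioned at 20-50 um, scanned with a 4-5 um proton beam at a survey
#' fluence of 200 nC/mm^2 (high-statistics confirmation at 20,000 nC/mm^2),
#' titanium micro-particles with log-normal equivalent diameters (moment-
#' matched to mean 16.17 um, sd 12.03 um, implying ~59% of particles at or
#' below 15 um) concentrated near the implant/tissue interface, and mean
#' true-footprint circularity near 0.72.
#'
#' Intensity-scale parameters (`particle_intensity`, `background_rate`,
#' confuser brightness, sulfur rates) are free parameters of the generator,
#' not values reported by any study; see the methods vignette.
#'
#' @param specimen_width_mm extent away from the implant/tissue interface (x).
#' @param specimen_depth_mm apico-coronal extent from the mucosal margin (y).
#' @param thickness_um section thickness.
#' @param pixel_size_um raster pixel pitch.
#' @param beam_fwhm_um Gaussian beam full width at half maximum.
#' @param zone_densities volumetric particle densities (particles/mm^3) for
#'   the distance bands `[0,1)`, `[1,2)`, `[2,Inf)` mm from the interface.
#' @param size_meanlog,size_sdlog log-normal parameters of the true equivalent
#'   diameter in um.
#' @param axis_ratio_range uniform range of the footprint ellipse axis ratio.
#' @param roughness_max maximum radial boundary-roughness amplitude
#'   (relative), uniform per particle on `[0, roughness_max]`.
#' @param particle_intensity expected Ti counts per um^2 of particle footprint
#'   at the reference fluence.
#' @param background_rate expected stray Ti counts per pixel at the reference
#'   fluence.
#' @param false_source_rate confuser blobs per mm^2 of specimen.
#' @param confuser_peak_range uniform range of confuser peak amplitude
#'   (counts/pixel, survey scale; does not scale with fluence).
#' @param s_tissue_rate,s_outside_rate expected S counts per pixel inside /
#'   outside the outline at the reference fluence.
#' @param tile_size_um mosaic sub-region edge length.
#' @param reference_fluence_nc_mm2 fluence at which the intensity parameters
#'   are expressed (the survey pass).
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(specimen_width_mm = 4, specimen_depth_mm = 3,
                         thickness_um = 25, pixel_size_um = 2,
                         beam_fwhm_um = 4.5,
                         zone_densities = c(260, 159, 152),
                         size_meanlog = 2.563, size_sdlog = 0.664,
                         axis_ratio_range = c(0.25, 1),
                         roughness_max = 0.45,
                         particle_intensity = 50,
                         background_rate = 0.05,
                         false_source_rate = 2,
                         confuser_peak_range = c(2, 4),
                         s_tissue_rate = 3, s_outside_rate = 0.02,
                         tile_size_um = 1000,
                         reference_fluence_nc_mm2 = 200,
                         seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  stopifnot(all(spec$zone_densities >= 0), all(is.finite(spec$zone_densities)),
            length(spec$zone_densities) == 3,
            spec$beam_fwhm_um > 0, spec$pixel_size_um > 0,
            spec$tile_size_um >= spec$pixel_size_um,
            spec$particle_intensity >= 0, spec$background_rate >= 0,
            spec$false_source_rate >= 0,
            spec$reference_fluence_nc_mm2 > 0)
  spec$seed <- as.integer(seed)
  spec
}

#' Rectangular phantom geometry for a spec
#'
#' Outline `[m, m + width] x [m, m + depth]` um, inset by a frame margin `m`
#' so the scan raster extends past the specimen on every side (as a real
#' mosaic scan does; without the inset, beam blur running off the frame edge
#' would erode the tissue signal exactly at the specimen boundary). The
#' interface is the left outline edge, the mucosal margin the top edge.
#' Optionally one inflammation polygon covers the `inflamed_fraction` of the
#' specimen closest to the interface.
#'
#' @param spec a `phantom_spec`.
#' @param inflamed_fraction fraction (by width) marked inflamed; 0 for none.
#' @param margin_um frame margin around the specimen.
#' @return a `specimen_geometry`.
#' @export
phantom_geometry <- function(spec, inflamed_fraction = 0, margin_um = 100) {
  W <- spec$specimen_width_mm * 1000
  D <- spec$specimen_depth_mm * 1000
  m <- margin_um
  outline <- rbind(c(m, m), c(m + W, m), c(m + W, m + D), c(m, m + D))
  infl <- list()
  if (inflamed_fraction > 0) {
    w <- W * inflamed_fraction
    infl <- list(rbind(c(m, m), c(m + w, m), c(m + w, m + D), c(m, m + D)))
  }
  specimen_geometry(outline = outline,
                    interface_line = rbind(c(m, m), c(m, m + D)),
                    margin_line = rbind(c(m, m), c(m + W, m)),
                    inflammation_zones = infl,
                    thickness_um = spec$thickness_um)
}

# Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Zone label from horizontal distance
#' @param d_mm distance from the interface in mm.
#' @param band_edges_mm inner band edges, default `c(1, 2)`.
#' @return integer zone label (1-based); half-open bands `[0,1), [1,2), [2,Inf)`.
#' @export
zone_from_distance <- function(d_mm, band_edges_mm = c(1, 2)) {
  findInterval(d_mm, band_edges_mm) + 1L
}

# Area (mm^2) of outline intersected with each distance band, by a regular
# grid of probe points (pitch in um). Deterministic.
band_areas_mm2 <- function(geometry, band_edges_mm = c(1, 2), pitch_um = 10) {
  bb <- apply(geometry$outline, 2, range)
  gx <- seq(bb[1, 1] + pitch_um / 2, bb[2, 1], by = pitch_um)
  gy <- seq(bb[1, 2] + pitch_um / 2, bb[2, 2], by = pitch_um)
  pts <- expand.grid(x = gx, y = gy)
  inside <- points_in_polygon(pts$x, pts$y, geometry$outline)
  d <- min_distance_to_polyline(pts$x[inside], pts$y[inside], geometry$interface_line) / 1000
  z <- zone_from_distance(d, band_edges_mm)
  areas <- vapply(1:3, function(k) sum(z == k), 0) * (pitch_um / 1000)^2
  areas
}

# Sample one irregular particle footprint polygon: rough ellipse with the
# requested equivalent-circle diameter. Consumes RNG draws.
particle_footprint <- function(x, y, diameter_um, axis_ratio_range, roughness_max,
                               n_vertices = 64) {
  q <- stats::runif(1, axis_ratio_range[1], axis_ratio_range[2])
  amp <- stats::runif(1, 0, roughness_max)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- q / sqrt(q^2 * cos(theta)^2 + sin(theta)^2)
  for (h in 2:8) {
    r <- r * (1 + (amp * stats::runif(1) / sqrt(h)) *
                cos(h * theta + stats::runif(1, 0, 2 * pi)))
  }
  r <- pmax(r, 0.1)
  omega <- stats::runif(1, 0, 2 * pi)
  poly <- cbind(r * cos(theta), r * sin(theta))
  poly <- rigid_transform(poly, theta = omega)
  s <- sqrt(pi * (diameter_um / 2)^2 / polygon_area(poly))
  sweep(poly * s, 2, c(x, y), "+")
}

#' Sample a ground-truth particle field
#'
#' Particle counts per distance band are Poisson with mean
#' `zone_density x band area x thickness`; centres are uniform within the
#' band-outline intersection; footprints are rough ellipses drawn from the
#' size and shape model. Confuser sources are placed uniformly over the
#' outline at `false_source_rate` per mm^2.
#'
#' @param spec a `phantom_spec`.
#' @param geometry a `specimen_geometry`; defaults to [phantom_geometry()].
#' @return an object of class `ground_truth`: `particles` (data.frame with
#'   id, centre, true diameter/area/circularity, zone), `footprints` (list of
#'   polygons) and `confusers` (data.frame with centre and survey-visible
#'   peak amplitude).
#' @export
sample_particle_field <- function(spec, geometry = phantom_geometry(spec)) {
  with_seed(spec$seed, {
    areas <- band_areas_mm2(geometry)
    vol_factor <- geometry$thickness_um / 1000
    bb <- apply(geometry$outline, 2, range)
    parts <- list(); foots <- list(); pid <- 0L
    for (k in 1:3) {
      lambda <- spec$zone_densities[k] * areas[k] * vol_factor
      if (areas[k] == 0 && spec$zone_densities[k] > 0) {
        warning(sprintf("band %d has zero area; positive density ignored", k))
        next
      }
      n <- stats::rpois(1, lambda)
      if (n == 0) next
      got <- 0
      while (got < n) {
        m <- max(32, 4 * (n - got))
        cx <- stats::runif(m, bb[1, 1], bb[2, 1])
        cy <- stats::runif(m, bb[1, 2], bb[2, 2])
        ok <- points_in_polygon(cx, cy, geometry$outline)
        if (any(ok)) {
          d_mm <- min_distance_to_polyline(cx[ok], cy[ok], geometry$interface_line) / 1000
          ok2 <- zone_from_distance(d_mm) == k
          cx <- cx[ok][ok2]; cy <- cy[ok][ok2]
          take <- seq_len(min(length(cx), n - got))
          for (t in take) {
            pid <- pid + 1L
            dia <- stats::rlnorm(1, spec$size_meanlog, spec$size_sdlog)
            fp <- particle_footprint(cx[t], cy[t], dia,
                                     spec$axis_ratio_range, spec$roughness_max)
            foots[[pid]] <- fp
            parts[[pid]] <- data.frame(
              id = pid, x_um = cx[t], y_um = cy[t],
              diameter_um = dia, area_um2 = pi * (dia / 2)^2,
              circularity = min(1, 4 * pi * polygon_area(fp) / ring_perimeter(fp)^2),
              zone = k)
          }
          got <- got + length(take)
        }
      }
    }
    particles <- if (pid > 0) do.call(rbind, parts) else
      data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                 diameter_um = numeric(0), area_um2 = numeric(0),
                 circularity = numeric(0), zone = integer(0))
    # confusers: uniform over the outline
    n_conf <- stats::rpois(1, spec$false_source_rate * polygon_area(geometry$outline) / 1e6)
    conf <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                       peak = numeric(0))
    got <- 0
    while (got < n_conf) {
      m <- max(32, 4 * (n_conf - got))
      cx <- stats::runif(m, bb[1, 1], bb[2, 1])
      cy <- stats::runif(m, bb[1, 2], bb[2, 2])
      ok <- which(points_in_polygon(cx, cy, geometry$outline))
      take <- ok[seq_len(min(length(ok), n_conf - got))]
      if (length(take)) {
        conf <- rbind(conf, data.frame(
          id = got + seq_along(take), x_um = cx[take], y_um = cy[take],
          peak = stats::runif(length(take), spec$confuser_peak_range[1],
                              spec$confuser_peak_range[2])))
        got <- got + length(take)
      }
    }
    structure(list(particles = particles, footprints = foots, confusers = conf),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d particle(s) [zones: %s], %d confuser(s)\n",
              nrow(x$particles),
              paste(tabulate(x$particles$zone, 3), collapse = "/"),
              nrow(x$confusers)))
  invisible(x)
}

# Normalised Gaussian kernel blur via FFT convolution (circular boundary,
# conserves total mass). sigma in pixels.
gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  half <- ceiling(3 * sigma_px)
  k <- 2 * half + 1
  kmax <- min(dim(mat)) - (1 - min(dim(mat)) %% 2)  # largest odd <= min dim
  if (k > kmax) { k <- max(1, kmax); half <- (k - 1) / 2 }
  if (k < 3) return(mat)
  g <- stats::dnorm(-half:half, sd = sigma_px)
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  # zero padding: signal scanned off the frame edge is lost, never wrapped;
  # clamp FFT ringing (inputs are non-negative count fields)
  pmax(as.matrix(EBImage::filter2(mat, kern, boundary = 0)), 0)
}

# Pixel coverage field (fraction of each pixel inside any particle footprint),
# by sub x sub sub-pixel sampling restricted to each footprint's bounding box
# (6x6 keeps the integrated-mass quantisation error below ~0.3%).
coverage_field <- function(truth, nr, nc, pixel_size_um, sub = 6) {
  cov <- matrix(0, nr, nc)
  off <- (seq_len(sub) - 0.5) / sub  # sub-pixel offsets in pixel units
  for (fp in truth$footprints) {
    bb <- apply(fp, 2, range)
    j0 <- max(1L, floor(bb[1, 1] / pixel_size_um) + 1L)
    j1 <- min(nc, ceiling(bb[2, 1] / pixel_size_um))
    i0 <- max(1L, floor(bb[1, 2] / pixel_size_um) + 1L)
    i1 <- min(nr, ceiling(bb[2, 2] / pixel_size_um))
    if (j1 < j0 || i1 < i0) next
    sx <- as.vector(outer(off, (j0 - 1):(j1 - 1), "+")) * pixel_size_um
    sy <- as.vector(outer(off, (i0 - 1):(i1 - 1), "+")) * pixel_size_um
    gx <- rep(sx, times = length(sy))
    gy <- rep(sy, each = length(sx))
    inside <- points_in_polygon(gx, gy, fp)
    frac <- matrix(inside, nrow = length(sx), ncol = length(sy))
    # collapse sub x sub blocks to per-pixel fractions
    npx <- j1 - j0 + 1L; npy <- i1 - i0 + 1L
    dim(frac) <- c(sub, npx, sub, npy)
    pixfrac <- apply(frac, c(2, 4), sum) / sub^2
    cov[i0:i1, j0:j1] <- cov[i0:i1, j0:j1] + t(pixfrac)
  }
  pmin(cov, 1)
}

#' Render elemental maps from a ground truth
#'
#' Expected Ti counts per pixel are `(footprint coverage x particle_intensity
#' + background_rate) x (fluence / reference_fluence)`, blurred by the beam
#' Gaussian, with confuser blobs added at their fixed survey-scale amplitude
#' (their expectation does not grow with fluence, which is what makes them
#' identifiable on high-statistics confirmation), then Poisson-sampled.
#' The S map is a uniform tissue rate inside the outline and near-zero
#' outside, under the same noise model.
#'
#' @param truth a `ground_truth`.
#' @param spec a `phantom_spec`.
#' @param geometry the `specimen_geometry` the truth was sampled on.
#' @param fluence_nc_mm2 fluence of this pass.
#' @param noise if `FALSE`, return the Poisson expectation instead of a draw.
#' @param seed RNG seed for the noise draw; default derives from the spec seed
#'   and the fluence so different passes are independent but reproducible.
#' @param dim optional `c(nrow, ncol)` of the raster; must cover the specimen.
#' @param elements which maps to render (`"ti"`, `"s"`); the confirmation
#'   pass typically needs only Ti.
#' @return list with elements `ti` and `s` (`elemental_map`s; `NULL` if not
#'   rendered).
#' @export
render_maps <- function(truth, spec, geometry, fluence_nc_mm2,
                        noise = TRUE, seed = NULL, dim = NULL,
                        elements = c("ti", "s")) {
  px <- spec$pixel_size_um
  bb <- apply(geometry$outline, 2, range)
  need_nc <- ceiling(bb[2, 1] / px); need_nr <- ceiling(bb[2, 2] / px)
  if (is.null(dim)) dim <- c(need_nr, need_nc)
  if (dim[1] < need_nr || dim[2] < need_nc)
    stop("pixel grid smaller than specimen")
  nr <- dim[1]; nc <- dim[2]
  if (is.null(seed))
    seed <- (spec$seed + 101L * (round(fluence_nc_mm2) %% 9973L)) %% 2147483647L
  scale <- fluence_nc_mm2 / spec$reference_fluence_nc_mm2
  sigma_px <- spec$beam_fwhm_um / (2 * sqrt(2 * log(2))) / px
  want_ti <- "ti" %in% elements
  want_s <- "s" %in% elements

  cov <- coverage_field(truth, nr, nc, px)
  e_ti <- (cov * spec$particle_intensity * px^2 + spec$background_rate) * scale
  e_ti <- gaussian_blur(e_ti, sigma_px)
  # confusers: fixed survey-scale Gaussian blobs
  if (nrow(truth$confusers) > 0) {
    xs <- (seq_len(nc) - 0.5) * px
    ys <- (seq_len(nr) - 0.5) * px
    s2 <- max(sigma_px * px, px / 2)^2
    for (i in seq_len(nrow(truth$confusers))) {
      cx <- truth$confusers$x_um[i]; cy <- truth$confusers$y_um[i]
      gx <- exp(-(xs - cx)^2 / (2 * s2))
      gy <- exp(-(ys - cy)^2 / (2 * s2))
      e_ti <- e_ti + truth$confusers$peak[i] * outer(gy, gx)
    }
  }
  # sulfur: tissue-shaped background
  e_s <- NULL
  if (want_s) {
    inside <- rasterize_polygon(geometry$outline, nr, nc, px)
    e_s <- (ifelse(inside, spec$s_tissue_rate, spec$s_outside_rate)) * scale
    e_s <- gaussian_blur(e_s, sigma_px)
  }

  ti <- e_ti; s <- e_s
  if (noise) {
    with_seed(seed, {
      ti <- matrix(stats::rpois(length(e_ti), e_ti), nr, nc)
      if (want_s) s <- matrix(stats::rpois(length(e_s), e_s), nr, nc)
    })
  }
  list(ti = if (want_ti) elemental_map(ti, "Ti", px, fluence_nc_mm2) else NULL,
       s = if (want_s) elemental_map(s, "S", px, fluence_nc_mm2) else NULL)
}

#' Render a mosaic of sub-region tiles
#'
#' Tiles of edge `tile_size_um` partition the specimen bounding box (edge
#' tiles may be partial). The per-pixel values are those of the full-frame
#' render, so stitching the tiles reproduces [render_maps()] exactly,
#' independent of the tiling.
#'
#' @inheritParams render_maps
#' @return list of tiles, each `list(rows, cols, ti, s)` where `rows`/`cols`
#'   are the pixel index ranges in the full frame and `ti`/`s` carry tile
#'   origins in specimen coordinates.
#' @export
render_mosaic <- function(truth, spec, geometry, fluence_nc_mm2,
                          noise = TRUE, seed = NULL) {
  full <- render_maps(truth, spec, geometry, fluence_nc_mm2,
                      noise = noise, seed = seed)
  px <- spec$pixel_size_um
  nr <- nrow(full$ti$counts); nc <- ncol(full$ti$counts)
  t_px <- max(1L, as.integer(round(spec$tile_size_um / px)))
  row_starts <- seq(1L, nr, by = t_px)
  col_starts <- seq(1L, nc, by = t_px)
  tiles <- list()
  for (r0 in row_starts) for (c0 in col_starts) {
    r1 <- min(nr, r0 + t_px - 1L); c1 <- min(nc, c0 + t_px - 1L)
    org <- c((c0 - 1L) * px, (r0 - 1L) * px)
    tiles[[length(tiles) + 1L]] <- list(
      rows = c(r0, r1), cols = c(c0, c1),
      ti = elemental_map(full$ti$counts[r0:r1, c0:c1, drop = FALSE], "Ti",
                         px, fluence_nc_mm2, origin_um = org),
      s = elemental_map(full$s$counts[r0:r1, c0:c1, drop = FALSE], "S",
                        px, fluence_nc_mm2, origin_um = org))
  }
  tiles
}

#' Stitch mosaic tiles back into full-frame maps
#' @param tiles output of [render_mosaic()].
#' @return list with `ti` and `s` matrices.
#' @export
stitch_mosaic <- function(tiles) {
  nr <- max(vapply(tiles, function(t) t$rows[2], 0L))
  nc <- max(vapply(tiles, function(t) t$cols[2], 0L))
  ti <- matrix(NA_real_, nr, nc); s <- matrix(NA_real_, nr, nc)
  for (t in tiles) {
    ti[t$rows[1]:t$rows[2], t$cols[1]:t$cols[2]] <- t$ti$counts
    s[t$rows[1]:t$rows[2], t$cols[1]:t$cols[2]] <- t$s$counts
  }
  list(ti = ti, s = s)
}

#' Analytic fraction of particles at or below a diameter
#'
#' Closed form under the generator's log-normal size model; used to verify
#' size-distribution recovery.
#'
#' @param spec a `phantom_spec`.
#' @param threshold_um diameter threshold (default 15).
#' @return probability in `[0, 1]`.
#' @export
small_fraction_analytic <- function(spec, threshold_um = 15) {
  stats::plnorm(threshold_um, spec$size_meanlog, spec$size_sdlog)
}
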