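# Two-pass particle detection on survey Ti maps: blob-of-revolution (circular
# matched-filter) candidate search, high-statistics confirmation, lower-
# threshold calibration from false detections, and segmentation into
# background-free labelled regions.

# 8-connected component labelling (breadth-first) over a logical matrix.
# Returns an integer matrix of labels (0 = background).
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  nb_off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  cur <- 0L
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue
      queue <- integer(0)
      rows <- (p - 1L) %% nr + 1L
      for (k in seq_along(nb_off)) {
        q <- p + nb_off[k]
        # guard row wrap-around for vertical/diagonal moves
        dr <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)[k]
        ok <- q >= 1L & q <= nr * nc & (rows + dr >= 1L) & (rows + dr <= nr)
        q <- q[ok]
        q <- q[mask[q] & lab[q] == 0L]
        if (length(q)) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

# Neighbourhood (3x3) maximum by shifting; -Inf padding at the frame border.
neighborhood_max <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts$dr[k]; dc <- shifts$dc[k]
    if (dr == 0 && dc == 0) next
    sh <- matrix(-Inf, nr, nc)
    r_src <- max(1, 1 - dr):min(nr, nr - dr)
    c_src <- max(1, 1 - dc):min(nc, nc - dc)
    sh[r_src + dr, c_src + dc] <- m[r_src, c_src]
    out <- pmax(out, sh)
  }
  out
}

disk_kernel <- function(r_px) {
  half <- ceiling(r_px)
  g <- expand.grid(x = -half:half, y = -half:half)
  inside <- g$x^2 + g$y^2 <= r_px^2 + 1e-9
  k <- matrix(as.numeric(inside), 2 * half + 1, 2 * half + 1)
  k / sum(k)
}

#' Detect candidate particles on a survey Ti map
#'
#' Circular matched-filter voting over a beam-smoothed map: the map is
#' convolved with normalised disk kernels spanning `radius_range_um`, the vote
#' at each pixel is the best response over radii, and candidates are the local
#' maxima of the vote map above its `sensitivity` quantile (over positive
#' votes), with non-maximum suppression at the candidate scale. This stage is
#' tuned for recall: false positives are expected and are handled by
#' high-statistics confirmation and threshold calibration downstream.
#'
#' @param ti_map survey-pass `elemental_map` (element Ti).
#' @param radius_range_um candidate radius range; lower bound >= 0.75 um
#'   (half the 1.5 um detectability floor).
#' @param sensitivity quantile of positive votes used as the vote floor.
#' @param beam_fwhm_um smoothing scale (beam full width at half maximum).
#' @param n_radii number of radius steps (log-spaced).
#' @return data.frame of candidates sorted by descending peak intensity:
#'   `candidate_id`, pixel centre (`row`, `col`, `x_um`, `y_um`), estimated
#'   `radius_um`, `vote`, raw `peak_intensity`, and a `support` list-column of
#'   pixel linear indices.
#' @export
detect_candidates <- function(ti_map, radius_range_um = c(0.75, 20),
                              sensitivity = 0.99, beam_fwhm_um = 4.5,
                              n_radii = 6) {
  validate_elemental_map(ti_map)
  stopifnot(radius_range_um[1] >= 0.75)
  px <- ti_map$pixel_size_um
  counts <- ti_map$counts
  sigma_px <- beam_fwhm_um / (2 * sqrt(2 * log(2))) / px
  radii_px <- unique(pmax(1, round(exp(seq(log(max(1, radius_range_um[1] / px)),
                                           log(max(1, radius_range_um[2] / px)),
                                           length.out = n_radii)))))
  if (min(dim(counts)) < 2 * max(radii_px) + 1)
    stop("map smaller than smallest detection kernel")
  sm <- gaussian_blur(counts, sigma_px)
  vote <- matrix(-Inf, nrow(counts), ncol(counts))
  best_r <- matrix(radii_px[1], nrow(counts), ncol(counts))
  for (r in radii_px) {
    resp <- as.matrix(EBImage::filter2(sm, disk_kernel(r), boundary = 0))
    upd <- resp > vote
    vote[upd] <- resp[upd]
    best_r[upd] <- r
  }
  pos <- vote[vote > 0]
  empty <- data.frame(candidate_id = integer(0), row = integer(0),
                      col = integer(0), x_um = numeric(0), y_um = numeric(0),
                      radius_um = numeric(0), vote = numeric(0),
                      peak_intensity = numeric(0))
  empty$support <- list()
  if (!length(pos)) return(empty)
  # vote floor: the sensitivity quantile of the noise-dominated vote
  # population (positive votes below a robust outlier ceiling), so that a few
  # very bright particles cannot drag the floor above the noise tail
  noise_pop <- pos[pos <= stats::median(pos) + 8 * stats::mad(pos)]
  if (!length(noise_pop)) noise_pop <- pos
  floor_v <- stats::quantile(noise_pop, sensitivity, names = FALSE)
  # numerical floor: discard FFT-residue maxima far below one count
  floor_v <- max(floor_v, 1e-6 * max(vote))
  is_max <- vote >= neighborhood_max(vote) & vote >= floor_v & vote > 0
  idx <- which(is_max)
  if (!length(idx)) return(empty)
  ord <- order(vote[idx], decreasing = TRUE)
  idx <- idx[ord]
  nr <- nrow(counts)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  rads <- best_r[idx]
  keep <- logical(length(idx))
  kr <- numeric(0); kc <- numeric(0); ks <- numeric(0)
  for (i in seq_along(idx)) {
    sep <- pmax(2, pmax(rads[i], ks))
    if (!length(kr) || all((rows[i] - kr)^2 + (cols[i] - kc)^2 > sep^2)) {
      keep[i] <- TRUE
      kr <- c(kr, rows[i]); kc <- c(kc, cols[i]); ks <- c(ks, rads[i])
    }
  }
  rows <- rows[keep]; cols <- cols[keep]; rads <- rads[keep]; vt <- vote[idx][keep]
  support <- vector("list", length(rows))
  peak <- numeric(length(rows))
  for (i in seq_along(rows)) {
    r <- rads[i]
    half <- ceiling(r)
    rr <- max(1, rows[i] - half):min(nr, rows[i] + half)
    cc <- max(1, cols[i] - half):min(ncol(counts), cols[i] + half)
    g <- expand.grid(r = rr, c = cc)
    g <- g[(g$r - rows[i])^2 + (g$c - cols[i])^2 <= r^2 + 1e-9, ]
    support[[i]] <- (g$c - 1L) * nr + g$r
    peak[i] <- max(counts[support[[i]]])
  }
  out <- data.frame(candidate_id = seq_along(rows), row = rows, col = cols,
                    x_um = ti_map$origin_um[1] + (cols - 0.5) * px,
                    y_um = ti_map$origin_um[2] + (rows - 0.5) * px,
                    radius_um = rads * px, vote = vt, peak_intensity = peak)
  out$support <- support
  out <- out[order(-out$peak_intensity, out$candidate_id), ]
  out$candidate_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Confirm candidates against a high-statistics map
#'
#' A candidate is confirmed when its integrated high-statistics counts exceed
#' the expected background over its support by at least `min_snr` background
#' standard deviations (Poisson): `sum - E[bg] > min_snr * sqrt(E[bg])`.
#' Genuine Ti particles scale with fluence and pass easily; confuser sources
#' whose signal does not grow with dose fall below the criterion.
#'
#' @param candidates output of [detect_candidates()] (same raster grid).
#' @param high_stat_map confirmation-pass `elemental_map`.
#' @param min_snr signal-to-noise multiple required for confirmation.
#' @param background_rate expected background counts per pixel on the
#'   high-statistics map; estimated as the map median when `NULL`.
#' @return data.frame: `candidate_id`, `confirmed`, `high_stat_intensity`.
#' @export
confirm_candidates <- function(candidates, high_stat_map, min_snr = 5,
                               background_rate = NULL) {
  validate_elemental_map(high_stat_map)
  counts <- high_stat_map$counts
  if (nrow(candidates) == 0)
    return(data.frame(candidate_id = integer(0), confirmed = logical(0),
                      high_stat_intensity = numeric(0)))
  n <- length(counts)
  outside <- vapply(candidates$support,
                    function(s) any(s < 1 | s > n), TRUE)
  if (any(outside))
    stop("candidate(s) outside the high-statistics map: ",
         paste(candidates$candidate_id[outside], collapse = ", "))
  if (is.null(background_rate)) background_rate <- stats::median(counts)
  sums <- vapply(candidates$support, function(s) sum(counts[s]), 0)
  ebg <- background_rate * lengths(candidates$support)
  data.frame(candidate_id = candidates$candidate_id,
             confirmed = (sums - ebg) > min_snr * sqrt(ebg),
             high_stat_intensity = sums)
}

#' Calibrate the lower concentration threshold from false detections
#'
#' The threshold is the largest survey-scale peak intensity among candidates
#' the confirmation pass rejected, plus one count, so that applying it removes
#' every false detection. If no candidate was rejected the threshold is zero.
#' If a confirmed particle falls at or below the threshold the guarantee of
#' keeping all micro-particles is unattainable; a warning reports the
#' conflict rather than hiding it.
#'
#' @param results output of [confirm_candidates()].
#' @param candidates output of [detect_candidates()].
#' @return object of class `detection_threshold`: `value` (counts, survey
#'   scale) and `provenance` (false-detection peak intensities used).
#' @export
calibrate_threshold <- function(results, candidates) {
  if (nrow(candidates) == 0) stop("no candidates: threshold undefined")
  m <- merge(candidates[, c("candidate_id", "peak_intensity")], results,
             by = "candidate_id")
  false_peaks <- m$peak_intensity[!m$confirmed]
  value <- if (length(false_peaks)) max(false_peaks) + 1 else 0
  lost <- m$peak_intensity[m$confirmed] <= value
  if (any(lost))
    warning(sprintf(paste0("%d confirmed particle(s) fall at or below the ",
                           "calibrated threshold (%g) and would be removed"),
                    sum(lost), value))
  structure(list(value = value, provenance = false_peaks),
            class = "detection_threshold")
}

#' @export
print.detection_threshold <- function(x, ...) {
  cat(sprintf("<detection_threshold> %g counts (from %d false detection(s))\n",
              x$value, length(x$provenance)))
  invisible(x)
}

#' Segment particles above the calibrated threshold
#'
#' Pixels strictly above the threshold are foreground (ties are background);
#' 8-connected components below the minimum equivalent diameter are discarded.
#'
#' @param ti_map survey `elemental_map`.
#' @param threshold a `detection_threshold` or a bare numeric (counts).
#' @param min_diameter_um minimum equivalent-circle diameter retained.
#' @return object of class `particle_segmentation`: `labels` (integer matrix,
#'   0 background, 1..n particles), `regions` (list of pixel linear indices),
#'   `pixel_size_um`, `origin_um`, `threshold`.
#' @export
segment_particles <- function(ti_map, threshold, min_diameter_um = 1.5) {
  validate_elemental_map(ti_map)
  thr <- if (inherits(threshold, "detection_threshold")) threshold$value else threshold
  mask <- ti_map$counts > thr
  lab <- label_components_8(mask)
  n <- max(lab)
  regions <- list()
  out_lab <- matrix(0L, nrow(lab), ncol(lab))
  keep <- 0L
  if (n > 0) {
    px2 <- ti_map$pixel_size_um^2
    idx_by <- split(seq_along(lab)[lab > 0], lab[lab > 0])
    for (k in seq_len(n)) {
      reg <- idx_by[[as.character(k)]]
      eq_d <- 2 * sqrt(length(reg) * px2 / pi)
      if (eq_d >= min_diameter_um) {
        keep <- keep + 1L
        out_lab[reg] <- keep
        regions[[keep]] <- reg
      }
    }
  }
  structure(list(labels = out_lab, regions = regions,
                 pixel_size_um = ti_map$pixel_size_um,
                 origin_um = ti_map$origin_um, threshold = thr),
            class = "particle_segmentation")
}

#' @export
print.particle_segmentation <- function(x, ...) {
  cat(sprintf("<particle_segmentation> %d region(s) above threshold %g\n",
              length(x$regions), x$threshold))
  invisible(x)
}

#' Background-free map
#'
#' Survey counts retained on segmented foreground, zero elsewhere.
#' @param ti_map survey `elemental_map`.
#' @param seg a `particle_segmentation` on the same grid.
#' @return an `elemental_map`.
#' @export
background_free_map <- function(ti_map, seg) {
  counts <- ti_map$counts
  counts[seg$labels == 0L] <- 0
  elemental_map(counts, ti_map$element, ti_map$pixel_size_um,
                ti_map$fluence_nc_mm2, ti_map$origin_um)
}
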