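# Independent brute-force oracles, deliberately implemented differently from
# the package code paths they check.

# Signed-rank two-sided p by explicit enumeration of every sign pattern.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}

# Mann-Whitney two-sided p by enumeration of all group labelings (tie-free).
oracle_mann_whitney_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_all <- apply(utils::combn(n, na), 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

# Dense-sampling point-to-polyline distance (1 um steps along each segment).
oracle_polyline_distance <- function(px, py, polyline, step = 1) {
  best <- Inf
  for (i in seq_len(nrow(polyline) - 1)) {
    p1 <- polyline[i, ]; p2 <- polyline[i + 1, ]
    len <- sqrt(sum((p2 - p1)^2))
    ts <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
    sx <- p1[1] + ts * (p2[1] - p1[1])
    sy <- p1[2] + ts * (p2[2] - p1[2])
    best <- min(best, sqrt((sx - px)^2 + (sy - py)^2))
  }
  best
}

# Pixel-mask Jaccard overlap of two polygons on a common grid.
polygon_jaccard <- function(a, b, pixel_size_um, nr, nc) {
  ma <- rasterize_polygon(a, nr, nc, pixel_size_um)
  mb <- rasterize_polygon(b, nr, nc, pixel_size_um)
  sum(ma & mb) / sum(ma | mb)
}
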