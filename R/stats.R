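# Per-ROI density metrics and the study-style statistics: paired Wilcoxon
# signed-rank, Mann-Whitney U, ordinary least squares on per-sample densities,
# and the mean-split Ti-high/Ti-low grouping.

#' Per-ROI metrics
#'
#' Volume is ROI area times section thickness; the volumetric density is the
#' particle count over that volume; the percent area is the summed particle
#' area over the ROI area.
#'
#' @param particles data.frame of particles assigned to this ROI (needs
#'   `area_um2`); may have zero rows.
#' @param roi_name label, e.g. `"entire"`, `"zone1"`.
#' @param area_mm2 ROI area.
#' @param thickness_um section thickness.
#' @return one-row data.frame: `roi_name`, `area_mm2`, `volume_mm3`,
#'   `n_particles`, `pct_area_particles`, `volumetric_density`.
#' @export
roi_metrics <- function(particles, roi_name, area_mm2, thickness_um) {
  stopifnot(area_mm2 >= 0, thickness_um > 0)
  n <- nrow(particles)
  if (area_mm2 == 0 && n > 0)
    stop("inconsistent assignment: particles in a zero-area ROI")
  volume <- area_mm2 * thickness_um / 1000
  pct <- if (area_mm2 > 0) 100 * sum(particles$area_um2) / (area_mm2 * 1e6) else 0
  data.frame(roi_name = roi_name, area_mm2 = area_mm2, volume_mm3 = volume,
             n_particles = n,
             pct_area_particles = pct,
             volumetric_density = if (volume > 0) n / volume else 0)
}

# Exact null distribution of the signed-rank statistic by enumeration of all
# 2^m sign patterns over the (mid-)ranks.
signed_rank_distribution <- function(ranks) {
  m <- length(ranks)
  w <- 0
  for (r in ranks) w <- as.vector(outer(w, c(0, r), "+"))
  w
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences of zero are dropped (configurable); absolute differences are
#' ranked with mid-ranks for ties; `W` is the sum of positive ranks. The
#' two-sided p-value is exact (full enumeration of the `2^m` sign patterns)
#' for `m <= exact_limit` non-zero pairs, and otherwise uses the
#' tie-corrected, continuity-corrected normal approximation (the correction
#' keeps the approximation within 0.02 of the exact p at the enumeration
#' boundary).
#'
#' @param x,y paired measurements, or differences in `x` with `y = NULL`.
#' @param exact_limit largest `m` for which the exact enumeration is used.
#' @param zero_method `"drop"` (convention used here) keeps only non-zero
#'   differences.
#' @return object of class `paired_test`: `n_pairs`, `m` (non-zero pairs),
#'   `statistic` (W), `p_value`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_limit = 12,
                                 zero_method = c("drop")) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) x else x - y
  stopifnot(length(d) >= 1)
  n_pairs <- length(d)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) stop("test undefined: all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (m <= exact_limit) {
    dist <- signed_rank_distribution(r)
    p <- min(1, 2 * min(mean(dist <= W + 1e-9), mean(dist >= W - 1e-9)))
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(n_pairs = n_pairs, m = m, statistic = W, p_value = p,
                 method = method), class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, m = %d non-zero of %d pairs, p = %.4g (%s)\n",
              x$statistic, x$m, x$n_pairs, x$p_value, x$method))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Mid-ranks for ties; `U` is reported for the first group. Exact p-value by
#' enumeration of all group labelings when `n_a + n_b <= exact_limit` and
#' there are no ties; tie-corrected, continuity-corrected normal
#' approximation otherwise. Fully tied data carry no ordering evidence and
#' give p = 1.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact_limit largest combined n for exact enumeration.
#' @return object of class `rank_sum_test`: `n_a`, `n_b`, `statistic` (U of
#'   group a), `p_value`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_limit = 12) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  if (n <= exact_limit && !has_ties) {
    combos <- utils::combn(n, na)
    Us <- apply(combos, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9)))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1  # all observations tied: no ordering evidence
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(n_a = na, n_b = nb, statistic = U, p_value = p,
                 method = method), class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U: U = %g (n = %d, %d), p = %.4g (%s)\n",
              x$statistic, x$n_a, x$n_b, x$p_value, x$method))
  invisible(x)
}

#' Group implant systems into the three analysis categories
#'
#' `Astra Osseospeed`, `Nobel TiUnite`, and `Others`, by pattern match on the
#' system/surface string.
#'
#' @param system character vector of implant system/surface labels.
#' @return factor with the three levels (alphabetical; `Astra Osseospeed`
#'   is the reference under treatment coding).
#' @export
recode_implant_system <- function(system) {
  out <- rep("Others", length(system))
  out[grepl("osseospeed", system, ignore.case = TRUE)] <- "Astra Osseospeed"
  out[grepl("tiunite", system, ignore.case = TRUE)] <- "Nobel TiUnite"
  factor(out, levels = c("Astra Osseospeed", "Nobel TiUnite", "Others"))
}

#' Linear regression of volumetric density on sample covariates
#'
#' Ordinary least squares with treatment (dummy) coding of categorical
#' predictors; the reference level is the first alphabetically unless the
#' variable is already a factor with explicit levels.
#'
#' @param data per-sample data.frame (one row per specimen).
#' @param formula model formula, e.g.
#'   `volumetric_density ~ implant_system + years_in_function`.
#' @return object of class `regression_result`: `coefficients` data.frame
#'   (estimate, 95% CI, p per term), `reference_levels`, `n`, and the
#'   underlying `fit`.
#' @export
density_regression <- function(data, formula) {
  data <- as.data.frame(data)
  chr <- vapply(data, is.character, TRUE)
  data[chr] <- lapply(data[chr], factor)
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  n <- stats::nobs(fit)
  if (n <= length(stats::coef(fit)))
    stop("fewer observations than parameters")
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      p_value = sm[, 4], row.names = NULL)
  facs <- Filter(is.factor, stats::model.frame(fit)[-1])
  refs <- vapply(facs, function(f) levels(f)[1], "")
  structure(list(coefficients = coefs, reference_levels = refs, n = n,
                 fit = fit), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS on %d samples:\n", x$n))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Mean-split Ti-high / Ti-low grouping
#'
#' The threshold is the arithmetic mean of the supplied per-sample densities
#' (or an explicit override). A sample is `Ti-high` when its density strictly
#' exceeds the threshold; equality goes to `Ti-low`.
#'
#' @param densities named (or unnamed) numeric vector of per-sample
#'   volumetric densities (particles/mm^3), length >= 2.
#' @param threshold optional explicit threshold; default `mean(densities)`.
#' @return data.frame: `sample_id`, `density`, `label`, `threshold`.
#' @export
split_ti_groups <- function(densities, threshold = NULL) {
  stopifnot(length(densities) >= 2)
  thr <- if (is.null(threshold)) mean(densities) else threshold
  ids <- names(densities) %||% as.character(seq_along(densities))
  data.frame(sample_id = ids, density = as.numeric(densities),
             label = ifelse(densities > thr, "Ti-high", "Ti-low"),
             threshold = thr)
}
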