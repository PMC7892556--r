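# Quantification of shear-wave-elastography stiffness maps: ROI statistics,
# replicate averaging, percent-of-area histograms, radial-gradient analysis,
# soft/stiff classification and stiffness-growth correlation.

#' Young's modulus from shear-wave speed
#'
#' For soft, nearly incompressible, isotropic tissue of constant density rho,
#' the Young's modulus is `E = 3 * rho * vs^2`, reported in kPa.
#'
#' @param vs shear-wave speed in m/s (>= 0).
#' @param rho tissue density in kg/m^3 (> 0). No default: the conversion is
#'   only defined once a density is assumed explicitly.
#' @return Young's modulus in kPa.
#' @export
young_modulus_from_shear_speed <- function(vs, rho) {
  if (any(vs < 0)) stop("shear-wave speed must be non-negative")
  if (any(rho <= 0)) stop("density must be positive")
  3 * rho * vs^2 / 1000
}

#' ROI summary statistics
#'
#' Minimum, maximum, mean and sample standard deviation (n - 1) of the
#' stiffness values inside an ROI.
#'
#' @param map a `stiffness_map`.
#' @param roi a `tumor_roi`.
#' @return named list `min`, `max`, `mean`, `sd` (kPa).
#' @export
summarize_roi <- function(map, roi) {
  stopifnot(inherits(map, "stiffness_map"), inherits(roi, "tumor_roi"))
  v <- map$values[roi$pixel_idx]
  if (length(v) == 0) stop("empty ROI")
  list(min = min(v), max = max(v), mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else 0)
}

#' Pick the representative frame of a cine loop
#'
#' The frame with the least coupling-gel signal: gel is not supposed to carry
#' any shear-wave signal, so gel-region stiffness is noise. Ties go to the
#' lowest index.
#'
#' @param frames list of `stiffness_map`.
#' @param gel_mask logical matrix marking gel pixels.
#' @return integer frame index.
#' @export
select_representative_frame <- function(frames, gel_mask) {
  if (length(frames) == 0) stop("empty frame list")
  stopifnot(is.logical(gel_mask), any(gel_mask))
  gel_means <- vapply(frames, function(f) mean(f$values[gel_mask]), numeric(1))
  which.min(gel_means)  # which.min returns the first minimum
}

#' Noise floor from coupling-gel pixels
#'
#' 95th percentile (linear interpolation) of gel-pixel stiffness; used for
#' frame quality control only, never to censor tumor pixels.
#'
#' @param gel_values numeric vector of gel-pixel stiffness (kPa), >= 30 values.
#' @param probs percentile, default 0.95.
#' @return threshold in kPa.
#' @export
estimate_noise_floor <- function(gel_values, probs = 0.95) {
  if (length(gel_values) < 30) stop("need at least 30 gel pixels")
  unname(stats::quantile(gel_values, probs = probs, type = 7))
}

#' Mean tumor stiffness of an acquisition set
#'
#' Unweighted mean of the per-replicate ROI means, mirroring the averaging of
#' the mean stiffness over the repeated acquisitions at each timepoint.
#'
#' @param acq an `acquisition_set`.
#' @return mean stiffness in kPa.
#' @export
mean_tumor_stiffness <- function(acq) {
  stopifnot(inherits(acq, "acquisition_set"))
  if (length(acq$maps) == 0) stop("zero replicates")
  means <- mapply(function(m, r) summarize_roi(m, r)$mean,
                  acq$maps, acq$rois)
  mean(means)
}

#' Caliper tumor volume
#'
#' `V = a * b^2 / 2` with `a` the major and `b` the minor diameter. Axes must
#' be ordered by the caller; a < b is an error, not silently swapped.
#'
#' @param a major diameter (mm).
#' @param b minor diameter (mm).
#' @return volume in mm^3.
#' @export
caliper_volume <- function(a, b) {
  if (any(b <= 0)) stop("diameters must be positive")
  if (any(a < b)) stop("major diameter a must be >= minor diameter b")
  a * b^2 / 2
}

#' Percent-of-area stiffness histogram
#'
#' Right-open 1-kPa bins over [0, 200); the final bin absorbs values >= 200.
#' Counts are expressed as percentages of the ROI area rather than raw bin
#' counts, compensating for the growing pixel number as tumors grow.
#'
#' @param map a `stiffness_map`.
#' @param roi a `tumor_roi`.
#' @param bin_width bin width in kPa.
#' @param range histogram support (kPa).
#' @return data.frame with `lower`, `upper`, `percent`; percentages sum to 100.
#' @export
stiffness_histogram <- function(map, roi, bin_width = 1, range = c(0, 200)) {
  v <- map$values[roi$pixel_idx]
  if (length(v) == 0) stop("empty ROI")
  edges <- seq(range[1], range[2], by = bin_width)
  idx <- pmin(pmax(floor((v - range[1]) / bin_width), 0),
              length(edges) - 2) + 1L
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(lower = edges[-length(edges)],
             upper = edges[-1],
             percent = 100 * counts / length(v))
}

#' Center-to-edge stiffness decrease
#'
#' Ordinary least-squares fit of pixel stiffness on normalized radius; the
#' decrease is the fitted drop across r_norm 0 -> 1, i.e. minus the slope.
#' Unbiased for a linear radial profile and uses every ROI pixel.
#'
#' @param records data.frame from [radial_records()].
#' @return decrease in kPa.
#' @export
center_to_edge_decrease <- function(records) {
  x <- records$r_norm
  y <- records$stiffness_kpa
  if (length(x) < 30) stop("need at least 30 radial records")
  vx <- stats::var(x)
  if (vx < 1e-12) stop("degenerate design: all r_norm equal")
  if (diff(range(x)) < 0.5)
    warning("r_norm spread below 0.5; extrapolated decrease is unreliable")
  -stats::cov(x, y) / vx
}

#' Spearman rank correlation with a large-sample p-value
#'
#' Average ranks for ties; two-sided p from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors (>= 3 finite pairs).
#' @return list `rho`, `p`, `n`, and `degenerate` (TRUE when x or y is
#'   constant, in which case rho and p are NA).
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite values")
  if (stats::var(x) < 1e-15 || stats::var(y) < 1e-15) {
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

#' Soft/stiff tumor classification
#'
#' Soft below the cut, stiff at or above it. The default 40 kPa cut on mean
#' tumor stiffness separates all reported soft (<= 31.8 kPa) and stiff
#' (>= 42.5 kPa) removal ranges; the boundary value itself is labeled stiff.
#'
#' @param mean_kpa mean tumor stiffness (kPa), finite and >= 0.
#' @param cut_kpa classification cut (kPa).
#' @return character vector of `"soft"` / `"stiff"` labels.
#' @export
classify_soft_stiff <- function(mean_kpa, cut_kpa = 40) {
  if (any(!is.finite(mean_kpa)) || any(mean_kpa < 0))
    stop("mean stiffness must be finite and non-negative")
  ifelse(mean_kpa < cut_kpa, "soft", "stiff")
}

#' Cohort-level stiffness-growth correlation
#'
#' Spearman correlation over all (mean stiffness, area) measurement pairs of
#' one model, pooled across tumors: each measurement of a tumor at one
#' timepoint is one point.
#'
#' @param measurements data.frame with columns `mean_kpa` and `area_mm2`
#'   (extra columns such as `tumor_id`, `day` are carried but unused).
#' @return as [spearman()].
#' @export
cohort_stiffness_growth_correlation <- function(measurements) {
  stopifnot(all(c("mean_kpa", "area_mm2") %in% names(measurements)))
  spearman(measurements$mean_kpa, measurements$area_mm2)
}

#' Tumor growth rate
#'
#' OLS slope of area on day over a longitudinal series.
#'
#' @param day acquisition days, strictly increasing.
#' @param area_mm2 areas (mm^2).
#' @return growth rate in mm^2/day.
#' @export
growth_rate <- function(day, area_mm2) {
  if (length(day) < 2) stop("need at least 2 timepoints")
  if (any(diff(day) <= 0)) stop("days must be strictly increasing")
  stats::cov(day, area_mm2) / stats::var(day)
}

#' Two-group comparison wrappers
#'
#' Thin wrappers with a fixed two-sided convention around the standard tests
#' used for cohort summaries: Welch's t and Mann-Whitney.
#'
#' @param x,y numeric group vectors.
#' @return list `statistic`, `p`.
#' @export
welch_t <- function(x, y) {
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' @rdname welch_t
#' @export
mann_whitney <- function(x, y) {
  ht <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}
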