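# Synthetic shear-wave-elastography phantoms: longitudinal elliptical tumors
# with a center-to-edge stiffness gradient on a soft coupling-gel background,
# emitted together with a ground-truth record for parameter-recovery tests.

#' Stiffness-phantom preset
#'
#' The three presets emulate the stiffness regimes of the xenograft models:
#' a Mesenchymal tumor that stiffens at its core as it grows
#' (`mesenchymal_stiff`), a Mesenchymal tumor that stays soft
#' (`mesenchymal_soft`), and a Non-Mesenchymal tumor that stays soft
#' (`non_mesenchymal`). Soft presets are radially flat; the stiff preset
#' develops a linear center-to-edge gradient whose amplitude is coupled to
#' relative area growth.
#'
#' @param name one of `"mesenchymal_stiff"`, `"mesenchymal_soft"`,
#'   `"non_mesenchymal"`.
#' @param ... overrides for any preset field: `center_kpa`, `edge_kpa`,
#'   `pixel_noise_sd`, `clip_range`, `gel_mean`, `gel_sd`, `growth`
#'   (list with `area0_mm2`, `area_final_mm2`, `n_timepoints`, `model`),
#'   `stiffness_coupling`, `radial_exponent`.
#' @return a validated list of class `swe_preset`.
#' @export
swe_preset <- function(name = c("mesenchymal_stiff", "mesenchymal_soft",
                                "non_mesenchymal"), ...) {
  name <- match.arg(name)
  growth_default <- list(area0_mm2 = 30, area_final_mm2 = 120,
                         n_timepoints = 10L, model = "exponential")
  base <- switch(name,
    mesenchymal_stiff = list(center_kpa = 120, edge_kpa = 40,
                             pixel_noise_sd = 6, clip_range = c(0, 200),
                             stiffness_coupling = 1),
    mesenchymal_soft  = list(center_kpa = 18, edge_kpa = 18,
                             pixel_noise_sd = 6, clip_range = c(0, 40),
                             stiffness_coupling = 0),
    non_mesenchymal   = list(center_kpa = 22, edge_kpa = 22,
                             pixel_noise_sd = 6, clip_range = c(0, 40),
                             stiffness_coupling = 0))
  p <- c(list(name = name), base,
         list(gel_mean = 3, gel_sd = 1.5, growth = growth_default,
              radial_exponent = 1))
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), c(names(p), "growth"))
    if (length(unknown)) stop("unknown preset fields: ",
                              paste(unknown, collapse = ", "))
    if (!is.null(dots$growth)) {
      p$growth[names(dots$growth)] <- dots$growth
      dots$growth <- NULL
    }
    p[names(dots)] <- dots
  }
  validate_swe_preset(p)
  class(p) <- "swe_preset"
  p
}

validate_swe_preset <- function(p) {
  with(p, {
    if (!(center_kpa >= edge_kpa && edge_kpa >= 0))
      stop("preset invariant violated: need center_kpa >= edge_kpa >= 0")
    if (clip_range[1] > edge_kpa) stop("clip lower bound exceeds edge_kpa")
    if (clip_range[2] < center_kpa) stop("clip upper bound below center_kpa")
    if (growth$n_timepoints < 2) stop("growth must have >= 2 timepoints")
    if (growth$area0_mm2 <= 0 || growth$area_final_mm2 < growth$area0_mm2)
      stop("growth areas must be positive and non-decreasing")
    if (stiffness_coupling < 0 || stiffness_coupling > 1)
      stop("stiffness_coupling must be in [0, 1]")
    if (pixel_noise_sd < 0 || gel_sd < 0 || gel_mean < 0)
      stop("noise parameters must be non-negative")
  })
  invisible(p)
}

# Tumor area (mm^2) prescribed by the preset growth model at a 1-based
# timepoint, and the relative growth fraction in [0, 1].
growth_area <- function(preset, timepoint) {
  g <- preset$growth
  stopifnot(timepoint >= 1, timepoint <= g$n_timepoints)
  f <- (timepoint - 1) / (g$n_timepoints - 1)
  area <- switch(g$model,
    linear = g$area0_mm2 + (g$area_final_mm2 - g$area0_mm2) * f,
    exponential = g$area0_mm2 * (g$area_final_mm2 / g$area0_mm2)^f,
    stop("unknown growth model: ", g$model))
  relg <- if (g$area_final_mm2 > g$area0_mm2) {
    (area - g$area0_mm2) / (g$area_final_mm2 - g$area0_mm2)
  } else 0
  list(area_mm2 = area, rel_growth = relg)
}

# Core stiffness at a timepoint: interpolates from edge_kpa toward center_kpa
# as stiffness_coupling scales relative area growth.
center_stiffness_at <- function(preset, timepoint) {
  relg <- growth_area(preset, timepoint)$rel_growth
  preset$edge_kpa + (preset$center_kpa - preset$edge_kpa) *
    (1 - preset$stiffness_coupling * (1 - relg))
}

#' Generate one synthetic stiffness map
#'
#' Renders an elliptical tumor (random axis ratio in [0.7, 1] and random
#' orientation, both derived from the tumor-level seed so the same tumor
#' keeps its shape across timepoints and replicates) whose area follows the
#' preset growth model. Pixel stiffness inside the contour is
#' `edge + (center_t - edge) * (1 - r_norm^exponent)` plus Gaussian noise,
#' clipped to the preset clip range; pixels outside are coupling-gel draws
#' `N(gel_mean, gel_sd)` truncated at 0. Bit-for-bit reproducible from
#' `(preset, timepoint, replicate, seed)`.
#'
#' @param preset a `swe_preset`.
#' @param timepoint 1-based timepoint index (<= `growth$n_timepoints`).
#' @param seed integer seed identifying the tumor.
#' @param replicate replicate acquisition index (changes only the noise).
#' @param map_size map side in pixels.
#' @param pixel_spacing_mm pixel spacing (mm/px).
#' @return list with `map` (a `stiffness_map`), `roi` (a `tumor_roi`) and
#'   `truth` (one-row data.frame of ground-truth values).
#' @export
generate_stiffness_map <- function(preset, timepoint, seed, replicate = 1L,
                                   map_size = 256L, pixel_spacing_mm = 0.1) {
  validate_swe_preset(preset)
  ga <- growth_area(preset, timepoint)
  if (ga$area_mm2 <= 0) stop("non-positive tumor area")
  # tumor-level geometry: fixed across timepoints and replicates
  geo <- withr::with_seed(mix_seed(seed, 101), {
    list(q = stats::runif(1, 0.7, 1.0), theta = stats::runif(1, 0, pi))
  })
  a_mm <- sqrt(ga$area_mm2 / (pi * geo$q))   # semi-major (mm)
  b_mm <- geo$q * a_mm                       # semi-minor (mm)
  if (a_mm / pixel_spacing_mm > map_size / 2 - 4)
    stop("tumor does not fit in the field of view")
  c0 <- (map_size - 1) / 2
  phi <- seq(0, 2 * pi, length.out = 129L)[-129L]
  ca <- cos(geo$theta); sa <- sin(geo$theta)
  vx <- (a_mm * cos(phi) * ca - b_mm * sin(phi) * sa) / pixel_spacing_mm + c0
  vy <- (a_mm * cos(phi) * sa + b_mm * sin(phi) * ca) / pixel_spacing_mm + c0
  contour <- cbind(x = vx, y = vy)
  roi <- tumor_roi(contour, c(map_size, map_size))

  # analytic normalized elliptical radius at the ROI pixels
  dx <- (roi$pixels[, 1] - c0) * pixel_spacing_mm
  dy <- (roi$pixels[, 2] - c0) * pixel_spacing_mm
  u <- (dx * ca + dy * sa) / a_mm
  v <- (-dx * sa + dy * ca) / b_mm
  r <- sqrt(u * u + v * v)

  center_t <- center_stiffness_at(preset, timepoint)
  profile <- preset$edge_kpa +
    (center_t - preset$edge_kpa) * (1 - r^preset$radial_exponent)

  n <- map_size * map_size
  values <- withr::with_seed(mix_seed(seed, timepoint, replicate), {
    gel <- pmax(0, stats::rnorm(n, preset$gel_mean, preset$gel_sd))
    noise <- stats::rnorm(length(profile), 0, preset$pixel_noise_sd)
    m <- matrix(gel, map_size, map_size)
    m[roi$pixel_idx] <- pmin(pmax(profile + noise, preset$clip_range[1]),
                             preset$clip_range[2])
    m
  })
  gel_mask <- matrix(TRUE, map_size, map_size)
  gel_mask[roi$pixel_idx] <- FALSE

  k <- preset$radial_exponent
  truth <- data.frame(
    preset = preset$name,
    timepoint = as.integer(timepoint),
    replicate = as.integer(replicate),
    seed = as.integer(seed),
    true_area_mm2 = tumor_area(roi, pixel_spacing_mm),
    model_area_mm2 = ga$area_mm2,
    # disk average of the radial profile: E[1 - r^k] = 1 - 2/(k + 2)
    true_mean_kpa = preset$edge_kpa +
      (center_t - preset$edge_kpa) * (1 - 2 / (k + 2)),
    true_center_kpa = center_t,
    true_center_to_edge_decrease = center_t - preset$edge_kpa,
    stringsAsFactors = FALSE)

  list(map = stiffness_map(values, pixel_spacing_mm, gel_mask = gel_mask,
                           frame_id = sprintf("%s_s%d_t%02d_r%d", preset$name,
                                              seed, timepoint, replicate)),
       roi = roi,
       truth = truth)
}

#' Replicate acquisitions of one tumor at one timepoint
#'
#' @param maps list of `stiffness_map` replicates.
#' @param rois list of matching `tumor_roi` (one per replicate).
#' @param timepoint_days acquisition day.
#' @return an `acquisition_set`.
#' @export
acquisition_set <- function(maps, rois, timepoint_days) {
  stopifnot(length(maps) >= 1, length(maps) == length(rois))
  sp <- vapply(maps, function(m) m$pixel_spacing_mm, numeric(1))
  if (length(unique(sp)) != 1) stop("replicates differ in pixel spacing")
  structure(list(maps = maps, rois = rois,
                 timepoint_days = timepoint_days),
            class = "acquisition_set")
}

#' Generate a longitudinal growth series for one tumor
#'
#' One tumor followed over all preset timepoints, with `n_replicates`
#' acquisitions per timepoint that differ only in their noise realization
#' (probe repositioning is not simulated). Acquisition days are spaced
#' `days_between` apart, emulating twice-weekly imaging.
#'
#' @param preset a `swe_preset`.
#' @param n_replicates replicate acquisitions per timepoint (>= 1).
#' @param seed integer tumor seed.
#' @param days_between days between consecutive timepoints.
#' @inheritParams generate_stiffness_map
#' @return list with `timepoints` (list of `acquisition_set`) and `truth`
#'   (data.frame, one row per timepoint).
#' @export
generate_growth_series <- function(preset, n_replicates = 3L, seed,
                                   days_between = 3.5, map_size = 256L,
                                   pixel_spacing_mm = 0.1) {
  stopifnot(n_replicates >= 1)
  nt <- preset$growth$n_timepoints
  timepoints <- vector("list", nt)
  truth <- vector("list", nt)
  for (t in seq_len(nt)) {
    reps <- lapply(seq_len(n_replicates), function(r) {
      generate_stiffness_map(preset, t, seed, replicate = r,
                             map_size = map_size,
                             pixel_spacing_mm = pixel_spacing_mm)
    })
    timepoints[[t]] <- acquisition_set(
      maps = lapply(reps, `[[`, "map"),
      rois = lapply(reps, `[[`, "roi"),
      timepoint_days = (t - 1) * days_between)
    tr <- reps[[1]]$truth
    tr$replicate <- NULL
    tr$timepoint_days <- (t - 1) * days_between
    truth[[t]] <- tr
  }
  list(timepoints = timepoints, truth = do.call(rbind, truth))
}
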