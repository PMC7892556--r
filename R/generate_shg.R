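# Synthetic SHG fiber fields: smooth random polylines rendered with a
# Gaussian cross-section whose full width at half maximum equals the nominal
# fiber thickness, distributed over z-slices, with full per-fiber truth.

# Distance from grid pixels to one segment, accumulated as Gaussian intensity.
render_segment <- function(img, x1, y1, x2, y2, sigma_px, amp = 1) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- ceiling(3 * sigma_px) + 1L
  xlo <- max(0L, floor(min(x1, x2)) - pad); xhi <- min(nc - 1L, ceiling(max(x1, x2)) + pad)
  ylo <- max(0L, floor(min(y1, y2)) - pad); yhi <- min(nr - 1L, ceiling(max(y1, y2)) + pad)
  if (xhi < xlo || yhi < ylo) return(img)
  gx <- rep(xlo:xhi, times = yhi - ylo + 1L)
  gy <- rep(ylo:yhi, each = xhi - xlo + 1L)
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  tt <- if (l2 > 0) pmin(pmax(((gx - x1) * dx + (gy - y1) * dy) / l2, 0), 1) else 0
  dist <- sqrt((gx - (x1 + tt * dx))^2 + (gy - (y1 + tt * dy))^2)
  val <- amp * exp(-dist^2 / (2 * sigma_px^2))
  idx <- gx * nr + gy + 1L
  img[idx] <- pmax(img[idx], val)
  img
}

# One smooth random polyline of the requested arc length, inside the margin.
random_polyline <- function(length_px, field_px, margin_px, curvature_sd,
                            max_tries = 100) {
  n_seg <- max(2L, round(length_px / 4))
  step <- length_px / n_seg
  for (try in seq_len(max_tries)) {
    x <- stats::runif(1, margin_px, field_px - 1 - margin_px)
    y <- stats::runif(1, margin_px, field_px - 1 - margin_px)
    ang <- stats::runif(1, 0, 2 * pi)
    pts <- matrix(NA_real_, n_seg + 1L, 2)
    pts[1, ] <- c(x, y)
    ok <- TRUE
    for (k in seq_len(n_seg)) {
      ang <- ang + stats::rnorm(1, 0, curvature_sd)
      x <- x + step * cos(ang); y <- y + step * sin(ang)
      if (x < margin_px || x > field_px - 1 - margin_px ||
          y < margin_px || y > field_px - 1 - margin_px) { ok <- FALSE; break }
      pts[k + 1L, ] <- c(x, y)
    }
    if (ok) return(pts)
  }
  stop("could not place a fiber inside the field of view")
}

polyline_length <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

# Dense sample points along a polyline (for the spacing check).
polyline_points <- function(pts, spacing = 1) {
  out <- list()
  for (k in seq_len(nrow(pts) - 1L)) {
    a <- pts[k, ]; b <- pts[k + 1L, ]
    L <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = max(2L, ceiling(L / spacing) + 1L))
    out[[k]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Generate a synthetic SHG z-stack with fiber ground truth
#'
#' Fibers are smooth random polylines with Gaussian cross-section (FWHM equal
#' to the nominal thickness), placed without mutual contact so that the
#' recovered fiber count is well defined, distributed across slices over a
#' low-amplitude background.
#'
#' @param n_fibers number of fibers (0 gives a blank stack and empty truth).
#' @param length_range_um fiber arc-length range (um).
#' @param thickness_range_um fiber thickness (FWHM) range (um).
#' @param pixel_size_um pixel size (um/px).
#' @param n_slices number of z slices.
#' @param field_px image side in pixels.
#' @param seed integer seed.
#' @param curvature_sd per-step direction jitter (radians); 0 gives straight
#'   fibers.
#' @param bg_sd background noise amplitude (fraction of fiber peak 1.0).
#' @param gap_px minimum clearance between fiber surfaces, in pixels.
#' @param z_step_um z spacing recorded in the stack metadata.
#' @return list with `stack` (rows x cols x slices array), `pixel_size_um`,
#'   `z_step_um` and `truth` (data.frame: `fiber_id`, `length_um`,
#'   `thickness_um`, `slice`; attribute `"vertices"` holds the polylines).
#' @export
generate_shg_image <- function(n_fibers, length_range_um = c(30, 60),
                               thickness_range_um = c(1, 2.5),
                               pixel_size_um = 0.5, n_slices = 5L,
                               field_px = 256L, seed = 1L,
                               curvature_sd = 0.12, bg_sd = 0.01,
                               gap_px = 4, z_step_um = 5) {
  stopifnot(all(length_range_um > 0), all(thickness_range_um > 0),
            pixel_size_um > 0, n_slices >= 1)
  margin_px <- 6
  if (max(length_range_um) / pixel_size_um > field_px - 2 * margin_px)
    stop("fiber longer than the field of view")
  withr::with_seed(mix_seed(seed, 301), {
    stack <- array(abs(stats::rnorm(field_px * field_px * n_slices, 0, bg_sd)),
                   dim = c(field_px, field_px, n_slices))
    if (n_fibers == 0) {
      truth <- data.frame(fiber_id = integer(0), length_um = numeric(0),
                          thickness_um = numeric(0), slice = integer(0))
      attr(truth, "vertices") <- list()
      return(list(stack = stack, pixel_size_um = pixel_size_um,
                  z_step_um = z_step_um, truth = truth))
    }
    polylines <- list()
    occupied <- NULL   # dense points of accepted fibers, with their half-width
    th_um <- numeric(n_fibers)
    sl <- integer(n_fibers)
    for (f in seq_len(n_fibers)) {
      th_um[f] <- stats::runif(1, thickness_range_um[1], thickness_range_um[2])
      len_um <- stats::runif(1, length_range_um[1], length_range_um[2])
      placed <- FALSE
      for (try in seq_len(400)) {
        pts <- random_polyline(len_um / pixel_size_um, field_px, margin_px,
                               curvature_sd)
        dense <- polyline_points(pts, spacing = 1)
        if (!is.null(occupied)) {
          dmin <- min(sqrt(outer(dense[, 1], occupied[, 1], `-`)^2 +
                           outer(dense[, 2], occupied[, 2], `-`)^2))
          # surfaces must clear by gap_px; when the field gets crowded the
          # clearance relaxes, but never below actual surface contact + 1 px
          gap_eff <- if (try <= 200) gap_px else max(1, gap_px / 2)
          need <- (th_um[f] + max(th_um[seq_len(f - 1)])) / (2 * pixel_size_um) +
            gap_eff
          if (dmin < need) next
        }
        polylines[[f]] <- pts
        occupied <- rbind(occupied, dense)
        placed <- TRUE
        break
      }
      if (!placed) stop("cannot place ", n_fibers, " non-contacting fibers")
      sl[f] <- sample.int(n_slices, 1)
      sigma_px <- (th_um[f] / pixel_size_um) / (2 * sqrt(2 * log(2)))
      for (k in seq_len(nrow(pts) - 1L)) {
        stack[, , sl[f]] <- render_segment(stack[, , sl[f]],
                                           pts[k, 1], pts[k, 2],
                                           pts[k + 1L, 1], pts[k + 1L, 2],
                                           sigma_px)
      }
    }
    truth <- data.frame(
      fiber_id = seq_len(n_fibers),
      length_um = vapply(polylines, polyline_length, numeric(1)) * pixel_size_um,
      thickness_um = th_um,
      slice = sl)
    attr(truth, "vertices") <- polylines
    list(stack = stack, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
         truth = truth)
  })
}
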