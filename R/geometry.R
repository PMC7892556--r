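# Geometry convention used throughout the package: pixel coordinates are
# 0-based, x to the right, y down, with vertices and pixel centers expressed
# at pixel-center positions. Matrices store values[y + 1, x + 1].

#' Stiffness map container
#'
#' A 2D raster of Young's modulus values (kPa) with its pixel spacing and an
#' optional gel (background) mask.
#'
#' @param values numeric matrix of stiffness values in kPa (rows = y).
#' @param pixel_spacing_mm pixel spacing in mm (square pixels).
#' @param gel_mask optional logical matrix, TRUE where the pixel is coupling
#'   gel rather than tissue.
#' @param frame_id optional identifier of the acquisition frame.
#' @return an object of class `stiffness_map`.
#' @export
stiffness_map <- function(values, pixel_spacing_mm, gel_mask = NULL,
                          frame_id = NA_character_) {
  stopifnot(is.matrix(values), all(is.finite(values)), all(values >= 0),
            is.numeric(pixel_spacing_mm), pixel_spacing_mm > 0)
  if (!is.null(gel_mask)) {
    stopifnot(is.logical(gel_mask), identical(dim(gel_mask), dim(values)))
  }
  structure(list(values = values,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 gel_mask = gel_mask,
                 frame_id = frame_id),
            class = "stiffness_map")
}

#' @export
print.stiffness_map <- function(x, ...) {
  cat(sprintf("<stiffness_map> %d x %d px, %.3g mm/px, range %.1f-%.1f kPa\n",
              nrow(x$values), ncol(x$values), x$pixel_spacing_mm,
              min(x$values), max(x$values)))
  invisible(x)
}

# Single-point even-odd test with an explicit on-boundary check.
point_in_polygon <- function(px, py, contour, eps = 1e-9) {
  xs <- contour[, 1]; ys <- contour[, 2]
  m <- nrow(contour)
  inside <- FALSE
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    xa <- xs[i]; ya <- ys[i]; xb <- xs[j]; yb <- ys[j]
    # on-segment?
    dx <- xb - xa; dy <- yb - ya; l2 <- dx * dx + dy * dy
    tt <- if (l2 > 0) ((px - xa) * dx + (py - ya) * dy) / l2 else 0
    tt <- min(max(tt, 0), 1)
    if (abs(px - (xa + tt * dx)) < eps && abs(py - (ya + tt * dy)) < eps) {
      return(FALSE)  # boundary points are excluded by convention
    }
    if ((ya > py) != (yb > py)) {
      xint <- xa + (py - ya) / (yb - ya) * (xb - xa)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

#' Pixels whose centers fall strictly inside a polygon
#'
#' Even-odd rule; pixel centers lying on the contour itself are excluded.
#' This is the single pixel-inclusion convention used by every module.
#'
#' @param contour numeric m x 2 matrix of polygon vertices `(x, y)` in 0-based
#'   pixel-center coordinates; the polygon is implicitly closed.
#' @param shape integer vector `c(n_rows, n_cols)` of the pixel grid.
#' @return integer n x 2 matrix of interior pixel centers, columns `x`, `y`.
#' @export
pixels_in_contour <- function(contour, shape) {
  contour <- as.matrix(contour)
  stopifnot(ncol(contour) == 2, nrow(contour) >= 3, all(is.finite(contour)))
  xs <- contour[, 1]; ys <- contour[, 2]
  area2 <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys))
  if (area2 < 1e-12) stop("degenerate polygon: zero area")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  x0 <- max(0L, as.integer(floor(min(xs)))); x1 <- min(nc - 1L, as.integer(ceiling(max(xs))))
  y0 <- max(0L, as.integer(floor(min(ys)))); y1 <- min(nr - 1L, as.integer(ceiling(max(ys))))
  if (x1 < x0 || y1 < y0) stop("contour lies outside the pixel grid")
  gx <- rep(x0:x1, times = y1 - y0 + 1L)
  gy <- rep(y0:y1, each = x1 - x0 + 1L)
  inside <- logical(length(gx))
  onedge <- logical(length(gx))
  m <- nrow(contour)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    xa <- xs[i]; ya <- ys[i]; xb <- xs[j]; yb <- ys[j]
    crosses <- (ya > gy) != (yb > gy)
    if (any(crosses)) {
      xint <- xa + (gy - ya) / (yb - ya) * (xb - xa)
      inside <- xor(inside, crosses & (gx < xint))
      onedge <- onedge | (crosses & abs(gx - xint) < 1e-9)
    }
    dx <- xb - xa; dy <- yb - ya; l2 <- dx * dx + dy * dy
    if (l2 > 0) {
      tt <- pmin(pmax(((gx - xa) * dx + (gy - ya) * dy) / l2, 0), 1)
      onedge <- onedge | (abs(gx - (xa + tt * dx)) < 1e-9 &
                          abs(gy - (ya + tt * dy)) < 1e-9)
    }
  }
  keep <- inside & !onedge
  if (!any(keep)) stop("empty pixel set: the contour encloses no pixel centers")
  cbind(x = gx[keep], y = gy[keep])
}

#' Tumor region of interest
#'
#' Builds the derived pixel set and barycenter from a hand-drawn (or
#' generated) closed contour.
#'
#' @param contour m x 2 matrix of vertices `(x, y)`, 0-based pixel centers.
#' @param shape grid dimensions `c(n_rows, n_cols)` of the parent map.
#' @return an object of class `tumor_roi` with elements `contour`, `shape`,
#'   `pixels` (n x 2), `pixel_idx` (linear indices into the value matrix),
#'   `barycenter` (`c(x, y)`), and `barycenter_inside`.
#' @export
tumor_roi <- function(contour, shape) {
  pixels <- pixels_in_contour(contour, shape)
  bary <- colMeans(pixels)
  structure(list(contour = as.matrix(contour),
                 shape = as.integer(shape),
                 pixels = pixels,
                 pixel_idx = pixels[, 1] * as.integer(shape[1]) + pixels[, 2] + 1L,
                 barycenter = bary,
                 barycenter_inside = point_in_polygon(bary[1], bary[2],
                                                      as.matrix(contour))),
            class = "tumor_roi")
}

#' @export
print.tumor_roi <- function(x, ...) {
  cat(sprintf("<tumor_roi> %d px, barycenter (%.1f, %.1f)\n",
              nrow(x$pixels), x$barycenter[1], x$barycenter[2]))
  invisible(x)
}

#' ROI barycenter
#'
#' Unweighted centroid of the ROI pixel-center coordinates, the reference
#' point of all radial stiffness profiles.
#'
#' @param roi a `tumor_roi`.
#' @return numeric `c(x, y)` in pixel units.
#' @export
barycenter <- function(roi) {
  stopifnot(inherits(roi, "tumor_roi"), nrow(roi$pixels) > 0)
  colMeans(roi$pixels)
}

#' Tumor area from the ROI pixel set
#'
#' @param roi a `tumor_roi`.
#' @param pixel_spacing_mm pixel spacing in mm.
#' @return area in mm^2 (`|pixel set| * spacing^2`).
#' @export
tumor_area <- function(roi, pixel_spacing_mm) {
  stopifnot(inherits(roi, "tumor_roi"), nrow(roi$pixels) > 0,
            pixel_spacing_mm > 0)
  nrow(roi$pixels) * pixel_spacing_mm^2
}

# Normalized radius of every ROI pixel: distance to barycenter divided by the
# distance from the barycenter to the contour along the same ray. Falls back
# to d / d_max when the barycenter lies outside the polygon (non-convex ROI).
roi_normalized_radius <- function(roi, tol = 0.05) {
  px <- roi$pixels
  b <- roi$barycenter
  dx <- px[, 1] - b[1]
  dy <- px[, 2] - b[2]
  dpx <- sqrt(dx * dx + dy * dy)
  if (!roi$barycenter_inside) {
    warning("barycenter outside polygon; falling back to r_norm = d / d_max")
    return(list(d_px = dpx, r_norm = dpx / max(dpx), fallback = TRUE))
  }
  xs <- roi$contour[, 1]; ys <- roi$contour[, 2]
  m <- nrow(roi$contour)
  tmin <- rep(Inf, length(dpx))
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    ex <- xs[j] - xs[i]; ey <- ys[j] - ys[i]
    wx <- xs[i] - b[1]; wy <- ys[i] - b[2]
    det <- ex * dy - ey * dx            # per-pixel determinant of [d, -e]
    ok <- abs(det) > 1e-12
    tt <- (ex * wy - ey * wx) / det
    uu <- (dx * wy - dy * wx) / det
    valid <- ok & uu >= -1e-9 & uu <= 1 + 1e-9 & tt > 1e-9
    tmin[valid] <- pmin(tmin[valid], tt[valid])
  }
  r <- ifelse(dpx == 0, 0, 1 / tmin)
  if (any(!is.finite(r))) {
    # no ray-edge intersection found (should not happen for simple polygons)
    r[!is.finite(r)] <- dpx[!is.finite(r)] / max(dpx)
  }
  r <- pmin(r, 1 + tol)
  list(d_px = dpx, r_norm = r, fallback = FALSE)
}

#' Per-pixel radial records of a stiffness map
#'
#' For every ROI pixel: Euclidean distance to the barycenter (mm), the
#' normalized radius (0 at the barycenter, 1 on the contour along the ray
#' from the barycenter through the pixel) and the pixel stiffness.
#'
#' @param map a `stiffness_map`.
#' @param roi a `tumor_roi` on the same grid.
#' @return data.frame with columns `x`, `y`, `distance_mm`, `r_norm`,
#'   `stiffness_kpa`.
#' @export
radial_records <- function(map, roi) {
  stopifnot(inherits(map, "stiffness_map"), inherits(roi, "tumor_roi"),
            identical(dim(map$values), as.integer(roi$shape)))
  rad <- roi_normalized_radius(roi)
  data.frame(x = roi$pixels[, 1],
             y = roi$pixels[, 2],
             distance_mm = rad$d_px * map$pixel_spacing_mm,
             r_norm = rad$r_norm,
             stiffness_kpa = map$values[roi$pixel_idx])
}

#' Split an ROI into equal-area center and periphery
#'
#' Center pixels have normalized radius below 1/sqrt(2), which encloses half
#' the area of a disk; the periphery is the remainder. The two masks are
#' disjoint and their union is the ROI.
#'
#' @param roi a `tumor_roi`.
#' @return list with logical vectors `center` and `periphery` (aligned with
#'   `roi$pixels`), plus `center_idx` / `periphery_idx` linear indices.
#' @export
partition_center_periphery <- function(roi) {
  stopifnot(inherits(roi, "tumor_roi"))
  if (nrow(roi$pixels) < 8) stop("ROI too small to split (< 8 px)")
  rad <- roi_normalized_radius(roi)
  center <- rad$r_norm <= 1 / sqrt(2)
  list(center = center,
       periphery = !center,
       center_idx = roi$pixel_idx[center],
       periphery_idx = roi$pixel_idx[!center])
}
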