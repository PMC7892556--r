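# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and, where the package delegates to a stats:: routine, avoid
# that routine too) so that implementation and oracle can only agree by
# computing the same quantity.

bf_summary <- function(v) {
  n <- length(v)
  mn <- v[1]; mx <- v[1]; s <- 0
  for (x in v) { if (x < mn) mn <- x; if (x > mx) mx <- x; s <- s + x }
  mu <- s / n
  ss <- 0
  for (x in v) ss <- ss + (x - mu)^2
  list(min = mn, max = mx, mean = mu,
       sd = if (n > 1) sqrt(ss / (n - 1)) else 0)
}

# average ranks by explicit sorting
bf_rank <- function(x) {
  ord <- order(x)
  r <- numeric(length(x))
  i <- 1
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[ord[j + 1]] == x[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

bf_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

bf_spearman_rho <- function(x, y) bf_pearson(bf_rank(x), bf_rank(y))

# no-ties closed form 1 - 6 sum d^2 / (n (n^2 - 1))
bf_spearman_noties <- function(x, y) {
  d <- bf_rank(x) - bf_rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

bf_ols_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

bf_t_unpaired <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, p = 2 * pt(abs(tt), df = na + nb - 2, lower.tail = FALSE))
}

bf_t_paired <- function(a, b) {
  d <- a - b
  n <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(t = tt, p = 2 * pt(abs(tt), df = n - 1, lower.tail = FALSE))
}

# winding-angle point-in-polygon: independent of the crossing-count test
bf_inside_winding <- function(px, py, contour) {
  xs <- contour[, 1] - px
  ys <- contour[, 2] - py
  n <- nrow(contour)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(ys[i], xs[i])
    a2 <- atan2(ys[j], xs[j])
    da <- a2 - a1
    if (da > pi) da <- da - 2 * pi
    if (da < -pi) da <- da + 2 * pi
    total <- total + da
  }
  abs(total) > pi  # ~2*pi inside, ~0 outside
}

bf_arc_length <- function(pts) {
  s <- 0
  for (k in seq_len(nrow(pts) - 1)) {
    s <- s + sqrt(sum((pts[k + 1, ] - pts[k, ])^2))
  }
  s
}

bf_integrated_density <- function(img, mask, pixel_area) {
  s <- 0
  for (i in which(mask)) s <- s + img[i]
  s * pixel_area
}

# small square-contour helper: rectangle of pixel centers
rect_contour <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# circle contour of radius r (px) centered at (cx, cy)
disk_contour <- function(cx, cy, r, n = 96) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(phi), y = cy + r * sin(phi))
}

# a small preset whose tumors fit in tiny test maps
tiny_stiff_preset <- function(...) {
  swe_preset("mesenchymal_stiff",
             growth = list(area0_mm2 = 3, area_final_mm2 = 12,
                           n_timepoints = 5L), ...)
}

tiny_soft_preset <- function(name = "mesenchymal_soft", ...) {
  swe_preset(name,
             growth = list(area0_mm2 = 3, area_final_mm2 = 12,
                           n_timepoints = 5L), ...)
}
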