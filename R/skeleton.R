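# Binary-image thinning and skeleton path extraction used by the fiber
# morphometry stage. Zhang-Suen thinning (parallel, 2-subiteration) reduces a
# fiber mask to 8-connected one-pixel-wide lines; paths are then traced
# between endpoints, with short spurs pruned and junctions split.

# Shift a (padded) logical matrix by (dy, dx); pads with FALSE.
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
  oky <- ys >= 1 & ys <= nr; okx <- xs >= 1 & xs <= nc
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

# 8-neighbourhood in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW),
# with rows = y (down) and columns = x (right).
zs_neighbours <- function(m) {
  list(p2 = shift_mat(m, -1,  0), p3 = shift_mat(m, -1,  1),
       p4 = shift_mat(m,  0,  1), p5 = shift_mat(m,  1,  1),
       p6 = shift_mat(m,  1,  0), p7 = shift_mat(m,  1, -1),
       p8 = shift_mat(m,  0, -1), p9 = shift_mat(m, -1, -1))
}

#' Morphological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' @param mask logical matrix (TRUE = foreground).
#' @return logical matrix of the same shape, one-pixel-wide skeleton.
#' @export
thin_mask <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- mask > 0
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- zs_neighbours(m)
      b <- Reduce(`+`, nb)
      seq9 <- nb[c("p2", "p3", "p4", "p5", "p6", "p7", "p8", "p9", "p2")]
      a <- 0
      for (k in 1:8) a <- a + (!seq9[[k]] & seq9[[k + 1]])
      cond <- m & b >= 2 & b <= 6 & a == 1
      if (sub == 1) {
        cond <- cond & !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
      } else {
        cond <- cond & !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Count of 8-connected skeleton neighbours at every pixel.
neighbour_count <- function(m) {
  Reduce(`+`, zs_neighbours(m))
}

# Crossing number: 0 -> 1 transitions around the 8-neighbourhood. A pixel on
# a simple 8-connected curve has 2 (1 at an endpoint), so a true junction has
# >= 3 transitions; the raw neighbour count misfires on staircase pixels.
crossing_number <- function(m) {
  nb <- zs_neighbours(m)
  seq9 <- nb[c("p2", "p3", "p4", "p5", "p6", "p7", "p8", "p9", "p2")]
  a <- 0
  for (k in 1:8) a <- a + (!seq9[[k]] & seq9[[k + 1]])
  a
}

# 8-connected component labels of a logical matrix (small inputs: skeletons).
label8 <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nr <- nrow(m)
  idx_fg <- which(m)
  cur <- 0L
  for (start in idx_fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      y <- (p - 1L) %% nr + 1L
      x <- (p - 1L) %/% nr + 1L
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        yy <- y + dy; xx <- x + dx
        if (yy < 1 || yy > nr || xx < 1 || xx > ncol(m)) next
        q <- (xx - 1L) * nr + yy
        if (m[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Skeleton-true 8-neighbours of a linear index, minus excluded indices.
neighbours_of <- function(skel, p, exclude = integer(0)) {
  nr <- nrow(skel)
  y <- (p - 1L) %% nr + 1L
  x <- (p - 1L) %/% nr + 1L
  out <- integer(0)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    yy <- y + dy; xx <- x + dx
    if (yy < 1 || yy > nr || xx < 1 || xx > ncol(skel)) next
    q <- (xx - 1L) * nr + yy
    if (skel[q] && !(q %in% exclude)) out <- c(out, q)
  }
  out
}

# Remove skeleton spurs: branches shorter than prune_px that run from an
# endpoint into a junction. Iterated until stable (at most a few passes).
prune_spurs <- function(skel, prune_px = 3) {
  repeat {
    nb <- neighbour_count(skel)
    cn <- crossing_number(skel)
    endpoints <- which(skel & nb == 1)
    removed_any <- FALSE
    for (e in endpoints) {
      if (!skel[e]) next
      path <- integer(0)
      cur <- e
      hit_junction <- FALSE
      while (length(path) < prune_px) {
        if (cn[cur] >= 3) { hit_junction <- TRUE; break }
        path <- c(path, cur)
        nbrs <- neighbours_of(skel, cur, exclude = path)
        if (length(nbrs) == 0) break
        cur <- nbrs[[1]]
      }
      if (hit_junction && length(path) > 0 && length(path) < prune_px) {
        skel[path] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  skel
}

# Order the pixels of one junction-free skeleton component into a path.
trace_component <- function(skel, comp_idx) {
  nr <- nrow(skel)
  comp <- matrix(FALSE, nr, ncol(skel))
  comp[comp_idx] <- TRUE
  cn <- crossing_number(comp)
  endpoints <- comp_idx[cn[comp_idx] <= 1]
  start <- if (length(endpoints)) endpoints[[1]] else comp_idx[[1]]
  path <- integer(0)
  visited <- matrix(FALSE, nr, ncol(skel))
  cur <- start
  repeat {
    path <- c(path, cur)
    visited[cur] <- TRUE
    y <- (cur - 1L) %% nr + 1L; x <- (cur - 1L) %/% nr + 1L
    nxt <- 0L
    best <- 3L  # prefer 4-neighbours over diagonals for a cleaner chain
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- y + dy; xx <- x + dx
      if (yy < 1 || yy > nr || xx < 1 || xx > ncol(skel)) next
      q <- (xx - 1L) * nr + yy
      if (comp[q] && !visited[q]) {
        w <- abs(dy) + abs(dx)
        if (w < best) { best <- w; nxt <- q }
      }
    }
    if (nxt == 0L) break
    cur <- nxt
  }
  cbind(x = (path - 1L) %/% nr, y = (path - 1L) %% nr)  # 0-based (x, y)
}

#' Extract fiber paths from a skeleton
#'
#' Junction pixels (>= 3 skeleton neighbours) split the skeleton; spurs
#' shorter than `prune_px` are removed first, and remaining components
#' shorter than `prune_px` are dropped.
#'
#' @param skel logical skeleton matrix (from [thin_mask()]).
#' @param prune_px minimum branch length kept, in pixels.
#' @return list of n x 2 matrices of ordered 0-based `(x, y)` path pixels.
#' @export
skeleton_paths <- function(skel, prune_px = 3) {
  skel <- prune_spurs(skel, prune_px)
  junctions <- skel & crossing_number(skel) >= 3
  branches <- skel & !junctions
  lab <- label8(branches)
  paths <- list()
  for (k in seq_len(max(lab))) {
    comp_idx <- which(lab == k)
    if (length(comp_idx) < prune_px) next
    paths[[length(paths) + 1L]] <- trace_component(branches, comp_idx)
  }
  paths
}
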