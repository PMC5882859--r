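# Internal array helpers shared by the filtering and morphology code.
#
# All stacks are numeric 3D arrays indexed [z, y, x] (1-based internally).
# Public coordinates are 0-based voxel indices in (z, y, x) order; the
# conversion happens only at the seed/geometry surface, never inside the
# array code.

# Separable box maximum with half-widths (kz, ky, kx), window clipped at
# the borders (compiled sliding-window kernel).
box_max_3d <- function(a, kz, ky, kx) {
  storage.mode(a) <- "double"
  .box_filter_3d(a, dim(a), as.integer(c(kz, ky, kx)), TRUE)
}

# Separable box mean with half-width k on every axis; windows are clipped
# at the borders and average only the voxels present.
box_mean_3d <- function(a, k) {
  storage.mode(a) <- "double"
  k <- as.integer(k)
  .box_filter_3d(a, dim(a), c(k, k, k), FALSE)
}

# Binary dilation of a logical array by a box of half-width r (Chebyshev
# ball), via the separable running maximum on a 0/1 array.
dilate_box <- function(mask, r) {
  box_max_3d(array(as.numeric(mask), dim(mask)), r, r, r) > 0
}

# Integer histogram of a stack with values in [0, maxint].
int_hist <- function(v, maxint) {
  tabulate(as.integer(v) + 1L, nbins = maxint + 1L)
}

# Order statistic from an integer histogram: the value at rank r (1-based).
value_at_rank <- function(counts, r) {
  cs <- cumsum(counts)
  which(cs >= r)[1L] - 1L
}

# Label 26-connected components among marked voxels of a 3D grid.
# `lin` is a sorted vector of 1-based linear indices into an array of
# dimension `d`; returns an integer component label per entry of `lin`.
label_components_26 <- function(lin, d) {
  if (length(lin) == 0L) return(integer(0))
  .label26(as.numeric(lin), as.integer(d))
}

# Proper intersection test for two closed segments p1-p2 and p3-p4
# (2-vectors c(y, x)).  Shared endpoints do not count as a crossing.
segments_cross <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c) {
    v <- (b[2] - a[2]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[2] - a[2])
    sign(v)
  }
  d1 <- orient(p3, p4, p1)
  d2 <- orient(p3, p4, p2)
  d3 <- orient(p1, p2, p3)
  d4 <- orient(p1, p2, p4)
  (d1 != d2 && d3 != d4 && d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0)
}

# Does a polyline (n x 2 matrix, columns y,x) properly self-intersect?
polyline_self_intersects <- function(p) {
  ns <- nrow(p) - 1L
  if (ns < 3L) return(FALSE)
  for (i in seq_len(ns - 2L)) {
    for (j in seq(i + 2L, ns)) {
      if (segments_cross(p[i, ], p[i + 1L, ], p[j, ], p[j + 1L, ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Signed shoelace area of a polygon (n x 2 matrix, columns y,x), implicit
# closure between the last and first vertex.  Units: pixel^2.
shoelace_area <- function(p) {
  y <- p[, 1]; x <- p[, 2]
  yn <- c(y[-1], y[1]); xn <- c(x[-1], x[1])
  sum(x * yn - xn * y) / 2
}

# Minimum distance from point (py, px) to the segments of a polygon/polyline.
point_segment_dist <- function(py, px, p) {
  a <- p
  b <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  vy <- b[, 1] - a[, 1]; vx <- b[, 2] - a[, 2]
  wy <- py - a[, 1]; wx <- px - a[, 2]
  len2 <- vy^2 + vx^2
  t <- ifelse(len2 > 0, pmin(pmax((wy * vy + wx * vx) / len2, 0), 1), 0)
  dy <- wy - t * vy; dx <- wx - t * vx
  sqrt(min(dy^2 + dx^2))
}

# Even-odd ray-casting point-in-polygon (boundary handled by the caller
# through point_segment_dist).
point_in_polygon <- function(py, px, p) {
  n <- nrow(p)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    yi <- p[i, 1]; xi <- p[i, 2]
    yj <- p[j, 1]; xj <- p[j, 2]
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

`%||%` <- function(a, b) if (is.null(a)) b else a
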