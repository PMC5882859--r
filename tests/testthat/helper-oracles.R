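# Shared fixtures and independent oracles used across the suite.

# Wrap a numeric vector as a 1 x 1 x n image stack.
vec_stack <- function(v, bitdepth = 8L) {
  image_stack(array(v, c(1, 1, length(v))), bitdepth = bitdepth)
}

# Independent moment-preserving threshold oracle: solve the three-moment
# two-level system with polyroot (a different solver than the package's
# closed-form quadratic), then brute-force all representable gray levels
# for the one whose cumulative fraction is nearest the moment-preserving
# fraction (ties toward the lower level).
oracle_moment_threshold <- function(v, maxint = 255L) {
  counts <- tabulate(as.integer(v) + 1L, maxint + 1L)
  n <- sum(counts)
  g <- seq_along(counts) - 1
  pr <- counts / n
  m1 <- sum(pr * g); m2 <- sum(pr * g^2); m3 <- sum(pr * g^3)
  cd <- m2 - m1^2
  c0 <- (m1 * m3 - m2^2) / cd
  c1 <- (m1 * m2 - m3) / cd
  rt <- sort(Re(polyroot(c(c0, c1, 1))))
  p0 <- (rt[2] - m1) / (rt[2] - rt[1])
  lv <- which(counts > 0) - 1
  top <- lv[length(lv)]
  cf <- cumsum(pr)[seq_len(top)]
  best <- Inf; bt <- NA_integer_
  for (t in 0:(top - 1L)) {
    d <- abs(cf[t + 1L] - p0)
    if (d < best - 1e-15) { best <- d; bt <- t }
  }
  bt
}

# Exhaustive local-maxima oracle: per-voxel loop over the anisotropic
# clipped box neighborhood (kernel = half-widths (kx, ky, kz)).
oracle_local_maxima <- function(a, kernel, tol = 0) {
  d <- dim(a)
  out <- array(FALSE, d)
  kx <- kernel[1]; ky <- kernel[2]; kz <- kernel[3]
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    nb <- a[max(1, z - kz):min(d[1], z + kz),
            max(1, y - ky):min(d[2], y + ky),
            max(1, x - kx):min(d[3], x + kx)]
    out[z, y, x] <- a[z, y, x] >= max(nb) - tol && a[z, y, x] > 0
  }
  out
}

# Brute-force surround shell: all voxels within Chebyshev distance r of
# the mask, excluding the mask, found by direct enumeration.
oracle_surround_shell <- function(mask, r) {
  d <- dim(mask)
  shell <- array(FALSE, d)
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    z <- idx[i, 1]; y <- idx[i, 2]; x <- idx[i, 3]
    shell[max(1, z - r):min(d[1], z + r),
          max(1, y - r):min(d[2], y + r),
          max(1, x - r):min(d[3], x + r)] <- TRUE
  }
  shell & !mask
}

# Small synthetic scene used by several detection tests.
small_scene <- function(seed = 11, n = 12L, shape = c(40L, 160L, 160L), ...) {
  generate_cell_stack(synth_params(shape = shape, n_cells = n,
                                   rng_seed = seed, ...))
}

# Circularly roll a 3D array by (sz, sy, sx); content at index i moves to
# i + s (modulo the axis extent).
roll3 <- function(a, s) {
  d <- dim(a)
  ix <- function(n, k) ((seq_len(n) - 1 - k) %% n) + 1
  a[ix(d[1], s[1]), ix(d[2], s[2]), ix(d[3], s[3])]
}
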