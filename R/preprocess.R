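#' Subtract spectral crosstalk between channels
#'
#' Calcein blue emission leaks into the green detector band; before any
#' counting on the green channel the leaked component is removed by scaled
#' subtraction: `out = max(0, target - coefficient * source)`, rounded back
#' to the integer grid.  Bit depth is preserved.
#'
#' @param target [image_stack] receiving the correction.
#' @param source [image_stack] of the leaking channel; same shape.
#' @param coefficient unitless leakage coefficient, `>= 0`.  The microscope
#'   calibration is not part of this package; 1.0 (straight subtraction) is
#'   the default and the synthetic generator uses a known value so the
#'   correction is testable.
#' @return An [image_stack] with the same metadata as `target`.
#' @export
subtract_crosstalk <- function(target, source, coefficient = 1.0) {
  if (!identical(dim(target$voxels), dim(source$voxels))) {
    stop("shape mismatch between target and source", call. = FALSE)
  }
  if (!is.finite(coefficient) || coefficient < 0) {
    stop("coefficient must be finite and >= 0", call. = FALSE)
  }
  v <- .clamp_round(target$voxels - coefficient * source$voxels,
                    0, 2^target$bitdepth - 1)
  image_stack(v, voxel_size = target$voxel_size, channel = target$channel,
              bitdepth = target$bitdepth)
}

# Moment-preserving (Tsai 1985) threshold from an integer histogram.
# Returns the gray level t such that binarizing at `> t` preserves the
# first three intensity moments: the foreground fraction is fixed by the
# closed-form two-level solution and t is placed at the corresponding
# p-tile of the cumulative histogram.
moment_threshold_from_hist <- function(counts) {
  n <- sum(counts)
  g <- seq_along(counts) - 1
  pr <- counts / n
  m1 <- sum(pr * g)
  m2 <- sum(pr * g^2)
  m3 <- sum(pr * g^3)
  cd <- m2 - m1^2
  if (cd <= 0) stop("degenerate histogram", call. = FALSE)
  c0 <- (m1 * m3 - m2^2) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) disc <- 0
  z0 <- (-c1 - sqrt(disc)) / 2
  z1 <- (-c1 + sqrt(disc)) / 2
  p0 <- if (z1 > z0) (z1 - m1) / (z1 - z0) else 0.5
  p0 <- min(max(p0, 0), 1)
  # the p-tile step: the gray level whose cumulative fraction is nearest
  # the moment-preserving fraction (ties toward the lower level); the
  # threshold stays below the top occupied level so the mask is nonempty
  lvls <- which(counts > 0) - 1L
  top <- lvls[length(lvls)]
  cf <- cumsum(pr)[seq_len(top)]
  unname(which.min(abs(cf - p0)) - 1L)
}

#' Moment-preserving segmentation of cell areas
#'
#' Port of the "Moment" auto-threshold (Tsai's moment-preserving criterion):
#' the threshold is chosen so that the binarized stack preserves the first
#' three intensity moments of the pooled 3D histogram.  One threshold per
#' stack, computed at the native bit depth.
#'
#' @param stack an [image_stack] with at least two distinct intensities.
#' @return `list(threshold = <intensity>, mask = <logical 3D array>)`, where
#'   the mask marks voxels strictly above the threshold.
#' @export
moment_threshold <- function(stack) {
  v <- stack$voxels
  maxint <- 2^stack$bitdepth - 1
  counts <- int_hist(v, maxint)
  if (sum(counts > 0) < 2L) stop("degenerate histogram", call. = FALSE)
  t <- moment_threshold_from_hist(counts)
  list(threshold = t, mask = array(v > t, dim(v)))
}

# Linear rescale parameters for enhance_contrast: clip levels (lo, hi) from
# the integer histogram and the multiplicative gain onto [0, maxint].
contrast_transform <- function(v, maxint, saturated_fraction, tail_split) {
  counts <- int_hist(v, maxint)
  n <- sum(counts)
  f_lo <- saturated_fraction * tail_split
  f_hi <- saturated_fraction * (1 - tail_split)
  r_lo <- max(1, ceiling(f_lo * n))
  r_hi <- min(n, n - floor(f_hi * n) + 1)
  lo <- value_at_rank(counts, r_lo)
  hi <- value_at_rank(counts, r_hi)
  list(lo = lo, hi = hi, scale = if (hi > lo) maxint / (hi - lo) else NA_real_)
}

#' Standardized contrast enhancement
#'
#' Monotone linear rescale of the whole stack so that a fixed fraction of
#' voxels saturates at the dynamic-range extremes (split between the low and
#' high tails), after which the stack occupies the full bit-depth range.
#' This is the normalization that makes dim stacks (e.g. raw 8-bit maxima of
#' only 20-25) comparable with bright ones; the ordering of unclipped voxels
#' is preserved.
#'
#' @param stack an [image_stack].
#' @param saturated_fraction total fraction of voxels allowed to clip;
#'   default 0.012 (1.2%).
#' @param tail_split fraction of the saturated budget spent on the low tail;
#'   default 0.5 (even split), set 0 for high-tail-only clipping.
#' @return An [image_stack]; attribute `"transform"` carries
#'   `list(lo, hi, scale)` so downstream cutoffs stated on the raw scale can
#'   be mapped onto the enhanced scale.  A constant stack is returned
#'   unchanged with a `warning`.
#' @export
enhance_contrast <- function(stack, saturated_fraction = 0.012,
                             tail_split = 0.5) {
  if (saturated_fraction < 0 || saturated_fraction >= 1) {
    stop("saturated_fraction must be in [0, 1)", call. = FALSE)
  }
  maxint <- 2^stack$bitdepth - 1
  tr <- contrast_transform(stack$voxels, maxint, saturated_fraction,
                           tail_split)
  if (!is.finite(tr$scale)) {
    warning("constant image: contrast enhancement skipped")
    out <- stack
    attr(out, "transform") <- list(lo = tr$lo, hi = tr$hi, scale = 1)
    return(out)
  }
  v <- .clamp_round((stack$voxels - tr$lo) * tr$scale, 0, maxint)
  out <- image_stack(v, voxel_size = stack$voxel_size,
                     channel = stack$channel, bitdepth = stack$bitdepth)
  attr(out, "transform") <- tr
  out
}
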