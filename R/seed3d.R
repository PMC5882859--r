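#' Detection parameters for 3D seed counting
#'
#' @param mean_kernel half-width in pixels of the 3D mean filter applied to
#'   the enhanced stack before maxima extraction; 1 (a 3x3x3 box) per the
#'   original processing chain.
#' @param localmax_kernel half-widths `(kx, ky, kz)` in pixels of the
#'   anisotropic local-maximum neighborhood; the defaults (6, 8, 10) suit
#'   calvarial osteolineage cells and should be matched to the cell size
#'   (x is the most useful axis for separating abutting cells).
#' @param saturated_fraction clip fraction for [enhance_contrast];
#'   default 0.012.
#' @param surround_radius half-width in pixels of the box dilation defining
#'   the cell-surrounding shell; default 3.
#' @param gating_steps step background gating table: a list of
#'   `c(signal_level_upper_bound, offset_above_mode)` pairs with strictly
#'   increasing upper bounds, on the raw intensity scale.  The default
#'   `[(64, 1), (128, 2), (255, 4)]` keeps the surround cutoff a small
#'   increment above the background mode so that the Tukey fence stays below
#'   saturation even on heavily enhanced dim stacks; calibrate to your
#'   detector if background statistics differ.
#' @param plateau_tol equality tolerance (intensity units) for the
#'   local-maximum plateau test.  Saturated cells form near-flat plateaus in
#'   the filtered stack, and a single sub-saturated voxel perturbs a 3x3x3
#'   mean by only 1/27 of a gray level; a tolerance of one quantization step
#'   keeps each such plateau a single cluster instead of fragmenting it into
#'   several seeds.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(mean_kernel = 1L,
                             localmax_kernel = c(6L, 8L, 10L),
                             saturated_fraction = 0.012,
                             surround_radius = 3L,
                             gating_steps = list(c(64, 1), c(128, 2),
                                                 c(255, 4)),
                             plateau_tol = 1) {
  if (mean_kernel < 1) stop("kernel must be >= 1", call. = FALSE)
  localmax_kernel <- as.integer(localmax_kernel)
  if (length(localmax_kernel) != 3L || any(localmax_kernel < 1L)) {
    stop("localmax_kernel must be three half-widths >= 1 (kx, ky, kz)",
         call. = FALSE)
  }
  if (surround_radius < 1) stop("surround_radius must be >= 1", call. = FALSE)
  validate_gating(gating_steps)
  if (plateau_tol < 0) stop("plateau_tol must be >= 0", call. = FALSE)
  structure(list(mean_kernel = as.integer(mean_kernel),
                 localmax_kernel = localmax_kernel,
                 saturated_fraction = saturated_fraction,
                 surround_radius = as.integer(surround_radius),
                 gating_steps = gating_steps,
                 plateau_tol = plateau_tol),
            class = "detection_params")
}

validate_gating <- function(gating_steps) {
  if (!is.list(gating_steps) || length(gating_steps) == 0L) {
    stop("gating_steps must be a nonempty list of (bound, offset) pairs",
         call. = FALSE)
  }
  bounds <- vapply(gating_steps, function(s) as.numeric(s[1]), numeric(1))
  offsets <- vapply(gating_steps, function(s) as.numeric(s[2]), numeric(1))
  if (any(diff(bounds) <= 0)) {
    stop("gating upper bounds must be strictly increasing", call. = FALSE)
  }
  if (any(offsets < 0)) stop("gating offsets must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' 3D mean filter
#'
#' Each voxel is replaced by the mean over its `(2*kernel+1)^3` box
#' neighborhood, edge-clamped (the window is clipped at the borders and
#' averages only the voxels present).  The intensity scale is preserved;
#' the output carries fractional intensities.
#'
#' @param stack an [image_stack].
#' @param kernel half-width in pixels, `>= 1`.
#' @return An [image_stack] with filtered (numeric) voxels.
#' @export
mean_filter_3d <- function(stack, kernel = 1L) {
  if (kernel < 1) stop("kernel must be >= 1", call. = FALSE)
  v <- box_mean_3d(stack$voxels, as.integer(kernel))
  out <- stack
  out$voxels <- v
  out
}

#' Anisotropic 3D local maxima
#'
#' A voxel is marked iff its value equals the maximum over the box
#' neighborhood with half-widths `(kz, ky, kx)` (clipped at borders, within
#' `tol`) and is strictly positive.  Plateaus yield connected marked
#' clusters; with `tol = 0` any two 26-adjacent marked voxels necessarily
#' share the same value.
#'
#' @param stack an [image_stack] (typically mean-filtered).
#' @param kernel half-widths `(kx, ky, kz)` in pixels, as in
#'   [detection_params].
#' @param tol plateau equality tolerance in intensity units (default 0,
#'   exact equality); see the `plateau_tol` argument of
#'   [detection_params].
#' @return A logical 3D array of the stack's shape.
#' @export
local_maxima_3d <- function(stack, kernel = c(6L, 8L, 10L), tol = 0) {
  kernel <- as.integer(kernel)
  if (any(kernel < 1L)) stop("kernel half-widths must be >= 1", call. = FALSE)
  v <- stack$voxels
  mx <- box_max_3d(v, kz = kernel[3], ky = kernel[2], kx = kernel[1])
  array(v >= mx - tol & v > 0, dim(v))
}

#' Background mode of a raw stack
#'
#' The most frequent intensity of the raw (pre-enhancement) stack, i.e. the
#' background level; ties break toward the lower intensity.
#'
#' @param raw an [image_stack].
#' @return Integer intensity.
#' @export
background_mode <- function(raw) {
  counts <- int_hist(raw$voxels, 2^raw$bitdepth - 1)
  which.max(counts) - 1L
}

#' Step background gating cutoff
#'
#' The lower cutoff of the cell-surrounding histogram: the raw background
#' mode plus a step offset selected by the stack's signal level.  Stacks
#' that undergo more rigorous contrast enhancement inherently carry higher
#' (amplified) background, so the gate excludes the noise floor before the
#' surround mean is taken.
#'
#' @param mode background mode intensity (raw scale).
#' @param signal_level raw signal level of the stack (the package uses the
#'   raw maximum intensity).
#' @param gating a gating table as in [detection_params]; the first step
#'   whose upper bound is `>= signal_level` applies.  A signal level beyond
#'   the last bound uses the last step, with a warning.
#' @param maxint dynamic-range ceiling used to clamp the cutoff.
#' @return Cutoff intensity on the raw scale.
#' @export
step_gate_cutoff <- function(mode, signal_level, gating, maxint = 255) {
  validate_gating(gating)
  bounds <- vapply(gating, function(s) as.numeric(s[1]), numeric(1))
  offsets <- vapply(gating, function(s) as.numeric(s[2]), numeric(1))
  i <- which(bounds >= signal_level)[1L]
  if (is.na(i)) {
    warning("signal level ", signal_level, " exceeds last gating bound; ",
            "using last step")
    i <- length(bounds)
  }
  min(max(mode + offsets[i], 0), maxint)
}

#' Mean intensity of the cell surrounding
#'
#' The surround region is the segmented cell mask dilated by a box of
#' half-width `surround_radius`, minus the mask itself.  The returned value
#' is the mean of surround voxels at or above the gating cutoff; if no
#' voxel passes the gate the ungated surround mean is returned (the gate is
#' a noise-floor guard, not a hard filter).
#'
#' The gate may be evaluated against a companion image instead of
#' `enhanced` itself: the counting pipeline derives the cutoff from the
#' *raw* background mode, so it tests each shell voxel's raw intensity
#' while averaging the corresponding values of the working (filtered)
#' stack.  This keeps the gate on the scale where mode and offsets are
#' defined, independent of the enhancement gain.
#'
#' @param enhanced [image_stack] whose intensities are averaged.
#' @param cell_mask logical 3D array of segmented cell voxels.
#' @param surround_radius dilation half-width in pixels, `>= 1`.
#' @param cutoff gating cutoff, on the intensity scale of `gate` (or of
#'   `enhanced` when no gate image is given).
#' @param gate optional [image_stack] of the same shape whose values the
#'   cutoff is tested against; default `NULL` gates on `enhanced` itself.
#' @return Mean surround intensity (the `x` of the Tukey fence).
#' @export
surround_mean <- function(enhanced, cell_mask, surround_radius = 3L,
                          cutoff = 0, gate = NULL) {
  if (surround_radius < 1) stop("surround_radius must be >= 1", call. = FALSE)
  if (!any(cell_mask)) stop("no cells segmented", call. = FALSE)
  shell <- dilate_box(cell_mask, as.integer(surround_radius)) & !cell_mask
  vals <- enhanced$voxels[shell]
  gvals <- if (is.null(gate)) vals else gate$voxels[shell]
  gated <- vals[gvals >= cutoff]
  if (length(gated) == 0L) mean(vals) else mean(gated)
}

#' Tukey-fence outlier threshold under the exponential background model
#'
#' The surround histogram is modeled as an exponential distribution with
#' mean `x`; its closed-form quartiles are `Q1 = x*ln(4/3)` and
#' `Q3 = x*ln(4)`, and the upper Tukey fence is
#' `T = Q3 + 1.5*(Q3 - Q1) = x*(ln 4 + 1.5*ln 3)`.  Intensities above `T`
#' are anomalies with respect to the background, i.e. true cells.
#'
#' @param x mean cell-surrounding intensity, `>= 0`.
#' @return An object of class `tukey_threshold` with fields `x`, `Q1`, `Q3`
#'   and `T`.  `T` is homogeneous of degree 1 in `x`.
#' @export
tukey_threshold <- function(x) {
  if (!is.finite(x) || x < 0) stop("x must be >= 0", call. = FALSE)
  q1 <- x * log(4 / 3)
  q3 <- x * log(4)
  structure(list(x = x, Q1 = q1, Q3 = q3, T = q3 + 1.5 * (q3 - q1)),
            class = "tukey_threshold")
}

#' @export
print.tukey_threshold <- function(x, ...) {
  cat(sprintf("<tukey_threshold> x=%.4g Q1=%.4g Q3=%.4g T=%.4g\n",
              x$x, x$Q1, x$Q3, x$T))
  invisible(x)
}

#' A set of detected 3D seeds
#'
#' @param seeds data frame with columns `z, y, x` (0-based fractional voxel
#'   coordinates) and `peak_intensity`.
#' @param channel channel role the seeds were detected on.
#' @param params the [detection_params] used (provenance).
#' @return An object of class `seed_set` with a `count` field.
#' @export
seed_set <- function(seeds, channel = NA_character_, params = NULL) {
  seeds <- as.data.frame(seeds)
  if (nrow(seeds) > 0 &&
      !all(c("z", "y", "x", "peak_intensity") %in% names(seeds))) {
    stop("seeds need columns z, y, x, peak_intensity", call. = FALSE)
  }
  structure(list(seeds = seeds, channel = channel, params = params,
                 count = nrow(seeds)),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> %d seeds on %s\n", x$count,
              ifelse(is.na(x$channel), "(unassigned)", x$channel)))
  invisible(x)
}

#' Count detected cells
#' @param seeds a [seed_set].
#' @return Integer count.
#' @export
count_cells <- function(seeds) seeds$count

#' Automatic 3D seed detection and cell counting
#'
#' The two-step counting chain: the raw channel is contrast-enhanced to a
#' standardized saturation fraction, cell areas are segmented on the
#' enhanced stack by the moment-preserving threshold, the stack is smoothed
#' with a 3D mean filter, and the result is scanned for anisotropic local
#' maxima.  Maxima clusters are labeled by 26-connectivity and filtered
#' against the Tukey fence `T` computed from the gated mean of the
#' cell-surrounding shell of the filtered stack; the representative
#' intensity of a cluster is its peak in the filtered stack, the image the
#' maxima are extracted from (the image the cluster filter thresholds).
#' Each surviving cluster contributes one seed at its intensity-weighted
#' centroid.  The step-gating cutoff is derived from the raw background
#' mode and signal level and tests the shell voxels' raw intensities, so
#' the noise-floor guard is independent of the enhancement gain.
#'
#' Deterministic for fixed input and parameters; an empty result (count 0)
#' is valid.
#'
#' @param stack a [multichannel_stack].
#' @param channel channel role to count.
#' @param params a [detection_params].
#' @return A [seed_set]; seed coordinates are 0-based `(z, y, x)`.
#' @export
detect_seeds <- function(stack, channel, params = detection_params()) {
  channel <- match_channel_role(channel)
  if (!channel %in% names(stack$channels)) {
    stop("channel ", channel, " not present in stack", call. = FALSE)
  }
  raw <- stack$channels[[channel]]
  maxint <- 2^raw$bitdepth - 1

  enh <- enhance_contrast(raw, params$saturated_fraction)
  seg <- moment_threshold(enh)
  filt <- mean_filter_3d(enh, params$mean_kernel)
  maxima <- local_maxima_3d(filt, params$localmax_kernel,
                            tol = params$plateau_tol)

  mode <- background_mode(raw)
  signal <- max(raw$voxels)
  cutoff_raw <- step_gate_cutoff(mode, signal, params$gating_steps,
                                 maxint = maxint)

  xbar <- surround_mean(filt, seg$mask, params$surround_radius,
                        cutoff = cutoff_raw, gate = raw)
  fence <- tukey_threshold(xbar)

  lin <- which(maxima)
  if (length(lin) == 0L) {
    return(seed_set(data.frame(z = numeric(0), y = numeric(0),
                               x = numeric(0), peak_intensity = numeric(0)),
                    channel = channel, params = params))
  }
  d <- dim(raw$voxels)
  lab <- label_components_26(lin, d)
  w <- filt$voxels[lin]
  peaks <- tapply(w, lab, max)
  survivors <- as.integer(names(peaks))[peaks > fence$T]
  if (length(survivors) == 0L) {
    return(seed_set(data.frame(z = numeric(0), y = numeric(0),
                               x = numeric(0), peak_intensity = numeric(0)),
                    channel = channel, params = params))
  }
  sel <- lab %in% survivors
  lin <- lin[sel]
  lab <- lab[sel]
  w <- w[sel]
  z <- (lin - 1) %% d[1]
  r <- (lin - 1) %/% d[1]
  y <- r %% d[2]
  x <- r %/% d[2]
  sw <- tapply(w, lab, sum)
  seeds <- data.frame(
    z = as.numeric(tapply(w * z, lab, sum) / sw),
    y = as.numeric(tapply(w * y, lab, sum) / sw),
    x = as.numeric(tapply(w * x, lab, sum) / sw),
    peak_intensity = as.numeric(tapply(w, lab, max)))
  seeds <- seeds[order(seeds$z, seeds$y, seeds$x), , drop = FALSE]
  rownames(seeds) <- NULL
  seed_set(seeds, channel = channel, params = params)
}

#' Write a seed set to CSV (`z,y,x,peak_intensity`)
#' @param seeds a [seed_set].
#' @param path output CSV path.
#' @export
write_seeds <- function(seeds, path) {
  utils::write.csv(seeds$seeds, path, row.names = FALSE)
  invisible(path)
}

#' Read a seed set from CSV
#' @param path CSV with columns `z,y,x,peak_intensity` (0-based coordinates).
#' @param channel optional channel role.
#' @export
read_seeds <- function(path, channel = NA_character_) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  seed_set(utils::read.csv(path), channel = channel)
}
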