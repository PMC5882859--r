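#' Synthetic-scene generator parameters
#'
#' Defaults emulate the acquisition conditions of the counting validation:
#' a 400 x 400 um field of view rastered at 512 x 512 px (0.781 um/px), a
#' 50-slice (50 um) z-stack at 1 um interval, 150-400 cells per region, and
#' two channel profiles -- `"egfp"` for the dim reporter (pre-enhancement
#' peak intensities of only 20-25 in 8 bits, exercising the rigorous
#' contrast-enhancement path) and `"tdtomato"` for the bright lineage label.
#' The background is exponential noise, so the exponential-quartile model
#' behind the Tukey fence holds exactly in the cell surrounding.
#'
#' @param shape stack shape `(nz, ny, nx)` in voxels.
#' @param n_cells integer count, or a `(min, max)` range sampled uniformly.
#' @param radius_range `(r_min, r_max)`: per-axis Gaussian sigmas of the
#'   rendered cells are drawn uniformly from this range (pixels), giving the
#'   size variation the counting algorithm must tolerate.
#' @param profile `"tdtomato"` (bright) or `"egfp"` (dim); sets the default
#'   `intensity_range` and channel role.
#' @param intensity_range `(i_min, i_max)` peak amplitudes; `NULL` uses the
#'   profile default (20-25 for egfp, 150-250 for tdtomato).
#' @param background_mean mean of the exponential background noise
#'   (intensity units); 0 gives an exactly zero background.  The default 2
#'   reflects the low autofluorescence floor of a band-limited two-photon
#'   detection channel (the dim-channel case has whole-image maxima of
#'   20-25, bounding the background well below that).
#' @param min_separation `(sz, sy, sx)`: no two cell centers may fall
#'   within this box of each other.  The default (12, 10, 8) exceeds the
#'   default local-maximum half-widths (10, 8, 6) in (z, y, x) so that
#'   well-separated cells stay separable.
#' @param margin `(mz, my, mx)` border margin for cell centers.
#' @param crosstalk_coefficient if `> 0`, a companion calcein-blue-like
#'   channel is generated and `coefficient * companion` is leaked into the
#'   target channel (then re-rounded), so crosstalk subtraction is testable
#'   against the clean truth.
#' @param bitdepth 8 or 16.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param centers optional `n x 3` matrix of fixed 0-based `(z, y, x)` cell
#'   centers, bypassing random placement (separation is not re-checked).
#' @param rng_seed integer seed; generation is bit-identical for a fixed
#'   seed.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(shape = c(50L, 512L, 512L),
                         n_cells = c(150L, 400L),
                         radius_range = c(1.5, 3),
                         profile = c("tdtomato", "egfp"),
                         intensity_range = NULL,
                         background_mean = 2,
                         min_separation = c(12, 10, 8),
                         margin = c(6, 10, 10),
                         crosstalk_coefficient = 0,
                         bitdepth = 8L,
                         voxel_size = c(1, 0.781, 0.781),
                         centers = NULL,
                         rng_seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(intensity_range)) {
    intensity_range <- if (profile == "egfp") c(20, 25) else c(150, 250)
  }
  maxint <- 2^bitdepth - 1
  stopifnot(all(shape >= 1), radius_range[1] >= 1,
            intensity_range[2] <= maxint, background_mean >= 0,
            crosstalk_coefficient >= 0)
  structure(list(shape = as.integer(shape), n_cells = n_cells,
                 radius_range = radius_range, profile = profile,
                 intensity_range = intensity_range,
                 background_mean = background_mean,
                 min_separation = min_separation, margin = margin,
                 crosstalk_coefficient = crosstalk_coefficient,
                 bitdepth = as.integer(bitdepth),
                 voxel_size = as.numeric(voxel_size),
                 centers = centers, rng_seed = as.integer(rng_seed)),
            class = "synth_params")
}

# Rejection-sample n cell centers with the pairwise box-separation rule.
sample_centers <- function(n, shape, margin, sep) {
  zmin <- margin[1]; zmax <- shape[1] - 1 - margin[1]
  ymin <- margin[2]; ymax <- shape[2] - 1 - margin[2]
  xmin <- margin[3]; xmax <- shape[3] - 1 - margin[3]
  if (zmax < zmin || ymax < ymin || xmax < xmin) {
    stop("margins exceed stack shape", call. = FALSE)
  }
  cz <- cy <- cx <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 400L * n
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("infeasible packing: could not place ", n,
           " cells at the requested separation", call. = FALSE)
    }
    z <- stats::runif(1, zmin, zmax)
    y <- stats::runif(1, ymin, ymax)
    x <- stats::runif(1, xmin, xmax)
    if (placed > 0L) {
      i <- seq_len(placed)
      clash <- any(abs(cz[i] - z) <= sep[1] & abs(cy[i] - y) <= sep[2] &
                     abs(cx[i] - x) <= sep[3])
      if (clash) next
    }
    placed <- placed + 1L
    cz[placed] <- z; cy[placed] <- y; cx[placed] <- x
  }
  cbind(z = cz, y = cy, x = cx)
}

# Render anisotropic Gaussian blobs into a zero array (separable kernels,
# local patches only).  centers are 0-based; sigmas and amps are per cell.
render_blobs <- function(shape, centers, sigmas, amps) {
  a <- array(0, shape)
  for (i in seq_len(nrow(centers))) {
    c1 <- centers[i, ] + 1  # 1-based fractional
    ext <- ceiling(3.2 * sigmas[i, ])
    z0 <- max(1, floor(c1[1] - ext[1])); z1 <- min(shape[1], ceiling(c1[1] + ext[1]))
    y0 <- max(1, floor(c1[2] - ext[2])); y1 <- min(shape[2], ceiling(c1[2] + ext[2]))
    x0 <- max(1, floor(c1[3] - ext[3])); x1 <- min(shape[3], ceiling(c1[3] + ext[3]))
    gz <- exp(-0.5 * ((z0:z1 - c1[1]) / sigmas[i, 1])^2)
    gy <- exp(-0.5 * ((y0:y1 - c1[2]) / sigmas[i, 2])^2)
    gx <- exp(-0.5 * ((x0:x1 - c1[3]) / sigmas[i, 3])^2)
    blob <- amps[i] * (gz %o% gy %o% gx)
    a[z0:z1, y0:y1, x0:x1] <- a[z0:z1, y0:y1, x0:x1] + blob
  }
  a
}

#' Generate a synthetic cell stack with exact ground truth
#'
#' Cells are rendered as anisotropic Gaussian blobs at uniformly sampled
#' centers obeying the minimum-separation rule, on top of exponential
#' background noise; intensities are rounded to the integer grid and
#' clipped at the bit depth.  With a positive crosstalk coefficient a
#' companion CALCEIN_BLUE channel is generated and leaked into the target
#' channel.  The scene also carries an analytic bone-front geometry (see
#' [generate_bone_geometry]) so every downstream stage has a closed-form
#' reference.
#'
#' @param params a [synth_params].
#' @return A `synth_scene`: `stack` ([multichannel_stack]), `truth`
#'   ([ground_truth]), `geometry` ([region_geometry]), `analytic_volumes`
#'   ([volume_report]), and `clean` (the pre-crosstalk target
#'   [image_stack], present only when crosstalk is simulated).
#' @export
generate_cell_stack <- function(params = synth_params()) {
  set.seed(params$rng_seed)
  shape <- params$shape
  maxint <- 2^params$bitdepth - 1
  role <- if (params$profile == "egfp") "EGFP" else "TDTOMATO"

  n <- if (length(params$n_cells) > 1L) {
    sample(seq.int(params$n_cells[1], params$n_cells[2]), 1L)
  } else {
    as.integer(params$n_cells)
  }

  centers <- params$centers
  if (is.null(centers)) {
    centers <- if (n > 0L) {
      sample_centers(n, shape, params$margin, params$min_separation)
    } else {
      matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("z", "y", "x")))
    }
  } else {
    centers <- as.matrix(centers)
    colnames(centers) <- c("z", "y", "x")
    n <- nrow(centers)
  }

  sigmas <- matrix(stats::runif(3 * n, params$radius_range[1],
                                params$radius_range[2]), ncol = 3)
  amps <- stats::runif(n, params$intensity_range[1],
                       params$intensity_range[2])
  signal <- render_blobs(shape, centers, sigmas, amps)

  bg <- if (params$background_mean > 0) {
    array(stats::rexp(prod(shape), rate = 1 / params$background_mean), shape)
  } else {
    0
  }
  clean <- .clamp_round(signal + bg, 0, maxint)
  clean_stack <- image_stack(clean, voxel_size = params$voxel_size,
                             channel = role, bitdepth = params$bitdepth)

  channels <- list()
  if (params$crosstalk_coefficient > 0) {
    ncomp <- max(10L, round(n / 10))
    comp_centers <- sample_centers(ncomp, shape, params$margin,
                                   params$min_separation)
    comp_sig <- matrix(stats::runif(3 * ncomp, 2, 4), ncol = 3)
    comp_amp <- stats::runif(ncomp, 100, 200)
    comp <- .clamp_round(render_blobs(shape, comp_centers, comp_sig,
                                      comp_amp), 0, maxint)
    observed <- .clamp_round(clean + params$crosstalk_coefficient * comp,
                             0, maxint)
    channels[[role]] <- image_stack(observed, voxel_size = params$voxel_size,
                                    channel = role,
                                    bitdepth = params$bitdepth)
    channels[["CALCEIN_BLUE"]] <- image_stack(comp,
                                              voxel_size = params$voxel_size,
                                              channel = "CALCEIN_BLUE",
                                              bitdepth = params$bitdepth)
  } else {
    channels[[role]] <- clean_stack
  }

  geom <- generate_bone_geometry(shape = shape,
                                 voxel_size = params$voxel_size)

  structure(list(stack = multichannel_stack(channels,
                                            region_id = paste0("synth-", params$rng_seed)),
                 truth = ground_truth(as.data.frame(centers), channel = role,
                                      shape = shape),
                 geometry = geom$geometry,
                 analytic_volumes = geom$analytic_volumes,
                 clean = if (params$crosstalk_coefficient > 0) clean_stack,
                 params = params),
            class = "synth_scene")
}

#' Analytic bone-front geometry (prism/wedge fixture)
#'
#' Straight front polylines whose enclosed volume has a closed form: the
#' old fronts sit `old_offset_px` from the lateral frame edges and the new
#' fronts advance toward the suture by a gap varying linearly in z from
#' `gap[1]` to `gap[2]` pixels (a prism when constant, a wedge otherwise).
#' The suture boundary is the rectangle between the two new fronts.
#'
#' The analytic report uses the exact discrete sum
#' `sum_z gap(z) * (ny - 1) * dy * dx * dz`, which the trapezoid rule makes
#' exact for linear profiles.
#'
#' @param shape stack shape `(nz, ny, nx)`.
#' @param old_offset_px distance of the old fronts from the lateral frame
#'   edges, pixels.
#' @param gap_frontal_px,gap_parietal_px `(start, end)` new-bone gaps in
#'   pixels at the first and last slice.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param depth_slices slices integrated in the analytic report (default
#'   all).
#' @return `list(geometry = <region_geometry>,
#'   analytic_volumes = <volume_report>)`.
#' @export
generate_bone_geometry <- function(shape = c(50L, 512L, 512L),
                                   old_offset_px = round(0.15 * shape[3]),
                                   gap_frontal_px = c(20, 20),
                                   gap_parietal_px = c(15, 15),
                                   voxel_size = c(1, 0.781, 0.781),
                                   depth_slices = shape[1]) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  zf <- if (nz > 1) (seq_len(nz) - 1) / (nz - 1) else 0
  gap_f <- gap_frontal_px[1] + (gap_frontal_px[2] - gap_frontal_px[1]) * zf
  gap_p <- gap_parietal_px[1] + (gap_parietal_px[2] - gap_parietal_px[1]) * zf
  xo_f <- old_offset_px
  xo_p <- nx - 1 - old_offset_px
  if (any(xo_f + gap_f >= xo_p - gap_p)) {
    stop("crossing profile: fronts overlap the suture", call. = FALSE)
  }
  vline <- function(x) cbind(y = c(0, ny - 1), x = c(x, x))
  slices <- lapply(seq_len(nz), function(i) {
    xnf <- xo_f + gap_f[i]
    xnp <- xo_p - gap_p[i]
    list(z = i - 1L,
         fronts = list(
           old_front_frontal = vline(xo_f),
           new_front_frontal = vline(xnf),
           old_front_parietal = vline(xo_p),
           new_front_parietal = vline(xnp),
           suture_boundary = cbind(y = c(0, ny - 1, ny - 1, 0),
                                   x = c(xnf, xnf, xnp, xnp))))
  })
  geom <- region_geometry(slices, voxel_size = voxel_size,
                          frame = c(ny, nx), n_slices = nz)
  vs <- voxel_size
  h <- (ny - 1) * vs[2]
  sl <- seq_len(depth_slices)
  vf <- um3_to_mm3(sum(gap_f[sl] * vs[3] * h) * vs[1])
  vp <- um3_to_mm3(sum(gap_p[sl] * vs[3] * h) * vs[1])
  su <- um3_to_mm3(sum((xo_p - gap_p[sl] - xo_f - gap_f[sl]) * vs[3] * h) * vs[1])
  list(geometry = geom,
       analytic_volumes = volume_report(vf, vp, su, depth_slices, vs[1]))
}

#' Generate a paired Day-0/Day-28 study with known effects
#'
#' Emulates the paired longitudinal design: each region carries a Day-0
#' baseline (new-bone-volume proxy and cell counts) and a Day-28 follow-up
#' whose fractional changes realize the requested effects in expectation,
#' with independent Gaussian region-level noise (in percentage points).
#' Baselines themselves vary across regions.  Quantities are kept on a
#' continuous scale so the requested effects are exact when `noise_sd_pct`
#' is 0.
#'
#' @param n_regions number of regions, `>= 1`.
#' @param bone_growth_pct expected percent change of new-bone volume.
#' @param expansion_pct expected percent change of the labeled population.
#' @param incorporation_ratio expected Day-28 osteocyte count as a fraction
#'   of the Day-0 cell count (the "normalized incorporation" readout).
#' @param noise_sd_pct SD of the region-level noise, percentage points.
#' @param baseline_volume_mm3 mean Day-0 new-bone-volume proxy.
#' @param baseline_cells mean Day-0 labeled-cell count.
#' @param rng_seed integer seed.
#' @return A data frame with one row per region: baselines, follow-ups,
#'   osteocyte counts, and the realized `delta_volume_pct`,
#'   `delta_cells_pct` and `incorporation_pct`.
#' @export
generate_paired_study <- function(n_regions,
                                  bone_growth_pct = 41,
                                  expansion_pct = 30,
                                  incorporation_ratio = 0.10,
                                  noise_sd_pct = 10,
                                  baseline_volume_mm3 = 5e-4,
                                  baseline_cells = 200,
                                  rng_seed = 1L) {
  if (n_regions < 1L) stop("n_regions must be >= 1", call. = FALSE)
  if (bone_growth_pct <= -100 || expansion_pct <= -100) {
    stop("inconsistent effects: negative volumes", call. = FALSE)
  }
  set.seed(as.integer(rng_seed))
  v0 <- baseline_volume_mm3 * (1 + stats::runif(n_regions, -0.2, 0.2))
  c0 <- baseline_cells * (1 + stats::runif(n_regions, -0.2, 0.2))
  dv <- bone_growth_pct + stats::rnorm(n_regions, 0, noise_sd_pct)
  dc <- expansion_pct + stats::rnorm(n_regions, 0, noise_sd_pct)
  inc <- pmax(incorporation_ratio * 100 +
                stats::rnorm(n_regions, 0, noise_sd_pct / 2), 0)
  dv <- pmax(dv, -100 + 1e-9)
  dc <- pmax(dc, -100 + 1e-9)
  data.frame(region = seq_len(n_regions),
             volume_d0_mm3 = v0,
             volume_d28_mm3 = v0 * (1 + dv / 100),
             cells_d0 = c0,
             cells_d28 = c0 * (1 + dc / 100),
             osteocytes_d28 = c0 * inc / 100,
             delta_volume_pct = dv,
             delta_cells_pct = dc,
             incorporation_pct = inc)
}
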