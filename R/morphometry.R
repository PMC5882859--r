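# Polygon enclosed by an old and a new bone front within one z-slice: the
# old polyline followed by the reversed new polyline; the connecting
# segments run along the frame edges when both fronts span the frame.
between_fronts_polygon <- function(old_front, new_front) {
  rbind(old_front, new_front[rev(seq_len(nrow(new_front))), , drop = FALSE])
}

#' Area enclosed between two bone fronts in one slice
#'
#' The old (calcein blue) and new (tetracycline) fronts of one bone are
#' polylines spanning the slice frame; the newly apposed bone is the simple
#' polygon closed by the two polylines and the frame edges.  The area is
#' computed by the shoelace formula in pixel^2 and scaled by `dy * dx`.
#'
#' @param old_front,new_front `n x 2` matrices, columns `(y, x)`, 0-based
#'   voxel coordinates, consistent orientation (both running the same way
#'   across the frame).
#' @param voxel_size `(dz, dy, dx)` in micrometres (only `dy`, `dx` are
#'   used here).
#' @param bounds optional `(ny, nx)` frame extent (consistency checking).
#' @return Area in um^2, `>= 0`.
#' @export
slice_area_between_fronts <- function(old_front, new_front,
                                      voxel_size = c(1, 1, 1),
                                      bounds = NULL) {
  for (p in list(old_front, new_front)) {
    if (!is.matrix(p) || nrow(p) < 2L) {
      stop("degenerate front", call. = FALSE)
    }
  }
  for (i in seq_len(nrow(old_front) - 1L)) {
    for (j in seq_len(nrow(new_front) - 1L)) {
      if (segments_cross(old_front[i, ], old_front[i + 1L, ],
                         new_front[j, ], new_front[j + 1L, ])) {
        stop("fronts intersect", call. = FALSE)
      }
    }
  }
  poly <- between_fronts_polygon(old_front, new_front)
  abs(shoelace_area(poly)) * voxel_size[2] * voxel_size[3]
}

# Area of the suture boundary polygon of one slice (auto-closed), um^2.
suture_slice_area <- function(boundary, voxel_size) {
  abs(shoelace_area(boundary)) * voxel_size[2] * voxel_size[3]
}

#' Volume report
#'
#' @param new_bone_frontal,new_bone_parietal,suture_volume volumes in mm^3.
#' @param n_slices number of z-slices integrated.
#' @param dz z-spacing in micrometres.
#' @return An object of class `volume_report` with the derived
#'   `new_bone_total` (frontal + parietal) and `depth` (`n_slices * dz`, um).
#' @export
volume_report <- function(new_bone_frontal, new_bone_parietal,
                          suture_volume, n_slices, dz) {
  stopifnot(new_bone_frontal >= 0, new_bone_parietal >= 0,
            suture_volume >= 0)
  structure(list(new_bone_frontal = new_bone_frontal,
                 new_bone_parietal = new_bone_parietal,
                 new_bone_total = new_bone_frontal + new_bone_parietal,
                 suture_volume = suture_volume,
                 n_slices = as.integer(n_slices),
                 depth = n_slices * dz),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf(paste0("<volume_report> over %d slices (%.0f um):\n",
                     "  new bone frontal  %.4g mm^3\n",
                     "  new bone parietal %.4g mm^3\n",
                     "  new bone total    %.4g mm^3\n",
                     "  suture            %.4g mm^3\n"),
              x$n_slices, x$depth, x$new_bone_frontal, x$new_bone_parietal,
              x$new_bone_total, x$suture_volume))
  invisible(x)
}

# um^3 -> mm^3 happens in exactly one place.
um3_to_mm3 <- function(v) v * 1e-9

#' 3D bone and suture volumes from per-slice fronts
#'
#' Per-slice areas between the old and new fronts of each bone, and of the
#' suture boundary polygon, are summed over the first `depth_slices` slices,
#' multiplied by the z-spacing, and converted to mm^3.  The 50-slice default
#' matches the standardized 50-um analysis layer.
#'
#' @param geometry a [region_geometry] covering at least `depth_slices`
#'   slices.
#' @param depth_slices number of z-slices to integrate (default 50).
#' @return A [volume_report].
#' @export
measure_volumes <- function(geometry, depth_slices = 50L) {
  n <- length(geometry$slices)
  if (n < depth_slices) {
    stop("geometry covers ", n, " slices; ", depth_slices, " requested",
         call. = FALSE)
  }
  vs <- geometry$voxel_size
  a_f <- a_p <- a_s <- 0
  for (i in seq_len(depth_slices)) {
    fr <- geometry$slices[[i]]$fronts
    if (!is.null(fr$old_front_frontal) && !is.null(fr$new_front_frontal)) {
      a_f <- a_f + slice_area_between_fronts(fr$old_front_frontal,
                                             fr$new_front_frontal, vs)
    }
    if (!is.null(fr$old_front_parietal) && !is.null(fr$new_front_parietal)) {
      a_p <- a_p + slice_area_between_fronts(fr$old_front_parietal,
                                             fr$new_front_parietal, vs)
    }
    if (!is.null(fr$suture_boundary)) {
      a_s <- a_s + suture_slice_area(fr$suture_boundary, vs)
    }
  }
  volume_report(new_bone_frontal = um3_to_mm3(a_f * vs[1]),
                new_bone_parietal = um3_to_mm3(a_p * vs[1]),
                suture_volume = um3_to_mm3(a_s * vs[1]),
                n_slices = depth_slices, dz = vs[1])
}

#' Count osteocytes incorporated into new bone
#'
#' A seed is counted when its position lies inside the new-bone polygon
#' (between the old and new front) of its z-slice for either bone.  Cells
#' sitting exactly on the fluorochrome border lines are included
#' (boundary-inclusive within `boundary_tol` pixels); seeds inside the
#' optional exclusion mask (vessel walls, marrow cavities) and seeds in the
#' old bone or suture are never counted.  Seeds on slices without geometry
#' are skipped with a warning.
#'
#' @param seeds a [seed_set] in the stack's coordinate frame.
#' @param geometry a [region_geometry] for the same region.
#' @param exclusion_mask optional logical 3D array; `TRUE` voxels exclude
#'   seeds.
#' @param boundary_tol point-on-border tolerance in pixels (default 0.5).
#' @param by_bone if `TRUE`, return per-bone counts as well.
#' @return Integer count (or a list with `total`, `frontal`, `parietal`
#'   when `by_bone = TRUE`).
#' @export
classify_osteocytes <- function(seeds, geometry, exclusion_mask = NULL,
                                boundary_tol = 0.5, by_bone = FALSE) {
  zs <- vapply(geometry$slices, function(s) s$z, integer(1))
  n_f <- n_p <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(seeds$seeds))) {
    s <- seeds$seeds[i, ]
    if (!is.null(exclusion_mask)) {
      iz <- round(s$z) + 1L; iy <- round(s$y) + 1L; ix <- round(s$x) + 1L
      d <- dim(exclusion_mask)
      if (iz >= 1 && iz <= d[1] && iy >= 1 && iy <= d[2] &&
          ix >= 1 && ix <= d[3] && isTRUE(exclusion_mask[iz, iy, ix])) {
        next
      }
    }
    si <- match(round(s$z), zs)
    if (is.na(si)) {
      skipped <- skipped + 1L
      next
    }
    fr <- geometry$slices[[si]]$fronts
    in_f <- in_p <- FALSE
    if (!is.null(fr$old_front_frontal) && !is.null(fr$new_front_frontal)) {
      poly <- between_fronts_polygon(fr$old_front_frontal,
                                     fr$new_front_frontal)
      in_f <- point_in_polygon(s$y, s$x, poly) ||
        point_segment_dist(s$y, s$x, poly) <= boundary_tol
    }
    if (!in_f && !is.null(fr$old_front_parietal) &&
        !is.null(fr$new_front_parietal)) {
      poly <- between_fronts_polygon(fr$old_front_parietal,
                                     fr$new_front_parietal)
      in_p <- point_in_polygon(s$y, s$x, poly) ||
        point_segment_dist(s$y, s$x, poly) <= boundary_tol
    }
    n_f <- n_f + in_f
    n_p <- n_p + in_p
  }
  if (skipped > 0L) {
    warning(skipped, " seed(s) on slices without geometry were skipped")
  }
  if (by_bone) {
    list(total = n_f + n_p, frontal = n_f, parietal = n_p)
  } else {
    n_f + n_p
  }
}

#' Osteocyte incorporation rate (cell density)
#'
#' @param count number of osteocytes counted in the new bone.
#' @param volume_report a [volume_report] with `new_bone_total > 0`.
#' @return Density in cells/mm^3.
#' @export
cell_density <- function(count, volume_report) {
  if (count < 0) stop("count must be >= 0", call. = FALSE)
  if (volume_report$new_bone_total <= 0) stop("no new bone", call. = FALSE)
  count / volume_report$new_bone_total
}

#' Fractional change between Day 0 and Day 28
#'
#' The longitudinal normalization applied to every measured parameter:
#' `(m_d28 - m_d0) / m_d0 * 100`, in percent of the Day-0 baseline.
#'
#' @param m_d0 baseline measurement, `> 0`.
#' @param m_d28 follow-up measurement.
#' @return Percent change.
#' @export
fractional_change <- function(m_d0, m_d28) {
  if (any(!is.finite(m_d0)) || any(m_d0 <= 0)) {
    stop("baseline measurement must be > 0", call. = FALSE)
  }
  (m_d28 - m_d0) / m_d0 * 100
}
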