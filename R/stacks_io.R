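#' Channel roles recognized by the pipeline
#'
#' The five acquisition channels of the multiphoton setup: second harmonic
#' generation of bone collagen, the EGFP reporter of Prx1+ skeletal stem
#' cells, the tdTomato lineage label of their progeny, and the calcein blue /
#' tetracycline fluorochromes marking the old and new bone mineralization
#' fronts.
#'
#' @export
CHANNEL_ROLES <- c("SHG", "EGFP", "TDTOMATO", "CALCEIN_BLUE", "TETRACYCLINE")

match_channel_role <- function(channel) {
  ch <- toupper(as.character(channel))
  if (length(ch) != 1L || !ch %in% CHANNEL_ROLES) {
    stop("unknown channel role '", channel, "'; must be one of ",
         paste(CHANNEL_ROLES, collapse = ", "), call. = FALSE)
  }
  ch
}

#' One channel's 3D image stack
#'
#' Container for a single fluorescence (or SHG) channel: an integer-valued
#' voxel array in `[z, y, x]` order together with the physical voxel size.
#' The z axis is depth from the skull surface; stacks are acquired at 1 um
#' z-interval by default.
#'
#' @param voxels 3D numeric array, dimensions `(nz, ny, nx)`, values in
#'   `[0, 2^bitdepth - 1]`.  Integer grids are expected on input/output;
#'   intermediate processing stages (e.g. mean filtering) may carry
#'   fractional intensities.
#' @param voxel_size numeric length-3 `(dz, dy, dx)` in micrometres, all
#'   positive.  The default lateral size 0.781 um/px corresponds to a
#'   400x400 um field of view rastered at 512x512.
#' @param channel one of [CHANNEL_ROLES], or `NA` for an unassigned stack.
#' @param bitdepth 8 or 16.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size = c(1, 0.781, 0.781),
                        channel = NA_character_, bitdepth = 8L) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("voxels must be a 3D array (z, y, x)", call. = FALSE)
  }
  if (dim(voxels)[1] < 1L) stop("stack needs at least 1 slice", call. = FALSE)
  bitdepth <- as.integer(bitdepth)
  if (!bitdepth %in% c(8L, 16L)) stop("bitdepth must be 8 or 16", call. = FALSE)
  maxint <- 2^bitdepth - 1
  rng <- range(voxels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > maxint) {
    stop("intensities must lie in [0, ", maxint, "]", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("voxel_size must be three positive numbers (dz, dy, dx)",
         call. = FALSE)
  }
  if (!is.na(channel)) channel <- match_channel_role(channel)
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 channel = channel, bitdepth = bitdepth),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %s  %d x %d x %d (z,y,x)  %d-bit  voxel %.3g x %.3g x %.3g um\n",
              ifelse(is.na(x$channel), "(unassigned)", x$channel),
              d[1], d[2], d[3], x$bitdepth,
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Multi-channel z-stack for one imaged region
#'
#' @param channels named list of [image_stack] objects; names are channel
#'   roles, at most one stack per role.  All member stacks must share shape
#'   and voxel size.
#' @param region_id free-text region identifier.
#' @param timepoint `"D0"`, `"D28"`, or `NA`.
#' @return An object of class `multichannel_stack`.
#' @export
multichannel_stack <- function(channels, region_id = "", timepoint = NA_character_) {
  if (length(channels) < 1L) stop("empty channel mapping", call. = FALSE)
  names(channels) <- vapply(names(channels), match_channel_role, character(1))
  if (anyDuplicated(names(channels))) {
    stop("at most one stack per channel role", call. = FALSE)
  }
  ref <- channels[[1]]
  for (ch in channels) {
    if (!inherits(ch, "image_stack")) {
      stop("channels must be image_stack objects", call. = FALSE)
    }
    if (!identical(dim(ch$voxels), dim(ref$voxels))) {
      stop("inconsistent page shapes across channels", call. = FALSE)
    }
    if (!isTRUE(all.equal(ch$voxel_size, ref$voxel_size))) {
      stop("channels must share voxel size", call. = FALSE)
    }
  }
  if (!is.na(timepoint) && !timepoint %in% c("D0", "D28")) {
    stop("timepoint must be D0, D28 or NA", call. = FALSE)
  }
  structure(list(channels = channels, region_id = region_id,
                 timepoint = timepoint),
            class = "multichannel_stack")
}

#' @export
print.multichannel_stack <- function(x, ...) {
  cat(sprintf("<multichannel_stack> region '%s' %s: %s\n", x$region_id,
              ifelse(is.na(x$timepoint), "", x$timepoint),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Ground-truth cell centroids for validation
#'
#' @param centroids data frame or matrix with columns `z, y, x`; 0-based
#'   voxel coordinates, fractional values allowed.
#' @param channel channel role the truth refers to.
#' @param shape optional stack shape `(nz, ny, nx)` used to check bounds.
#' @return An object of class `ground_truth` with fields `centroids`,
#'   `count` and `channel`.
#' @export
ground_truth <- function(centroids, channel = NA_character_, shape = NULL) {
  centroids <- as.data.frame(centroids)
  if (!all(c("z", "y", "x") %in% names(centroids))) {
    stop("centroids need columns z, y, x", call. = FALSE)
  }
  centroids <- centroids[, c("z", "y", "x")]
  if (!is.null(shape)) {
    ok <- centroids$z >= 0 & centroids$z <= shape[1] - 1 &
      centroids$y >= 0 & centroids$y <= shape[2] - 1 &
      centroids$x >= 0 & centroids$x <= shape[3] - 1
    if (!all(ok)) stop("centroids outside stack bounds", call. = FALSE)
  }
  if (!is.na(channel)) channel <- match_channel_role(channel)
  structure(list(centroids = centroids, count = nrow(centroids),
                 channel = channel),
            class = "ground_truth")
}

#' Read ground-truth centroids from CSV
#'
#' @param path CSV file with header `z,y,x` (0-based voxel coordinates).
#' @inheritParams ground_truth
#' @export
read_ground_truth <- function(path, channel = NA_character_, shape = NULL) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  ground_truth(utils::read.csv(path), channel = channel, shape = shape)
}

#' Write ground-truth centroids to CSV
#' @param truth a [ground_truth] object.
#' @param path output CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth$centroids, path, row.names = FALSE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a multi-channel stack as a multi-page TIFF
#'
#' Pages are written channel by channel, slices in z order, losslessly at the
#' stack's native bit depth.  Acquisition metadata (voxel size, bit depth,
#' channel-to-page mapping, region id and timepoint) is stored in a JSON
#' sidecar `<path>.json`, since baseline TIFF carries no 3D voxel-size tags.
#'
#' @param stack a [multichannel_stack].
#' @param path destination TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "multichannel_stack")) {
    stop("stack must be a multichannel_stack", call. = FALSE)
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: ", path, call. = FALSE)
  bitdepth <- stack$channels[[1]]$bitdepth
  maxint <- 2^bitdepth - 1
  pages <- list()
  page_map <- list()
  p <- 1L
  for (role in names(stack$channels)) {
    v <- stack$channels[[role]]$voxels
    nz <- dim(v)[1]
    for (z in seq_len(nz)) {
      pages[[p]] <- v[z, , ] / maxint
      p <- p + 1L
    }
    page_map[[role]] <- seq.int(p - nz, p - 1L)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bitdepth,
                  compression = "none")
  meta <- list(voxel_size = stack$channels[[1]]$voxel_size,
               bitdepth = bitdepth,
               shape = dim(stack$channels[[1]]$voxels),
               channels = page_map,
               region_id = stack$region_id,
               timepoint = stack$timepoint)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-channel stack from a multi-page TIFF
#'
#' Metadata is taken from the JSON sidecar written by [write_stack] when
#' present; otherwise `channel_map` and `voxel_size` must be supplied.
#' Intensities are preserved bit-exactly.
#'
#' @param path TIFF file path.
#' @param channel_map named list mapping channel roles to 1-based page
#'   indices, e.g. `list(TDTOMATO = 1:5)`.  Overrides the sidecar.
#' @param voxel_size `(dz, dy, dx)` in micrometres; overrides the sidecar.
#' @param region_id,timepoint optional overrides.
#' @return A [multichannel_stack].
#' @export
read_stack <- function(path, channel_map = NULL, voxel_size = NULL,
                       region_id = NULL, timepoint = NULL) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  channel_map <- channel_map %||% meta$channels
  voxel_size <- voxel_size %||% meta$voxel_size
  if (is.null(voxel_size)) stop("voxel size unknown for ", path, call. = FALSE)
  if (is.null(channel_map) || length(channel_map) == 0L) {
    stop("no channel map for ", path, call. = FALSE)
  }
  bitdepth <- as.integer(meta$bitdepth %||% 8L)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(m) identical(dim(m), shp), logical(1)))) {
    stop("inconsistent page shapes in ", path, call. = FALSE)
  }
  channels <- list()
  for (role in names(channel_map)) {
    idx <- as.integer(unlist(channel_map[[role]]))
    if (any(idx < 1L | idx > length(pages))) {
      stop("channel map references missing pages in ", path, call. = FALSE)
    }
    v <- array(0, c(length(idx), shp[1], shp[2]))
    for (i in seq_along(idx)) v[i, , ] <- pages[[idx[i]]]
    channels[[role]] <- image_stack(v, voxel_size = voxel_size,
                                    channel = role, bitdepth = bitdepth)
  }
  multichannel_stack(channels,
                     region_id = region_id %||% meta$region_id %||% "",
                     timepoint = timepoint %||% meta$timepoint %||% NA_character_)
}

FRONT_LABELS <- c("old_front_frontal", "new_front_frontal",
                  "old_front_parietal", "new_front_parietal",
                  "suture_boundary")

#' Per-region bone-front geometry
#'
#' Manual segmentations of the old (calcein blue) and new (tetracycline)
#' bone fronts of the frontal and parietal bones, plus the suture boundary,
#' one set of labeled polylines per z-slice.  Coordinates are 0-based voxel
#' units `(y, x)` in the frame of the associated stack; front polylines run
#' across the frame in y, the suture boundary is a closed polygon.
#'
#' @param slices list of entries `list(z = <int>, fronts = <named list>)`;
#'   each front is an `n x 2` matrix with columns `(y, x)` and `n >= 2`.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param frame `(ny, nx)` extent of the slice frame in pixels.
#' @param n_slices optional stack depth used to range-check slice indices.
#' @return An object of class `region_geometry`.
#' @export
region_geometry <- function(slices, voxel_size = c(1, 0.781, 0.781),
                            frame = NULL, n_slices = NULL) {
  if (length(slices) < 1L) stop("geometry has no slices", call. = FALSE)
  zs <- vapply(slices, function(s) as.numeric(s$z), numeric(1))
  if (any(diff(zs) <= 0)) {
    stop("slice indices must be strictly increasing", call. = FALSE)
  }
  if (any(zs < 0)) stop("slice index out of stack range", call. = FALSE)
  if (!is.null(n_slices) && any(zs > n_slices - 1)) {
    stop("slice index out of stack range", call. = FALSE)
  }
  slices <- lapply(slices, function(s) {
    fronts <- s$fronts
    for (lab in names(fronts)) {
      if (!lab %in% FRONT_LABELS) {
        stop("unknown front label '", lab, "'", call. = FALSE)
      }
      p <- fronts[[lab]]
      if (!is.matrix(p)) {
        p <- matrix(as.numeric(unlist(p)), ncol = 2, byrow = TRUE)
      }
      storage.mode(p) <- "double"
      colnames(p) <- c("y", "x")
      if (nrow(p) < 2L) stop("degenerate front '", lab, "'", call. = FALSE)
      if (polyline_self_intersects(p)) {
        stop("self-intersecting polyline '", lab, "'", call. = FALSE)
      }
      fronts[[lab]] <- p
    }
    list(z = as.integer(s$z), fronts = fronts)
  })
  structure(list(slices = slices, voxel_size = as.numeric(voxel_size),
                 frame = frame),
            class = "region_geometry")
}

#' Read region geometry from JSON
#'
#' Schema: `{voxel_size: [dz,dy,dx], frame: [ny,nx],
#' slices: [{z: <int>, fronts: {<label>: [[y,x], ...]}}]}` with labels among
#' `old_front_frontal`, `new_front_frontal`, `old_front_parietal`,
#' `new_front_parietal`, `suture_boundary`.  The schema is deliberately
#' tool-agnostic so manual segmentations from any viewer can be exported.
#'
#' @param path JSON file path.
#' @param n_slices optional stack depth for range checking.
#' @return A [region_geometry].
#' @export
read_geometry <- function(path, n_slices = NULL) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  slices <- lapply(j$slices, function(s) {
    fronts <- lapply(s$fronts, function(pl) {
      matrix(unlist(lapply(pl, as.numeric)), ncol = 2, byrow = TRUE,
             dimnames = list(NULL, c("y", "x")))
    })
    list(z = s$z, fronts = fronts)
  })
  region_geometry(slices,
                  voxel_size = as.numeric(unlist(j$voxel_size %||% c(1, 0.781, 0.781))),
                  frame = if (!is.null(j$frame)) as.numeric(unlist(j$frame)),
                  n_slices = n_slices)
}

#' Write region geometry to JSON
#' @param geometry a [region_geometry].
#' @param path output JSON path.
#' @export
write_geometry <- function(geometry, path) {
  j <- list(voxel_size = geometry$voxel_size,
            frame = geometry$frame,
            slices = lapply(geometry$slices, function(s) {
              list(z = s$z,
                   fronts = lapply(s$fronts, function(p) {
                     lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ]))
                   }))
            }))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
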