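vline <- function(x, h = 100) cbind(y = c(0, h), x = c(x, x))

test_that("slice area between fronts: parallel, identical and trapezoid cases", {
  expect_equal(slice_area_between_fronts(vline(0), vline(10),
                                         voxel_size = c(1, 1, 1)), 1000)
  expect_equal(slice_area_between_fronts(vline(4), vline(4),
                                         voxel_size = c(1, 1, 1)), 0)
  trap <- cbind(y = c(0, 100), x = c(10, 20))
  expect_equal(slice_area_between_fronts(vline(0), trap,
                                         voxel_size = c(1, 1, 1)), 1500)
  # areas scale with the pixel size
  expect_equal(slice_area_between_fronts(vline(0), vline(10),
                                         voxel_size = c(1, 0.5, 2)), 1000)
})

test_that("crossing or degenerate fronts are rejected", {
  a <- cbind(y = c(0, 100), x = c(0, 20))
  b <- cbind(y = c(0, 100), x = c(20, 0))
  expect_error(slice_area_between_fronts(a, b), "fronts intersect")
  expect_error(slice_area_between_fronts(a[1, , drop = FALSE], b),
               "degenerate front")
})

test_that("measure_volumes integrates areas over depth and converts units", {
  # constant 10,000 um^2 per slice over 50 slices at dz = 1 um
  geom <- generate_bone_geometry(shape = c(50L, 101L, 400L),
                                 old_offset_px = 50,
                                 gap_frontal_px = c(100, 100),
                                 gap_parietal_px = c(100, 100),
                                 voxel_size = c(1, 1, 1))
  rep <- measure_volumes(geom$geometry, 50)
  expect_equal(rep$new_bone_frontal, 5e-4, tolerance = 1e-12)
  expect_equal(rep$new_bone_total,
               rep$new_bone_frontal + rep$new_bone_parietal)
  expect_equal(rep$depth, 50)
  expect_error(measure_volumes(geom$geometry, 60), "covers 50 slices")
})

test_that("zero gap gives zero volume", {
  geom <- generate_bone_geometry(shape = c(50L, 101L, 200L),
                                 gap_frontal_px = c(0, 0),
                                 gap_parietal_px = c(0, 0),
                                 voxel_size = c(1, 1, 1))
  rep <- measure_volumes(geom$geometry, 50)
  expect_equal(rep$new_bone_total, 0)
})

test_that("measured volumes match the analytic prism/wedge closed form within 1%", {
  for (gaps in list(c(10, 10), c(10, 20), c(5.5, 17.25))) {
    geom <- generate_bone_geometry(shape = c(50L, 101L, 220L),
                                   gap_frontal_px = gaps,
                                   gap_parietal_px = rev(gaps) / 2,
                                   voxel_size = c(1, 0.781, 0.781))
    rep <- measure_volumes(geom$geometry, 50)
    av <- geom$analytic_volumes
    expect_equal(rep$new_bone_frontal, av$new_bone_frontal,
                 tolerance = 0.01)
    expect_equal(rep$new_bone_parietal, av$new_bone_parietal,
                 tolerance = 0.01)
    expect_equal(rep$suture_volume, av$suture_volume, tolerance = 0.01)
  }
})

test_that("volume additivity: two z-blocks sum to the single pass", {
  geom <- generate_bone_geometry(shape = c(50L, 101L, 220L),
                                 gap_frontal_px = c(8, 26),
                                 voxel_size = c(1, 0.9, 0.9))$geometry
  full <- measure_volumes(geom, 50)
  lo <- geom; lo$slices <- geom$slices[1:20]
  hi <- geom; hi$slices <- geom$slices[21:50]
  a <- measure_volumes(lo, 20)
  b <- measure_volumes(hi, 30)
  expect_equal(a$new_bone_total + b$new_bone_total, full$new_bone_total,
               tolerance = 1e-9)
  expect_equal(a$suture_volume + b$suture_volume, full$suture_volume,
               tolerance = 1e-9)
})

test_that("osteocyte classification is boundary-inclusive and excludes old bone", {
  geom <- generate_bone_geometry(shape = c(5L, 101L, 200L),
                                 old_offset_px = 30,
                                 gap_frontal_px = c(20, 20),
                                 gap_parietal_px = c(20, 20),
                                 voxel_size = c(1, 1, 1))$geometry
  mk <- function(z, y, x) seed_set(data.frame(z = z, y = y, x = x,
                                              peak_intensity = 255))
  # squarely inside the frontal new bone (x in (30, 50))
  expect_identical(classify_osteocytes(mk(2, 50, 40), geom), 1L)
  # exactly on the new (tetracycline) front line: included
  expect_identical(classify_osteocytes(mk(2, 50, 50), geom), 1L)
  # exactly on the old (calcein) front line: included
  expect_identical(classify_osteocytes(mk(2, 50, 30), geom), 1L)
  # old bone (x < 30) and suture (between the new fronts): excluded
  expect_identical(classify_osteocytes(mk(2, 50, 15), geom), 0L)
  expect_identical(classify_osteocytes(mk(2, 50, 100), geom), 0L)
  # exclusion mask removes an otherwise-counted seed
  excl <- array(FALSE, c(5, 101, 200))
  excl[3, 51, 41] <- TRUE
  expect_identical(classify_osteocytes(mk(2, 50, 40), geom,
                                       exclusion_mask = excl), 0L)
  # seeds on slices without geometry are skipped with a warning
  expect_warning(n <- classify_osteocytes(mk(7, 50, 40), geom),
                 "without geometry")
  expect_identical(n, 0L)
})

test_that("classification matches an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  geom <- generate_bone_geometry(shape = c(3L, 101L, 220L),
                                 old_offset_px = 25,
                                 gap_frontal_px = c(18, 40),
                                 gap_parietal_px = c(30, 12),
                                 voxel_size = c(1, 1, 1))$geometry
  set.seed(77)
  pts <- data.frame(z = 1, y = runif(1000, 1, 99), x = runif(1000, 1, 218))
  fr <- geom$slices[[2]]$fronts
  polys <- list(rbind(fr$old_front_frontal,
                      fr$new_front_frontal[2:1, ]),
                rbind(fr$old_front_parietal,
                      fr$new_front_parietal[2:1, ]))
  near_border <- sapply(seq_len(nrow(pts)), function(i) {
    any(sapply(polys, function(p)
      ivmhisto:::point_segment_dist(pts$y[i], pts$x[i], p) < 0.75))
  })
  pts <- pts[!near_border, ]
  oracle <- sapply(seq_len(nrow(pts)), function(i) {
    any(sapply(polys, function(p)
      mgcv::in.out(rbind(p, p[1, ]), cbind(pts$y[i], pts$x[i]))))
  })
  got <- classify_osteocytes(
    seed_set(data.frame(pts, peak_intensity = 255)), geom)
  expect_identical(got, sum(oracle))
  expect_gt(sum(oracle), 0)
})

test_that("cell density divides count by total new-bone volume", {
  geom <- generate_bone_geometry(shape = c(50L, 101L, 400L),
                                 old_offset_px = 50,
                                 gap_frontal_px = c(100, 100),
                                 gap_parietal_px = c(100, 100),
                                 voxel_size = c(1, 1, 1))
  rep <- measure_volumes(geom$geometry, 50)   # total 1e-3 mm^3
  expect_equal(cell_density(10, rep), 10 / rep$new_bone_total)
  expect_equal(cell_density(0, rep), 0)
  zero <- volume_report(0, 0, 0, 50, 1)
  expect_error(cell_density(10, zero), "no new bone")
})

test_that("fractional change follows the Day-28/Day-0 normalization", {
  expect_equal(fractional_change(100, 130), 30)
  expect_equal(fractional_change(57.2, 57.2), 0)
  expect_equal(fractional_change(200, 190), -5)
  expect_error(fractional_change(0, 10), "baseline")
  # documented asymmetry: dM(a,b) = -dM(b,a) * b / a
  a <- 120; b <- 90
  expect_equal(fractional_change(a, b),
               -fractional_change(b, a) * b / a)
})
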