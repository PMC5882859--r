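test_that("mean filter preserves constants and spreads a point source", {
  st <- image_stack(array(50, c(4, 4, 4)))
  expect_equal(mean_filter_3d(st, 1)$voxels, st$voxels)

  v <- array(0, c(7, 7, 7))
  v[4, 4, 4] <- 27
  out <- mean_filter_3d(image_stack(v), 1)$voxels
  expect_equal(sum(out == 1), 27)
  expect_equal(sum(out), 27)
  expect_error(mean_filter_3d(st, 0), "kernel must be >= 1")
})

test_that("mean filter clips windows at the borders", {
  v <- array(0, c(3, 3, 3))
  v[1, 1, 1] <- 27
  out <- mean_filter_3d(image_stack(v), 1)$voxels
  # corner window holds 8 voxels only
  expect_equal(out[1, 1, 1], 27 / 8)
  expect_equal(out[2, 2, 2], 1)
})

test_that("local maxima match the exhaustive neighborhood oracle", {
  blob <- function(a, c0, sig, amp) {
    d <- dim(a)
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      a[z, y, x] <- a[z, y, x] +
        amp * exp(-0.5 * sum(((c(z, y, x) - c0) / sig)^2))
    }
    a
  }
  a <- array(0, c(9, 15, 25))
  a <- blob(a, c(5, 8, 8), c(2, 2, 2), 100)
  a <- blob(a, c(5, 8, 12), c(2, 2, 2), 80)   # 4 px apart in x
  st <- image_stack(round(a))
  kern <- c(6L, 8L, 10L)
  mask <- local_maxima_3d(st, kern)
  expect_identical(mask, oracle_local_maxima(round(a), kern))
  lab <- ivmhisto:::label_components_26(which(mask), dim(a))
  expect_identical(max(lab), 1L)   # merged: one cluster for both blobs
})

test_that("well-separated blobs give disjoint maxima clusters", {
  a <- array(0, c(30, 40, 40))
  put <- function(a, c0, amp) {
    z <- c0[1]; y <- c0[2]; x <- c0[3]
    a[(z - 3):(z + 3), (y - 3):(y + 3), (x - 3):(x + 3)] <-
      a[(z - 3):(z + 3), (y - 3):(y + 3), (x - 3):(x + 3)] +
      amp * outer(outer(exp(-0.5 * ((-3:3) / 1.5)^2),
                        exp(-0.5 * ((-3:3) / 1.5)^2)),
                  exp(-0.5 * ((-3:3) / 1.5)^2))
    a
  }
  a <- put(a, c(8, 10, 10), 200)
  a <- put(a, c(22, 30, 30), 150)
  st <- image_stack(round(a))
  mask <- local_maxima_3d(st, c(6, 8, 10))
  lab <- ivmhisto:::label_components_26(which(mask), dim(a))
  expect_identical(max(lab), 2L)
})

test_that("background mode returns the most frequent intensity, ties toward lower", {
  v <- array(0, c(2, 10, 10))
  v[1, 1, 1:10] <- 200
  expect_identical(background_mode(image_stack(v)), 0L)
  w <- c(rep(5, 1000), rep(20, 1000))
  expect_identical(background_mode(vec_stack(w)), 5L)
  set.seed(3)
  u <- array(c(rep(7, 5000), sample(0:255, 500, TRUE)), c(5, 10, 110))
  expect_identical(background_mode(image_stack(u)), 7L)
})

test_that("step gating selects the first applicable step and clamps", {
  steps <- list(c(50, 2), c(255, 6))
  expect_equal(step_gate_cutoff(5, 30, steps), 7)
  expect_equal(step_gate_cutoff(5, 200, steps), 11)
  expect_warning(out <- step_gate_cutoff(5, 300, steps), "exceeds last")
  expect_equal(out, 11)
  expect_error(step_gate_cutoff(5, 30, list()), "nonempty")
  expect_error(detection_params(gating_steps = list(c(100, 2), c(50, 3))),
               "strictly increasing")
})

test_that("surround mean averages the gated dilation shell", {
  v <- array(50, c(5, 5, 5))
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  expect_equal(surround_mean(image_stack(v), m, 3, 0), 50)

  # shell values half 10s, half 30s; cutoff 20 keeps only the 30s
  v2 <- array(10, c(3, 9, 9))
  m2 <- array(FALSE, dim(v2))
  m2[2, 5, 5] <- TRUE
  sh <- oracle_surround_shell(m2, 2)
  idx <- which(sh)
  v2[idx[seq(1, length(idx), 2)]] <- 30
  got <- surround_mean(image_stack(v2), m2, 2, 20)
  expect_equal(got, 30)

  expect_error(surround_mean(image_stack(v), array(FALSE, c(5, 5, 5)), 3, 0),
               "no cells segmented")
})

test_that("surround shell equals brute-force dilation on a hand-built fixture", {
  set.seed(21)
  v <- array(sample(0:255, 125, TRUE), c(5, 5, 5))
  m <- array(FALSE, c(5, 5, 5))
  m[2, 2, 2] <- TRUE
  m[4, 4, 4] <- TRUE
  sh <- oracle_surround_shell(m, 1)
  expect_equal(surround_mean(image_stack(v), m, 1, 0), mean(v[sh]))
  # gate above every shell voxel: falls back to the ungated mean
  expect_equal(surround_mean(image_stack(v), m, 1, 256), mean(v[sh]))
})

test_that("the Tukey fence follows the exponential closed form and scales linearly", {
  expect_equal(tukey_threshold(0)$T, 0)
  k <- log(4) + 1.5 * log(3)
  t1 <- tukey_threshold(1)
  expect_equal(t1$Q1, log(4 / 3))
  expect_equal(t1$Q3, log(4))
  expect_equal(t1$T, k)
  expect_equal(tukey_threshold(10)$T, 10 * k)
  for (x in c(0.3, 2, 57.2)) {
    for (c in c(0.5, 3, 11)) {
      expect_equal(tukey_threshold(c * x)$T, c * tukey_threshold(x)$T)
    }
    th <- tukey_threshold(x)
    expect_true(th$T >= th$Q3 && th$Q3 >= th$Q1 && th$Q1 >= 0)
  }
  expect_error(tukey_threshold(-1), "x must be >= 0")
})

test_that("detect_seeds counts well-separated synthetic cells exactly", {
  sc <- small_scene(seed = 11, n = 20L)
  seeds <- detect_seeds(sc$stack, "TDTOMATO")
  expect_identical(count_cells(seeds), 20L)
  dev <- centroid_deviation(seeds, sc$truth, match_radius = 5)
  expect_lte(max(dev$mean_abs_dev), 2)
  expect_identical(dev$n_matched, 20L)
})

test_that("no seed pair sits within one voxel on all three axes", {
  sc <- small_scene(seed = 12, n = 15L)
  s <- detect_seeds(sc$stack, "TDTOMATO")$seeds
  for (i in seq_len(nrow(s) - 1)) {
    for (j in seq(i + 1, nrow(s))) {
      expect_true(any(abs(s[i, c("z", "y", "x")] - s[j, c("z", "y", "x")]) > 1))
    }
  }
})

test_that("cells below the Tukey fence yield an empty (count 0) result", {
  sc <- generate_cell_stack(synth_params(shape = c(30L, 96L, 96L),
                                         n_cells = 10L,
                                         intensity_range = c(3, 5),
                                         background_mean = 20,
                                         rng_seed = 4))
  seeds <- detect_seeds(sc$stack, "TDTOMATO")
  expect_identical(count_cells(seeds), 0L)
})

test_that("detect_seeds is translation-equivariant away from borders", {
  sc <- generate_cell_stack(synth_params(shape = c(40L, 192L, 192L),
                                         n_cells = 12L,
                                         margin = c(14, 16, 16),
                                         rng_seed = 8))
  s <- c(3L, 5L, 7L)
  rolled <- sc$stack
  rolled$channels$TDTOMATO$voxels <- roll3(sc$stack$channels$TDTOMATO$voxels, s)
  a <- detect_seeds(sc$stack, "TDTOMATO")$seeds
  b <- detect_seeds(rolled, "TDTOMATO")$seeds
  expect_identical(nrow(a), nrow(b))
  shifted <- a
  shifted$z <- a$z + s[1]; shifted$y <- a$y + s[2]; shifted$x <- a$x + s[3]
  ord <- function(d) d[order(d$z, d$y, d$x), c("z", "y", "x")]
  expect_equal(unname(as.matrix(ord(shifted))), unname(as.matrix(ord(b))),
               tolerance = 1e-8)
})

test_that("adding one well-separated bright cell raises the count by exactly one", {
  base <- small_scene(seed = 13, n = 12L)
  extra <- c(z = 33, y = 140, x = 140)
  sep <- synth_params()$min_separation
  tt <- as.matrix(base$truth$centroids)
  clash <- any(abs(tt[, 1] - extra[1]) <= sep[1] &
                 abs(tt[, 2] - extra[2]) <= sep[2] &
                 abs(tt[, 3] - extra[3]) <= sep[3])
  expect_false(clash)
  plus <- generate_cell_stack(synth_params(shape = c(40L, 160L, 160L),
                                           centers = rbind(tt, extra),
                                           rng_seed = 13))
  n0 <- count_cells(detect_seeds(base$stack, "TDTOMATO"))
  n1 <- count_cells(detect_seeds(plus$stack, "TDTOMATO"))
  expect_identical(n1, n0 + 1L)
})

test_that("count_cells is the seed count and concatenation adds", {
  empty <- seed_set(data.frame(z = numeric(0), y = numeric(0),
                               x = numeric(0), peak_intensity = numeric(0)))
  expect_identical(count_cells(empty), 0L)
  s <- data.frame(z = 1:20, y = 1:20, x = 1:20, peak_intensity = 255)
  expect_identical(count_cells(seed_set(s)), 20L)
  both <- seed_set(rbind(s, data.frame(z = 31:35, y = 1:5, x = 1:5,
                                       peak_intensity = 200)))
  expect_identical(count_cells(both), 25L)
})

test_that("seed CSV round trips", {
  dir <- withr::local_tempdir()
  sc <- small_scene(seed = 14, n = 8L, shape = c(30L, 120L, 120L))
  seeds <- detect_seeds(sc$stack, "TDTOMATO")
  path <- file.path(dir, "seeds.csv")
  write_seeds(seeds, path)
  back <- read_seeds(path, channel = "TDTOMATO")
  expect_equal(back$seeds, seeds$seeds)
  expect_identical(back$count, seeds$count)
})
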