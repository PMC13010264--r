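test_that("map_frame and frame_stack validate their geometry", {
  h <- matrix(0, 10, 12)
  expect_error(map_frame(h, matrix(0, 10, 11)), "dim")
  expect_error(map_frame(h, h, pixel_size = 0), "pixel_size")
  f1 <- map_frame(h, h, time = 0)
  f2 <- map_frame(h, h, time = 5)
  expect_error(frame_stack(list(f2, f1)), "increasing")
  st <- frame_stack(list(f1, f2))
  expect_equal(length(st), 2L)
  expect_error(map_frame(h, h, background_mask = matrix(TRUE, 10, 12),
                         fiber_mask = matrix(TRUE, 10, 12)), "disjoint")
})

test_that("plane leveling removes a known tilt and is idempotent", {
  set.seed(2)
  n <- 60
  bg_noise <- matrix(rnorm(n * n, 0, 0.1), n, n)
  tilt <- 0.01 * row(bg_noise) + 0.02 * col(bg_noise)
  fiber <- matrix(FALSE, n, n); fiber[25:35, ] <- TRUE
  h <- bg_noise + tilt + ifelse(fiber, 15, 0)
  fr <- map_frame(h, matrix(100, n, n), background_mask = !fiber,
                  fiber_mask = fiber)
  lev <- level_plane(fr)
  expect_lt(sd(lev$height[!fiber]), 0.11)          # residual ~ noise floor
  expect_lt(abs(median(lev$height[!fiber])), 1e-9)
  lev2 <- level_plane(lev)
  expect_equal(lev2$height, lev$height, tolerance = 1e-9)
  # tilt confined to the fiber leaves the leveling untouched
  h2 <- bg_noise + ifelse(fiber, 15 + tilt, 0)
  fr2 <- map_frame(h2, matrix(100, n, n), background_mask = !fiber)
  lev3 <- level_plane(fr2)
  base <- level_plane(map_frame(bg_noise + ifelse(fiber, 15, 0),
                                matrix(100, n, n), background_mask = !fiber))
  expect_equal(lev3$height[!fiber], base$height[!fiber], tolerance = 0.02)
  # insufficient background
  fr3 <- map_frame(h, matrix(100, n, n),
                   background_mask = matrix(FALSE, n, n))
  fr3$background_mask[1, 1:3] <- TRUE
  expect_error(level_plane(fr3), "background")
})

test_that("segmentation keeps elongated objects and drops specks", {
  set.seed(3)
  n <- 80
  h <- matrix(rnorm(n * n, 0, 0.2), n, n)
  h[38:44, 10:70] <- h[38:44, 10:70] + 20          # ridge, aspect >> 3
  h[10:12, 10:12] <- h[10:12, 10:12] + 20          # 9-px speck
  fr <- map_frame(h, matrix(100, n, n))
  seg <- segment_fiber(level_plane(fr), height_threshold = 5)
  footprint <- 7 * 61
  expect_lt(abs(sum(seg$fiber_mask) - footprint), 2 * (7 + 61) + 4)
  expect_false(any(seg$fiber_mask[10:12, 10:12]))
  expect_true(any(attr(seg, "excluded_mask")[10:12, 10:12]))
  expect_warning(segment_fiber(map_frame(matrix(0, 20, 20),
                                         matrix(1, 20, 20))), "empty")
})

test_that("HOPG normalization fixes the background and cancels gain", {
  set.seed(4)
  n <- 50
  bg <- matrix(TRUE, n, n); bg[20:30, ] <- FALSE
  E <- matrix(95, n, n); E[!bg] <- 15
  fr <- map_frame(matrix(0, n, n), E, background_mask = bg,
                  fiber_mask = !bg)
  nm <- normalize_modulus(fr, E_hopg_nominal = 100)
  expect_equal(mean(nm$modulus[bg]), 100, tolerance = 1e-12)
  # already-nominal background: identity
  fr2 <- map_frame(matrix(0, n, n), matrix(100, n, n), background_mask = bg)
  expect_equal(normalize_modulus(fr2, 100)$modulus, fr2$modulus)
  # uniform 2x drift is invisible after correction
  fr3 <- fr; fr3$modulus <- fr$modulus * 2
  expect_equal(normalize_modulus(fr3, 100)$modulus, nm$modulus,
               tolerance = 1e-12)
  fr4 <- fr; fr4$modulus <- fr$modulus * 0
  expect_error(normalize_modulus(fr4, 100), "positive")
})

test_that("nanodomain ROIs enforce the minimum analysis area", {
  roi <- nanodomain_roi(c(1, 50), c(1, 50), pixel_size = 2)
  expect_equal(roi$area_nm2, 10000)
  expect_equal(roi$n_px, 2500L)
  expect_error(nanodomain_roi(c(1, 10), c(1, 10), pixel_size = 2), "minimum")
})

test_that("E*_av is an exact arithmetic mean with ROI-split consistency", {
  n <- 100
  vals <- matrix(rep(c(10, 20), each = n * n / 2), n, n)
  fr <- map_frame(matrix(5, n, n), vals, fiber_mask = matrix(TRUE, n, n))
  expect_equal(as.numeric(estar_av(fr)), 15)
  const <- map_frame(matrix(5, n, n), matrix(7, n, n),
                     fiber_mask = matrix(TRUE, n, n))
  expect_equal(as.numeric(estar_av(const)), 7)
  # splitting a domain: whole mean equals count-weighted mean of parts
  set.seed(5)
  fr$modulus <- matrix(rnorm(n * n, 15, 2), n, n)
  left <- nanodomain_roi(c(1, n), c(1, 37), pixel_size = 2)
  right <- nanodomain_roi(c(1, n), c(38, n), pixel_size = 2)
  e_l <- estar_av(fr, left); e_r <- estar_av(fr, right)
  nl <- attr(e_l, "n"); nr <- attr(e_r, "n")
  expect_equal((as.numeric(e_l) * nl + as.numeric(e_r) * nr) / (nl + nr),
               as.numeric(estar_av(fr)), tolerance = 1e-12)
  # insufficient points -> excluded flag
  tiny <- estar_av(fr, nanodomain_roi(c(1, 50), c(1, 50), pixel_size = 2),
                   min_points = 3000)
  expect_true(attr(tiny, "excluded"))
  expect_true(is.na(tiny))
})

test_that("E* distribution summaries detect shape and irregularity", {
  set.seed(6)
  # left-skewed unimodal: reflected gamma around a 15 MPa peak
  v <- 18 - rgamma(4000, shape = 2, scale = 1.5)
  s <- estar_distribution(frame_from_values(v))
  expect_lt(s$skewness, 0)
  expect_true(s$unimodal)
  expect_false(s$excluded)
  expect_equal(s$mean, mean(v), tolerance = 1e-6)
  # constant field
  sc <- estar_distribution(frame_from_values(rep(12, 3600)))
  expect_equal(sc$mode, 12)
  expect_equal(sc$mean, 12)
  expect_equal(sc$skewness, 0)
  expect_true(sc$unimodal)
  # well-separated mixture is flagged irregular
  vb <- c(rnorm(2000, 10, 0.8), rnorm(2000, 25, 0.8))
  sb <- estar_distribution(frame_from_values(vb))
  expect_false(sb$unimodal)
  expect_true(sb$excluded)
  # insufficient data
  si <- estar_distribution(frame_from_values(rnorm(100, 15)),
                           min_points = 2500)
  expect_true(si$excluded)
})

test_that("fiber volume integrates heights over the mask", {
  h <- matrix(0, 5, 5); h[3, 3] <- 10
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  fr <- map_frame(h, matrix(1, 5, 5), pixel_size = 2, fiber_mask = m)
  expect_equal(fiber_volume(fr), 40)
  expect_equal(fiber_volume(fr, mask = matrix(FALSE, 5, 5)), 0)
  # unleveled frame warns
  fr2 <- map_frame(h + 3, matrix(1, 5, 5), pixel_size = 2, fiber_mask = m,
                   background_mask = !m)
  expect_warning(fiber_volume(fr2), "leveled")
})

test_that("relative activity tracks the programmed pixel-sum decay", {
  n <- 20
  mk <- function(h, t) map_frame(matrix(h, n, n), matrix(1, n, n),
                                 time = t, fiber_mask = matrix(TRUE, n, n))
  # constant stack
  st <- frame_stack(lapply(0:3, function(i) mk(10, i * 5)))
  expect_equal(relative_activity(st)$activity, c(NA, 0, 0, 0))
  # exactly 1% of P0 per minute
  hs <- 10 * (1 - 0.01 * (0:3) * 5)
  st2 <- frame_stack(Map(mk, hs, (0:3) * 5))
  expect_equal(relative_activity(st2)$activity, c(NA, 1, 1, 1),
               tolerance = 1e-12)
  st3 <- frame_stack(lapply(0:1, function(i) mk(0, i * 5)))
  expect_error(relative_activity(st3), "zero")
})

test_that("0-100% scaling is affine-invariant and guards constants", {
  expect_equal(scale_series(c(10, 15, 20)), c(0, 50, 100))
  expect_warning(out <- scale_series(c(5, 5, 5)), "undefined")
  expect_true(all(is.na(out)))
  v <- c(3, 9, 4, 7)
  expect_equal(scale_series(v), scale_series(2.5 * v - 7))
})

test_that("text map IO round-trips matrices", {
  set.seed(7)
  m <- matrix(rnorm(30), 5, 6)
  path <- withr::local_tempfile(fileext = ".txt")
  write_map_txt(m, path)
  expect_equal(read_map_txt(path), m, tolerance = 1e-9)
})
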