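test_that("trajectories normalize volume and drop flagged frames", {
  tr <- degradation_trajectory(times = c(0, 5, 10, 15),
                               volumes = c(200, 180, 160, 140),
                               estar_av = c(10, 11, 12, 13))
  expect_equal(tr$rel_volume, c(1, 0.9, 0.8, 0.7))
  expect_equal(tr$estar_scaled, c(0, 100 / 3, 200 / 3, 100))
  expect_equal(tr$activity[2], 100 * 0.1 / 5)
  # flagged frames vanish
  tr2 <- degradation_trajectory(times = c(0, 5, 10, 15),
                                volumes = c(200, 180, 160, 140),
                                estar_av = c(10, NA, 12, 13),
                                excluded = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(tr2$time, c(0, 15))
  expect_error(degradation_trajectory(1:3, c(1, 1, 1), c(1, 1, 1),
                                      excluded = rep(TRUE, 3)), "empty")
})

test_that("a no-enzyme control keeps relative volume at unity", {
  ph <- small_phantom()
  sc <- degradation_scenario("ablation", n_frames = 4, ablation_rate_nm = 0)
  res <- gen_ablation_stack(ph, sc, seed = 31)
  tr <- build_trajectory(process_stack(res$stack))
  expect_true(all(abs(tr$rel_volume - 1) < 0.02))
})

test_that("rate-stiffness correlation has the programmed sign structure", {
  # activity proportional to (100 - scaled stiffness): strong anticorrelation
  set.seed(32)
  est <- seq(10, 30, length.out = 12)
  sc <- scale_series(est)
  act <- 0.05 * (100 - sc) + rnorm(12, 0, 0.05)
  tr <- data.frame(activity = c(NA, act[-1]), estar_scaled = sc)
  cc <- correlate_rate_stiffness(tr)
  expect_lt(cc$spearman, -0.9)
  expect_lt(cc$slope, 0)
  # constant activity against varying stiffness: slope ~ 0
  tr2 <- data.frame(activity = c(NA, rep(2, 11)), estar_scaled = sc)
  cc2 <- correlate_rate_stiffness(tr2)
  expect_equal(cc2$slope, 0, tolerance = 1e-12)
  # constant stiffness: undefined flag
  tr3 <- data.frame(activity = c(NA, act[-1]), estar_scaled = rep(50, 12))
  expect_true(correlate_rate_stiffness(tr3)$undefined)
  # rank correlation invariant under affine rescale of the stiffness
  tr4 <- tr; tr4$estar_scaled <- 3 * tr$estar_scaled - 40
  expect_equal(correlate_rate_stiffness(tr4)$spearman, cc$spearman)
})

test_that("pattern classification separates linear from flat-then-rising", {
  # exactly linear -> continuous
  loss <- seq(0, 60, length.out = 12)
  tr_lin <- data.frame(rel_volume = 1 - loss / 100,
                       estar_scaled = loss * 5 / 3)
  expect_equal(classify_pattern(tr_lin)$label, "continuous")
  # flat then linear with a breakpoint at 40% loss
  set.seed(33)
  y <- ifelse(loss < 40, 0, (loss - 40) * 5) + rnorm(12, 0, 1.5)
  tr_bi <- data.frame(rel_volume = 1 - loss / 100,
                      estar_scaled = scale_series(y))
  pat <- classify_pattern(tr_bi)
  expect_equal(pat$label, "biphasic")
  expect_lt(abs(pat$breakpoint - 40), 5)
  # too few points
  short <- data.frame(rel_volume = c(1, 0.9, 0.8),
                      estar_scaled = c(0, 50, 100))
  expect_true(classify_pattern(short)$insufficient_data)
})

test_that("pure noise rarely triggers a confident biphasic call", {
  set.seed(34)
  fp <- vapply(1:60, function(i) {
    tr <- degradation_trajectory(
      times = seq(0, 90, 10),
      volumes = 1e5 * (1 - 0.03 * (0:9)) * (1 + rnorm(10, 0, 0.01)),
      estar_av = 15 + rnorm(10, 0, 0.3))
    classify_pattern(tr)$label == "biphasic"
  }, logical(1))
  expect_lte(mean(fp), 0.10)
})

test_that("breakpoint estimates tighten as noise vanishes", {
  loss <- seq(0, 60, length.out = 15)
  bp_err <- vapply(c(2, 0.5, 0), function(sd) {
    set.seed(35)
    errs <- vapply(1:10, function(i) {
      y <- ifelse(loss < 35, 0, (loss - 35) * 4) + rnorm(15, 0, sd)
      p <- classify_pattern(data.frame(rel_volume = 1 - loss / 100,
                                       estar_scaled = y))
      if (is.na(p$breakpoint)) NA_real_ else abs(p$breakpoint - 35)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  expect_lt(bp_err[3], 1e-6)
  expect_lte(bp_err[3], bp_err[1] + 1e-9)
})
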