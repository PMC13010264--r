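test_that("phantom rasterization matches the closed-form ridge volume", {
  ph <- gen_fibril_phantom()
  raster <- sum(ph$height0) * ph$pixel_size^2
  expect_lt(abs(raster / ph$volume_true - 1), 0.02)
  ph2 <- small_phantom(width_nm = 24, height_nm = 16, shell_thickness_nm = 6)
  expect_lt(abs(sum(ph2$height0) * 4 / ph2$volume_true - 1), 0.02)
})

test_that("core-shell depth profile hits its construction endpoints", {
  ph <- gen_fibril_phantom()
  expect_equal(depth_modulus(ph, 0), ph$E_shell)
  expect_equal(depth_modulus(ph, ph$shell_thickness_nm), ph$E_core)
  expect_equal(depth_modulus(ph, ph$shell_thickness_nm + 5), ph$E_core)
  d <- seq(0, ph$shell_thickness_nm, length.out = 20)
  expect_true(all(diff(depth_modulus(ph, d)) > 0))
  # initial surface: shell modulus, softened inside soft segments
  E0 <- fibrildyn:::surface_modulus_map(ph, 0, ph$height0 > 0)
  on_fiber <- ph$height0 > 0
  expect_true(all(abs(E0[on_fiber] -
    rep(ph$E_shell * ph$soft_col_factor, each = nrow(E0))[on_fiber]) < 1e-9))
})

test_that("phantom geometry constraints are enforced", {
  expect_error(gen_fibril_phantom(length_nm = 100), ">= 250")
  expect_error(gen_fibril_phantom(E_core = 10, E_shell = 15), "E_core")
  expect_error(gen_fibril_phantom(shell_thickness_nm = 12, height_nm = 20),
               "shell thickness")
  expect_error(gen_fibril_phantom(soft_factor = 1.5), "soft_factor")
})

test_that("a zero-rate ablation scenario leaves the stack static", {
  ph <- small_phantom()
  sc <- degradation_scenario("ablation", n_frames = 3, ablation_rate_nm = 0,
                             drift_nm_per_frame = c(0, 0),
                             height_noise_sd = 0, modulus_noise_frac = 0,
                             gain_jitter = 0, tilt_nm_per_px = c(0, 0))
  res <- gen_ablation_stack(ph, sc, seed = 1)
  expect_equal(res$truth$volume, rep(res$truth$volume[1], 3))
  act <- relative_activity(res$stack, masks = res$truth$masks)
  expect_equal(act$activity, c(NA, 0, 0))
})

test_that("uncoupled full-depth erosion removes the fiber entirely", {
  ph <- small_phantom()
  sc <- degradation_scenario("ablation", n_frames = 3,
                             ablation_rate_nm = 15,
                             stiffness_coupling = FALSE)
  res <- gen_ablation_stack(ph, sc, seed = 1)
  expect_equal(res$truth$volume[3], 0)
  expect_true(is.na(res$truth$surface_modulus[3]))
})

test_that("ablation truth couples stiffness rise to volume loss", {
  ph <- gen_fibril_phantom()
  res <- gen_ablation_stack(ph, seed = 3)
  tr <- res$truth
  expect_true(all(diff(tr$volume) < 0))
  expect_true(all(diff(tr$surface_modulus) > 0))
  # erosion never exceeds the shell under stiffness coupling
  expect_lt(max(tr$surface_modulus), ph$E_core)
})

test_that("pipeline recovers the programmed ablation volume schedule", {
  ph <- gen_fibril_phantom()
  res <- gen_ablation_stack(ph, seed = 4)
  pr <- process_stack(res$stack)
  rel_meas <- pr$per_frame$volume_nm3 / pr$per_frame$volume_nm3[1]
  rel_true <- res$truth$volume / res$truth$volume[1]
  expect_lt(max(abs(rel_meas - rel_true)), 0.03)
})

test_that("fragmentation truth is flat-then-rising with conserved order", {
  ph <- gen_fibril_phantom()
  for (seed in c(2, 5)) {
    res <- gen_fragmentation_stack(ph, seed = seed, corrupt = FALSE)
    tr <- res$truth
    loss <- 100 * (1 - tr$volume / tr$volume[1])
    m <- tr$surface_modulus / tr$surface_modulus[1]
    expect_true(all(diff(tr$volume) <= 0))
    # early loss (first 20%) leaves the surface stiffness within 5%
    expect_lt(max(abs(m[loss <= 20] - 1)), 0.05)
    # by the end the stiffness has risen appreciably
    expect_gt(m[length(m)], 1.2)
    expect_true(is.finite(tr$breakpoint_loss_pct))
  }
})

test_that("fragmentation stacks are reproducible under a fixed seed", {
  ph <- small_phantom()
  a <- gen_fragmentation_stack(ph, seed = 9)
  b <- gen_fragmentation_stack(ph, seed = 9)
  expect_identical(a$truth$volume, b$truth$volume)
  expect_identical(a$stack$frames[[5]]$height, b$stack$frames[[5]]$height)
  sc0 <- degradation_scenario("fragmentation", nucleation_intensity = 0,
                              late_ablation_rate_nm = 0)
  expect_warning(gen_fragmentation_stack(ph, sc0, seed = 1), "no-op|nucleate")
})

test_that("trajectory generator reports ground truth consistently", {
  tr <- gen_degradation_trajectory("ablation", seed = 21)
  expect_s3_class(tr, "degradation_trajectory")
  truth <- attr(tr, "truth")
  expect_equal(nrow(tr), length(truth$volume))
  expect_true(all(diff(tr$rel_volume) < 0.02))
  tr2 <- gen_degradation_trajectory("ablation", seed = 21)
  expect_identical(tr$estar_av, tr2$estar_av)
})
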