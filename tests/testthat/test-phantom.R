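test_that("kidney shape is a single component with near-ellipse area", {
  cfg <- phantom_config(image_size = c(128, 128), semi_axes = c(32, 17),
                        notch_depth = 0)
  m <- make_kidney_shape(cfg)
  expect_equal(sum(m$labels), pi * 32 * 17, tolerance = 0.02)
  expect_equal(max(EBImage::bwlabel(m$labels)), 1)
  cfgn <- phantom_config(image_size = c(128, 128), semi_axes = c(32, 17),
                         notch_depth = 0.35)
  mn <- make_kidney_shape(cfgn)
  expect_equal(max(EBImage::bwlabel(mn$labels)), 1)
  expect_gte(sum(mn$labels), 0.5 * pi * 32 * 17)
  expect_lt(sum(mn$labels), sum(m$labels))
  expect_identical(make_kidney_shape(cfgn)$labels, mn$labels) # deterministic
  expect_error(phantom_config(image_size = c(64, 64), semi_axes = c(40, 20)),
               "bounds")
})

test_that("enhancement follows the gamma-variate curve exactly when noiseless", {
  cfg <- phantom_config(image_size = c(96, 96), n_frames = 30, semi_axes = c(24, 13),
                        t0 = 5, alpha = 3, beta_t = 0.5, noise_var = 0, seed = 2)
  sq <- make_dce_sequence(cfg)
  kid <- sq$truth$labels == 1
  means <- vapply(sq$frames, function(f) mean(f$pixels[kid]), numeric(1))
  # pre-arrival frames carry exactly the baseline
  expect_true(all(abs(means[1:5] - cfg$baseline) < 1e-12))
  # analytic peak at t0 + alpha/beta
  expect_equal(which.max(means), cfg$t0 + cfg$alpha / cfg$beta_t)
  # gamma-variate shape: non-decreasing up to the peak, non-increasing after
  pk <- which.max(means)
  expect_true(all(diff(means[cfg$t0:pk]) >= 0))
  expect_true(all(diff(means[pk:length(means)]) <= 0))
})

test_that("configured noise variance is realized on the pixel scale", {
  cfg0 <- phantom_config(image_size = c(128, 128), n_frames = 2, semi_axes = c(32, 17),
                         noise_var = 0, seed = 5)
  cfg1 <- phantom_config(image_size = c(128, 128), n_frames = 2, semi_axes = c(32, 17),
                         noise_var = 0.01, seed = 5)
  clean <- make_dce_sequence(cfg0)$frames[[1]]$pixels
  noisy <- make_dce_sequence(cfg1)$frames[[1]]$pixels
  expect_equal(stats::var(as.vector(noisy - clean)), 0.01, tolerance = 0.2)
})

test_that("early frames have strictly lower contrast-to-noise ratio than the peak frame", {
  cfg <- phantom_config(image_size = c(96, 96), n_frames = 20, semi_axes = c(24, 13),
                        t0 = 6, beta_t = 0.5, noise_var = 0.01, seed = 9)
  sq <- make_dce_sequence(cfg)
  kid <- sq$truth$labels == 1
  cnr <- vapply(sq$frames, function(f) {
    abs(mean(f$pixels[kid]) - mean(f$pixels[!kid])) / sqrt(cfg$noise_var)
  }, numeric(1))
  peak <- which.max(vapply(sq$frames, function(f) mean(f$pixels[kid]), numeric(1)))
  expect_true(all(cnr[1:min(5, cfg$t0)] < cnr[peak]))
})

test_that("zero corruption reproduces the truth exactly and corruption is seeded", {
  truth <- small_sequence()$truth
  u0 <- corrupt_probability_map(truth, corruption_config())
  expect_identical(u0$p_kidney, truth$labels + 0)
  cc <- corruption_config(n_fp_blobs = 3, fp_blob_radius = c(4, 7), n_fn_holes = 2,
                          fn_hole_radius = c(2, 4), boundary_blur_sigma = 1,
                          label_noise_level = 0.1, seed = 7)
  u1 <- corrupt_probability_map(truth, cc)
  u2 <- corrupt_probability_map(truth, cc)
  expect_identical(u1$p_kidney, u2$p_kidney)
  expect_true(all(u1$p_kidney >= 0 & u1$p_kidney <= 1))
})

test_that("planted FP blobs create exactly that many extra components", {
  truth <- small_sequence()$truth
  cc <- corruption_config(n_fp_blobs = 3, fp_blob_radius = c(4, 6), seed = 21)
  u <- corrupt_probability_map(truth, cc)
  comp <- EBImage::bwlabel((u$p_kidney > 0.5) * 1L)
  expect_equal(max(comp), 1 + 3)
})

test_that("overlap with truth degrades monotonically in blob and hole counts", {
  truth <- small_sequence()$truth
  d_blob <- vapply(0:3, function(k) {
    cc <- corruption_config(n_fp_blobs = k, fp_blob_radius = c(4, 6), seed = 13)
    u <- corrupt_probability_map(truth, cc)
    dice(label_mask((u$p_kidney > 0.5) * 1L), truth)
  }, numeric(1))
  expect_true(all(diff(d_blob) <= 0))
  d_hole <- vapply(0:3, function(k) {
    cc <- corruption_config(n_fn_holes = k, fn_hole_radius = c(2, 4), seed = 13)
    u <- corrupt_probability_map(truth, cc)
    dice(label_mask((u$p_kidney > 0.5) * 1L), truth)
  }, numeric(1))
  expect_true(all(diff(d_hole) <= 0))
})

test_that("cohorts are deterministic and geometrically varied", {
  base <- small_base_config(noise_var = 0)
  co1 <- make_cohort(4, base, small_native_variability(), seed = 5)
  co2 <- make_cohort(4, base, small_native_variability(), seed = 5)
  for (i in 1:4) {
    expect_identical(co1[[i]]$truth$labels, co2[[i]]$truth$labels)
  }
  dd <- utils::combn(4, 2, function(ij) dice(co1[[ij[1]]]$truth, co1[[ij[2]]]$truth))
  expect_true(any(dd < 1))
  zero <- lapply(cohort_variability("native"), function(x) 0)
  co0 <- make_cohort(3, base, zero, seed = 5)
  expect_identical(co0[[1]]$truth$labels, co0[[2]]$truth$labels)
  expect_identical(co0[[2]]$truth$labels, co0[[3]]$truth$labels)
  expect_error(make_cohort(1, base), "at least 2")
})
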