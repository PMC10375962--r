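# independent scalar evaluation of the Bayesian label-probability formulas,
# used as the oracle against the vectorized implementation
prior_oracle <- function(n_k, n, beta, l = 2) {
  o <- if (n_k == 0 || n_k == n) 1 else 2
  p_obs <- function(n_l) ((n_l + beta) / (n + beta * o)) * (n / (n + l - o))
  p_unseen <- (1 / (l - o)) * (1 - n / (n + l - o))
  if (o == 2) c(k = p_obs(n_k), b = p_obs(n - n_k))
  else if (n_k == n) c(k = p_obs(n), b = p_unseen)
  else c(k = p_unseen, b = p_obs(n))
}

masks_with_count <- function(n_k, n) {
  lapply(seq_len(n), function(i) label_mask(matrix((i <= n_k) * 1L, 8, 8)))
}

test_that("prior probabilities match hand evaluations of the smoothing formulas", {
  # pixel kidney in 2 of 3, beta = 1: (2+1)/(3+2) = 0.6
  p <- build_shape_prior(masks_with_count(2, 3), beta = 1)
  expect_equal(p$p_kidney[1, 1], 0.6, tolerance = 1e-12)
  # pixel kidney in all 4, beta = 1: [(4+1)/(4+1)]*[4/5] = 0.8, unseen 0.2
  p4 <- build_shape_prior(masks_with_count(4, 4), beta = 1)
  expect_equal(p4$p_kidney[1, 1], 0.8, tolerance = 1e-12)
  expect_equal(1 - p4$p_kidney[1, 1], 0.2, tolerance = 1e-12)
})

test_that("prior matches the scalar oracle on exhaustive small count tables", {
  for (n in 2:6) for (n_k in 0:n) for (beta in c(0.5, 1, 2)) {
    p <- build_shape_prior(masks_with_count(n_k, n), beta = beta)
    expected <- prior_oracle(n_k, n, beta)
    expect_equal(p$p_kidney[1, 1], unname(expected["k"]), tolerance = 1e-12,
                 label = sprintf("P_K at N=%d N_K=%d beta=%g", n, n_k, beta))
    expect_equal(1 - p$p_kidney[1, 1], unname(expected["b"]), tolerance = 1e-12)
    # normalization and strict interior
    expect_true(all(p$p_kidney > 0 & p$p_kidney < 1))
  }
})

test_that("Laplace-smoothing reduction holds for observed-both pixels at beta = 1", {
  for (n in c(3, 5, 8)) for (n_k in 1:(n - 1)) {
    p <- build_shape_prior(masks_with_count(n_k, n), beta = 1)
    expect_equal(p$p_kidney[1, 1], (n_k + 1) / (n + 2), tolerance = 1e-12)
  }
})

test_that("P_K approaches 1 monotonically as the kidney count saturates", {
  ladder <- vapply(2:100, function(n) {
    build_shape_prior(masks_with_count(n, n), beta = 1)$p_kidney[1, 1]
  }, numeric(1))
  expect_true(all(diff(ladder) > 0))
  expect_true(all(ladder < 1))
})

test_that("prior rejects invalid inputs", {
  expect_error(build_shape_prior(masks_with_count(1, 1)), "at least 2")
  expect_error(build_shape_prior(masks_with_count(1, 3), beta = 0), "positive")
  bad <- c(masks_with_count(1, 2), list(label_mask(matrix(0, 9, 9))))
  expect_error(build_shape_prior(bad), "geometries")
})

test_that("affine transforms compose, invert and apply consistently", {
  tf <- affine_transform(matrix(c(cos(0.3), sin(0.3), -sin(0.3), cos(0.3)), 2, 2),
                         c(4, -2))
  pts <- cbind(c(1, 10, 5), c(2, 7, 9))
  back <- apply_affine(invert_affine(tf), apply_affine(tf, pts))
  expect_equal(back, pts, tolerance = 1e-12)
  comp <- compose_affine(invert_affine(tf), tf)
  expect_equal(comp$A, diag(2), tolerance = 1e-12)
  expect_equal(comp$t, c(0, 0), tolerance = 1e-12)
  expect_error(affine_transform(matrix(0, 2, 2)), "singular")
})

test_that("mask warping is exact for integer translations and near-lossless on round trips", {
  m <- disk_mask(64, 64, 30, 28, 15)
  expect_identical(warp_mask(m, affine_transform())$labels, m$labels)
  tf <- affine_transform(diag(2), c(3, 5))
  shifted <- warp_mask(m, tf)$labels
  expect_identical(shifted[10:60, 10:60], m$labels[10:60 - 5, 10:60 - 3])
  rot <- affine_transform(matrix(c(cos(0.2), sin(0.2), -sin(0.2), cos(0.2)), 2, 2),
                          c(2, -1))
  m30 <- disk_mask(96, 96, 48, 48, 30)
  rt <- warp_mask(warp_mask(m30, rot), invert_affine(rot))
  expect_gte(dice(rt, m30), 0.98)
})

test_that("registration recovers identity, translations and rotations", {
  sq <- small_sequence(seed = 7, noise_var = 0)
  img <- sq$frames[[3]]
  self <- register_affine(img, img)
  expect_lt(max(abs(self$transform$A - diag(2))), 1e-2)
  expect_lt(max(abs(self$transform$t)), 0.1)

  tf_shift <- affine_transform(diag(2), c(7, -4))
  reg <- register_affine(warp_image(img, tf_shift), img)
  expect_lt(max(abs(reg$transform$t - (-tf_shift$t))), 0.5)

  a <- 10 * pi / 180
  tf_rot <- affine_transform(matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2),
                             c(64, 64) - c(64 * cos(a) - 64 * sin(a),
                                           64 * sin(a) + 64 * cos(a)))
  reg2 <- register_affine(warp_image(img, tf_rot), img)
  ang <- atan2(reg2$transform$A[2, 1], reg2$transform$A[1, 1]) * 180 / pi
  expect_lt(abs(ang - (-10)), 1)
  expect_error(register_affine(image_grid(matrix(1, 128, 128)), img), "constant")
})

test_that("the prior serializes and reloads faithfully", {
  prior <- small_prior()
  dir <- withr::local_tempdir()
  write_shape_prior(prior, dir)
  back <- read_shape_prior(dir)
  expect_lt(max(abs(back$p_kidney - prior$p_kidney)), 1e-6)
  expect_equal(back$n_images, prior$n_images)
  expect_equal(back$beta, prior$beta)
})
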