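uniform_prior <- function(h, w) {
  # P_K = P_B = 0.5 everywhere: two half-covering masks
  m1 <- label_mask(matrix(rep(c(1L, 0L), length.out = h * w), h, w))
  m2 <- label_mask(1L - m1$labels)
  build_shape_prior(list(m1, m2), beta = 1)
}

test_that("regularized Heaviside matches its closed form at branch and interior points", {
  eps <- 1.5
  expect_identical(heaviside_eps(2, eps), 1)       # above the band
  expect_identical(heaviside_eps(-2, eps), 0)      # below the band
  expect_equal(heaviside_eps(0, eps), 0.5, tolerance = 1e-15)
  # continuity at +/- eps: middle branch evaluates to exactly 1 and 0
  expect_equal(heaviside_eps(eps - 1e-15, eps), 1, tolerance = 1e-12)
  expect_equal(heaviside_eps(-eps + 1e-15, eps), 0, tolerance = 1e-12)
  phi <- seq(-2 * eps, 2 * eps, length.out = 2001)
  v <- heaviside_eps(phi, eps)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v >= 0 & v <= 1))
  expect_error(heaviside_eps(0, 0), "positive")
})

test_that("regularized Dirac is even, compact, maximal at zero and integrates to one", {
  eps <- 1.5
  expect_identical(dirac_eps(2, eps), 0)
  expect_equal(dirac_eps(0, eps), 2 / 3, tolerance = 1e-15) # 1/(2e) + 1/(2e) at e = 1.5
  phi <- seq(0, 2 * eps, length.out = 500)
  expect_equal(dirac_eps(phi, eps), dirac_eps(-phi, eps), tolerance = 1e-15)
  expect_true(all(dirac_eps(phi, eps) <= dirac_eps(0, eps)))
  int <- stats::integrate(function(x) dirac_eps(x, eps), -eps, eps,
                          subdivisions = 10000L, rel.tol = 1e-10)
  expect_equal(int$value, 1, tolerance = 1e-6)
})

test_that("the Dirac is the numerical derivative of the Heaviside", {
  eps <- 1.5
  phi <- seq(-2 * eps, 2 * eps, length.out = 4001)
  h <- 1e-6
  num <- (heaviside_eps(phi + h, eps) - heaviside_eps(phi - h, eps)) / (2 * h)
  expect_lt(max(abs(num - dirac_eps(phi, eps))), 1e-4)
})

test_that("curvature matches analytic values on canonical fields", {
  # signed-distance disk: curvature -1/r near the zero level
  for (r in c(10, 20, 40)) {
    phi <- init_phi(list(shape = "circle", center = c(64, 64), radius = r), c(128, 128))
    k <- curvature(phi)
    g <- expand.grid(row = 1:128, col = 1:128)
    d <- sqrt((g$col - 64)^2 + (g$row - 64)^2)
    sel <- abs(phi) < 0.5 & matrix(d, 128, 128) >= 3
    expect_equal(mean(k[sel]), -1 / r, tolerance = 0.05)
  }
  # planar field: zero curvature in the interior
  g <- coord <- expand.grid(row = 1:64, col = 1:64)
  plane <- matrix(0.3 * coord$col + 0.7 * coord$row, 64, 64)
  expect_lt(max(abs(curvature(plane)[3:62, 3:62])), 1e-10)
  # constant field: safeguard keeps everything finite and zero
  expect_true(all(curvature(matrix(1, 32, 32)) == 0))
})

test_that("energy terms evaluate exactly in degenerate configurations", {
  sq <- small_sequence()
  truth <- sq$truth
  u <- corrupt_probability_map(truth, corruption_config())
  prior <- small_prior()
  params <- levelset_params()
  h <- nrow(truth$labels); w <- ncol(truth$labels)
  # all-kidney phi: no zero crossing, V = 1 everywhere
  e_in <- levelset_energy(matrix(10, h, w), u, prior, params)
  expect_equal(e_in$E_length, 0)
  expect_equal(e_in$E_data, sum((1 - u$p_kidney) * (1 - prior$p_kidney)),
               tolerance = 1e-9)
  # all-background phi: V = 0 everywhere
  e_out <- levelset_energy(matrix(-10, h, w), u, prior, params)
  expect_equal(e_out$E_data, sum(u$p_kidney * prior$p_kidney), tolerance = 1e-9)
  # perfect agreement: U = P = truth indicator makes the data term vanish
  truth_prob <- probability_map(truth$labels + 0)
  fake_prior <- prior
  fake_prior$p_kidney <- truth$labels + 0
  # scale the signed distance so the pixel-quantized boundary (+/- 1 px) lies
  # outside the regularization band; V is then exactly the truth indicator
  phi_truth <- 2 * init_phi(list(shape = "from_mask", mask = truth), truth)
  e_perfect <- levelset_energy(phi_truth, truth_prob, fake_prior, params)
  expect_equal(e_perfect$E_data, 0, tolerance = 1e-12)
})

test_that("evolution updates only the band and follows the force sign", {
  prior <- uniform_prior(32, 32)
  u <- probability_map(matrix(0.5, 32, 32))
  params <- levelset_params()
  # |phi| > eps everywhere: nothing moves, bit-identical
  phi_far <- matrix(rep(c(5, -5), each = 16 * 32), 32, 32)
  expect_identical(evolve_step(phi_far, u, prior, params), phi_far)
  # balanced evidence: zero data force, flat phi stays put
  phi0 <- matrix(0.5, 32, 32)
  expect_identical(evolve_step(phi0, u, prior, params), phi0)
  # single band pixel with dominant kidney evidence rises (length term off)
  uk <- matrix(0.5, 32, 32); uk[16, 16] <- 0.9
  u2 <- probability_map(uk)
  p2 <- levelset_params(lambda1 = 1e-9, lambda2 = 6)
  phi1 <- evolve_step(phi0, u2, uniform_prior(32, 32), p2)
  expect_gt(phi1[16, 16], phi0[16, 16])
  expect_equal(phi1[1, 1], phi0[1, 1], tolerance = 1e-9)
})

test_that("band locality holds across a full segmentation run", {
  sq <- small_sequence()
  u <- corrupt_probability_map(sq$truth, corruption_config())
  prior <- small_prior()
  params <- levelset_params()
  phi <- init_phi(list(shape = "circle", center = c(30, 30), radius = 12), u)
  for (i in 1:5) {
    frozen <- abs(phi) > params$eps
    phi_next <- evolve_step(phi, u, prior, params)
    expect_identical(phi_next[frozen], phi[frozen])
    phi <- phi_next
  }
})

test_that("with a flat prior the data force reduces to the probability-map difference", {
  set.seed(42)
  h <- 48; w <- 48
  uk <- matrix(runif(h * w), h, w)
  u <- probability_map(uk)
  prior <- uniform_prior(h, w)
  params <- levelset_params(lambda1 = 1e-12) # isolate the data force
  phi <- matrix(runif(h * w, -1, 1), h, w)
  stepped <- evolve_step(phi, u, prior, params)
  idx <- cbind(sample(h, 100, TRUE), sample(w, 100, TRUE))
  for (r in seq_len(100)) {
    i <- idx[r, 1]; j <- idx[r, 2]
    # brute-force recomputation of the update at this pixel
    expected <- params$tau * dirac_eps(phi[i, j], params$eps) *
      params$lambda2 * 0.5 * (uk[i, j] - (1 - uk[i, j]))
    expected <- min(max(expected, -params$eps / 5), params$eps / 5)
    expect_equal(stepped[i, j] - phi[i, j], expected, tolerance = 1e-9)
  }
})

test_that("phi initialization is a signed distance with the inside-positive convention", {
  phi <- init_phi(list(shape = "circle", center = c(40, 50), radius = 20), c(96, 96))
  expect_equal(phi[50, 40], 20, tolerance = 1e-12)
  on_circle <- abs(phi) < 0.5
  expect_gt(sum(on_circle), 0)
  m <- disk_mask(96, 96, 48, 48, 25)
  phi_m <- init_phi(list(shape = "from_mask", mask = m), c(96, 96))
  interior <- EBImage::erode(m$labels, EBImage::makeBrush(5, "disc")) == 1
  exterior <- EBImage::dilate(m$labels, EBImage::makeBrush(5, "disc")) == 0
  expect_true(all(phi_m[interior] > 0))
  expect_true(all(phi_m[exterior] < 0))
  # two disjoint seeds: both interiors positive
  two <- label_mask(pmin(disk_mask(96, 96, 25, 25, 10)$labels +
                           disk_mask(96, 96, 70, 70, 10)$labels, 1L))
  phi2 <- init_phi(list(shape = "from_mask", mask = two), c(96, 96))
  expect_gt(phi2[25, 25], 0)
  expect_gt(phi2[70, 70], 0)
  expect_lt(phi2[48, 48], 0)
  expect_error(init_phi(list(shape = "circle", center = c(5, 5), radius = 10),
                        c(96, 96)), "outside")
})

test_that("segmentation recovers the phantom kidney from a far-off initialization", {
  sq <- small_prior_cohort()[[1]] # prior built from the same phantom cohort
  u <- corrupt_probability_map(sq$truth, corruption_config())
  prior <- small_prior()
  res <- segment_ls(sq$frames[[3]], u, prior,
                    list(shape = "circle", center = c(110, 16), radius = 10))
  expect_true(res$converged)
  expect_gte(dice(res$mask, sq$truth), 0.99)
  expect_lte(hd95(res$mask, sq$truth), 2)
  # energy descends from start to finish
  dg <- res$diagnostics
  expect_lt(dg$E_total[nrow(dg)], dg$E_total[1])
})

test_that("false-positive blobs outside the prior support are removed", {
  sq <- small_test_cohort()[[2]]
  prior <- small_prior()
  cc <- corruption_config(n_fp_blobs = 3, fp_blob_radius = c(4, 7), seed = 17)
  u <- corrupt_probability_map(sq$truth, cc, avoid = prior_avoid_mask(prior))
  expect_equal(max(EBImage::bwlabel((u$p_kidney > 0.5) * 1L)), 4)
  res <- segment_ls(NULL, u, prior, list(shape = "circle", center = c(25, 25), radius = 10))
  expect_equal(max(EBImage::bwlabel(res$mask$labels)), 1)
  for (b in attr(u, "corruption_components")$fp_blobs) {
    expect_equal(sum(res$mask$labels & b$mask), 0)
  }
})

test_that("parameter validation rejects non-positive weights and steps", {
  expect_error(levelset_params(lambda1 = 0), "positive")
  expect_error(levelset_params(eps = -1), "positive")
  expect_error(levelset_params(tau = 0), "positive")
  expect_error(levelset_params(max_iters = 0), "max_iters")
})
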