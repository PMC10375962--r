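# Shared fixtures, built in code and cached for the duration of the test run.
# Module tests work on 96-128 px grids (kidney semi-axes scaled with the
# grid); the acceptance tests use the native 256 x 256 geometry.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default small phantom: 128 px grid, enhanced frame at t = 3
small_base_config <- function(noise_var = 0.01, seed = 1) {
  phantom_config(image_size = c(128, 128), n_frames = 4, semi_axes = c(32, 17),
                 t0 = 1, beta_t = 1.5, noise_var = noise_var, seed = seed)
}

# shape-only jitter for co-aligned cohorts, scaled to the 128 grid
small_aligned_variability <- function() {
  vb <- cohort_variability("aligned")
  vb$semi_axes <- 2
  vb
}

# pose + shape jitter scaled to the 128 grid
small_native_variability <- function() {
  vb <- cohort_variability("native")
  vb$center <- 3
  vb$semi_axes <- 2
  vb
}

small_sequence <- function(seed = 3, noise_var = 0) {
  make_dce_sequence(small_base_config(noise_var = noise_var, seed = seed))
}

# co-aligned 12-subject cohort and its prior on the 128 grid, shared across tests
small_prior_cohort <- function() {
  cached("small_prior_cohort", {
    make_cohort(12, small_base_config(noise_var = 0),
                small_aligned_variability(), seed = 11)
  })
}

small_prior <- function() {
  cached("small_prior", {
    build_prior_from_cohort(small_prior_cohort(), beta = 1, register = FALSE)
  })
}

small_test_cohort <- function() {
  cached("small_test_cohort", {
    make_cohort(6, small_base_config(noise_var = 0.01),
                small_aligned_variability(), seed = 201)
  })
}

# region FP blobs must avoid so they stay outside the prior support
prior_avoid_mask <- function(prior) {
  label_mask((EBImage::dilate(1L * (prior$counts > 0),
                              EBImage::makeBrush(7, "disc")) == 1) * 1L)
}

# ---- native-scale (256 x 256) study fixtures for the acceptance suite ------

acc_base_config <- function(noise_var = 0.01, seed = 1) {
  phantom_config(n_frames = 4, t0 = 1, beta_t = 1.5, noise_var = noise_var,
                 seed = seed)
}

acc_prior <- function() {
  cached("acc_prior", {
    cohort <- make_cohort(30, acc_base_config(noise_var = 0),
                          cohort_variability("aligned"), seed = 11)
    build_prior_from_cohort(cohort, beta = 1, register = FALSE)
  })
}

acc_test_cohort <- function() {
  cached("acc_test_cohort", {
    make_cohort(20, acc_base_config(), cohort_variability("aligned"), seed = 99)
  })
}

acc_far_init <- function() list(shape = "circle", center = c(40, 40), radius = 18)

acc_corruption <- function(seed) {
  corruption_config(n_fp_blobs = 3, fp_blob_radius = c(6, 12), n_fn_holes = 2,
                    fn_hole_radius = c(4, 8), boundary_blur_sigma = 1.5,
                    seed = seed)
}

# the 20 corrupted-probability-map cases, segmented once and shared between
# the energy-descent and refinement checks
acc_corrupted_runs <- function() {
  cached("acc_corrupted_runs", {
    prior <- acc_prior()
    avoid <- prior_avoid_mask(prior)
    lapply(seq_along(acc_test_cohort()), function(i) {
      subj <- acc_test_cohort()[[i]]
      u <- corrupt_probability_map(subj$truth, acc_corruption(100 + i),
                                   avoid = avoid)
      res <- segment_ls(NULL, u, prior, acc_far_init())
      list(subject = subj, u = u, res = res,
           baseline = label_mask((u$p_kidney > 0.5) * 1L, u$spacing))
    })
  })
}

random_mask <- function(h = 32, w = 32, p = 0.3) {
  label_mask(matrix(stats::rbinom(h * w, 1, p), h, w))
}

disk_mask <- function(h, w, cx, cy, r, spacing = c(1, 1)) {
  g <- expand.grid(row = seq_len(h), col = seq_len(w))
  m <- matrix(((g$col - cx)^2 + (g$row - cy)^2 <= r^2) * 1L, h, w)
  label_mask(m, spacing)
}
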