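# Phase-1 providers of the kidney/background probability map U. The level-set
# phase depends only on the probability_map contract, so providers are
# interchangeable: a truth-derived oracle with controllable corruption, a
# two-class Gaussian intensity model, or the trainable convolutional network.

#' Provider configuration
#'
#' @param provider One of `"oracle_corrupted"`, `"intensity_bayes"`, `"cnn"`.
#' @param corruption A [corruption_config] (oracle provider).
#' @param class_params Optional list `(mu_k, mu_b, var_k, var_b)` for the
#'   intensity model; if `NULL` the parameters are fitted from the truth mask.
#' @param model A trained model artifact from [train_provider()] (cnn
#'   provider).
#' @return A list of class `provider_config`.
#' @export
provider_config <- function(provider = c("oracle_corrupted", "intensity_bayes", "cnn"),
                            corruption = corruption_config(),
                            class_params = NULL, model = NULL) {
  provider <- match.arg(provider)
  structure(list(provider = provider, corruption = corruption,
                 class_params = class_params, model = model),
            class = "provider_config")
}

# two-class Gaussian posterior with equal class priors
gaussian_posterior <- function(intensity, mu_k, mu_b, var_k, var_b) {
  if (var_k < 1e-12 || var_b < 1e-12) {
    stop("class variance below 1e-12; intensity model is degenerate", call. = FALSE)
  }
  lk <- stats::dnorm(intensity, mu_k, sqrt(var_k))
  lb <- stats::dnorm(intensity, mu_b, sqrt(var_b))
  lk / pmax(lk + lb, .Machine$double.xmin)
}

#' Produce a kidney probability map
#'
#' Dispatches to the configured provider. The oracle provider corrupts the
#' supplied truth mask; the intensity provider evaluates the posterior of a
#' two-class Gaussian model on min-max-normalized intensity with equal class
#' priors (fitting class means/variances from the truth regions when no
#' parameters are supplied, with a variance floor of 1e-6); the cnn provider
#' runs a trained network.
#'
#' @param image An [image_grid].
#' @param cfg A [provider_config].
#' @param truth Optional [label_mask]; required by the oracle provider and by
#'   the intensity provider in fitting mode.
#' @return A [probability_map] on the image grid.
#' @export
provide_probability_map <- function(image, cfg, truth = NULL) {
  stopifnot(inherits(image, "image_grid"), inherits(cfg, "provider_config"))
  switch(cfg$provider,
    oracle_corrupted = {
      if (is.null(truth)) stop("oracle provider requires the truth mask", call. = FALSE)
      corrupt_probability_map(truth, cfg$corruption)
    },
    intensity_bayes = {
      v <- normalize_intensity(image)$pixels
      cp <- cfg$class_params
      if (is.null(cp)) {
        if (is.null(truth)) {
          stop("intensity provider needs class_params or a truth mask to fit from",
               call. = FALSE)
        }
        kid <- truth$labels == 1L
        cp <- list(mu_k = mean(v[kid]), mu_b = mean(v[!kid]),
                   var_k = max(stats::var(v[kid]), 1e-6),
                   var_b = max(stats::var(v[!kid]), 1e-6))
      }
      probability_map(gaussian_posterior(v, cp$mu_k, cp$mu_b, cp$var_k, cp$var_b),
                      image$spacing)
    },
    cnn = {
      if (is.null(cfg$model)) stop("cnn provider requires a trained model", call. = FALSE)
      predict_provider(cfg$model, image)
    })
}

# exact rotations by multiples of 90 degrees (index permutations)
rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
rot180 <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]

# rotate about the image centre by `angle` radians (positive = counterclockwise
# in (x, y) = (col, row) coordinates)
rotation_about_center <- function(h, w, angle) {
  c0 <- c((w + 1) / 2, (h + 1) / 2)
  A <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  affine_transform(A, c0 - as.vector(A %*% c0))
}

shift_raster <- function(m, dx, dy, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h; ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Twelve-fold augmentation of an image/mask pair
#'
#' Produces exactly 12 variants per pair: 1 random integer translation, 5
#' rotations (-90, -45, +45, +90, 180 degrees), 2 flips (vertical,
#' horizontal), 3 Gaussian-noise variants (variances 0.01, 0.02, 0.05 on the
#' \[0, 1\]-normalized image), and 1 combined random translation + flip.
#' Geometric operations are applied identically to image and mask (mask by
#' nearest neighbour); noise touches the image only. Deterministic per seed.
#'
#' @param image An [image_grid].
#' @param mask The matching [label_mask].
#' @param seed Integer seed for the random translations and noise.
#' @param translation_frac Maximum random shift as a fraction of each image
#'   dimension (default 0.1).
#' @param noise_vars The three noise variances.
#' @return A named list of 12 `list(image =, mask =)` pairs.
#' @export
augment_pair <- function(image, mask, seed = 1L, translation_frac = 0.1,
                         noise_vars = c(0.01, 0.02, 0.05)) {
  stopifnot(inherits(image, "image_grid"), inherits(mask, "label_mask"))
  assert_same_geometry(raster_geometry(image), raster_geometry(mask))
  v <- normalize_intensity(image)$pixels
  m <- mask$labels
  h <- nrow(v); w <- ncol(v)
  sp <- image$spacing
  pair <- function(img_m, msk_m) {
    list(image = image_grid(img_m, sp), mask = label_mask(msk_m, sp))
  }
  rot_pair <- function(angle_deg) {
    a <- angle_deg * pi / 180
    if (angle_deg %% 90 == 0) {
      k <- (angle_deg / 90) %% 4
      im <- v; mm <- m
      for (i in seq_len(k %% 4)) { im <- rot90cw(im); mm <- rot90cw(mm) }
      if (!all(dim(im) == c(h, w))) { # non-square grids: fall back to resampling
        tf <- rotation_about_center(h, w, a)
        im <- warp_raster_matrix(v, tf, "bilinear")
        mm <- warp_raster_matrix(m, tf, "nearest", fill = 0L)
      }
      pair(im, mm)
    } else {
      tf <- rotation_about_center(h, w, a)
      pair(warp_raster_matrix(v, tf, "bilinear"),
           warp_raster_matrix(m, tf, "nearest", fill = 0L))
    }
  }
  shifts <- with_seed(seed, {
    list(t1 = round(stats::runif(2, -translation_frac, translation_frac) * c(w, h)),
         t2 = round(stats::runif(2, -translation_frac, translation_frac) * c(w, h)),
         flip2 = sample(c("v", "h"), 1))
  })
  noise <- with_seed(seed + 1L, {
    lapply(noise_vars, function(s2) matrix(stats::rnorm(h * w, 0, sqrt(s2)), h, w))
  })
  flip_v <- function(x) x[nrow(x):1, , drop = FALSE]
  flip_h <- function(x) x[, ncol(x):1, drop = FALSE]
  t2img <- shift_raster(v, shifts$t2[1], shifts$t2[2])
  t2msk <- shift_raster(m, shifts$t2[1], shifts$t2[2], fill = 0L)
  out <- list(
    translate   = pair(shift_raster(v, shifts$t1[1], shifts$t1[2]),
                       shift_raster(m, shifts$t1[1], shifts$t1[2], fill = 0L)),
    rot_m90     = rot_pair(-90),
    rot_m45     = rot_pair(-45),
    rot_p45     = rot_pair(45),
    rot_p90     = rot_pair(90),
    rot_180     = rot_pair(180),
    flip_v      = pair(flip_v(v), flip_v(m)),
    flip_h      = pair(flip_h(v), flip_h(m)),
    noise_0.01  = pair(v + noise[[1]], m),
    noise_0.02  = pair(v + noise[[2]], m),
    noise_0.05  = pair(v + noise[[3]], m),
    translate_flip = if (shifts$flip2 == "v") {
      pair(flip_v(t2img), flip_v(t2msk))
    } else {
      pair(flip_h(t2img), flip_h(t2msk))
    })
  out
}
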