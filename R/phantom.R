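# Synthetic DCE-MRI kidney phantom: a bean-shaped kidney whose mean intensity
# follows a gamma-variate first-pass enhancement curve over ~80 frames, two
# static non-kidney structures, and additive Gaussian noise on the normalized
# intensity scale. Stands in for clinical dynamic-contrast series.

#' Phantom configuration
#'
#' Defaults emulate a typical renal dynamic-contrast acquisition: 80 frames of
#' 256 x 256 pixels, a bean-shaped kidney, low-contrast pre-arrival frames and
#' strong enhancement around the gamma-variate peak.
#'
#' @param image_size `(rows, cols)`, default `c(256, 256)`.
#' @param n_frames Number of time points T, default 80.
#' @param center Kidney centre `(x, y)` = `(col, row)`; default is the image
#'   centre.
#' @param semi_axes `(a, b)` ellipse semi-axes in pixels (a = long axis).
#' @param orientation Rotation angle of the long axis, radians.
#' @param notch_depth Medial concavity depth as a fraction of `b`, in `[0, 1)`.
#' @param baseline Kidney pre-contrast intensity on the \[0, 1\] scale.
#' @param amplitude Peak enhancement added to the baseline.
#' @param alpha,beta_t Gamma-variate shape and rate; the enhancement peaks at
#'   `t0 + alpha / beta_t` frames.
#' @param t0 Contrast arrival frame (no enhancement for `t < t0`).
#' @param noise_var Variance of the additive zero-mean Gaussian noise applied
#'   to \[0, 1\]-normalized intensities (0.01 / 0.02 / 0.05 are the canonical
#'   levels).
#' @param spacing Physical pixel size `(row_mm, col_mm)`.
#' @param seed Integer RNG seed; every phantom operation is deterministic in
#'   its configuration and seed.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(256, 256), n_frames = 80,
                           center = NULL, semi_axes = c(60, 32),
                           orientation = pi / 6, notch_depth = 0.35,
                           baseline = 0.25, amplitude = 0.55,
                           alpha = 3, beta_t = 0.15, t0 = 6,
                           noise_var = 0.01, spacing = c(1, 1), seed = 1L) {
  cfg <- list(image_size = as.integer(image_size), n_frames = as.integer(n_frames),
              center = center, semi_axes = as.numeric(semi_axes),
              orientation = as.numeric(orientation), notch_depth = as.numeric(notch_depth),
              baseline = baseline, amplitude = amplitude,
              alpha = alpha, beta_t = beta_t, t0 = as.integer(t0),
              noise_var = noise_var, spacing = spacing, seed = as.integer(seed))
  if (is.null(cfg$center)) {
    cfg$center <- c(cfg$image_size[2] / 2, cfg$image_size[1] / 2)
  }
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (any(cfg$image_size < 8)) stop("image_size must be at least 8 x 8", call. = FALSE)
  if (cfg$n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  a <- cfg$semi_axes[1]; b <- cfg$semi_axes[2]
  if (a < 4 || b < 4) stop("semi-axes must be >= 4 pixels", call. = FALSE)
  if (cfg$notch_depth < 0 || cfg$notch_depth >= 1) {
    stop("notch_depth must lie in [0, 1)", call. = FALSE)
  }
  # the rotated ellipse must fit with a 2-pixel margin
  r <- max(a, b)
  cx <- cfg$center[1]; cy <- cfg$center[2]
  if (cx - r < 2 || cy - r < 2 ||
      cx + r > cfg$image_size[2] - 2 || cy + r > cfg$image_size[1] - 2) {
    stop("kidney geometry exceeds the image bounds (2-pixel margin required)",
         call. = FALSE)
  }
  if (cfg$t0 < 1) stop("t0 must be >= 1", call. = FALSE)
  if (cfg$alpha <= 0 || cfg$beta_t <= 0) stop("alpha and beta_t must be positive", call. = FALSE)
  if (cfg$noise_var < 0) stop("noise_var must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Probability-map corruption configuration
#'
#' Emulates the characteristic failure modes of a segmentation CNN:
#' false-positive blobs in the background, false-negative holes inside the
#' kidney, boundary blur and pixel-level label noise.
#'
#' @param n_fp_blobs Number of false-positive disks planted in the background.
#' @param fp_blob_radius Length-2 range (pixels) for blob radii.
#' @param n_fn_holes Number of false-negative disks planted inside the kidney.
#' @param fn_hole_radius Length-2 range (pixels) for hole radii.
#' @param fp_prob Probability value planted in FP blobs (default 0.9 — a
#'   confident but not saturated false detection).
#' @param fn_prob Probability value planted in FN holes (default 0.1).
#' @param boundary_blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @param label_noise_level Amplitude of additive uniform noise, in `[0, 0.5)`.
#' @param seed Integer RNG seed.
#' @return A validated list of class `corruption_config`.
#' @export
corruption_config <- function(n_fp_blobs = 0, fp_blob_radius = c(4, 8),
                              n_fn_holes = 0, fn_hole_radius = c(3, 6),
                              fp_prob = 0.9, fn_prob = 0.1,
                              boundary_blur_sigma = 0, label_noise_level = 0,
                              seed = 1L) {
  cfg <- list(n_fp_blobs = as.integer(n_fp_blobs),
              fp_blob_radius = as.numeric(fp_blob_radius),
              n_fn_holes = as.integer(n_fn_holes),
              fn_hole_radius = as.numeric(fn_hole_radius),
              fp_prob = fp_prob, fn_prob = fn_prob,
              boundary_blur_sigma = boundary_blur_sigma,
              label_noise_level = label_noise_level, seed = as.integer(seed))
  if (cfg$n_fp_blobs < 0 || cfg$n_fn_holes < 0) stop("counts must be >= 0", call. = FALSE)
  if (any(cfg$fp_blob_radius < 0) || any(cfg$fn_hole_radius < 0)) {
    stop("radii must be >= 0", call. = FALSE)
  }
  if (cfg$boundary_blur_sigma < 0) stop("boundary_blur_sigma must be >= 0", call. = FALSE)
  if (cfg$label_noise_level < 0 || cfg$label_noise_level >= 0.5) {
    stop("label_noise_level must lie in [0, 0.5)", call. = FALSE)
  }
  structure(cfg, class = "corruption_config")
}

# pixel-centre coordinate grids: X = col index, Y = row index
coord_grids <- function(h, w) {
  list(X = matrix(rep(seq_len(w), each = h), h, w),
       Y = matrix(rep(seq_len(h), times = w), h, w))
}

# rasterize a rotated ellipse with an optional medial notch (bean shape)
bean_indicator <- function(h, w, center, semi_axes, orientation, notch_depth) {
  g <- coord_grids(h, w)
  a <- semi_axes[1]; b <- semi_axes[2]
  dx <- g$X - center[1]; dy <- g$Y - center[2]
  co <- cos(orientation); si <- sin(orientation)
  u <- dx * co + dy * si     # along the long axis
  v <- -dx * si + dy * co    # along the short axis
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (notch_depth > 0) {
    # subtract a disk centred on one long side; cut depth 1.2*b*notch_depth
    # stays well below 2b, keeping the region 4-connected and removing far
    # less than half the area
    rn <- 1.2 * b * notch_depth
    notch <- (u^2 + (v + b)^2) <= rn^2
    inside <- inside & !notch
  }
  inside * 1L
}

#' Generate the phantom kidney shape
#'
#' A single 4-connected bean-shaped region: a rotated ellipse with a medial
#' concave notch whose depth is controlled by `notch_depth` (0 gives the plain
#' ellipse).
#'
#' @param cfg A [phantom_config].
#' @return A [label_mask].
#' @export
make_kidney_shape <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  m <- bean_indicator(h, w, cfg$center, cfg$semi_axes, cfg$orientation, cfg$notch_depth)
  label_mask(m, cfg$spacing)
}

# normalized gamma-variate enhancement curve: 0 before t0, peak 1 at t0 + alpha/beta
gamma_variate <- function(t, t0, alpha, beta_t) {
  s <- pmax(t - t0, 0) * beta_t / alpha
  ifelse(t <= t0, 0, (s^alpha) * exp(alpha * (1 - s)))
}

# static background structures anchored to the kidney geometry: the whole
# scene (body outline plus two organ-like structures) shares the kidney's
# position and orientation, the way a subject's anatomy moves as one under
# patient positioning — this is what makes scene-level affine registration
# meaningful on phantoms
phantom_background <- function(h, w, center, semi_axes, orientation = 0) {
  g <- coord_grids(h, w)
  bg <- matrix(0.10, h, w)
  co <- cos(orientation); si <- sin(orientation)
  place <- function(off) center + c(off[1] * co - off[2] * si,
                                    off[1] * si + off[2] * co)
  s <- min(h, w)
  body_c <- place(c(0.04 * s, 0.03 * s))
  body <- ((g$X - body_c[1])^2 + (g$Y - body_c[2])^2) <= (0.46 * s)^2
  bg[body] <- 0.15
  # organ 1: large ellipse beside the kidney (liver-like)
  o1c <- place(c(0.24 * s, 0.12 * s))
  o1 <- bean_indicator(h, w, pmin(pmax(o1c, 0.12 * s), c(w, h) - 0.12 * s),
                       c(0.17 * s, 0.09 * s), orientation - 0.4, 0)
  bg[o1 == 1] <- 0.40
  # organ 2: compact disk below the kidney (spine-like)
  o2c <- place(c(-0.05 * s, 0.30 * s))
  o2 <- ((g$X - o2c[1])^2 + (g$Y - o2c[2])^2) <= (0.05 * s)^2
  bg[o2] <- 0.55
  bg
}

#' Generate a dynamic contrast-enhanced phantom sequence
#'
#' Frames share one geometry; the kidney's mean intensity follows
#' `baseline + amplitude * g(t)` where `g` is a gamma-variate curve that is 0
#' before the arrival frame `t0` and peaks (value 1) at `t0 + alpha/beta_t`.
#' Background structures are static, so the pre-arrival frames have a strictly
#' lower kidney/background contrast-to-noise ratio than the peak frame.
#' Zero-mean Gaussian noise of variance `noise_var` is added on the \[0, 1\]
#' intensity scale (values are left unclipped so the configured variance is
#' exact).
#'
#' @param cfg A [phantom_config].
#' @return A [dce_sequence] with the ground-truth kidney mask attached.
#' @export
make_dce_sequence <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  truth <- make_kidney_shape(cfg)
  bg <- phantom_background(h, w, cfg$center, cfg$semi_axes, cfg$orientation)
  kid <- truth$labels == 1L
  tt <- seq_len(cfg$n_frames)
  enh <- gamma_variate(tt, cfg$t0, cfg$alpha, cfg$beta_t)
  frames <- with_seed(cfg$seed, {
    lapply(tt, function(t) {
      px <- bg
      px[kid] <- cfg$baseline + cfg$amplitude * enh[t]
      if (cfg$noise_var > 0) {
        px <- px + matrix(stats::rnorm(h * w, 0, sqrt(cfg$noise_var)), h, w)
      }
      image_grid(px, cfg$spacing)
    })
  })
  dce_sequence(frames, truth, subject_id = sprintf("phantom_seed%d", cfg$seed))
}

# rejection-sample n disjoint disk centres in `allowed` (logical matrix), with
# radii drawn from `radius_range`; disks must not touch each other
sample_disjoint_disks <- function(allowed, n, radius_range, max_tries = 5000) {
  h <- nrow(allowed); w <- ncol(allowed)
  g <- coord_grids(h, w)
  ok_idx <- which(allowed)
  if (!length(ok_idx) && n > 0) stop("no room to place disks", call. = FALSE)
  disks <- list()
  tries <- 0
  while (length(disks) < n && tries < max_tries) {
    tries <- tries + 1
    r <- stats::runif(1, radius_range[1], radius_range[2])
    i <- sample(ok_idx, 1)
    cy <- (i - 1) %% h + 1
    cx <- (i - 1) %/% h + 1
    if (cx - r < 1 || cy - r < 1 || cx + r > w || cy + r > h) next
    d2 <- (g$X - cx)^2 + (g$Y - cy)^2
    if (any(d2 <= (r + 1)^2 & !allowed)) next
    clash <- FALSE
    for (d in disks) {
      if (sqrt((d$cx - cx)^2 + (d$cy - cy)^2) <= d$r + r + 2) { clash <- TRUE; break }
    }
    if (clash) next
    disks[[length(disks) + 1]] <- list(cx = cx, cy = cy, r = r, mask = d2 <= r^2)
  }
  if (length(disks) < n) stop("could not place the requested number of disks", call. = FALSE)
  disks
}

#' Corrupt a truth mask into a CNN-like probability map
#'
#' Starts from `U_K = truth`, plants `n_fp_blobs` high-probability disks in the
#' background (rejection-sampled to be disjoint from the kidney dilated by 3
#' pixels, from each other, and from any additional `avoid` region) and
#' `n_fn_holes` low-probability disks fully inside the kidney, adds uniform
#' label noise, blurs, and clips to \[0, 1\]. With an all-zero corruption
#' configuration the output equals the truth exactly.
#'
#' @param truth A [label_mask].
#' @param ccfg A [corruption_config].
#' @param avoid Optional [label_mask]: additional region FP blobs must not
#'   touch (e.g. the support of a shape prior).
#' @return A [probability_map]; the planted blob/hole geometry is attached as
#'   attribute `"corruption_components"` (list of disk descriptors).
#' @export
corrupt_probability_map <- function(truth, ccfg, avoid = NULL) {
  stopifnot(inherits(truth, "label_mask"), inherits(ccfg, "corruption_config"))
  u <- truth$labels + 0.0
  h <- nrow(u); w <- ncol(u)
  kid_dil <- EBImage::dilate(truth$labels, EBImage::makeBrush(7, "disc"))
  forbidden <- kid_dil == 1
  if (!is.null(avoid)) {
    assert_same_geometry(raster_geometry(truth), raster_geometry(avoid))
    forbidden <- forbidden | avoid$labels == 1
  }
  fp <- list()
  if (ccfg$n_fp_blobs > 0) {
    fp <- with_seed(ccfg$seed, {
      sample_disjoint_disks(!forbidden, ccfg$n_fp_blobs, ccfg$fp_blob_radius)
    })
    for (d in fp) u[d$mask] <- ccfg$fp_prob
  }
  fn <- list()
  if (ccfg$n_fn_holes > 0) {
    # holes must lie fully inside the kidney: erode by the max hole radius
    rmax <- ceiling(ccfg$fn_hole_radius[2])
    core <- EBImage::erode(truth$labels, EBImage::makeBrush(2 * rmax + 3, "disc")) == 1
    fn <- with_seed(ccfg$seed + 1L, {
      sample_disjoint_disks(core, ccfg$n_fn_holes, ccfg$fn_hole_radius)
    })
    for (d in fn) u[d$mask] <- ccfg$fn_prob
  }
  if (ccfg$label_noise_level > 0) {
    u <- u + with_seed(ccfg$seed + 2L, {
      matrix(stats::runif(h * w, -ccfg$label_noise_level, ccfg$label_noise_level), h, w)
    })
  }
  if (ccfg$boundary_blur_sigma > 0) {
    u <- EBImage::gblur(u, sigma = ccfg$boundary_blur_sigma)
  }
  u <- pmin(pmax(u, 0), 1)
  out <- probability_map(u, truth$spacing)
  attr(out, "corruption_components") <- list(fp_blobs = fp, fn_holes = fn)
  out
}

#' Cohort variability profiles
#'
#' Jitter half-ranges for [make_cohort()]. The `"native"` profile includes
#' pose variation (translation, orientation) on top of anatomical shape
#' variation, emulating subjects scanned in their own frames — use it when
#' the pipeline performs affine registration. The `"aligned"` profile keeps
#' only the anatomical variation that affine registration cannot remove
#' (semi-axes, notch depth, enhancement), with a 1-pixel residual pose
#' jitter, emulating an already co-registered cohort. The geometric
#' half-ranges are expressed for the default 256 x 256 geometry; scale them
#' with the kidney when using smaller grids.
#'
#' @param profile `"native"` or `"aligned"`.
#' @return A named list of jitter half-ranges for [make_cohort()].
#' @export
cohort_variability <- function(profile = c("native", "aligned")) {
  profile <- match.arg(profile)
  if (profile == "native") {
    list(center = 6, semi_axes = 4, orientation = 0.1, notch_depth = 0.05,
         baseline = 0.03, amplitude = 0.08, t0 = 2)
  } else {
    list(center = 1, semi_axes = 4, orientation = 0.02, notch_depth = 0.05,
         baseline = 0.03, amplitude = 0.08, t0 = 2)
  }
}

#' Generate a cohort of phantom subjects
#'
#' Subjects share the base configuration but jitter their kidney geometry and
#' enhancement parameters, emulating anatomical variation across patients. The
#' cohort is the training material for the probabilistic shape prior.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param base_cfg A [phantom_config] providing the central parameter values.
#' @param variability Named list of half-ranges for uniform jitter; recognized
#'   names: `center` (pixels), `semi_axes` (pixels), `orientation` (radians),
#'   `notch_depth`, `baseline`, `amplitude`, `t0` (frames). Defaults give a
#'   moderately varied cohort.
#' @param seed Master seed; each subject receives a derived sub-seed.
#' @return A list of [dce_sequence] objects.
#' @export
make_cohort <- function(n_subjects, base_cfg,
                        variability = cohort_variability("native"),
                        seed = 1L) {
  stopifnot(inherits(base_cfg, "phantom_config"))
  if (n_subjects < 2) stop("a cohort needs at least 2 subjects", call. = FALSE)
  vb <- function(name, default = 0) {
    if (!is.null(variability[[name]])) variability[[name]] else default
  }
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 10L, n_subjects))
  cohort <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    jit <- with_seed(sub_seeds[i], {
      list(center = stats::runif(2, -vb("center"), vb("center")),
           semi_axes = stats::runif(2, -vb("semi_axes"), vb("semi_axes")),
           orientation = stats::runif(1, -vb("orientation"), vb("orientation")),
           notch_depth = stats::runif(1, -vb("notch_depth"), vb("notch_depth")),
           baseline = stats::runif(1, -vb("baseline"), vb("baseline")),
           amplitude = stats::runif(1, -vb("amplitude"), vb("amplitude")),
           t0 = round(stats::runif(1, -vb("t0"), vb("t0"))))
    })
    cfg_i <- phantom_config(
      image_size = base_cfg$image_size, n_frames = base_cfg$n_frames,
      center = base_cfg$center + jit$center,
      semi_axes = pmax(base_cfg$semi_axes + jit$semi_axes, 4),
      orientation = base_cfg$orientation + jit$orientation,
      notch_depth = min(max(base_cfg$notch_depth + jit$notch_depth, 0), 0.95),
      baseline = base_cfg$baseline + jit$baseline,
      amplitude = base_cfg$amplitude + jit$amplitude,
      alpha = base_cfg$alpha, beta_t = base_cfg$beta_t,
      t0 = max(1L, base_cfg$t0 + jit$t0),
      noise_var = base_cfg$noise_var, spacing = base_cfg$spacing,
      seed = sub_seeds[i])
    seq_i <- make_dce_sequence(cfg_i)
    seq_i$subject_id <- sprintf("subject_%02d", i)
    if (max(EBImage::bwlabel(seq_i$truth$labels)) != 1) {
      stop("cohort truth mask is not a single connected component", call. = FALSE)
    }
    cohort[[i]] <- seq_i
  }
  cohort
}
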