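# End-to-end orchestration: cohort -> shape prior -> probability map ->
# (optional) alignment to prior space -> level-set segmentation -> inverse
# mapping -> evaluation. The paired threshold baseline evaluates the raw
# probability map at 0.5 with the same cases and seeds, so the refinement
# gained by the level-set phase can be read off directly.

#' Pipeline run configuration
#'
#' @param cohort List of [dce_sequence] test subjects (phantoms or loaded
#'   data).
#' @param prior A `shape_prior`; if `NULL`, one is built from `prior_cohort`.
#' @param prior_cohort Cohort used to build the prior when `prior` is `NULL`.
#' @param provider A [provider_config].
#' @param params A [levelset_params].
#' @param init Init spec for [init_phi()].
#' @param frame Frame selector per subject: `"peak"` or an index.
#' @param register If `TRUE`, each test image is affinely aligned to the
#'   prior's reference frame (the probability map is warped with the same
#'   transform, bilinear, re-clipped to \[0, 1\]) and the segmentation is
#'   mapped back to native space with the inverse transform. Use `FALSE` for
#'   cohorts generated on the prior's grid.
#' @param beta Pseudo-count when building the prior internally.
#' @param spacing Physical pixel size for metrics; defaults to each truth's.
#' @param out_dir Optional directory for masks, diagnostics and the results
#'   CSV.
#' @param seed Master seed recorded in the manifest.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(cohort, prior = NULL, prior_cohort = NULL,
                       provider = provider_config(), params = levelset_params(),
                       init = list(shape = "circle", center = c(32, 32), radius = 15),
                       frame = "peak", register = FALSE, beta = 1,
                       spacing = NULL, out_dir = NULL, seed = 1L) {
  if (!length(cohort)) stop("run_config: empty test cohort", call. = FALSE)
  if (is.null(prior) && is.null(prior_cohort)) {
    stop("run_config: supply a prior or a prior_cohort to build one from", call. = FALSE)
  }
  if (!is.null(out_dir) && !dir.exists(dirname(out_dir))) {
    stop("run_config: parent of out_dir does not exist", call. = FALSE)
  }
  structure(list(cohort = cohort, prior = prior, prior_cohort = prior_cohort,
                 provider = provider, params = params, init = init,
                 frame = frame, register = isTRUE(register), beta = beta,
                 spacing = spacing, out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

pick_frame <- function(subj, frame) {
  if (identical(frame, "peak")) {
    means <- vapply(subj$frames, function(f) mean(f$pixels), numeric(1))
    subj$frames[[which.max(means)]]
  } else subj$frames[[frame]]
}

resolve_prior <- function(cfg) {
  if (!is.null(cfg$prior)) cfg$prior
  else build_prior_from_cohort(cfg$prior_cohort, beta = cfg$beta,
                               register = cfg$register)
}

# run one case through provider (+ alignment) + level set; returns native-space
# mask plus per-case bookkeeping
run_case <- function(subj, prior, cfg) {
  img <- pick_frame(subj, cfg$frame)
  u <- provide_probability_map(img, cfg$provider, truth = subj$truth)
  tf <- affine_transform()
  if (cfg$register) {
    reg <- align_to_prior(img, prior)
    tf <- reg$transform
    img <- reg$warped
    u_w <- warp_raster_matrix(u$p_kidney, tf, "bilinear", fill = 0)
    u <- probability_map(pmin(pmax(u_w, 0), 1), u$spacing)
  }
  res <- segment_ls(img, u, prior, cfg$init, cfg$params)
  mask_native <- if (cfg$register) warp_mask(res$mask, invert_affine(tf)) else res$mask
  list(mask = mask_native, u = u, transform = tf, ls = res)
}

#' Run the full two-phase segmentation pipeline
#'
#' For each test subject: obtain the probability map from the configured
#' provider, optionally align to the prior's reference space, evolve the
#' level-set contour, map the mask back to native space, and evaluate against
#' truth. Per-case failures are recorded and the run continues; a run with
#' zero successful cases is an error.
#'
#' @param cfg A [run_config].
#' @return A list of class `pipeline_result`: `evaluation` ([evaluate_cohort]
#'   tibble), `cases` (per-case list with masks and diagnostics), `prior`,
#'   `failures` (named list of error messages), and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  prior <- resolve_prior(cfg)
  cases <- list(); failures <- list()
  for (subj in cfg$cohort) {
    out <- tryCatch(run_case(subj, prior, cfg), error = function(e) e)
    if (inherits(out, "error")) {
      failures[[subj$subject_id]] <- conditionMessage(out)
      next
    }
    cases[[subj$subject_id]] <- c(out, list(truth = subj$truth))
  }
  if (!length(cases)) {
    stop("pipeline: no case completed successfully; first error: ",
         failures[[1]], call. = FALSE)
  }
  ev <- evaluate_cohort(lapply(names(cases), function(id) {
    list(case_id = id, result = cases[[id]]$mask, truth = cases[[id]]$truth)
  }), spacing = cfg$spacing)
  ev$converged <- vapply(cases, function(cs) cs$ls$converged, logical(1))
  ev$iterations <- vapply(cases, function(cs) cs$ls$iterations, integer(1))
  manifest <- list(seed = cfg$seed, provider = cfg$provider$provider,
                   params = unclass(cfg$params), init = cfg$init,
                   register = cfg$register, beta = prior$beta,
                   n_prior_images = prior$n_images,
                   subjects = names(cases), timestamp = NULL)
  res <- structure(list(evaluation = ev, cases = cases, prior = prior,
                        failures = failures, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_result(res, cfg$out_dir)
  res
}

#' Evaluate the threshold-0.5 baseline of the provider
#'
#' Thresholds the provider's probability map at 0.5 for the identical cases
#' and seeds, giving the paired phase-1-only comparison for the level-set
#' refinement.
#'
#' @param cfg A [run_config].
#' @return A list of class `pipeline_result` (no level-set diagnostics).
#' @export
run_baseline_threshold <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  cases <- list(); failures <- list()
  for (subj in cfg$cohort) {
    out <- tryCatch({
      img <- pick_frame(subj, cfg$frame)
      u <- provide_probability_map(img, cfg$provider, truth = subj$truth)
      list(mask = label_mask((u$p_kidney > 0.5) * 1L, u$spacing), u = u)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      failures[[subj$subject_id]] <- conditionMessage(out)
      next
    }
    cases[[subj$subject_id]] <- c(out, list(truth = subj$truth))
  }
  if (!length(cases)) stop("baseline: no case completed successfully", call. = FALSE)
  ev <- evaluate_cohort(lapply(names(cases), function(id) {
    list(case_id = id, result = cases[[id]]$mask, truth = cases[[id]]$truth)
  }), spacing = cfg$spacing)
  structure(list(evaluation = ev, cases = cases, prior = NULL,
                 failures = failures,
                 manifest = list(seed = cfg$seed, provider = cfg$provider$provider,
                                 baseline = "threshold_0.5")),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result: %d cases, %d failures>\n",
              nrow(x$evaluation), length(x$failures)))
  print(x$evaluation)
  invisible(x)
}

write_pipeline_result <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(as.data.frame(res$evaluation),
                   file.path(out_dir, "results.csv"), row.names = FALSE)
  yaml::write_yaml(res$manifest, file.path(out_dir, "manifest.yaml"))
  for (id in names(res$cases)) {
    cs <- res$cases[[id]]
    write_image(cs$mask, file.path(out_dir, sprintf("%s_mask.png", id)))
    if (!is.null(cs$ls)) {
      utils::write.csv(as.data.frame(cs$ls$diagnostics),
                       file.path(out_dir, sprintf("%s_diagnostics.csv", id)),
                       row.names = FALSE)
    }
  }
  invisible(out_dir)
}

#' Write a phantom cohort to disk in the subject-directory convention
#'
#' Each subject gets a directory with `frame_<t>.tif` (zero-padded, float
#' TIFF of the \[0, 1\]-scale intensities, clipped) and `truth.png`.
#'
#' @param cohort List of [dce_sequence] objects.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (subj in cohort) {
    sd <- file.path(dir, subj$subject_id)
    dir.create(sd, showWarnings = FALSE)
    wd <- max(2, nchar(as.character(length(subj$frames))))
    for (t in seq_along(subj$frames)) {
      f <- subj$frames[[t]]
      px <- pmin(pmax(f$pixels, 0), 1)
      write_image(image_grid(px, f$spacing),
                  file.path(sd, sprintf(paste0("frame_%0", wd, "d.tif"), t)))
    }
    write_image(subj$truth, file.path(sd, "truth.png"))
  }
  invisible(dir)
}

#' Read a subject directory written by [write_cohort()]
#' @param dir Path to one subject directory.
#' @param spacing Physical pixel size.
#' @return A [dce_sequence].
#' @export
read_subject <- function(dir, spacing = c(1, 1)) {
  frame_files <- sort(list.files(dir, pattern = "^frame_\\d+\\.", full.names = TRUE))
  if (!length(frame_files)) stop("no frame_<t> files in ", dir, call. = FALSE)
  truth_file <- list.files(dir, pattern = "^truth\\.", full.names = TRUE)[1]
  if (is.na(truth_file)) stop("no truth mask in ", dir, call. = FALSE)
  frames <- lapply(frame_files, read_image, kind = "intensity", spacing = spacing)
  truth <- read_image(truth_file, kind = "mask", spacing = spacing)
  dce_sequence(frames, truth, subject_id = basename(dir))
}
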