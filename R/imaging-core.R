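# Coordinate convention used throughout the package: rasters are R matrices
# indexed [row, col], 0-based pixel centres are not used -- indices are 1-based;
# a point (x, y) is (col, row). Physical spacing is (row_mm, col_mm).

#' Create an image grid
#'
#' A 2-D scalar raster holding a grayscale image \eqn{I(x, y)} on the image
#' domain, with physical pixel spacing in millimetres.
#'
#' @param pixels Numeric matrix of pixel intensities (arbitrary units).
#' @param spacing Numeric length-2 vector `(row_mm, col_mm)`, both positive.
#' @return An object of class `image_grid` with fields `pixels` and `spacing`.
#' @examples
#' img <- image_grid(matrix(runif(64), 8, 8))
#' dim(img$pixels)
#' @export
image_grid <- function(pixels, spacing = c(1, 1)) {
  pixels <- as_raster_matrix(pixels, "pixels")
  check_geometry(nrow(pixels), ncol(pixels), spacing)
  if (!all(is.finite(pixels))) stop("image pixels must all be finite", call. = FALSE)
  structure(list(pixels = pixels, spacing = as.numeric(spacing)),
            class = "image_grid")
}

#' Create a binary label mask
#'
#' Per-pixel kidney/background labelling: 1 = kidney, 0 = background.
#'
#' @param labels Matrix with values exactly in \{0, 1\} (logical accepted).
#' @param spacing Physical pixel size `(row_mm, col_mm)`.
#' @return An object of class `label_mask` with fields `labels` and `spacing`.
#' @export
label_mask <- function(labels, spacing = c(1, 1)) {
  labels <- as_raster_matrix(labels, "labels")
  check_geometry(nrow(labels), ncol(labels), spacing)
  if (!all(labels %in% c(0, 1))) {
    stop("mask values must be exactly 0 or 1", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing)),
            class = "label_mask")
}

#' Create a probability map
#'
#' Per-pixel kidney probability \eqn{U_K(x, y) \in [0, 1]}; the background
#' probability is implied as \eqn{U_B = 1 - U_K}, so the two always sum to one.
#'
#' @param p_kidney Numeric matrix with values in \[0, 1\].
#' @param spacing Physical pixel size `(row_mm, col_mm)`.
#' @return An object of class `probability_map` with field `p_kidney`.
#' @export
probability_map <- function(p_kidney, spacing = c(1, 1)) {
  p_kidney <- as_raster_matrix(p_kidney, "p_kidney")
  check_geometry(nrow(p_kidney), ncol(p_kidney), spacing)
  if (!all(is.finite(p_kidney))) stop("probabilities must be finite", call. = FALSE)
  if (min(p_kidney) < 0 || max(p_kidney) > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(p_kidney = p_kidney, spacing = as.numeric(spacing)),
            class = "probability_map")
}

#' Create a dynamic contrast-enhanced sequence
#'
#' An ordered series of frames acquired over time on one geometry, together
#' with the subject's ground-truth kidney mask.
#'
#' @param frames List of [image_grid] objects sharing one geometry.
#' @param truth A [label_mask] on the same geometry.
#' @param subject_id Character identifier.
#' @return An object of class `dce_sequence`.
#' @export
dce_sequence <- function(frames, truth, subject_id = "subject") {
  if (!length(frames)) stop("a sequence needs at least one frame", call. = FALSE)
  lapply(frames, function(f) {
    if (!inherits(f, "image_grid")) stop("frames must be image_grid objects", call. = FALSE)
  })
  if (!inherits(truth, "label_mask")) stop("truth must be a label_mask", call. = FALSE)
  g0 <- raster_geometry(frames[[1]])
  for (f in frames) assert_same_geometry(g0, raster_geometry(f))
  assert_same_geometry(g0, raster_geometry(truth))
  structure(list(frames = frames, truth = truth,
                 subject_id = as.character(subject_id)),
            class = "dce_sequence")
}

as_raster_matrix <- function(m, what) {
  if (is.logical(m)) m <- m * 1L
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] != 1L) stop("multi-channel rasters are not supported", call. = FALSE)
    m <- m[, , 1L]
  }
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("%s must be a 2-D numeric matrix", what), call. = FALSE)
  }
  m
}

check_geometry <- function(h, w, spacing) {
  if (h < 8 || w < 8) stop("raster must be at least 8 x 8", call. = FALSE)
  if (length(spacing) != 2 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be two strictly positive numbers", call. = FALSE)
  }
  invisible(TRUE)
}

raster_values <- function(obj) {
  if (inherits(obj, "image_grid")) obj$pixels
  else if (inherits(obj, "label_mask")) obj$labels
  else if (inherits(obj, "probability_map")) obj$p_kidney
  else stop("unsupported raster object", call. = FALSE)
}

raster_geometry <- function(obj) {
  v <- raster_values(obj)
  list(h = nrow(v), w = ncol(v), spacing = obj$spacing)
}

assert_same_geometry <- function(a, b) {
  if (a$h != b$h || a$w != b$w) {
    stop("raster geometries do not match", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %d x %d, spacing %.3g x %.3g mm, range [%.4g, %.4g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask %d x %d, %d kidney pixels>\n",
              nrow(x$labels), ncol(x$labels), sum(x$labels)))
  invisible(x)
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map %d x %d, mean p_kidney %.3f>\n",
              nrow(x$p_kidney), ncol(x$p_kidney), mean(x$p_kidney)))
  invisible(x)
}

#' @export
print.dce_sequence <- function(x, ...) {
  g <- raster_geometry(x$truth)
  cat(sprintf("<dce_sequence '%s': %d frames of %d x %d>\n",
              x$subject_id, length(x$frames), g$h, g$w))
  invisible(x)
}

supported_ext <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) "png"
  else if (grepl("\\.tiff?$", lower)) "tiff"
  else if (grepl("\\.nii(\\.gz)?$", lower)) "nifti"
  else stop(sprintf("unsupported image format: '%s'", basename(path)), call. = FALSE)
}

read_raw_raster <- function(path) {
  fmt <- supported_ext(path)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  a <- switch(fmt,
    png   = png::readPNG(path),
    tiff  = tiff::readTIFF(path),
    nifti = {
      v <- RNifti::readNifti(path)
      v <- drop(as.array(v))
      v
    })
  if (length(dim(a)) == 3L && fmt != "nifti") {
    # grayscale stored with an alpha or duplicated channels is still rejected:
    # this artifact is strictly single-channel
    stop("multi-channel images are not supported", call. = FALSE)
  }
  if (length(dim(a)) > 2L) stop("3-D volumes are not supported; supply single slices", call. = FALSE)
  if (!is.matrix(a)) stop("file did not decode to a 2-D raster", call. = FALSE)
  matrix(as.numeric(a), nrow(a), ncol(a)) # strip decoder attributes
}

#' Read an image, mask or probability raster
#'
#' Supported formats: PNG and TIFF (8/16-bit grayscale, float TIFF), and
#' single-slice NIfTI (`.nii` / `.nii.gz`). PNG/TIFF integer data are returned
#' on the decoder's \[0, 1\] scale; NIfTI values are returned as stored. Masks
#' must contain exactly two distinct values and are binarized by equality to
#' the larger one. Probability rasters must lie in \[0, 1\] after the
#' integer-format rescaling.
#'
#' @param path Path to the file.
#' @param kind One of `"intensity"`, `"mask"`, `"probability"`.
#' @param spacing Physical pixel size; for NIfTI, defaults to the stored
#'   `pixdim` when present.
#' @return An [image_grid], [label_mask] or [probability_map].
#' @export
read_image <- function(path, kind = c("intensity", "mask", "probability"),
                       spacing = NULL) {
  kind <- match.arg(kind)
  a <- read_raw_raster(path)
  if (is.null(spacing)) {
    spacing <- c(1, 1)
    if (supported_ext(path) == "nifti") {
      pd <- tryCatch(RNifti::pixdim(RNifti::readNifti(path)), error = function(e) NULL)
      if (!is.null(pd) && length(pd) >= 2 && all(pd[1:2] > 0)) spacing <- pd[1:2]
    }
  }
  switch(kind,
    intensity = image_grid(a, spacing),
    mask = {
      vals <- sort(unique(as.vector(a)))
      if (length(vals) != 2) {
        stop(sprintf("mask not binary: file contains %d distinct values", length(vals)),
             call. = FALSE)
      }
      label_mask((a == vals[2]) * 1L, spacing)
    },
    probability = {
      if (min(a) < 0 || max(a) > 1) {
        stop("probability values outside [0, 1] after rescaling", call. = FALSE)
      }
      probability_map(a, spacing)
    })
}

#' Write an image, mask or probability raster
#'
#' Masks round-trip bit-exactly through every supported format. Probability
#' maps written to float TIFF or NIfTI round-trip to float precision; written
#' to 8/16-bit PNG they are quantized (documented bound: 1/(2^bits - 1)).
#'
#' @param obj An [image_grid], [label_mask] or [probability_map].
#' @param path Destination path; format chosen from the extension.
#' @return Invisibly, `path`.
#' @export
write_image <- function(obj, path) {
  fmt <- supported_ext(path)
  if (!dir.exists(dirname(path))) stop("parent directory does not exist", call. = FALSE)
  v <- raster_values(obj)
  storage.mode(v) <- "double"
  if (fmt %in% c("png", "tiff") && (min(v) < 0 || max(v) > 1)) {
    stop("PNG/TIFF output requires values in [0, 1]; use NIfTI for raw intensities",
         call. = FALSE)
  }
  switch(fmt,
    png   = png::writePNG(v, path),
    tiff  = {
      if (inherits(obj, "label_mask")) tiff::writeTIFF(v, path)
      else tiff::writeTIFF(v, path, bits.per.sample = 32L)
    },
    nifti = {
      img <- RNifti::asNifti(v, reference = NULL)
      RNifti::pixdim(img) <- obj$spacing
      RNifti::writeNifti(img, path)
    })
  invisible(path)
}

#' Min-max intensity normalization
#'
#' Rescales an image linearly so its values span \[0, 1\]. Idempotent on
#' already-normalized input; a constant image has no meaningful rescaling and
#' raises an error.
#'
#' @param img An [image_grid].
#' @return An [image_grid] with values spanning \[0, 1\].
#' @export
normalize_intensity <- function(img) {
  stopifnot(inherits(img, "image_grid"))
  rng <- range(img$pixels)
  if (diff(rng) == 0) stop("cannot normalize a constant image", call. = FALSE)
  image_grid((img$pixels - rng[1]) / diff(rng), img$spacing)
}

#' Display a raster with base graphics
#'
#' @param x A raster object ([image_grid], [label_mask] or [probability_map]).
#' @param mask Optional [label_mask] whose boundary is overdrawn.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot_raster <- function(x, mask = NULL, main = NULL, ...) {
  v <- raster_values(x)
  # orient so that row 1 is at the top, matching matrix printing
  graphics::image(t(v)[, nrow(v):1, drop = FALSE], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(v) / ncol(v), main = main, ...)
  if (!is.null(mask)) {
    b <- boundary_pixels(mask$labels)
    if (nrow(b)) {
      graphics::points((b[, 2] - 1) / (ncol(v) - 1),
                       1 - (b[, 1] - 1) / (nrow(v) - 1),
                       pch = ".", col = "yellow", cex = 2)
    }
  }
  invisible(x)
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}
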