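# Segmentation evaluation: Dice, intersection-over-union, and the 95th
# percentile Hausdorff distance between mask boundaries (spacing-weighted, so
# values are in mm when spacing is physical).

#' Dice similarity coefficient
#'
#' `2|A ∩ B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [label_mask] objects on one geometry.
#' @return A number in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "label_mask"), inherits(b, "label_mask"))
  assert_same_geometry(raster_geometry(a), raster_geometry(b))
  sa <- sum(a$labels); sb <- sum(b$labels)
  if (sa + sb == 0) return(1)
  2 * sum(a$labels & b$labels) / (sa + sb)
}

#' Intersection over union (Jaccard index)
#'
#' `|A ∩ B| / |A ∪ B|`; defined as 1 when both masks are empty. Satisfies the
#' identity `DS = 2 IU / (1 + IU)`.
#'
#' @inheritParams dice
#' @return A number in \[0, 1\].
#' @export
iou <- function(a, b) {
  stopifnot(inherits(a, "label_mask"), inherits(b, "label_mask"))
  assert_same_geometry(raster_geometry(a), raster_geometry(b))
  un <- sum(a$labels | b$labels)
  if (un == 0) return(1)
  sum(a$labels & b$labels) / un
}

# boundary pixels: foreground with at least one 4-neighbour background pixel
# (the image border counts as background); returns (row, col) matrix
boundary_pixels <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  core <- pad[2:(h + 1), 2:(w + 1)]
  nb <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  which(core == 1L & !nb, arr.ind = TRUE)
}

#' 95th percentile Hausdorff distance
#'
#' Boundary pixels are extracted as foreground pixels with a background
#' 4-neighbour. Directed distances from each boundary pixel of one mask to the
#' nearest boundary pixel of the other are weighted by the physical spacing;
#' the reported value is the maximum of the two directed 95th percentiles
#' (linear-interpolation percentiles).
#'
#' @inheritParams dice
#' @param spacing Physical pixel size `(row_mm, col_mm)`; defaults to the
#'   masks' stored spacing.
#' @param percentile Percentile in (0, 100\]; 100 gives the full Hausdorff
#'   distance.
#' @return Distance in physical units (>= 0).
#' @export
hd95 <- function(a, b, spacing = NULL, percentile = 95) {
  stopifnot(inherits(a, "label_mask"), inherits(b, "label_mask"))
  assert_same_geometry(raster_geometry(a), raster_geometry(b))
  if (sum(a$labels) == 0 || sum(b$labels) == 0) {
    stop("hd95 is undefined for an empty mask", call. = FALSE)
  }
  if (is.null(spacing)) spacing <- a$spacing
  pa <- boundary_pixels(a$labels); pb <- boundary_pixels(b$labels)
  pa <- sweep(pa, 2, spacing, "*"); pb <- sweep(pb, 2, spacing, "*")
  directed <- function(p, q) {
    # chunk the pairwise distance matrix to bound memory
    step <- max(1, floor(4e6 / nrow(q)))
    mins <- numeric(nrow(p))
    for (i0 in seq(1, nrow(p), by = step)) {
      idx <- i0:min(i0 + step - 1, nrow(p))
      d2 <- outer(p[idx, 1], q[, 1], "-")^2 + outer(p[idx, 2], q[, 2], "-")^2
      mins[idx] <- sqrt(apply(d2, 1, min))
    }
    mins
  }
  q <- percentile / 100
  max(stats::quantile(directed(pa, pb), q, type = 7, names = FALSE),
      stats::quantile(directed(pb, pa), q, type = 7, names = FALSE))
}

#' Evaluate a cohort of segmentations
#'
#' Per-case Dice, IoU and HD95 plus cohort mean and sample standard deviation
#' (n - 1 denominator) of each metric.
#'
#' @param cases List of `list(result = <label_mask>, truth = <label_mask>)`
#'   pairs (optionally with a `case_id`).
#' @param spacing Physical pixel size used for HD95; defaults to each truth
#'   mask's spacing.
#' @return An object of class `eval_result`: a tibble with columns `case_id`,
#'   `dice`, `iou`, `hd95` and attribute `summary` (tibble of mean/sd per
#'   metric; sd is 0 with a flag when there is a single case).
#' @export
evaluate_cohort <- function(cases, spacing = NULL) {
  if (!length(cases)) stop("no cases to evaluate", call. = FALSE)
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    tibble::tibble(
      case_id = cs$case_id %||% sprintf("case_%02d", i),
      dice = dice(cs$result, cs$truth),
      iou = iou(cs$result, cs$truth),
      hd95 = hd95(cs$result, cs$truth, spacing = spacing))
  })
  tab <- do.call(rbind, rows)
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  summ <- tibble::tibble(
    metric = c("dice", "iou", "hd95"),
    mean = c(mean(tab$dice), mean(tab$iou), mean(tab$hd95)),
    sd = c(sd0(tab$dice), sd0(tab$iou), sd0(tab$hd95)))
  structure(tab, summary = summ, single_case = length(cases) == 1,
            class = c("eval_result", class(tab)))
}

#' @export
print.eval_result <- function(x, ...) {
  NextMethod()
  s <- attr(x, "summary")
  cat("\nCohort summary (mean +/- sd):\n")
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  if (isTRUE(attr(x, "single_case"))) {
    cat("  (single case: sd reported as 0 by convention)\n")
  }
  invisible(x)
}

#' Cohort summary of an evaluation
#' @param x An `eval_result`.
#' @return Tibble with per-metric mean and sd.
#' @export
eval_summary <- function(x) attr(x, "summary")

#' Plot per-case evaluation metrics
#' @param object An `eval_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_result <- function(object, ...) {
  long <- rbind(
    data.frame(case_id = object$case_id, value = object$dice, metric = "dice"),
    data.frame(case_id = object$case_id, value = object$iou, metric = "iou"),
    data.frame(case_id = object$case_id, value = object$hd95, metric = "hd95"))
  ggplot2::ggplot(long, ggplot2::aes(x = metric, y = value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-case segmentation metrics") +
    ggplot2::theme_minimal()
}
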