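#' Count fluorescent beads by marker-based watershed segmentation
#'
#' Re-implements the bead-binding quantification pipeline: the image is
#' thresholded to binary, the distance transform of the mask is Gaussian
#' smoothed, regional maxima (at least `min_distance` apart) are taken as
#' markers, and a marker-based watershed restricted to the binary mask
#' assigns every foreground pixel to one bead. Objects smaller than
#' `min_area` pixels are discarded. Smoothing the distance transform rather
#' than the raw image keeps the maxima stable while preserving the
#' binary-then-smooth order of operations.
#'
#' @param image 2-D numeric matrix (grayscale).
#' @param sigma Gaussian smoothing sd for the distance transform (pixels).
#' @param threshold `"otsu"` or a fixed numeric threshold on the raw
#'   intensities.
#' @param min_distance minimum separation between bead markers (pixels);
#'   default 5 (the expected bead radius).
#' @param min_area minimum object area in pixels (default
#'   `0.25 * pi * min_distance^2`).
#' @return an object of class `bead_count`: `count`, `label_map` (integer
#'   matrix), `centers` (tibble of marker positions), `parameters_used`.
#' @examples
#' im <- synth_bead_image(5, image_size = 96, rng_seed = 1)
#' count_beads(im$image)$count
#' @export
count_beads <- function(image, sigma = 2, threshold = "otsu",
                        min_distance = 5, min_area = NULL) {
  if (length(dim(image)) != 2) abort("Input must be a single-channel 2-D image.")
  image <- as.matrix(image)
  min_area <- min_area %||% (0.25 * pi * min_distance^2)
  # threshold to binary
  if (identical(threshold, "otsu")) {
    rng <- range(image)
    norm <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > thr
    thr_used <- thr * diff(rng) + rng[1]
    # Otsu always splits the histogram, even for pure background; require
    # the foreground to stand clear of the background noise floor
    if (any(mask) && any(!mask)) {
      contrast <- mean(image[mask]) - mean(image[!mask])
      if (contrast < 3 * sd(image[!mask])) mask[] <- FALSE
    }
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    mask <- image > threshold
    thr_used <- threshold
  }
  params <- list(threshold = thr_used, threshold_method =
                   if (identical(threshold, "otsu")) "otsu" else "fixed",
                 sigma = sigma, min_distance = min_distance,
                 min_area = min_area)
  empty <- function() {
    structure(list(count = 0L,
                   label_map = matrix(0L, nrow(image), ncol(image)),
                   centers = tibble(x = numeric(0), y = numeric(0)),
                   parameters_used = params),
              class = "bead_count")
  }
  if (!any(mask)) return(empty())
  storage.mode(mask) <- "integer"
  dist <- EBImage::distmap(EBImage::Image(mask))
  smooth <- if (sigma > 0) EBImage::gblur(dist, sigma = sigma) else dist
  sm <- EBImage::imageData(smooth)
  # regional maxima: pixels equal to the local max within min_distance
  brush_size <- 2L * max(1L, round(min_distance)) + 1L
  localmax <- EBImage::imageData(
    EBImage::dilate(smooth, EBImage::makeBrush(brush_size, shape = "disc")))
  cand <- which(sm >= localmax - 1e-12 & mask == 1L & sm > 0, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty())
  # greedy pruning: strongest maxima first, deterministic tie-break
  vals <- sm[cand]
  ord <- order(-vals, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  keep_x <- numeric(0); keep_y <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    px <- cand[i, 1]; py <- cand[i, 2]
    if (length(keep_x) == 0 ||
        all((keep_x - px)^2 + (keep_y - py)^2 >= min_distance^2)) {
      keep_x <- c(keep_x, px); keep_y <- c(keep_y, py)
    }
  }
  markers <- matrix(0L, nrow(image), ncol(image))
  markers[cbind(keep_x, keep_y)] <- seq_along(keep_x)
  # marker-based watershed: region growing on the smoothed distance
  # transform, restricted to the binary mask
  labels <- EBImage::imageData(
    EBImage::propagate(smooth, seeds = EBImage::Image(markers),
                       mask = EBImage::Image(mask)))
  storage.mode(labels) <- "integer"
  # drop small objects and relabel contiguously
  sizes <- tabulate(labels[labels > 0L])
  small <- which(sizes < min_area)
  if (length(small)) labels[labels %in% small] <- 0L
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids)) {
    relab <- integer(max(ids))
    relab[ids] <- seq_along(ids)
    pos <- labels > 0L
    labels[pos] <- relab[labels[pos]]
  }
  structure(list(
    count = length(ids),
    label_map = labels,
    centers = tibble(x = keep_x[ids], y = keep_y[ids]),
    parameters_used = params), class = "bead_count")
}

#' @export
print.bead_count <- function(x, ...) {
  cat(sprintf("<bead_count> %d beads (threshold %.3g, sigma %.1f, min distance %.1f px)\n",
              x$count, x$parameters_used$threshold, x$parameters_used$sigma,
              x$parameters_used$min_distance))
  invisible(x)
}

#' @method glance bead_count
#' @export
glance.bead_count <- function(x, ...) {
  tibble(count = x$count,
         threshold = x$parameters_used$threshold,
         sigma = x$parameters_used$sigma,
         min_distance = x$parameters_used$min_distance)
}

#' Summarise bead counts per condition
#'
#' Aggregates per-field bead counts into per-condition mean, sd and n, with
#' fold change relative to a named reference condition.
#'
#' @param counts data frame with columns `condition` and `count` (one row
#'   per imaged field).
#' @param reference reference condition for the fold change (default: the
#'   first condition in the table).
#' @return tibble with `condition`, `mean`, `sd`, `n`, `fold_change`.
#' @examples
#' summarize_fields(data.frame(condition = rep(c("DMSO", "CytoD"), each = 3),
#'                             count = c(10, 11, 9, 30, 29, 31)),
#'                  reference = "DMSO")
#' @export
summarize_fields <- function(counts, reference = NULL) {
  stopifnot(all(c("condition", "count") %in% names(counts)))
  if (nrow(counts) == 0) abort("No counts supplied.")
  conds <- unique(counts$condition)
  reference <- reference %||% conds[1]
  if (!reference %in% conds) {
    abort(sprintf("Unknown reference condition '%s'.", reference))
  }
  out <- counts |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean = mean(.data$count), sd = sd(.data$count),
                     n = dplyr::n(), .groups = "drop")
  ref_mean <- out$mean[out$condition == reference]
  if (ref_mean == 0) abort("Reference condition has zero mean count.")
  dplyr::mutate(out, fold_change = .data$mean / ref_mean)
}

#' Read / write grayscale bead images as TIFF
#'
#' Thin wrappers around the `tiff` package for the bead-counting pipeline:
#' images are carried in R as plain numeric matrices.
#'
#' @param path TIFF file path.
#' @param image numeric matrix with values in [0, 1] (clipped on write).
#' @return `read_image_tiff()` returns a numeric matrix (the first channel
#'   of multi-channel files).
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Package 'tiff' is required to read TIFF images.")
  }
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  as.matrix(img)
}

#' @rdname read_image_tiff
#' @export
write_image_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Package 'tiff' is required to write TIFF images.")
  }
  img <- pmin(pmax(as.matrix(image), 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = 16L)
  invisible(path)
}
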