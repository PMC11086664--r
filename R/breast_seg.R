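#' Convert a probability map to a both-breasts binary mask
#'
#' Thresholds the probability map (default 0.25), keeps the largest
#' 8-connected object as the region containing both breasts, and fills holes.
#'
#' @param prob a `probability_map` (see [predict_probability()]) or a numeric
#'   matrix with values in \[0, 1\].
#' @param threshold probability threshold in (0, 1); default 0.25.
#' @return Logical matrix, a single connected component.
#' @export
postprocess_mask <- function(prob, threshold = 0.25) {
  p <- if (inherits(prob, "probability_map")) prob$data else prob
  stopifnot(is.matrix(p), threshold > 0, threshold < 1)
  bin <- p > threshold
  if (!any(bin)) {
    stop("postprocess_mask: no pixel above threshold ", threshold,
         "; exam is unsegmentable")
  }
  mask <- largest_component(bin)
  fill_holes_2d(mask)
}

#' Split a both-breasts mask into affected and unaffected breast masks
#'
#' The mask is vertically split at the horizontal center of its bounding box
#' (`split_mode = "bbox"`) or at its centroid column (`"centroid"`). Columns
#' strictly left of the split column form the left side. Sides are labeled
#' affected/unaffected according to `affected_side`; with
#' `affected_side = "unknown"` only left/right labels are returned.
#'
#' @param both_mask logical matrix, single non-empty component.
#' @param affected_side `"left"`, `"right"`, or `"unknown"`.
#' @param split_mode `"bbox"` (default) or `"centroid"`.
#' @return An object of class `breast_masks`: `both`, `left`, `right`,
#'   `affected`, `unaffected` (the latter two NULL when side is unknown),
#'   `split_column`, `affected_side`.
#' @export
split_breasts <- function(both_mask, affected_side = "unknown",
                          split_mode = c("bbox", "centroid")) {
  split_mode <- match.arg(split_mode)
  affected_side <- match.arg(affected_side, c("left", "right", "unknown"))
  stopifnot(is.matrix(both_mask), any(both_mask))
  cols <- which(colSums(both_mask) > 0)
  split_column <- if (split_mode == "bbox") {
    min(cols) + (max(cols) - min(cols) + 1L) %/% 2L
  } else {
    w <- which(both_mask, arr.ind = TRUE)
    as.integer(round(mean(w[, 2])))
  }
  left <- both_mask; left[, split_column:ncol(both_mask)] <- FALSE
  right <- both_mask & !left
  res <- list(both = both_mask, left = left, right = right,
              affected = NULL, unaffected = NULL,
              split_column = split_column, affected_side = affected_side)
  if (affected_side != "unknown") {
    res$affected <- if (affected_side == "left") left else right
    res$unaffected <- if (affected_side == "left") right else left
  }
  structure(res, class = "breast_masks")
}

#' Non-learned fallback breast segmenter
#'
#' Provided so the pipeline can run without a training step; this is not the
#' U-Net pathway. The projection is blurred, log-compressed, and clustered
#' into three intensity classes (k-means on the 1D intensities with
#' quantile-initialized centers, so the result is deterministic); the two
#' brightest classes are kept as breast candidates before the usual
#' largest-component and hole-filling post-processing.
#'
#' @param mip a `projection_image` or numeric matrix.
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @return A `probability_map` with a crisp 0/1 foreground map, suitable for
#'   [postprocess_mask()].
#' @export
fallback_segmenter <- function(mip, blur_sigma = 3) {
  img <- if (inherits(mip, "projection_image")) mip$data else mip
  sm <- EBImage::gblur(EBImage::Image(img), sigma = blur_sigma)
  v <- log1p(as.numeric(sm))
  centers <- unique(quantile(v, c(0.2, 0.6, 0.95)))
  if (length(centers) < 3L) {
    # degenerate (near-constant) image: everything is foreground
    return(structure(list(data = matrix(1, nrow(img), ncol(img))),
                     class = "probability_map"))
  }
  km <- kmeans(v, centers = matrix(centers, ncol = 1))
  bright <- order(km$centers)[2:3]
  fg <- matrix(as.numeric(km$cluster %in% bright), nrow(img), ncol(img))
  structure(list(data = fg), class = "probability_map")
}

#' Derive breast masks from a projection image
#'
#' Convenience wrapper running the chosen segmenter, the probability
#' threshold, largest-object selection, hole filling, and the vertical split.
#'
#' @param mip a `projection_image` (second post-contrast subtraction MIP in
#'   the standard pipeline).
#' @param model a trained `unet_model`, or NULL to use the fallback segmenter.
#' @param affected_side,threshold,split_mode see [split_breasts()] and
#'   [postprocess_mask()].
#' @return A `breast_masks` object.
#' @export
segment_breasts <- function(mip, model = NULL, affected_side = "unknown",
                            threshold = 0.25, split_mode = "bbox") {
  prob <- if (is.null(model)) fallback_segmenter(mip) else predict_probability(model, mip)
  both <- postprocess_mask(prob, threshold)
  split_breasts(both, affected_side, split_mode)
}
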