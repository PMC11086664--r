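#' Quantize a projection image to 8-bit display intensities
#'
#' Projection images are kept at floating-point precision through the
#' pipeline; scoring operates on 8-bit display-style images with "pixel
#' values ranging from 0 to 255". By default a fixed window \[0, 255\] is
#' used — subtraction intensities are treated as display-scale units and
#' values above the window clip, so one intensity unit means the same thing
#' in every exam (a per-image percentile window would normalize away the
#' between-exam amplitude differences the score relies on). Set
#' `window_max = NULL` to window at the `window_percentile` quantile of the
#' in-mask intensities instead. To keep before- and after-removal scores on
#' one intensity scale, compute the window from the pre-removal projection
#' and pass it on via `window_max`.
#'
#' @param proj a `projection_image` or numeric matrix.
#' @param mask logical matrix defining the in-mask intensity distribution
#'   (used only for percentile windowing); NULL uses the whole image.
#' @param window_max upper window intensity (default 255); NULL to use the
#'   percentile window.
#' @param window_percentile upper window percentile used when
#'   `window_max = NULL`.
#' @return list with `image` (integer matrix 0..255) and `window_max`.
#' @export
quantize_projection <- function(proj, mask = NULL, window_max = 255,
                                window_percentile = 99.9) {
  img <- if (inherits(proj, "projection_image")) proj$data else proj
  vals <- if (is.null(mask)) img else img[mask]
  if (is.null(window_max)) {
    window_max <- as.numeric(quantile(vals, window_percentile / 100))
  }
  if (window_max <= 0) {
    warning("quantize_projection: degenerate window (all-zero image)")
    return(list(image = matrix(0L, nrow(img), ncol(img)), window_max = 0))
  }
  q <- round(pmin(pmax(img / window_max, 0), 1) * 255)
  list(image = matrix(as.integer(q), nrow(img), ncol(img)), window_max = window_max)
}

#' Rescale a quantized image for scoring
#'
#' `mode = "original"` uses the 0..255 intensities as-is. `mode = "rescaled"`
#' (the default scoring variant) maps the 8-bit range 0..255 linearly to
#' 0..1, i.e. divides by 255. `mode = "minmax"` instead maps the image so
#' its own minimum becomes 0 and its maximum 1 (min-max over `mask`, or an
#' explicit `range`); min-max normalization cancels the between-exam
#' enhancement-amplitude differences the BPE score relies on, so it is
#' offered as an alternative reading, not the default. A constant image maps
#' to all zeros with a warning under `"minmax"`.
#'
#' @param image numeric/integer matrix (typically a quantized projection).
#' @param mode `"rescaled"`, `"original"`, or `"minmax"`.
#' @param mask optional logical matrix over which min/max are taken
#'   (`"minmax"` only).
#' @param range optional explicit `c(lo, hi)` mapping range for `"minmax"`,
#'   e.g. the range of the pre-removal image so that before/after
#'   lesion-removal scores share one intensity scale.
#' @return Numeric matrix.
#' @export
rescale_image <- function(image, mode = c("rescaled", "original", "minmax"),
                          mask = NULL, range = NULL) {
  mode <- match.arg(mode)
  if (mode == "original") return(image + 0)
  if (mode == "rescaled") return(image / 255)
  if (is.null(range)) {
    vals <- if (is.null(mask)) image else image[mask]
    range <- c(min(vals), max(vals))
  }
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) {
    warning("rescale_image: degenerate (constant) image; returning zeros")
    return(image * 0)
  }
  (image - lo) / (hi - lo)
}

#' Computer BPE score: mean masked pixel intensity
#'
#' @param image numeric matrix.
#' @param mask logical matrix of the same shape; must be non-empty.
#' @return The arithmetic mean of `image` over `mask`.
#' @export
compute_score <- function(image, mask) {
  stopifnot(identical(dim(image), dim(mask)))
  if (!any(mask)) stop("compute_score: empty mask")
  mean(image[mask])
}

#' Score an exam over the full image-variant grid
#'
#' Emits one record per combination of region (both / affected / unaffected),
#' projection type (MIP / AIP), post-contrast time point (first / second),
#' rescale mode (original / rescaled) and lesion-removal state. The
#' quantization window of each (time point, projection type) cell is computed
#' from the pre-removal projection and shared with the removed variant so the
#' two are on one intensity scale; consequently the unaffected breast's score
#' is identical before and after removal.
#'
#' @param study a [dce_study()].
#' @param masks a `breast_masks` object with affected/unaffected sides set
#'   (else only the `both` region is scored).
#' @param lesion a `lesion_mask` or NULL for no removal (removed-variant
#'   scores then equal the non-removed ones).
#' @param time_points integer vector of post-contrast time points.
#' @param ring_width border ring width for lesion removal.
#' @param window_max,window_percentile see [quantize_projection()].
#' @param clip_negative see [subtract()].
#' @return data.frame of score records: exam_id, region, projection_type,
#'   time_point, rescale_mode, lesion_removed, score, rating.
#' @export
score_grid <- function(study, masks, lesion = NULL, time_points = c(1L, 2L),
                       ring_width = 1L, window_max = 255,
                       window_percentile = 99.9, clip_negative = TRUE) {
  stopifnot(inherits(study, "dce_study"), inherits(masks, "breast_masks"))
  regions <- list(both = masks$both)
  if (!is.null(masks$affected)) {
    regions$affected <- masks$affected
    regions$unaffected <- masks$unaffected
  }
  has_lesion <- !is.null(lesion) && any(if (inherits(lesion, "lesion_mask")) lesion$mask_3d else lesion)
  rows <- list()
  for (tp in time_points) {
    sv <- subtract(study, tp, clip_negative = clip_negative)
    sv_rm <- if (has_lesion) remove_lesion(sv, lesion, ring_width)$volume else sv
    for (ptype in c("MIP", "AIP")) {
      proj <- project(sv, ptype)
      proj_rm <- if (has_lesion) project(sv_rm, ptype) else proj
      qz <- quantize_projection(proj, masks$both, window_max, window_percentile)
      qz_rm <- quantize_projection(proj_rm, masks$both, window_max = qz$window_max)
      for (rn in names(regions)) {
        rmask <- regions[[rn]]
        for (mode in c("original", "rescaled")) {
          for (removed in c(FALSE, TRUE)) {
            qi <- if (removed) qz_rm$image else qz$image
            img <- rescale_image(qi, mode, mask = rmask)
            rows[[length(rows) + 1L]] <- data.frame(
              exam_id = study$exam_id, region = rn, projection_type = ptype,
              time_point = tp, rescale_mode = mode, lesion_removed = removed,
              score = compute_score(img, rmask), rating = study$rating,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}
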