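#' Pipeline configuration
#'
#' Collects every stage parameter with the defaults used throughout:
#' FCM with c = 3 clusters (background / enhancing parenchyma / lesion), fuzziness m = 2, tolerance 1e-5, at most 300
#' iterations and membership threshold 0.5; a 1-pixel border ring for lesion
#' removal; U-Net probability threshold 0.25 with a bounding-box-center
#' vertical split; a fixed 8-bit quantization window of \[0, 255\] display
#' units (set `window_max = NULL` for percentile windowing); empirical ROC
#' analysis.
#'
#' @param ... overrides for any default listed above.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fcm_c = 3L, fcm_m = 2, fcm_tol = 1e-5, fcm_max_iter = 300L,
    membership_threshold = 0.5, fcm_init = "range",
    ring_width = 1L,
    unet_threshold = 0.25, split_mode = "bbox",
    window_max = 255, window_percentile = 99.9, clip_negative = TRUE,
    time_points = c(1L, 2L),
    roc_method = "empirical", n_comparisons = 1L,
    roi_pad = 8L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown pipeline_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Build a lesion ROI box from a bounding box with padding
#'
#' @param bbox 2 x 3 matrix (rows lo/hi; columns slice/row/col), e.g. the
#'   `lesion_bbox` of a phantom truth.
#' @param grid_shape grid dimensions to clamp against.
#' @param pad padding in voxels on each side (in-plane; half in slices).
#' @return ROI list (`slice`, `row`, `col`) for [segment_lesion()].
#' @export
lesion_roi <- function(bbox, grid_shape, pad = 8L) {
  pads <- c(max(1L, pad %/% 2L), pad, pad)
  lo <- pmax(1L, bbox["lo", ] - pads)
  hi <- pmin(grid_shape, bbox["hi", ] + pads)
  list(slice = c(lo[1], hi[1]), row = c(lo[2], hi[2]), col = c(lo[3], hi[3]))
}

#' Run the full pipeline on one exam
#'
#' Stages: subtraction, FCM lesion segmentation (when an ROI is supplied),
#' electronic lesion removal, projection, breast-mask derivation from the
#' pre-removal second post-contrast subtraction MIP, and scoring over the
#' full image-variant grid. When the exam's affected side is unknown and a
#' lesion was segmented, the side containing the lesion centroid is used.
#'
#' @param study a [dce_study()].
#' @param config a [pipeline_config()].
#' @param model a trained `unet_model`, or NULL for the fallback segmenter.
#' @param roi lesion ROI (see [segment_lesion()]) or NULL to skip removal.
#' @return list: `records` (score data.frame), `lesion` (`lesion_mask` or
#'   NULL), `masks` (`breast_masks`).
#' @export
run_exam <- function(study, config = pipeline_config(), model = NULL, roi = NULL) {
  stopifnot(inherits(study, "dce_study"), inherits(config, "pipeline_config"))
  sv2 <- subtract(study, 2L, clip_negative = config$clip_negative)
  lesion <- NULL
  if (!is.null(roi)) {
    lesion <- segment_lesion(sv2, roi, c = config$fcm_c, m = config$fcm_m,
                             tol = config$fcm_tol, max_iter = config$fcm_max_iter,
                             membership_threshold = config$membership_threshold,
                             init = config$fcm_init, seed = config$seed)
  }
  mip2 <- project(sv2, "MIP")
  side <- study$affected_side
  masks <- segment_breasts(mip2, model, affected_side = "unknown",
                           threshold = config$unet_threshold,
                           split_mode = config$split_mode)
  if (side == "unknown" && !is.null(lesion) && any(lesion$mask_3d)) {
    w <- which(lesion$mask_3d, arr.ind = TRUE)
    side <- if (mean(w[, 3]) < masks$split_column) "left" else "right"
  }
  if (side != "unknown") {
    masks <- split_breasts(masks$both, side, config$split_mode)
  }
  records <- score_grid(study, masks, lesion, time_points = config$time_points,
                        ring_width = config$ring_width,
                        window_max = config$window_max,
                        window_percentile = config$window_percentile,
                        clip_negative = config$clip_negative)
  list(records = records, lesion = lesion, masks = masks)
}

#' Run the pipeline over a phantom cohort and evaluate
#'
#' Each exam is processed in isolation (one failing exam is reported, not
#' fatal). Lesion ROIs are derived from the phantom truth bounding boxes,
#' standing in for the manifest-supplied boxes of a clinical run. When at
#' least two rating classes are present, cohort-level evaluation is run:
#' Kendall tau-b and ROC for both classification tasks across the affected
#' breast image-variant grid, plus the after/before removal-ratio summary.
#'
#' @param cohort output of [generate_cohort()].
#' @param config a [pipeline_config()].
#' @param model optional trained `unet_model`.
#' @return list: `records` (all score records), `lesion_sizes` (data.frame),
#'   `evaluation` (see [evaluate_cohort()]; NULL if skipped), `failures`
#'   (character vector of failed exam ids).
#' @export
run_cohort <- function(cohort, config = pipeline_config(), model = NULL) {
  recs <- list(); sizes <- list(); failures <- character(0)
  for (ex in cohort$exams) {
    res <- tryCatch({
      roi <- NULL
      if (!is.null(ex$truth$lesion_bbox)) {
        roi <- lesion_roi(ex$truth$lesion_bbox, dim(ex$study$pre), config$roi_pad)
      }
      run_exam(ex$study, config, model, roi)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message("run_cohort: exam ", ex$study$exam_id, " failed: ", conditionMessage(res))
      failures <- c(failures, ex$study$exam_id)
      next
    }
    recs[[length(recs) + 1L]] <- res$records
    sizes[[length(sizes) + 1L]] <- data.frame(
      exam_id = ex$study$exam_id,
      lesion_size_mm = if (is.null(res$lesion)) 0 else res$lesion$size_mm,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  lesion_sizes <- do.call(rbind, sizes)
  evaluation <- NULL
  n_classes <- length(unique(records$rating))
  if (n_classes >= 2L) {
    evaluation <- evaluate_cohort(records, lesion_sizes,
                                  n_comparisons = config$n_comparisons,
                                  roc_method = config$roc_method)
  } else {
    message("run_cohort: fewer than 2 rating classes present; evaluation skipped")
  }
  list(records = records, lesion_sizes = lesion_sizes,
       evaluation = evaluation, failures = failures)
}

#' Cohort-level statistical evaluation of computer BPE scores
#'
#' For the affected breast after lesion removal, every image variant
#' (projection type x time point x rescale mode) is evaluated with Kendall
#' tau-b against the ordinal ratings and with ROC analysis for the
#' minimal-vs-marked and low-vs-high tasks. A region table (both / affected /
#' unaffected x removal state) is computed for the rescaled second
#' post-contrast MIP, and the after/before removal-ratio summary is attached.
#'
#' @param records score records (see [score_grid()]); `rating` must be set.
#' @param lesion_sizes data.frame with `exam_id`, `lesion_size_mm`.
#' @param n_comparisons Bonferroni family size applied to the ROC z-tests.
#' @param roc_method `"empirical"` or `"binormal"`.
#' @return list: `variant_table`, `region_table` (data.frames with tau and
#'   AUC columns), `ratio` (see [ratio_vs_size_table()]).
#' @export
evaluate_cohort <- function(records, lesion_sizes = NULL, n_comparisons = 1L,
                            roc_method = "empirical") {
  eval_one <- function(sub) {
    sub <- sub[order(sub$exam_id), ]
    tau <- tryCatch(kendall_tau_b(sub$rating, sub$score), error = function(e) NULL)
    aucs <- lapply(c("minimal_vs_marked", "low_vs_high"), function(task) {
      tryCatch({
        d <- dichotomize(sub$rating, task)
        roc_analysis(sub$score[d$keep], d$labels, method = roc_method,
                     n_comparisons = n_comparisons)
      }, error = function(e) NULL)
    })
    data.frame(
      n = nrow(sub),
      tau_b = if (is.null(tau)) NA_real_ else tau$tau_b,
      tau_p = if (is.null(tau)) NA_real_ else tau$p_value,
      auc_minimal_vs_marked = if (is.null(aucs[[1]])) NA_real_ else aucs[[1]]$auc,
      p_minimal_vs_marked = if (is.null(aucs[[1]])) NA_real_ else aucs[[1]]$p_corrected,
      auc_low_vs_high = if (is.null(aucs[[2]])) NA_real_ else aucs[[2]]$auc,
      p_low_vs_high = if (is.null(aucs[[2]])) NA_real_ else aucs[[2]]$p_corrected)
  }
  variant <- list()
  for (ptype in c("MIP", "AIP")) for (tp in unique(records$time_point)) {
    for (mode in c("original", "rescaled")) {
      sub <- records[records$region == "affected" & records$lesion_removed &
                       records$projection_type == ptype &
                       records$time_point == tp & records$rescale_mode == mode, ]
      if (nrow(sub) == 0) next
      variant[[length(variant) + 1L]] <- cbind(
        data.frame(projection_type = ptype, time_point = tp, rescale_mode = mode),
        eval_one(sub))
    }
  }
  region <- list()
  for (rn in unique(records$region)) for (removed in c(FALSE, TRUE)) {
    sub <- records[records$region == rn & records$lesion_removed == removed &
                     records$projection_type == "MIP" & records$time_point == 2L &
                     records$rescale_mode == "rescaled", ]
    if (nrow(sub) == 0) next
    region[[length(region) + 1L]] <- cbind(
      data.frame(region = rn, lesion_removed = removed), eval_one(sub))
  }
  ratio <- NULL
  if (!is.null(lesion_sizes) && any(lesion_sizes$lesion_size_mm > 0)) {
    with_lesion <- lesion_sizes$exam_id[lesion_sizes$lesion_size_mm > 0]
    ratio <- ratio_vs_size_table(records[records$exam_id %in% with_lesion, ],
                                 lesion_sizes)
  }
  list(variant_table = do.call(rbind, variant),
       region_table = do.call(rbind, region),
       ratio = ratio)
}
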