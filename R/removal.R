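#' Electronically remove a segmented lesion from a subtraction volume
#'
#' On every slice that intersects the lesion, lesion pixels are replaced by a
#' single constant: the mean intensity of the pixels bordering the slice's
#' lesion region. The border ring is the morphological dilation of the slice
#' lesion mask by a `(2 * ring_width + 1)` square structuring element
#' (8-connectivity at the default `ring_width = 1`), minus the lesion,
#' intersected with the image bounds. All other voxels are untouched and the
#' input is not mutated.
#'
#' @param subvol a `subtraction_volume` (see [subtract()]).
#' @param lesion a `lesion_mask` or logical 3D array on the same grid.
#' @param ring_width border ring width in pixels (>= 1).
#' @return list with `volume` (a new `subtraction_volume`, `lesion_removed =
#'   TRUE`) and `report` (class `removal_report`): `n_slices_modified`,
#'   `fill_values` (named by slice index), `n_voxels_replaced`, `warnings`.
#'   If a slice's ring is empty (the lesion fills the slice), the fill falls
#'   back to the volume-level border mean and a warning is recorded.
#' @export
remove_lesion <- function(subvol, lesion, ring_width = 1L) {
  stopifnot(inherits(subvol, "subtraction_volume"))
  m3 <- if (inherits(lesion, "lesion_mask")) lesion$mask_3d else lesion
  stopifnot(identical(dim(m3), dim(subvol$data)))
  out <- subvol$data
  brush <- matrix(1L, 2L * ring_width + 1L, 2L * ring_width + 1L)
  slices <- which(apply(m3, 1, any))
  fills <- numeric(0)
  warns <- character(0)
  if (length(slices) > 0) {
    # volume-level fallback: 3D 26-connected border ring, computed lazily
    vol_fill <- NULL
    volume_border_mean <- function() {
      if (is.null(vol_fill)) {
        ring3 <- array(FALSE, dim(m3))
        dm <- dim(m3)
        for (ds in -1:1) for (dr in -1:1) for (dc in -1:1) {
          if (ds == 0 && dr == 0 && dc == 0) next
          src_s <- intersect(seq_len(dm[1]), seq_len(dm[1]) - ds)
          src_r <- intersect(seq_len(dm[2]), seq_len(dm[2]) - dr)
          src_c <- intersect(seq_len(dm[3]), seq_len(dm[3]) - dc)
          ring3[src_s + ds, src_r + dr, src_c + dc] <-
            ring3[src_s + ds, src_r + dr, src_c + dc] | m3[src_s, src_r, src_c]
        }
        ring3 <- ring3 & !m3
        vol_fill <<- mean(subvol$data[ring3])
      }
      vol_fill
    }
    for (s in slices) {
      sm <- m3[s, , ]
      ring <- EBImage::dilate(sm * 1L, brush) > 0 & !sm
      if (any(ring)) {
        fill <- mean(subvol$data[s, , ][ring])
      } else {
        fill <- volume_border_mean()
        warns <- c(warns, sprintf(
          "slice %d: empty border ring (lesion fills the slice); volume-level border mean used", s))
      }
      sl <- out[s, , ]
      sl[sm] <- fill
      out[s, , ] <- sl
      fills[as.character(s)] <- fill
    }
  }
  vol <- structure(list(data = out, time_point = subvol$time_point,
                        spacing = subvol$spacing, lesion_removed = TRUE),
                   class = "subtraction_volume")
  report <- structure(list(n_slices_modified = length(slices),
                           fill_values = fills,
                           n_voxels_replaced = sum(m3),
                           warnings = warns),
                      class = "removal_report")
  list(volume = vol, report = report)
}

#' Ratio of BPE scores after vs before lesion removal
#'
#' @param score_after,score_before scalar computer BPE scores for the same
#'   exam/region/image variant, after and before electronic lesion removal.
#' @return `score_after / score_before`. `score_before` must be positive.
#' @export
removal_ratio <- function(score_after, score_before) {
  if (!is.finite(score_before) || score_before <= 0) {
    stop("removal_ratio is undefined: score_before must be > 0")
  }
  score_after / score_before
}

#' Project a subtraction volume to a 2D image
#'
#' Maximum-intensity projection (MIP) takes the per-pixel maximum over all
#' slices; average-intensity projection (AIP) the per-pixel arithmetic mean.
#' The projection axis is the slice axis (axis 1); no resampling is done.
#'
#' @param subvol a `subtraction_volume`.
#' @param projection_type `"MIP"` or `"AIP"`.
#' @return An object of class `projection_image`: `data` (rows x cols
#'   matrix), `projection_type`, `time_point`, `lesion_removed`.
#' @export
project <- function(subvol, projection_type = c("MIP", "AIP")) {
  projection_type <- match.arg(projection_type)
  stopifnot(inherits(subvol, "subtraction_volume"))
  a <- subvol$data
  dm <- dim(a)
  m <- matrix(a, dm[1], dm[2] * dm[3])
  img <- if (projection_type == "MIP") {
    matrix(apply(m, 2, max), dm[2], dm[3])
  } else {
    matrix(colMeans(m), dm[2], dm[3])
  }
  structure(list(data = img, projection_type = projection_type,
                 time_point = subvol$time_point,
                 lesion_removed = isTRUE(subvol$lesion_removed)),
            class = "projection_image")
}
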