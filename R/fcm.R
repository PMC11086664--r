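#' Fuzzy c-means clustering of voxel intensities
#'
#' Standard alternating (Bezdek) scheme on 1D intensities: memberships
#' `u_ik = (1 / d_ik^2)^(1/(m-1)) / sum_j (1 / d_ij^2)^(1/(m-1))` and centers
#' `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`, iterated until the largest center
#' shift drops below `tol`. The fuzzified within-cluster objective
#' `J = sum_ik u_ik^m d_ik^2` is non-increasing across iterations.
#'
#' @param values numeric vector of voxel intensities (>= `c` distinct values).
#' @param c number of clusters (>= 2).
#' @param m fuzziness exponent (> 1); 2 is the canonical choice.
#' @param tol convergence tolerance on the maximum center shift.
#' @param max_iter iteration cap; if reached, the result is returned with
#'   `converged = FALSE`.
#' @param init `"range"` (deterministic: centers equally spaced between min
#'   and max) or `"random"` (sampled data points, controlled by `seed`).
#' @param seed RNG seed, used only for `init = "random"`.
#' @return An object of class `fcm_result`: `membership` (n x c matrix, rows
#'   sum to 1), `centers` (ascending order not guaranteed; see
#'   `lesion_class`), `n_iterations`, `converged`, `objective` (trace),
#'   `lesion_class` (index of the cluster with the highest center).
#' @export
fcm_cluster <- function(values, c = 2L, m = 2, tol = 1e-5, max_iter = 300L,
                        init = c("range", "random"), seed = 1L) {
  init <- match.arg(init)
  x <- as.numeric(values)
  stopifnot(c >= 2L, m > 1, tol > 0, max_iter >= 1L)
  if (length(unique(x)) < c) {
    stop("degenerate input: need at least ", c, " distinct values, got ",
         length(unique(x)))
  }
  v <- if (init == "range") {
    seq(min(x), max(x), length.out = c)
  } else {
    with_seed(seed, sample(unique(x), c))
  }
  expo <- 2 / (m - 1)
  objective <- numeric(max_iter)  # `c` is the cluster count here, so no c() calls below
  converged <- FALSE
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(x, v, function(a, b) (a - b)^2)              # n x c
    zero <- d2 < .Machine$double.eps
    u <- (1 / pmax(d2, .Machine$double.eps))^(expo / 2)
    u <- u / rowSums(u)
    # voxels sitting exactly on a center get crisp membership there
    hit <- rowSums(zero) > 0
    if (any(hit)) u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    um <- u^m
    objective[it] <- sum(um * d2)
    v_new <- colSums(um * x) / colSums(um)
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < tol) { converged <- TRUE; break }
  }
  structure(list(membership = u, centers = v, n_iterations = it,
                 converged = converged, objective = objective[seq_len(it)],
                 lesion_class = which.max(v)),
            class = "fcm_result")
}

# 1-based inclusive ROI box: list/matrix with slice/row/col ranges
.roi_index <- function(roi, grid) {
  r <- rbind(slice = roi$slice, row = roi$row, col = roi$col)
  stopifnot(ncol(r) == 2, all(r[, 1] >= 1), all(r[, 2] <= grid), all(r[, 1] <= r[, 2]))
  r
}

#' Segment an enhancing lesion with 3D fuzzy c-means
#'
#' FCM is run on the subtraction intensities inside a rectangular region of
#' interest (a known diagnosed-lesion box). Voxels whose membership in the
#' brightest-center cluster exceeds `membership_threshold` are candidates; the
#' largest 26-connected component is kept and holes are filled slice-wise.
#'
#' The default is c = 3 clusters because a lesion ROI typically holds three
#' intensity populations on a subtraction volume — background/fat, enhancing
#' parenchyma, and the hyper-enhancing lesion; with c = 2 the bright cluster
#' merges the lesion with enhancing parenchyma whenever the box overlaps
#' fibroglandular tissue.
#'
#' @param subvol a `subtraction_volume` (see [subtract()]).
#' @param roi list with elements `slice`, `row`, `col`, each a length-2
#'   1-based inclusive index range within the grid.
#' @param c,m,tol,max_iter,membership_threshold,seed,init FCM parameters; see
#'   [fcm_cluster()]. `membership_threshold` defaults to 0.5.
#' @return An object of class `lesion_mask`: `mask_3d` (full-grid logical
#'   array), `size_mm`, `center_slice_index`, `fcm` (the `fcm_result`).
#'   An empty candidate set — including an ROI too uniform to support `c`
#'   clusters — yields an empty mask with `size_mm = 0` and a warning, not
#'   an error.
#' @export
segment_lesion <- function(subvol, roi, c = 3L, m = 2, tol = 1e-5,
                           max_iter = 300L, membership_threshold = 0.5,
                           init = "range", seed = 1L) {
  stopifnot(inherits(subvol, "subtraction_volume"))
  g <- dim(subvol$data)
  r <- .roi_index(roi, g)
  sub <- subvol$data[r[1, 1]:r[1, 2], r[2, 1]:r[2, 2], r[3, 1]:r[3, 2], drop = FALSE]
  fcm <- tryCatch(
    fcm_cluster(as.vector(sub), c = c, m = m, tol = tol,
                max_iter = max_iter, init = init, seed = seed),
    error = function(e) {
      if (!grepl("degenerate", conditionMessage(e))) stop(e)
      NULL
    })
  if (is.null(fcm)) {
    warning("segment_lesion: ROI intensities too uniform to cluster; empty lesion mask")
    return(structure(list(mask_3d = array(FALSE, g), size_mm = 0,
                          center_slice_index = NA_integer_, fcm = NULL),
                     class = "lesion_mask"))
  }
  cand <- array(fcm$membership[, fcm$lesion_class] > membership_threshold, dim(sub))
  mask_roi <- largest_component(cand)
  if (any(mask_roi)) mask_roi <- fill_holes_2d(mask_roi)
  mask <- array(FALSE, g)
  mask[r[1, 1]:r[1, 2], r[2, 1]:r[2, 2], r[3, 1]:r[3, 2]] <- mask_roi
  if (!any(mask)) {
    warning("segment_lesion: no voxel exceeded the membership threshold; empty lesion mask")
    return(structure(list(mask_3d = mask, size_mm = 0,
                          center_slice_index = NA_integer_, fcm = fcm),
                     class = "lesion_mask"))
  }
  sz <- lesion_size(mask, subvol$spacing)
  structure(list(mask_3d = mask, size_mm = sz$size_mm,
                 center_slice_index = sz$center_slice_index, fcm = fcm),
            class = "lesion_mask")
}

#' Lesion size: square root of the lesion area at the center slice
#'
#' The center lesion slice is the slice with maximal lesion area (ties broken
#' by the lower slice index); the size is the square root of that slice's
#' lesion area in mm^2, the conventional single-number size of an irregular
#' lesion.
#'
#' @param mask a `lesion_mask` or a logical 3D array.
#' @param spacing voxel spacing (slice, row, col) in mm; taken from the mask
#'   object if omitted there is no default for plain arrays.
#' @return list with `size_mm` and `center_slice_index`; an empty mask gives
#'   `size_mm = 0` with a warning.
#' @export
lesion_size <- function(mask, spacing) {
  m3 <- if (inherits(mask, "lesion_mask")) mask$mask_3d else mask
  stopifnot(length(dim(m3)) == 3L, length(spacing) == 3L)
  per_slice <- apply(m3, 1, sum)
  if (sum(per_slice) == 0) {
    warning("lesion_size: empty mask")
    return(list(size_mm = 0, center_slice_index = NA_integer_))
  }
  center <- which.max(per_slice)  # which.max takes the first (lowest) index on ties
  area_mm2 <- per_slice[center] * spacing[2] * spacing[3]
  list(size_mm = sqrt(area_mm2), center_slice_index = center)
}
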