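#' Construct a DCE-MRI study object
#'
#' The exam-level container used throughout the pipeline: one pre-contrast
#' volume and an ordered list of post-contrast volumes on a shared grid.
#' Axis convention: axis 1 = slice (through-plane), axes 2-3 = in-plane
#' rows x columns; projections collapse axis 1.
#'
#' @param exam_id character identifier.
#' @param pre 3D numeric array, pre-contrast volume.
#' @param posts list of 3D numeric arrays, post-contrast volumes in temporal
#'   order (index 1 = first post-contrast).
#' @param voxel_spacing_mm numeric length 3: (slice, row, col) spacing in mm.
#' @param affected_side `"left"`, `"right"` or `"unknown"` — the breast
#'   containing the diagnosed lesion.
#' @param rating optional ordinal BPE rating (one of [bpe_levels]) or NA.
#' @return An object of class `dce_study`.
#' @export
dce_study <- function(exam_id, pre, posts, voxel_spacing_mm,
                      affected_side = "unknown", rating = NA_character_) {
  stopifnot(length(dim(pre)) == 3L, is.list(posts), length(posts) >= 1L,
            length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0))
  affected_side <- match.arg(affected_side, c("left", "right", "unknown"))
  shapes <- vapply(posts, function(v) paste(dim(v), collapse = "x"), "")
  if (any(shapes != paste(dim(pre), collapse = "x"))) {
    stop("grid mismatch: all volumes must share the pre-contrast grid ",
         paste(dim(pre), collapse = "x"), "; got post shapes ",
         paste(unique(shapes), collapse = ", "))
  }
  if (!is.na(rating)) rating <- match.arg(rating, bpe_levels)
  structure(list(exam_id = exam_id, pre = pre, posts = posts,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 affected_side = affected_side, rating = rating),
            class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  cat("<dce_study>", x$exam_id, "\n",
      " grid:", paste(dim(x$pre), collapse = " x "),
      " spacing:", paste(x$voxel_spacing_mm, collapse = "/"), "mm\n",
      " post-contrast time points:", length(x$posts),
      " affected side:", x$affected_side,
      " rating:", x$rating, "\n")
  invisible(x)
}

#' Read / write a single volume as NIfTI
#'
#' Thin wrappers over RNifti preserving the (slice, row, col) axis convention:
#' on disk the fastest-varying NIfTI axis is the in-plane column.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol 3D numeric array in (slice, row, col) order.
#' @param voxel_spacing_mm (slice, row, col) spacing stored as pixdim.
#' @return `read_volume`: list with `data` (3D array, slice/row/col) and
#'   `spacing`; `write_volume`: the path, invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  a <- aperm(array(as.numeric(img), dim(img)), c(3, 2, 1))
  sp <- rev(RNifti::pixdim(img)[1:3])
  list(data = a, spacing = sp)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path, voxel_spacing_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(aperm(vol, c(3, 2, 1)))
  RNifti::pixdim(img) <- rev(voxel_spacing_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a DCE study from NIfTI files
#'
#' @param pre_path path to the pre-contrast NIfTI volume.
#' @param post_paths character vector of post-contrast volume paths in
#'   temporal order.
#' @inheritParams dce_study
#' @return A [dce_study()].
#' @export
load_study <- function(pre_path, post_paths, exam_id = "exam",
                       affected_side = "unknown", rating = NA_character_) {
  pre <- read_volume(pre_path)
  posts <- lapply(post_paths, read_volume)
  shapes <- vapply(posts, function(p) paste(dim(p$data), collapse = "x"), "")
  if (any(shapes != paste(dim(pre$data), collapse = "x"))) {
    stop("grid mismatch across time points: pre is ",
         paste(dim(pre$data), collapse = "x"), ", posts are ",
         paste(shapes, collapse = ", "))
  }
  dce_study(exam_id, pre$data, lapply(posts, `[[`, "data"),
            voxel_spacing_mm = pre$spacing,
            affected_side = affected_side, rating = rating)
}

#' Build a post-minus-pre subtraction volume
#'
#' Subtraction isolates contrast enhancement. Negative differences (noise,
#' slight misregistration) are clipped to 0 by default; clipping does not
#' change maximum-intensity projections but keeps average projections from
#' being pulled down by noise.
#'
#' @param study a [dce_study()].
#' @param time_point 1 (first post-contrast) or 2 (second), or `"first"` /
#'   `"second"`.
#' @param clip_negative clip negative differences to zero (default TRUE).
#' @return An object of class `subtraction_volume`: list with `data` (3D
#'   array), `time_point` (integer), `spacing`, `lesion_removed` (FALSE).
#' @export
subtract <- function(study, time_point = 2L, clip_negative = TRUE) {
  stopifnot(inherits(study, "dce_study"))
  if (is.character(time_point)) {
    time_point <- match(match.arg(time_point, c("first", "second")), c("first", "second"))
  }
  if (time_point < 1 || time_point > length(study$posts)) {
    stop("time point ", time_point, " not available; study has post-contrast points ",
         paste(seq_along(study$posts), collapse = ", "))
  }
  d <- study$posts[[time_point]] - study$pre
  if (clip_negative) d <- pmax(d, 0)
  structure(list(data = d, time_point = as.integer(time_point),
                 spacing = study$voxel_spacing_mm, lesion_removed = FALSE),
            class = "subtraction_volume")
}
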