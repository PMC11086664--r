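#' @title Synthetic DCE-MRI breast phantoms
#' @description Generators for bilateral breast phantoms with a programmed
#'   background parenchymal enhancement (BPE) level, optional hyper-enhancing
#'   lesion, and full ground-truth masks. Every downstream stage of the
#'   pipeline (lesion segmentation, electronic lesion removal, projection,
#'   breast segmentation, scoring, evaluation) can be trained and tested on
#'   these phantoms without any clinical data.
#' @name phantom
NULL

#' Ordinal BPE levels, in increasing order of enhancement
#' @export
bpe_levels <- c("minimal", "mild", "moderate", "marked")

# Programmed level maps. Amplitudes are fractions of the lesion-free dynamic
# range (200 intensity units); the enhancing-FGT fraction is the share of
# fibroglandular tissue that takes up contrast. Both are strictly increasing
# so that a level is expressed through intensity *and* volume of enhancement,
# mirroring how BPE is rated clinically.
.level_amplitude_frac <- c(minimal = 0.10, mild = 0.25, moderate = 0.45, marked = 0.70)
.level_enhancing_frac <- c(minimal = 0.30, mild = 0.50, moderate = 0.70, marked = 0.90)
.dynamic_range <- 200
.uptake <- function(t) if (t <= 2) c(0.6, 1.0)[t] else 1.0 + 0.05 * (t - 2)

# base (pre-contrast) tissue intensities and slight enhancement of fat/chest
.base_intensity <- c(background = 0, chest = 50, fat = 60, fgt = 80)
.fat_enh_amplitude <- 6
.chest_enh_amplitude <- 2

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

#' Specify a breast DCE-MRI phantom
#'
#' @param grid_shape integer vector (slices, rows, cols); each axis >= 16.
#' @param voxel_spacing_mm physical spacing (slice, row, col) in mm.
#' @param bpe_level one of `bpe_levels`.
#' @param fgt_fraction fraction of breast volume occupied by fibroglandular
#'   tissue, in (0, 1).
#' @param lesion_diameter_mm lesion diameter in mm; 0 means no lesion.
#' @param lesion_side `"left"`, `"right"`, or `"none"`; must be `"none"` iff
#'   `lesion_diameter_mm == 0`.
#' @param lesion_contrast_multiplier ratio of lesion enhancement amplitude to
#'   enhancing-FGT amplitude; >= 1.
#' @param noise_sd standard deviation of additive Gaussian noise, in intensity
#'   units (volumes are clipped at 0 after noise).
#' @param n_posts number of post-contrast time points (>= 2).
#' @param seed integer RNG seed; `(spec, seed)` fully determines the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 128L, 128L),
                         voxel_spacing_mm = c(2, 1, 1),
                         bpe_level = "mild",
                         fgt_fraction = 0.2,
                         lesion_diameter_mm = 0,
                         lesion_side = c("none", "left", "right"),
                         lesion_contrast_multiplier = 3,
                         noise_sd = 2,
                         n_posts = 2L,
                         seed = 1L) {
  lesion_side <- match.arg(lesion_side)
  bpe_level <- match.arg(bpe_level, bpe_levels)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L),
            length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0),
            fgt_fraction > 0, fgt_fraction < 1,
            lesion_diameter_mm >= 0,
            lesion_contrast_multiplier >= 1,
            noise_sd >= 0, n_posts >= 2L)
  if ((lesion_diameter_mm == 0) != (lesion_side == "none")) {
    stop("lesion_diameter_mm must be 0 exactly when lesion_side is \"none\"")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 bpe_level = bpe_level,
                 fgt_fraction = fgt_fraction,
                 lesion_diameter_mm = lesion_diameter_mm,
                 lesion_side = lesion_side,
                 lesion_contrast_multiplier = lesion_contrast_multiplier,
                 noise_sd = noise_sd,
                 n_posts = as.integer(n_posts),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# anatomy layout in voxel/physical coordinates, derived from the grid
.phantom_geometry <- function(spec) {
  g <- spec$grid_shape; sp <- spec$voxel_spacing_mm
  list(
    chest_rows = seq_len(max(6L, round(0.08 * g[2]))),      # posterior band
    y0 = max(6L, round(0.08 * g[2])) + 1L,                  # breast base row
    cz = (g[1] + 1) / 2,
    cx_left = 0.26 * (g[3] + 1),
    cx_right = 0.74 * (g[3] + 1),
    # wide enough that the breasts meet in a thin medial bridge near the
    # chest wall, so the region containing both breasts is one component
    semi_col_mm = 0.26 * g[3] * sp[3],
    semi_row_mm = 0.66 * g[2] * sp[2],
    semi_slice_mm = 0.44 * g[1] * sp[1]
  )
}

#' Generate one phantom DCE-MRI study with ground truth
#'
#' Builds two half-ellipsoid breasts anterior to a flat chest-wall band.
#' Fibroglandular tissue (FGT) is a blurred random blob field thresholded to
#' the requested volume fraction; a nested blob field selects the enhancing
#' subset, whose size grows with the programmed BPE level. Intensities follow
#' `intensity(t) = base + amplitude * uptake(t)` with uptake monotone in the
#' time-point index; the lesion's amplitude is the enhancing-FGT amplitude
#' times `lesion_contrast_multiplier`. Additive Gaussian noise is clipped at 0.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `study` (a [dce_study()]) and `truth`, a
#'   `phantom_truth` list of logical masks: `breast_mask_3d`, `left_mask_3d`,
#'   `right_mask_3d`, `fgt_mask_3d`, `lesion_mask_3d`, plus `true_bpe_level`
#'   and `lesion_bbox` (the lesion bounding box, NULL when no lesion).
#' @examples
#' ph <- generate_study(phantom_spec(bpe_level = "marked", seed = 7))
#' dim(ph$study$pre)
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape; sp <- spec$voxel_spacing_mm
  geo <- .phantom_geometry(spec)

  # physical coordinates of voxel centers
  z <- (seq_len(g[1]) - geo$cz) * sp[1]
  y <- (seq_len(g[2]) - geo$y0) * sp[2]
  xl <- (seq_len(g[3]) - geo$cx_left) * sp[3]
  xr <- (seq_len(g[3]) - geo$cx_right) * sp[3]

  Z <- array(rep(z, times = g[2] * g[3]), g)
  Y <- array(rep(rep(y, each = g[1]), times = g[3]), g)
  XL <- array(rep(xl, each = g[1] * g[2]), g)
  XR <- array(rep(xr, each = g[1] * g[2]), g)

  inside <- function(X) (X / geo$semi_col_mm)^2 + (Y / geo$semi_row_mm)^2 +
    (Z / geo$semi_slice_mm)^2 <= 1 & Y >= 0
  left_mask <- inside(XL)
  right_mask <- inside(XR)
  breast_mask <- left_mask | right_mask
  chest_mask <- array(FALSE, g); chest_mask[, geo$chest_rows, ] <- TRUE
  chest_mask <- chest_mask & !breast_mask

  out <- with_seed(spec$seed, {
    # FGT: blurred blob field thresholded to fgt_fraction of breast volume
    blob <- gaussian_smooth3(array(rnorm(prod(g)), g), sigma = c(1.5, 5, 5))
    thr <- quantile(blob[breast_mask], 1 - spec$fgt_fraction)
    fgt_mask <- breast_mask & blob >= thr
    # enhancing subset of FGT, nested blob field
    blob2 <- gaussian_smooth3(array(rnorm(prod(g)), g), sigma = c(1.5, 4, 4))
    f_enh <- .level_enhancing_frac[spec$bpe_level]
    thr2 <- quantile(blob2[fgt_mask], 1 - f_enh)
    enh_mask <- fgt_mask & blob2 >= thr2

    # lesion sphere
    lesion_mask <- array(FALSE, g)
    if (spec$lesion_side != "none") {
      r_mm <- spec$lesion_diameter_mm / 2
      cy_mm <- 0.35 * geo$semi_row_mm
      X <- if (spec$lesion_side == "left") XL else XR
      lesion_mask <- (X^2 + (Y - cy_mm)^2 + Z^2) <= r_mm^2
      if (!any(lesion_mask)) {
        stop("lesion_diameter_mm too small to cover any voxel at this spacing")
      }
      if (any(lesion_mask & !breast_mask)) {
        stop("lesion_diameter_mm = ", spec$lesion_diameter_mm,
             " mm does not fit inside the breast at this grid size")
      }
    }

    amp_fgt <- .level_amplitude_frac[spec$bpe_level] * .dynamic_range
    base <- array(.base_intensity["background"], g)
    base[chest_mask] <- .base_intensity["chest"]
    base[breast_mask] <- .base_intensity["fat"]
    base[fgt_mask] <- .base_intensity["fgt"]
    base[lesion_mask] <- .base_intensity["fgt"]

    amp <- array(0, g)
    amp[chest_mask] <- .chest_enh_amplitude
    amp[breast_mask] <- .fat_enh_amplitude
    amp[enh_mask] <- amp_fgt
    amp[lesion_mask] <- amp_fgt * spec$lesion_contrast_multiplier

    add_noise <- function(v) {
      if (spec$noise_sd > 0) v <- v + array(rnorm(prod(g), sd = spec$noise_sd), g)
      pmax(v, 0)
    }
    pre <- add_noise(base)
    posts <- lapply(seq_len(spec$n_posts), function(t) add_noise(base + .uptake(t) * amp))
    list(pre = pre, posts = posts, fgt_mask = fgt_mask, enh_mask = enh_mask,
         lesion_mask = lesion_mask)
  })

  lesion_bbox <- NULL
  if (any(out$lesion_mask)) {
    w <- which(out$lesion_mask, arr.ind = TRUE)
    lesion_bbox <- rbind(lo = apply(w, 2, min), hi = apply(w, 2, max))
    colnames(lesion_bbox) <- c("slice", "row", "col")
  }

  study <- dce_study(
    exam_id = sprintf("phantom-%s-%d", spec$bpe_level, spec$seed),
    pre = out$pre, posts = out$posts, voxel_spacing_mm = sp,
    affected_side = if (spec$lesion_side == "none") "unknown" else spec$lesion_side,
    rating = spec$bpe_level)

  truth <- structure(list(
    breast_mask_3d = breast_mask,
    left_mask_3d = left_mask,
    right_mask_3d = right_mask & !left_mask,
    fgt_mask_3d = out$fgt_mask,
    enhancing_mask_3d = out$enh_mask,
    lesion_mask_3d = out$lesion_mask,
    lesion_bbox = lesion_bbox,
    true_bpe_level = spec$bpe_level), class = "phantom_truth")

  list(study = study, truth = truth, spec = spec)
}

#' Generate a cohort of phantom studies
#'
#' Levels are sampled from `level_distribution`; per-study seeds are derived
#' deterministically from the cohort seed so the cohort is a pure function of
#' its arguments.
#'
#' @param n number of exams (>= 1).
#' @param level_distribution probabilities over the four BPE levels
#'   (minimal, mild, moderate, marked); must sum to 1.
#' @param seed cohort RNG seed.
#' @param lesion_diameter_range range (mm) from which lesion diameters are
#'   drawn uniformly; use `c(0, 0)` for a lesion-free cohort.
#' @param levels optional explicit vector of BPE levels (length `n`),
#'   overriding the random draw from `level_distribution` — e.g. a
#'   stratified design with equal counts per level.
#' @param ... further arguments passed to [phantom_spec()] (e.g. `grid_shape`,
#'   `noise_sd`).
#' @return A list with `exams` (list of [generate_study()] outputs) and
#'   `manifest` (data.frame: exam_id, rating, lesion_side, lesion_diameter_mm,
#'   seed) plus the realized `level_counts`.
#' @export
generate_cohort <- function(n, level_distribution = rep(0.25, 4), seed = 1L,
                            lesion_diameter_range = c(5, 30), levels = NULL, ...) {
  stopifnot(n >= 1, length(level_distribution) == 4,
            abs(sum(level_distribution) - 1) < 1e-8, all(level_distribution >= 0))
  if (!is.null(levels)) stopifnot(length(levels) == n, all(levels %in% bpe_levels))
  drange <- lesion_diameter_range
  stopifnot(length(drange) == 2, drange[1] <= drange[2], drange[1] >= 0)
  draw <- with_seed(seed, {
    levels_i <- if (is.null(levels)) {
      sample(bpe_levels, n, replace = TRUE, prob = level_distribution)
    } else as.character(levels)
    diam <- if (drange[2] == 0) rep(0, n) else runif(n, drange[1], drange[2])
    side <- sample(c("left", "right"), n, replace = TRUE)
    list(levels = levels_i, diam = diam, side = side)
  })
  exams <- vector("list", n)
  for (i in seq_len(n)) {
    has_lesion <- draw$diam[i] > 0
    sp <- phantom_spec(bpe_level = draw$levels[i],
                       lesion_diameter_mm = if (has_lesion) draw$diam[i] else 0,
                       lesion_side = if (has_lesion) draw$side[i] else "none",
                       seed = derive_seed(seed, i), ...)
    exams[[i]] <- generate_study(sp)
    exams[[i]]$study$exam_id <- sprintf("phantom-%03d", i)
  }
  manifest <- data.frame(
    exam_id = vapply(exams, function(e) e$study$exam_id, ""),
    rating = draw$levels,
    lesion_side = ifelse(draw$diam > 0, draw$side, "none"),
    lesion_diameter_mm = ifelse(draw$diam > 0, draw$diam, 0),
    seed = vapply(seq_len(n), function(i) derive_seed(seed, i), 0),
    stringsAsFactors = FALSE)
  list(exams = exams, manifest = manifest,
       level_counts = table(factor(draw$levels, levels = bpe_levels)))
}

#' Write a phantom study (volumes, truth masks, spec sidecar) to disk
#'
#' One NIfTI file per time point (`pre.nii.gz`, `post1.nii.gz`, ...), one per
#' truth mask, and a JSON sidecar with the generating spec.
#'
#' @param phantom output of [generate_study()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- phantom$study
  paths <- c(pre = file.path(dir, "pre.nii.gz"))
  write_volume(st$pre, paths["pre"], st$voxel_spacing_mm)
  for (t in seq_along(st$posts)) {
    p <- file.path(dir, sprintf("post%d.nii.gz", t))
    write_volume(st$posts[[t]], p, st$voxel_spacing_mm)
    paths[sprintf("post%d", t)] <- p
  }
  for (nm in c("breast_mask_3d", "fgt_mask_3d", "lesion_mask_3d")) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    write_volume(phantom$truth[[nm]] * 1L, p, st$voxel_spacing_mm)
    paths[nm] <- p
  }
  sidecar <- file.path(dir, "spec.json")
  jsonlite::write_json(unclass(phantom$spec), sidecar, auto_unbox = TRUE, digits = NA)
  paths["spec"] <- sidecar
  invisible(paths)
}
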