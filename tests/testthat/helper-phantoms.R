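# Shared fixtures, built in code and memoized so expensive phantoms are
# generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small, fast phantom grid used by most unit tests
small_spec <- function(...) {
  phantom_spec(grid_shape = c(16L, 64L, 64L), voxel_spacing_mm = c(2, 1.5, 1.5), ...)
}

small_lesion_phantom <- function() {
  cached("small_lesion", generate_study(
    small_spec(bpe_level = "moderate", lesion_diameter_mm = 10,
               lesion_side = "left", noise_sd = 0, seed = 5)))
}

# a plain subtraction_volume wrapper for hand-built arrays
as_subvol <- function(a, spacing = c(1, 1, 1), time_point = 2L) {
  structure(list(data = a, time_point = time_point, spacing = spacing,
                 lesion_removed = FALSE), class = "subtraction_volume")
}

# truth both-breast mask projected to 2D
truth_projection_mask <- function(truth) apply(truth$breast_mask_3d, c(2, 3), any)

# (image, mask) training pair from one phantom seed, at the default grid
unet_training_pair <- function(seed, bpe_level = NULL) {
  lv <- if (is.null(bpe_level)) bpe_levels[1 + (seed %% 4)] else bpe_level
  ph <- generate_study(phantom_spec(bpe_level = lv, seed = seed))
  mip <- project(subtract(ph$study, 2), "MIP")
  list(img = mip$data, mask = truth_projection_mask(ph$truth))
}
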