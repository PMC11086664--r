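test_that("FGT enhancement is strictly increasing across programmed BPE levels", {
  means <- vapply(bpe_levels, function(lv) {
    ph <- generate_study(small_spec(bpe_level = lv, noise_sd = 0, seed = 2))
    sv <- subtract(ph$study, 2)
    mean(sv$data[ph$truth$fgt_mask_3d])
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("lesion enhancement scales with the contrast multiplier", {
  ph <- generate_study(small_spec(bpe_level = "mild", noise_sd = 0,
                                  lesion_diameter_mm = 10, lesion_side = "left",
                                  lesion_contrast_multiplier = 3, seed = 3))
  sv <- subtract(ph$study, 2)
  mean_lesion <- mean(sv$data[ph$truth$lesion_mask_3d])
  mean_fgt <- mean(sv$data[ph$truth$fgt_mask_3d & !ph$truth$lesion_mask_3d])
  expect_gte(mean_lesion, 2 * mean_fgt)
})

test_that("identical spec and seed reproduce bit-identical volumes", {
  sp <- small_spec(bpe_level = "marked", lesion_diameter_mm = 8,
                   lesion_side = "right", seed = 17)
  a <- generate_study(sp); b <- generate_study(sp)
  expect_identical(a$study$pre, b$study$pre)
  expect_identical(a$study$posts, b$study$posts)
  expect_identical(a$truth$fgt_mask_3d, b$truth$fgt_mask_3d)
})

test_that("truth masks satisfy containment and partition invariants", {
  for (seed in c(1, 9)) {
    ph <- generate_study(small_spec(bpe_level = "moderate", seed = seed,
                                    lesion_diameter_mm = 12, lesion_side = "left"))
    tr <- ph$truth
    expect_true(all(tr$lesion_mask_3d[tr$lesion_mask_3d] & tr$breast_mask_3d[tr$lesion_mask_3d]))
    expect_false(any(tr$fgt_mask_3d & !tr$breast_mask_3d))
    expect_false(any(tr$left_mask_3d & tr$right_mask_3d))
    expect_identical(tr$left_mask_3d | tr$right_mask_3d, tr$breast_mask_3d)
  }
})

test_that("oversized lesions and inconsistent lesion fields are rejected", {
  expect_error(generate_study(small_spec(lesion_diameter_mm = 90, lesion_side = "left")),
               "does not fit")
  expect_error(small_spec(lesion_diameter_mm = 0, lesion_side = "left"), "lesion")
  expect_error(small_spec(lesion_diameter_mm = 5, lesion_side = "none"), "lesion")
})

test_that("subtraction is near zero in fat and positive in FGT on noiseless phantoms", {
  ph <- generate_study(small_spec(bpe_level = "moderate", noise_sd = 0, seed = 4))
  sv <- subtract(ph$study, 2)
  fat <- ph$truth$breast_mask_3d & !ph$truth$fgt_mask_3d
  expect_lt(mean(sv$data[fat]), 10)
  expect_gt(mean(sv$data[ph$truth$enhancing_mask_3d]), 5 * mean(sv$data[fat]))
  # true background (air) has no enhancement at all
  background <- ph$study$pre == 0
  expect_true(all(sv$data[background] == 0))
})

test_that("cohort generation honors the level distribution and is reproducible", {
  co <- generate_cohort(4, level_distribution = c(1, 0, 0, 0), seed = 2,
                        grid_shape = c(16L, 64L, 64L),
                        voxel_spacing_mm = c(2, 1.5, 1.5),
                        lesion_diameter_range = c(0, 0))
  expect_true(all(co$manifest$rating == "minimal"))
  co2 <- generate_cohort(4, level_distribution = c(1, 0, 0, 0), seed = 2,
                         grid_shape = c(16L, 64L, 64L),
                         voxel_spacing_mm = c(2, 1.5, 1.5),
                         lesion_diameter_range = c(0, 0))
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$exams[[1]]$study$pre, co2$exams[[1]]$study$pre)
})

test_that("realized level counts are multinomial under a uniform distribution", {
  # pool realized counts over two cohort seeds and test against the
  # programmed uniform distribution
  counts <- rep(0, 4)
  for (seed in 1:2) {
    co <- generate_cohort(60, seed = seed, grid_shape = c(16L, 32L, 32L),
                          voxel_spacing_mm = c(2, 2.5, 2.5),
                          lesion_diameter_range = c(0, 0))
    counts <- counts + as.numeric(co$level_counts)
  }
  p <- stats::chisq.test(counts, p = rep(0.25, 4))$p.value
  expect_gt(p, 0.01)
})

test_that("explicit level vectors override the random draw", {
  lv <- rep(bpe_levels, each = 2)
  co <- generate_cohort(8, levels = lv, seed = 3, grid_shape = c(16L, 64L, 64L),
                        voxel_spacing_mm = c(2, 1.5, 1.5),
                        lesion_diameter_range = c(5, 12))
  expect_identical(co$manifest$rating, lv)
  expect_identical(as.numeric(co$level_counts), rep(2, 4))
})
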