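test_that("rescaling modes map the quantized range as documented", {
  q <- matrix(c(0L, 128L, 255L, 64L), 2, 2)
  r <- rescale_image(q, "rescaled")
  expect_equal(r[1, 1], 0)
  expect_equal(r[1, 2], 1)
  expect_equal(r[2, 1], 128 / 255)
  mm <- rescale_image(matrix(c(50, 100, 150), 1, 3), "minmax")
  expect_equal(as.numeric(mm), c(0, 0.5, 1))
  expect_warning(z <- rescale_image(matrix(7, 3, 3), "minmax"), "degenerate")
  expect_true(all(z == 0))
  expect_identical(rescale_image(q, "original"), q + 0)
})

test_that("quantization windows and clips to 8-bit intensities", {
  img <- matrix(c(0, 100, 255, 400), 2, 2)
  q <- quantize_projection(img)
  expect_identical(q$image, matrix(c(0L, 100L, 255L, 255L), 2, 2))
  expect_equal(q$window_max, 255)
  qp <- quantize_projection(img, window_max = NULL, window_percentile = 100)
  expect_equal(qp$window_max, 400)
  expect_equal(qp$image[2, 2], 255L)
  expect_warning(q0 <- quantize_projection(matrix(0, 3, 3), window_max = NULL),
                 "degenerate")
  expect_true(all(q0$image == 0L))
})

test_that("the computer BPE score is the masked arithmetic mean", {
  img <- matrix(c(0.2, 0.4, 0.6, 0.9), 2, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_equal(compute_score(img, mask), 0.4)
  one <- matrix(FALSE, 2, 2); one[2, 2] <- TRUE
  expect_equal(compute_score(img, one), 0.9)
  expect_error(compute_score(img, matrix(FALSE, 2, 2)), "empty mask")
  set.seed(70)
  for (rep in 1:5) {
    im <- matrix(runif(900), 30, 30)
    mk <- matrix(runif(900) > 0.5, 30, 30)
    expect_equal(compute_score(im, mk), oracle_masked_mean(im, mk))
  }
})

test_that("score_grid emits the full variant grid with consistent removal semantics", {
  ph <- small_lesion_phantom()
  masks <- split_breasts(truth_projection_mask(ph$truth), "left")
  les <- structure(list(mask_3d = ph$truth$lesion_mask_3d, size_mm = 9,
                        center_slice_index = 8L), class = "lesion_mask")
  rec <- score_grid(ph$study, masks, les)
  # 3 regions x 2 projections x 2 time points x 2 modes x 2 removal states
  expect_equal(nrow(rec), 48L)
  expect_equal(sum(rec$region == "unaffected"), 16L)
  # unaffected-breast scores identical before vs after removal
  un <- rec[rec$region == "unaffected", ]
  for (key in split(un, interaction(un$projection_type, un$time_point, un$rescale_mode))) {
    expect_identical(key$score[!key$lesion_removed], key$score[key$lesion_removed])
  }
  # affected rescaled second-post MIP strictly lower after removal
  af <- rec[rec$region == "affected" & rec$projection_type == "MIP" &
              rec$time_point == 2 & rec$rescale_mode == "rescaled", ]
  expect_lt(af$score[af$lesion_removed], af$score[!af$lesion_removed])
})

test_that("without a lesion, removal-on and removal-off scores are identical", {
  ph <- cached("no_lesion_ph", generate_study(small_spec(bpe_level = "mild", seed = 23)))
  masks <- split_breasts(truth_projection_mask(ph$truth), "left")
  rec <- score_grid(ph$study, masks, lesion = NULL)
  by_var <- split(rec, interaction(rec$region, rec$projection_type,
                                   rec$time_point, rec$rescale_mode))
  for (key in by_var) {
    expect_identical(key$score[!key$lesion_removed], key$score[key$lesion_removed])
  }
})

test_that("original-mode scores are invariant to slice order of the source volume", {
  ph <- small_lesion_phantom()
  masks <- split_breasts(truth_projection_mask(ph$truth), "left")
  mip <- project(subtract(ph$study, 2), "MIP")
  s1 <- compute_score(rescale_image(quantize_projection(mip, masks$both)$image,
                                    "original"), masks$both)
  perm <- rev(seq_len(dim(ph$study$pre)[1]))
  st2 <- dce_study("perm", ph$study$pre[perm, , ],
                   lapply(ph$study$posts, function(p) p[perm, , ]),
                   ph$study$voxel_spacing_mm, "left", ph$study$rating)
  mip2 <- project(subtract(st2, 2), "MIP")
  s2 <- compute_score(rescale_image(quantize_projection(mip2, masks$both)$image,
                                    "original"), masks$both)
  expect_identical(s1, s2)
})

test_that("marked phantoms outscore minimal phantoms on every variant at zero noise", {
  scores <- lapply(c("minimal", "marked"), function(lv) {
    ph <- generate_study(small_spec(bpe_level = lv, noise_sd = 0, seed = 13))
    masks <- split_breasts(truth_projection_mask(ph$truth), "left")
    score_grid(ph$study, masks)
  })
  merged <- merge(scores[[1]], scores[[2]],
                  by = c("region", "projection_type", "time_point",
                         "rescale_mode", "lesion_removed"))
  expect_true(all(merged$score.y > merged$score.x))
})
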