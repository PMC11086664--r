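test_that("postprocessing keeps the largest thresholded object and fills holes", {
  p <- matrix(0.3, 10, 10)
  expect_true(all(postprocess_mask(p, 0.25)))

  p2 <- matrix(0, 30, 30)
  p2[2:4, 2:4] <- 0.9               # 9 px
  p2[10:25, 5:25] <- 0.9            # 336 px
  p2[15, 15] <- 0                   # hole
  m <- postprocess_mask(p2, 0.25)
  expect_false(any(m[2:4, 2:4]))
  expect_true(all(m[10:25, 5:25]))  # hole filled
  expect_error(postprocess_mask(matrix(0.1, 5, 5), 0.25), "unsegmentable")
})

test_that("component labeling agrees with a flood-fill oracle in 2D and 3D", {
  set.seed(55)
  for (rep in 1:3) {
    m2 <- matrix(runif(400) > 0.6, 20, 20)
    got <- bpescore:::label_components(m2)
    ora <- oracle_label(m2)
    # same partition: label images must be identical up to renumbering
    expect_equal(max(got), max(ora))
    expect_true(all(tapply(ora[m2], got[m2], function(v) length(unique(v))) == 1))
  }
  m3 <- array(runif(6 * 10 * 10) > 0.7, c(6, 10, 10))
  got3 <- bpescore:::label_components(m3)
  ora3 <- oracle_label(m3)
  expect_equal(max(got3), max(ora3))
  expect_true(all(tapply(ora3[m3], got3[m3], function(v) length(unique(v))) == 1))
})

test_that("the vertical split partitions the mask at the bounding-box center", {
  m <- matrix(FALSE, 20, 40)
  m[5:15, 11:30] <- TRUE            # columns 11..30
  bm <- split_breasts(m, affected_side = "right")
  expect_equal(bm$split_column, 21L)
  expect_true(all(which(colSums(bm$left) > 0) == 11:20))
  expect_identical(bm$affected, bm$right)
  expect_identical(bm$unaffected, bm$left)
  # partition property
  expect_identical(bm$affected | bm$unaffected, bm$both)
  expect_false(any(bm$affected & bm$unaffected))
  # unknown side: only left/right labels
  bu <- split_breasts(m)
  expect_null(bu$affected)
})

test_that("the fallback segmenter recovers the phantom breast region", {
  ph <- cached("fallback_ph", generate_study(phantom_spec(bpe_level = "mild", seed = 31)))
  mip <- project(subtract(ph$study, 2), "MIP")
  masks <- segment_breasts(mip, model = NULL, affected_side = "left")
  expect_gte(dice_coefficient(masks$both, truth_projection_mask(ph$truth)), 0.8)
  expect_equal(max(bpescore:::label_components(masks$both)), 1L)
})

test_that("a briefly trained U-Net segments held-out phantoms and is deterministic", {
  pairs <- cached("unet_pairs_small", lapply(1:10, unet_training_pair))
  imgs <- lapply(pairs, `[[`, "img"); msks <- lapply(pairs, `[[`, "mask")
  model <- cached("unet_small", train_segmenter(imgs, msks, epochs_max = 6, seed = 3))
  expect_true(all(diff(model$loss_history) < 0.1))  # non-increasing trend
  held <- unet_training_pair(901)
  prob <- predict_probability(model, held$img)
  expect_true(all(prob$data >= 0 & prob$data <= 1))
  expect_gt(mean(prob$data[held$mask]), mean(prob$data[!held$mask]))
  m <- postprocess_mask(prob, 0.25)
  expect_gte(dice_coefficient(m, held$mask), 0.8)
  # constant-zero input is handled without error
  p0 <- predict_probability(model, matrix(0, 128, 128))
  expect_true(all(p0$data >= 0 & p0$data <= 1))
  # determinism of training under a fixed seed (tiny run)
  m1 <- suppressWarnings(train_segmenter(imgs[1:4], msks[1:4], epochs_max = 2, seed = 9))
  m2 <- suppressWarnings(train_segmenter(imgs[1:4], msks[1:4], epochs_max = 2, seed = 9))
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$layers$out$W, m2$layers$out$W)
})

test_that("degenerate training inputs are flagged", {
  pairs <- cached("unet_pairs_small", lapply(1:10, unet_training_pair))
  expect_warning(train_segmenter(list(pairs[[1]]$img), list(pairs[[1]]$mask),
                                 epochs_max = 1),
                 "training pair")
  expect_warning(
    expect_warning(
      train_segmenter(list(pairs[[1]]$img, pairs[[2]]$img),
                      list(pairs[[1]]$mask, matrix(FALSE, 128, 128)),
                      epochs_max = 1),
      "empty reference"),
    "training pair")
})

test_that("model artifacts round-trip through the JSON file format", {
  pairs <- cached("unet_pairs_small", lapply(1:10, unet_training_pair))
  model <- cached("unet_small", train_segmenter(lapply(pairs, `[[`, "img"),
                                                lapply(pairs, `[[`, "mask"),
                                                epochs_max = 6, seed = 3))
  path <- file.path(tempdir(), "unet.json")
  save_segmenter(model, path)
  m2 <- load_segmenter(path)
  held <- unet_training_pair(902)
  expect_equal(predict_probability(m2, held$img)$data,
               predict_probability(model, held$img)$data, tolerance = 1e-12)
  unlink(path)
})
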