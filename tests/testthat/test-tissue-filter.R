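# Tissue classification: texture descriptors, one-vs-rest SVM training and
# SBNP filtering.

test_that("a constant frame has all-zero local-contrast features", {
  f <- matrix(120, 384, 384)
  v <- extract_texture_features(f)
  expect_true(all(v == 0))
})

test_that("feature extraction is deterministic and shift-tolerant", {
  px <- fix_plexus()
  f <- crop_mosaic(px, 200, 200, 384)$image
  expect_identical(extract_texture_features(f), extract_texture_features(f))
  # global additive shift within range leaves contrast features unchanged
  expect_equal(extract_texture_features(f + 10),
               extract_texture_features(f), tolerance = 1e-9)
  expect_error(extract_texture_features(array(0, c(4, 4, 3))), "grayscale")
})

test_that("epithelium and stroma textures separate in feature space", {
  ep <- extract_texture_features(make_nonsbnp_frame("epithelium", seed = 3))
  st <- extract_texture_features(make_nonsbnp_frame("stroma", seed = 3))
  expect_gt(max(abs(ep - st)), sd(c(ep, st)))
})

test_that("the trained model reaches high held-out accuracy", {
  model <- fix_tissue_model()
  expect_gte(model$train_accuracy, 0.95)
  te <- synth_tissue_frames(n_per_class = 10, seed = 77)
  pred <- predict_tissue(model, te$frames)
  expect_gte(mean(pred$label == te$labels), 0.90)
})

test_that("training contracts are enforced", {
  tr <- synth_tissue_frames(n_per_class = 12, seed = 1)
  two <- tr$labels != "stroma"
  expect_error(train_tissue_model(tr$frames[two], tr$labels[two]),
               "three tissue classes")
  few <- c(which(tr$labels == "sbnp")[1:12],
           which(tr$labels == "epithelium")[1:12],
           which(tr$labels == "stroma")[1:5])
  expect_error(train_tissue_model(tr$frames[few], tr$labels[few]),
               "at least 10")
})

test_that("prediction is deterministic for fixed data and seed", {
  tr <- synth_tissue_frames(n_per_class = 10, seed = 5)
  m1 <- train_tissue_model(tr$frames, tr$labels, seed = 2)
  m2 <- train_tissue_model(tr$frames, tr$labels, seed = 2)
  probe <- synth_tissue_frames(n_per_class = 4, seed = 31)
  expect_identical(predict_tissue(m1, probe$frames)$label,
                   predict_tissue(m2, probe$frames)$label)
})

test_that("filtering keeps SBNP frames, preserves indices and is idempotent", {
  model <- fix_tissue_model()
  eye <- fix_eye()
  plan1 <- scan_plan(eye$px, grid = c(1, 2), overlap = 0.5)
  sim <- sample_frames(eye$px, plan1, motion_model(0), noise_sd = 4,
                       insert_rate = 0.8, seed = 13)
  fl <- filter_sbnp(sim$frames, model)
  expect_equal(nrow(fl$report), length(sim$frames))
  # indices preserved
  kept_idx <- vapply(fl$frames, function(f) f$index, integer(1))
  expect_identical(kept_idx, fl$report$index[fl$report$kept])
  # idempotent
  fl2 <- filter_sbnp(fl$frames, model)
  expect_length(fl2$frames, length(fl$frames))
  # kept fraction close to true SBNP fraction
  true_frac <- mean(sim$truth$frames$label == "sbnp")
  expect_lt(abs(length(fl$frames) / length(sim$frames) - true_frac), 0.10)
})

test_that("a stroma-only sequence is emptied with a complete report", {
  model <- fix_tissue_model()
  frames <- lapply(1:4, function(k) make_nonsbnp_frame("stroma", seed = k))
  fl <- filter_sbnp(frames, model)
  expect_length(fl$frames, 0)
  expect_equal(nrow(fl$report), 4)
  expect_error(filter_sbnp(list(), model), "empty")
})
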