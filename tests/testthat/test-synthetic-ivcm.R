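# Synthetic IVCM generator: reproducibility, geometry bookkeeping, frame
# sampling consistency and the non-SBNP textures.

test_that("a single straight fiber without whorl gives one polyline and no branches", {
  px <- generate_plexus(canvas_um = c(1000, 1000), fiber_count = 1,
                        whorl_turns = 0, seed = 4)
  expect_length(px$centerlines, 1)
  expect_equal(nrow(px$branch_points), 0)
})

test_that("the generator is bit-identical under a fixed seed", {
  a <- generate_plexus(canvas_um = c(1000, 1000), fiber_count = 4, seed = 9)
  b <- generate_plexus(canvas_um = c(1000, 1000), fiber_count = 4, seed = 9)
  expect_identical(a$image, b$image)
  expect_identical(a$centerlines, b$centerlines)
  expect_identical(a$branch_points, b$branch_points)
})

test_that("total centerline length equals independent polyline re-summation", {
  px <- generate_plexus(canvas_um = c(1500, 1500), fiber_count = 20,
                        seed = 7)
  resum <- sum(vapply(px$centerlines, function(p) {
    d <- diff(p)
    sum(sqrt(d[, 1]^2 + d[, 2]^2))
  }, numeric(1))) / 1000
  expect_lt(abs(px$total_length_mm - resum), 1e-6)
  # every centerline point lies inside the canvas
  for (p in px$centerlines) {
    expect_true(all(p[, 1] >= 0 & p[, 1] <= 1500))
    expect_true(all(p[, 2] >= 0 & p[, 2] <= 1500))
  }
})

test_that("invalid generator parameters error", {
  expect_error(generate_plexus(canvas_um = c(500, 500)), "canvas")
  expect_error(generate_plexus(fiber_count = 0), "fiber_count")
  expect_error(make_nonsbnp_frame("nerve"), "kind")
})

test_that("a zero-drift noiseless frame is a pixel-exact crop of the phantom", {
  px <- fix_plexus()
  plan <- scan_plan(px, grid = c(1, 1))
  sim <- sample_frames(px, plan, motion_model(0), noise_sd = 0, seed = 1)
  o <- plan$frames
  crop <- px$image[(o$y_px + 1):(o$y_px + 384), (o$x_px + 1):(o$x_px + 384)]
  expect_identical(sim$frames[[1]]$image, crop)
})

test_that("consecutive zero-drift frames agree pixel-for-pixel on their overlap", {
  px <- fix_plexus()
  plan <- scan_plan(px, grid = c(1, 2), overlap = 0.5)
  sim <- sample_frames(px, plan, motion_model(0), noise_sd = 0, seed = 1)
  a <- sim$frames[[1]]$image
  b <- sim$frames[[2]]$image
  shift <- plan$frames$x_px[2] - plan$frames$x_px[1]
  expect_identical(a[, (shift + 1):384], b[, 1:(384 - shift)])
})

test_that("resampling the phantom at recorded row positions reproduces frames exactly", {
  px <- fix_plexus()
  plan <- scan_plan(px, grid = c(2, 2), overlap = 0.5)
  sim <- sample_frames(px, plan, motion_model(2, 48), noise_sd = 0, seed = 6)
  for (s in seq_along(sim$frames)) {
    rp <- sim$truth$row_positions[[s]]
    re <- round(clip8(sbnpmosaic:::cpp_sample_rows(px$image, rp[, 1],
                                                   rp[, 2], 384L)))
    expect_identical(sim$frames[[s]]$image, re)
  }
})

test_that("insertion labels replay exactly from the seeded draw sequence", {
  px <- fix_plexus()
  plan <- scan_plan(px, grid = c(2, 3), overlap = 0.5)
  sim <- sample_frames(px, plan, motion_model(0), noise_sd = 0,
                       insert_rate = 0.4, seed = 3)
  # independent replay of the generator's insertion draws
  set.seed(3)
  labels <- character(0)
  for (f in seq_len(nrow(plan$frames))) {
    while (runif(1) < 0.4) {
      labels <- c(labels, sample(c("epithelium", "stroma"), 1))
    }
    labels <- c(labels, "sbnp")
  }
  expect_identical(sim$truth$frames$label, labels)
})

test_that("frames whose footprint leaves the canvas are rejected by index", {
  px <- fix_plexus()
  plan <- scan_plan(px, grid = c(1, 1))
  plan$frames$x_px <- nrow(px$image) - 100   # push outside
  expect_error(sample_frames(px, plan, motion_model(0), seed = 1),
               "frame 1")
})

test_that("non-SBNP textures are distinct and reproducible", {
  ep <- make_nonsbnp_frame("epithelium", seed = 1)
  st <- make_nonsbnp_frame("stroma", seed = 1)
  expect_lt(mean(st$image > 128), mean(ep$image > 128))
  expect_identical(make_nonsbnp_frame("stroma", seed = 1)$image, st$image)
})

test_that("eye folders round-trip through TIFF with labels", {
  px <- fix_plexus()
  plan <- scan_plan(px, grid = c(1, 2), overlap = 0.5)
  sim <- sample_frames(px, plan, motion_model(0), noise_sd = 0,
                       insert_rate = 0.5, seed = 2)
  dir <- withr::local_tempdir()
  write_eye_folder(sim$frames, dir, truth = sim$truth)
  back <- read_eye_folder(dir)
  expect_length(back, length(sim$frames))
  for (k in seq_along(back)) {
    expect_equal(back[[k]]$image, sim$frames[[k]]$image)
    expect_identical(back[[k]]$label, sim$frames[[k]]$label)
  }
})

test_that("clipped-disc centerline length matches a fine-resampling oracle", {
  px <- fix_plexus()
  ctr <- px$whorl_center_um
  r <- 300
  via_clip <- plexus_length_in_disc(px, ctr, r, "full")
  # brute-force: resample finely, count inside segments by midpoint
  tot <- 0
  for (p in px$centerlines) {
    q <- sbnpmosaic:::resample_polyline(p, 0.25)
    mid <- (q[-1, , drop = FALSE] + q[-nrow(q), , drop = FALSE]) / 2
    seg <- sqrt(rowSums(diff(q)^2))
    inside <- (mid[, 1] - ctr[1])^2 + (mid[, 2] - ctr[2])^2 <= r^2
    tot <- tot + sum(seg[inside])
  }
  expect_lt(abs(via_clip - tot / 1000) / max(tot / 1000, 1e-9), 0.005)
})
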