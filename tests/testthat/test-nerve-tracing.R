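# Nerve tracing: enhancement, pixel classification, skeleton segmentation
# and gap bridging.

# draw an anti-aliased bright line on a mid-gray background
line_image <- function(n, p1, p2, width_sd = 1.5, bg = 90, peak = 230) {
  mask <- matrix(0, n, n)
  t <- seq(0, 1, length.out = 4 * n)
  rr <- round(p1[2] + t * (p2[2] - p1[2])) + 1
  cc <- round(p1[1] + t * (p2[1] - p1[1])) + 1
  ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
  mask[cbind(rr[ok], cc[ok])] <- 1
  k <- sbnpmosaic:::gaussian_kernel(width_sd)
  resp <- EBImage::filter2(mask, k, boundary = 0)
  ref <- sum(k[ceiling(nrow(k) / 2), ])
  round(pmin(pmax(bg + (peak - bg) * pmin(resp / ref, 1), 0), 255))
}

test_that("a constant image has essentially no line response", {
  resp <- enhance(matrix(128, 128, 128))
  expect_lt(max(resp), 1e-6 * 128)
})

test_that("the response ridge coincides with a straight line", {
  img <- line_image(128, c(10, 64), c(118, 64))
  resp <- enhance(img, tracer_config(tophat_radius_px = 6L))
  ridge_rows <- apply(resp[, 30:98], 2, which.max)
  expect_true(all(abs(ridge_rows - 65) <= 1))
})

test_that("orientation coverage: a rotated line peaks within 10% of axis-aligned", {
  img0 <- line_image(128, c(14, 64), c(114, 64))
  ang <- 37 * pi / 180
  ctr <- 64
  d <- 50 * c(cos(ang), sin(ang))
  img37 <- line_image(128, c(ctr - d[1], ctr - d[2]),
                      c(ctr + d[1], ctr + d[2]))
  cfg <- tracer_config(tophat_radius_px = 6L)
  p0 <- max(enhance(img0, cfg))
  p37 <- max(enhance(img37, cfg))
  expect_lt(abs(p37 - p0) / p0, 0.10)
})

test_that("a blank mosaic classifies to an empty map and empty graph", {
  blank <- matrix(100, 96, 96)
  expect_equal(sum(classify_pixels(blank)), 0)
  g <- trace_nerves(blank)
  expect_length(g$edges_um, 0)
  expect_equal(g$total_length_mm, 0)
})

test_that("pixel classification on a noiseless phantom crop is precise and complete", {
  px <- fix_plexus_dense()
  m <- crop_mosaic(px, 500, 500, 512)
  bin <- classify_pixels(m, config = tracer_config())
  # ground-truth centerline mask
  s <- px$um_per_px
  cl <- matrix(FALSE, 512, 512)
  for (p in px$centerlines) {
    q <- sbnpmosaic:::resample_polyline(p / s, 0.4)
    rr <- round(q[, 2]) - 500 + 1; cc <- round(q[, 1]) - 500 + 1
    ok <- rr >= 1 & rr <= 512 & cc >= 1 & cc <= 512
    cl[cbind(rr[ok], cc[ok])] <- TRUE
  }
  dil <- EBImage::dilate(matrix(as.integer(cl), 512, 512),
                         EBImage::makeBrush(9, "disc")) > 0
  bind <- EBImage::dilate(matrix(as.integer(bin), 512, 512),
                          EBImage::makeBrush(5, "disc")) > 0
  expect_gte(mean(bind[cl]), 0.8)     # recall
  expect_gte(mean(dil[bin]), 0.8)     # precision
  # determinism
  expect_identical(bin, classify_pixels(m, config = tracer_config()))
})

test_that("the strict mode errors and the fallback warns for missing classifiers", {
  blank <- matrix(100, 64, 64)
  expect_error(classify_pixels(blank, config = tracer_config(
    classifier = "svm", strict_classifier = TRUE)), "not trained")
  img <- line_image(64, c(5, 32), c(59, 32))
  expect_warning(classify_pixels(img, config = tracer_config(
    classifier = "svm")), "falling back")
})

test_that("a straight bar skeletonizes into one polyline of matching length", {
  b <- matrix(FALSE, 80, 80)
  b[38:42, 11:70] <- TRUE                  # 5 px wide, 60 px long
  segs <- postprocess(b, tracer_config())
  expect_length(segs$segments, 1)
  len <- sbnpmosaic:::polyline_length(segs$segments[[1]])
  expect_lt(abs(len - 59) / 59, 0.03)
  # tip reconstruction may bend a pixel at the very ends
  expect_true(all(abs(segs$segments[[1]][, 2] - 39) <= 2))
})

test_that("a Y junction yields one merged branch point", {
  b <- matrix(FALSE, 90, 90)
  b[44:48, 6:45] <- TRUE                    # stem, 5 px wide
  for (i in 0:34) {
    b[44 - i + 0:3, 45 + i] <- TRUE         # upper arm
    b[46 + i + 0:3, 45 + i] <- TRUE         # lower arm
  }
  segs <- postprocess(b, tracer_config())
  g <- bridge_gaps(segs, matrix(1, 90, 90), tracer_config(),
                   um_per_px = 1)
  expect_equal(nrow(g$branch_points_um), 1)
})

test_that("an isolated blob is pruned", {
  b <- matrix(FALSE, 60, 60)
  b[30:31, 30] <- TRUE
  segs <- postprocess(b, tracer_config())
  expect_length(segs$segments, 0)
})

test_that("a short gap on a bright line is bridged, a wide one is not", {
  img <- line_image(128, c(10, 64), c(118, 64))
  img[, 60:68] <- 90                        # ~9 px gap (about 9.4 um)
  cfg <- tracer_config()
  resp <- enhance(img, cfg)
  segs <- postprocess(classify_pixels(img, resp, cfg), cfg)
  expect_gte(length(segs$segments), 2)
  g <- bridge_gaps(segs, resp, cfg, um_per_px = ivcm_um_per_px())
  main <- sum(vapply(g$edges_um, sbnpmosaic:::polyline_length,
                     numeric(1)))
  # reconnected: total length spans most of the line
  expect_gt(main, 100 * ivcm_um_per_px())

  far <- tracer_config(max_gap_um = 4)
  g2 <- bridge_gaps(segs, resp, far, um_per_px = ivcm_um_per_px())
  expect_gt(length(g2$edges_um), length(g$edges_um))
})

test_that("the collinear continuation is cheaper than a perpendicular one", {
  cfg <- tracer_config()
  rn <- matrix(0.5, 64, 64)
  # outward tangents point toward the gap
  e_from <- data.frame(seg = 1, end = 2L, x = 30, y = 30, tx = 1, ty = 0)
  e_coll <- data.frame(seg = 2, end = 1L, x = 40, y = 30, tx = -1, ty = 0)
  e_perp <- data.frame(seg = 3, end = 1L, x = 30, y = 40, tx = 1, ty = 0)
  c_coll <- sbnpmosaic:::bridge_cost(e_from, e_coll, rn, 1, cfg)
  c_perp <- sbnpmosaic:::bridge_cost(e_from, e_perp, rn, 1, cfg)
  expect_lt(c_coll, c_perp)
})

test_that("lowering the candidate threshold never decreases traced length", {
  px <- fix_plexus_dense()
  m <- crop_mosaic(px, 600, 600, 384)
  g_hi <- trace_nerves(m, tracer_config(threshold = 0.7))
  g_lo <- trace_nerves(m, tracer_config(threshold = 0.45))
  expect_gte(g_lo$total_length_mm, g_hi$total_length_mm)
})

test_that("polyline lengths equal the skeleton chain-step re-summation", {
  px <- fix_plexus_dense()
  m <- crop_mosaic(px, 600, 600, 384)
  g <- trace_nerves(m, tracer_config())
  # oracle: per-edge re-summation counting diagonal steps as sqrt(2)
  oracle <- vapply(g$edges_um, function(p) {
    q <- p / g$um_per_px
    d <- abs(diff(q))
    sum(ifelse(d[, 1] > 0.5 & d[, 2] > 0.5, sqrt(2),
               pmax(d[, 1], d[, 2]))) * g$um_per_px
  }, numeric(1))
  expect_lt(abs(sum(oracle) - sum(g$edge_lengths_um)) /
              sum(g$edge_lengths_um), 0.01)
})

test_that("tracing is deterministic", {
  px <- fix_plexus_dense()
  m <- crop_mosaic(px, 300, 900, 256)
  g1 <- trace_nerves(m, tracer_config())
  g2 <- trace_nerves(m, tracer_config())
  expect_identical(g1$edges_um, g2$edges_um)
  expect_identical(g1$branch_points_um, g2$branch_points_um)
})
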