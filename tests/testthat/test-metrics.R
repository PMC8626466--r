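# SBNP quantification: areas, enhancement factor, CNFL/CNBD and the whorl
# region geometry.

test_that("mosaic area counts only valid pixels", {
  m <- sbnpmosaic:::as_mosaic(matrix(100, 384, 384))
  expect_equal(mosaic_area(m), 0.16, tolerance = 1e-12)
  m$mask[, 1:192] <- FALSE
  expect_equal(mosaic_area(m), 0.08, tolerance = 1e-12)
  m$mask[] <- FALSE
  expect_equal(mosaic_area(m), 0)
})

test_that("the enhancement factor is area over a single 400x400 um field", {
  expect_equal(enhancement_factor(0.16), 1.0)
  expect_equal(enhancement_factor(7.68), 48.0)
  expect_equal(enhancement_factor(0), 0)
})

test_that("a straight 0.4 mm nerve in a 0.16 mm2 frame gives CNFL 2.5", {
  s <- ivcm_um_per_px()
  g <- gt_graph(list(centerlines = list(cbind(c(5, 388.6), c(200, 200))),
                     branch_points = matrix(numeric(0), 0, 2),
                     um_per_px = s, total_length_mm = 0.3836))
  mask <- matrix(TRUE, 384, 384)
  expect_equal(cnfl(g, mask, 0.16, s), (388.6 - 5) / 1000 / 0.16,
               tolerance = 0.01)
  empty <- gt_graph(list(centerlines = list(),
                         branch_points = matrix(numeric(0), 0, 2),
                         um_per_px = s, total_length_mm = 0))
  expect_equal(cnfl(empty, mask, 0.16, s), 0)
  expect_error(cnfl(g, mask, 0), "positive")
})

test_that("CNBD counts branch points in the region", {
  s <- ivcm_um_per_px()
  g <- gt_graph(list(centerlines = list(cbind(c(0, 100), c(0, 100))),
                     branch_points = matrix(c(200, 200), 1, 2),
                     um_per_px = s, total_length_mm = 0.14))
  mask <- matrix(TRUE, 384, 384)
  expect_equal(cnbd(g, mask, 0.16, s), 6.25)
  g$branch_points_um <- matrix(numeric(0), 0, 2)
  expect_equal(cnbd(g, mask, 0.16, s), 0)
})

test_that("whorl masks have the right area and coverage flags", {
  m <- sbnpmosaic:::as_mosaic(matrix(100, 1000, 1000))
  ctr <- c(520, 520)
  full <- whorl_mask(m, whorl_region(ctr, 800, "full"))
  a_full <- sum(full) * m$um_per_px^2 * 1e-6
  expect_lt(abs(a_full - pi * 0.4^2) / (pi * 0.4^2), 0.01)
  expect_true(attr(full, "covered"))

  sup <- whorl_mask(m, whorl_region(ctr, 800, "superior"))
  a_sup <- sum(sup) * m$um_per_px^2 * 1e-6
  expect_lt(abs(a_sup - pi * 0.4^2 / 2) / (pi * 0.4^2 / 2), 0.01)

  edge <- whorl_mask(m, whorl_region(c(100, 100), 800, "full"))
  expect_false(attr(edge, "covered"))
  expect_error(whorl_mask(m, whorl_region(c(-5, 100), 400)), "outside")
})

test_that("superior plus inferior centerline length equals the full disc", {
  px <- fix_plexus()
  ctr <- px$whorl_center_um
  full <- plexus_length_in_disc(px, ctr, 400, "full")
  sup <- plexus_length_in_disc(px, ctr, 400, "superior")
  # inferior via reflecting the geometry about the centre row
  refl <- px
  refl$centerlines <- lapply(px$centerlines, function(p)
    cbind(p[, 1], 2 * ctr[2] - p[, 2]))
  inf <- plexus_length_in_disc(refl, ctr, 400, "superior")
  expect_lt(abs(sup + inf - full) / max(full, 1e-9), 0.005)
})

test_that("whorl CNFL on the ground-truth graph matches the clipping oracle", {
  px <- fix_plexus()
  g <- gt_graph(px)
  ctr <- px$whorl_center_um
  for (d in c(800, 400)) {
    reg <- whorl_region(ctr, d)
    a <- pi * (d / 2000)^2
    expect_lt(abs(cnfl(g, reg, a) -
                    plexus_length_in_disc(px, ctr, d / 2) / a) /
                max(plexus_length_in_disc(px, ctr, d / 2) / a, 1e-9),
              0.005)
  }
})

test_that("uniform-density content gives matching 400 and 800 um disc densities", {
  # synthetic uniform grid of horizontal lines, 40 um apart
  lines <- lapply(seq(0, 2000, by = 40), function(y)
    cbind(c(0, 2000), c(y, y)))
  px <- list(centerlines = lines, um_per_px = 400 / 384)
  g <- gt_graph(list(centerlines = lines,
                     branch_points = matrix(numeric(0), 0, 2),
                     um_per_px = 400 / 384, total_length_mm = NA))
  ctr <- c(1000, 1020)   # off the line grid to avoid boundary ties
  d800 <- cnfl(g, whorl_region(ctr, 800), pi * 0.4^2)
  d400 <- cnfl(g, whorl_region(ctr, 400), pi * 0.2^2)
  expect_lt(abs(d400 - d800) / d800, 0.05)
})

test_that("doubling the physical scale halves CNFL exactly", {
  px <- fix_plexus()
  g <- gt_graph(px)
  mask <- matrix(TRUE, nrow(px$image), ncol(px$image))
  area1 <- sum(mask) * px$um_per_px^2 * 1e-6
  v1 <- cnfl(g, mask, area1, px$um_per_px)
  # same pixel graph at doubled um/px: lengths double, areas quadruple
  g2 <- g
  g2$edges_um <- lapply(g$edges_um, function(p) p * 2)
  g2$um_per_px <- px$um_per_px * 2
  area2 <- sum(mask) * (2 * px$um_per_px)^2 * 1e-6
  v2 <- cnfl(g2, mask, area2, 2 * px$um_per_px)
  expect_equal(v2, v1 / 2, tolerance = 1e-9)
})

test_that("compute_metrics assembles the full record with coverage handling", {
  px <- fix_plexus_dense()
  m <- crop_mosaic(px, 400, 400, 1000)
  g <- trace_nerves(m, tracer_config())
  ctr_local <- px$whorl_center_um - c(400, 400) * px$um_per_px
  rec <- compute_metrics(m, g, ctr_local)
  expect_true(all(c("area_mm2", "enhancement_factor", "mcnfl", "mcnbd",
                    "wcnfl_800_full", "wcnbd_400_sup") %in% names(rec)))
  expect_gt(rec$area_mm2, 0)
  expect_true(rec$whorl_covered_800)
  expect_gt(rec$wcnfl_800_full, 0)
  # mCNFL within 10% of the ground-truth density of the same region
  gt <- gt_length_rect(px, 400, 400, 1000)
  expect_lt(abs(rec$mcnfl - gt / rec$area_mm2) / (gt / rec$area_mm2), 0.10)

  # whorl centred at a corner: all four whorl entries uncovered
  rec2 <- compute_metrics(m, g, c(10, 10))
  expect_false(rec2$whorl_covered_800)
  expect_false(rec2$whorl_covered_400)
  expect_true(is.na(rec2$wcnfl_800_full))
  expect_true(is.na(rec2$wcnbd_400_full))
})
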