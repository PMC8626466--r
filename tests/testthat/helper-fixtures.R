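# Shared fixtures, generated once per test run and memoised. All fixtures
# are seeded, so every run sees identical data.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small phantom for generator/metrics tests
fix_plexus <- function() fixture("plexus", function()
  generate_plexus(canvas_um = c(1500, 1500), fiber_count = 10,
                  whorl_turns = 2.5, seed = 11))

# denser phantom used for tracing tests (default fiber density)
fix_plexus_dense <- function() fixture("plexus_dense", function()
  generate_plexus(canvas_um = c(2000, 2000), fiber_count = 20, seed = 5))

# a fully-valid mosaic view of a phantom crop (0-based pixel origin r0/c0)
crop_mosaic <- function(px, r0, c0, n) {
  structure(list(image = px$image[(r0 + 1):(r0 + n), (c0 + 1):(c0 + n)],
                 mask = matrix(TRUE, n, n), um_per_px = px$um_per_px,
                 origin_px = c(x = c0, y = r0), n_frames = 1L,
                 component = 1L),
            class = "sbnp_mosaic")
}

# ground-truth centerline length inside a rectangular crop (mm), by fine
# resampling — the clipped-polyline oracle for rectangular regions
gt_length_rect <- function(px, r0, c0, n) {
  s <- px$um_per_px
  tot <- 0
  for (p in px$centerlines) {
    q <- sbnpmosaic:::resample_polyline(p, 0.5)
    mid <- (q[-1, , drop = FALSE] + q[-nrow(q), , drop = FALSE]) / 2
    seg <- sqrt(rowSums(diff(q)^2))
    inside <- mid[, 1] >= c0 * s & mid[, 1] <= (c0 + n - 1) * s &
      mid[, 2] >= r0 * s & mid[, 2] <= (r0 + n - 1) * s
    tot <- tot + sum(seg[inside])
  }
  tot / 1000
}

# small simulated eye: 3 x 3 raster over the small phantom, default noise
fix_eye <- function() fixture("eye", function() {
  px <- fix_plexus_dense()
  plan <- scan_plan(px, grid = c(3, 3), overlap = 0.5)
  sim <- sample_frames(px, plan, motion_model(3, 64), noise_sd = 4,
                       insert_rate = 0, seed = 3)
  list(px = px, plan = plan, sim = sim)
})

# trained tissue model on a small synthetic corpus
fix_tissue_model <- function() fixture("tissue_model", function() {
  tr <- synth_tissue_frames(n_per_class = 30, seed = 21, frame_px = 384L)
  train_tissue_model(tr$frames, tr$labels, seed = 21)
})

# a ground-truth nerve graph built directly from phantom bookkeeping
gt_graph <- function(px) {
  structure(list(edges_um = px$centerlines,
                 edge_lengths_um = vapply(px$centerlines,
                                          sbnpmosaic:::polyline_length,
                                          numeric(1)),
                 branch_points_um = px$branch_points,
                 endpoints_px = matrix(numeric(0), 0, 2),
                 skeleton = NULL, um_per_px = px$um_per_px,
                 total_length_mm = px$total_length_mm),
            class = "nerve_graph")
}
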