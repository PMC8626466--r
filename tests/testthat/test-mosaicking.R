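# Sub-image decomposition, regularized global alignment (vs a dense
# least-squares oracle) and mosaic rendering.

test_that("a 384-row frame decomposes into twelve 32-row slices that re-concatenate", {
  d <- decompose_frame(matrix(0, 384, 384))
  expect_equal(nrow(d), 12)
  expect_true(all(d$row_end - d$row_start == 32))
  expect_equal(d$row_start[1], 0)
  expect_equal(d$row_end[12], 384)
  # contiguous partition
  expect_equal(d$row_start[-1], d$row_end[-12])
})

test_that("the remainder rule assigns extra rows to the first slices", {
  d <- decompose_frame(matrix(0, 100, 50))
  h <- d$row_end - d$row_start
  expect_equal(h, c(rep(9L, 4), rep(8L, 8)))
  expect_equal(sum(h), 100)
  expect_error(decompose_frame(matrix(0, 11, 50)), "rows")
})

# dense least-squares oracle for the regularized system
dense_solve <- function(pairs, n, frame_of, config, anchor = 1L) {
  sys <- build_system(pairs, n, frame_of, config, anchor)
  A <- as.matrix(sys$A)
  list(x = qr.solve(crossprod(A), crossprod(A, sys$bx)),
       y = qr.solve(crossprod(A), crossprod(A, sys$by)),
       A = A, bx = sys$bx, by = sys$by)
}

test_that("three chained sub-images with exact differences are recovered exactly", {
  pairs <- data.frame(i = c(1, 2), j = c(2, 3), dx = c(5, 5), dy = c(0, 0))
  cfg <- alignment_config()
  sys <- build_system(pairs, 3, frame_of = c(1, 2, 3), cfg)
  px <- sbnpmosaic:::solve_ls(sys$A, sys$bx)
  py <- sbnpmosaic:::solve_ls(sys$A, sys$by)
  expect_equal(px, c(0, 5, 10), tolerance = 1e-9)
  expect_equal(py, c(0, 0, 0), tolerance = 1e-9)
})

test_that("a consistent redundant cycle solves with zero residual", {
  pairs <- data.frame(i = c(1, 2, 3), j = c(2, 3, 1),
                      dx = c(4, -1, -3), dy = c(2, 2, -4))
  cfg <- cfg <- alignment_config()
  sys <- build_system(pairs, 3, frame_of = c(1, 2, 3), cfg)
  px <- sbnpmosaic:::solve_ls(sys$A, sys$bx)
  res <- as.numeric(sys$A %*% px) - sys$bx
  expect_lt(max(abs(res)), 1e-9)
  expect_equal(px, c(0, 4, 3), tolerance = 1e-9)
})

test_that("an inconsistent cycle matches the dense least-squares oracle", {
  pairs <- data.frame(i = c(1, 2, 3), j = c(2, 3, 1),
                      dx = c(4, -1, 0), dy = c(0, 0, 0))   # sum = (3, 0)
  cfg <- alignment_config()
  sys <- build_system(pairs, 3, frame_of = c(1, 2, 3), cfg)
  px <- sbnpmosaic:::solve_ls(sys$A, sys$bx)
  oracle <- dense_solve(pairs, 3, c(1, 2, 3), cfg)
  expect_equal(px, as.numeric(oracle$x), tolerance = 1e-8)
  resid <- sqrt(sum((sys$A %*% px - sys$bx)^2))
  expect_gt(resid, 0.1)
})

test_that("sparse regularized solve equals the dense oracle on random instances", {
  cfg <- alignment_config()
  set.seed(42)
  for (case in 1:20) {
    n <- sample(6:24, 1)
    n_frames <- max(1, n %/% 6)
    frame_of <- sort(rep_len(seq_len(n_frames), n))
    npairs <- sample(n:(2 * n), 1)
    pairs <- data.frame(i = sample(n, npairs, replace = TRUE),
                        j = sample(n, npairs, replace = TRUE))
    pairs <- pairs[pairs$i != pairs$j, ]
    pairs$dx <- rnorm(nrow(pairs), 0, 20)
    pairs$dy <- rnorm(nrow(pairs), 0, 20)
    sys <- build_system(pairs, n, frame_of, cfg)
    px <- sbnpmosaic:::solve_ls(sys$A, sys$bx)
    py <- sbnpmosaic:::solve_ls(sys$A, sys$by)
    oracle <- dense_solve(pairs, n, frame_of, cfg)
    expect_lt(max(abs(px - as.numeric(oracle$x))), 1e-6)
    expect_lt(max(abs(py - as.numeric(oracle$y))), 1e-6)
  }
})

test_that("adding a constant to all true positions only changes the anchor", {
  cfg <- alignment_config()
  set.seed(3)
  n <- 9
  truth <- cbind(rnorm(n, 0, 30), rnorm(n, 0, 30))
  idx <- cbind(sample(n, 15, replace = TRUE), sample(n, 15, replace = TRUE))
  idx <- idx[idx[, 1] != idx[, 2], ]
  mk <- function(truth) {
    data.frame(i = idx[, 1], j = idx[, 2],
               dx = truth[idx[, 2], 1] - truth[idx[, 1], 1],
               dy = truth[idx[, 2], 2] - truth[idx[, 1], 2])
  }
  solve_xy <- function(pairs) {
    sys <- build_system(pairs, n, rep(1:3, each = 3), cfg)
    cbind(sbnpmosaic:::solve_ls(sys$A, sys$bx),
          sbnpmosaic:::solve_ls(sys$A, sys$by))
  }
  p1 <- solve_xy(mk(truth))
  p2 <- solve_xy(mk(sweep(truth, 2, c(100, -50), "+")))
  # re-anchor both and compare
  expect_equal(sweep(p1, 2, p1[1, ]), sweep(p2, 2, p2[1, ]),
               tolerance = 1e-8)
})

test_that("two identical frames register slice-to-slice at zero offset", {
  px <- fix_plexus()
  f <- crop_mosaic(px, 300, 300, 384)$image
  pairs <- register_pairs(list(f, f), alignment_config())
  same <- pairs[pairs$slice_i == pairs$slice_j, ]
  expect_gt(nrow(same), 0)
  expect_true(all(abs(same$dx) <= 0.5 & abs(same$dy) <= 0.5))
  expect_true(all(same$score > 0.9))
})

test_that("a known 64-px offset pair registers within a pixel of truth", {
  px <- fix_plexus()
  a <- crop_mosaic(px, 300, 300, 384)$image
  b <- crop_mosaic(px, 300, 364, 384)$image    # shifted 64 px in x
  pairs <- register_pairs(list(a, b), alignment_config())
  acc <- pairs[pairs$score >= alignment_config()$tau, ]
  expect_gt(nrow(acc), 5)
  expect_true(all(abs(acc$dx - 64) <= 1))
  expect_true(all(abs(acc$dy - 32 * (acc$slice_j - acc$slice_i)) <= 1))
})

test_that("disjoint-content frames yield no accepted registration", {
  set.seed(9)
  a <- matrix(round(runif(384^2, 0, 255)), 384, 384)
  b <- matrix(round(runif(384^2, 0, 255)), 384, 384)
  pairs <- register_pairs(list(a, b), alignment_config())
  expect_true(nrow(pairs) == 0 ||
                all(pairs$score < alignment_config()$tau))
})

test_that("a single frame renders to an identical mosaic with a full mask", {
  px <- fix_plexus()
  f <- crop_mosaic(px, 200, 200, 384)$image
  sol <- tibble::tibble(sub = 1:12, frame = 1L, slice = 1:12,
                        px = 0, py = 32 * (0:11), component = 1L)
  attr(sol, "slices") <- decompose_frame(f)
  m <- render_mosaic(list(f), sol, 1)
  expect_true(all(m$mask))
  expect_equal(dim(m$image), dim(f))
  expect_equal(m$image, f, tolerance = 1e-9)
})

test_that("exactly aligned noiseless frames agree with both sources in the overlap", {
  px <- fix_plexus()
  a <- crop_mosaic(px, 200, 200, 384)$image
  b <- crop_mosaic(px, 200, 392, 384)$image   # 192 px to the right
  mk_sol <- function() {
    sol <- tibble::tibble(sub = 1:24, frame = rep(1:2, each = 12),
                          slice = rep(1:12, 2),
                          px = rep(c(0, 192), each = 12),
                          py = rep(32 * (0:11), 2), component = 1L)
    attr(sol, "slices") <- decompose_frame(a)
    sol
  }
  m <- render_mosaic(list(a, b), mk_sol(), 1)
  # overlap columns 193..384 of the canvas equal frame a's columns 193..384
  expect_equal(m$image[, 193:384], a[, 193:384], tolerance = 1e-9)
  expect_equal(m$image[, 193:384], b[, 1:192], tolerance = 1e-9)
})

test_that("two disconnected frame groups yield two internally consistent components", {
  px <- fix_plexus()
  a1 <- crop_mosaic(px, 100, 100, 384)$image
  a2 <- crop_mosaic(px, 100, 292, 384)$image  # overlaps a1
  b1 <- crop_mosaic(px, 700, 700, 384)$image  # far away
  pairs <- register_pairs(list(a1, a2, b1), alignment_config())
  sol <- solve_alignment(pairs, alignment_config())
  expect_equal(attr(sol, "n_components"), 2)
  est <- as.data.frame(sol)
  # within the first component, frame 2 sits ~192 px right of frame 1
  d <- mean(est$px[est$frame == 2]) - mean(est$px[est$frame == 1])
  expect_lt(abs(d - 192), 2)
  out <- largest_mosaic(list(a1, a2, b1), sol)
  expect_equal(out$largest$n_frames, 2)
  expect_length(out$others, 1)
  expect_gt(mosaic_area(out$largest), mosaic_area(out$others[[1]]))
})
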