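# Synthetic IVCM data generator.
#
# Produces a ground-truth subbasal nerve plexus (SBNP) phantom, samples
# overlapping small-field frames from it along a serpentine raster scan with
# smooth per-row motion distortion and additive noise, and interleaves
# non-SBNP (epithelium / stroma) frames. Every output is reproducible from
# its seed and comes with the exact ground truth needed to validate the
# registration, mosaicking and tracing stages.

#' Default physical scale of a synthetic IVCM frame
#'
#' A 400 x 400 micrometre field imaged at 384 x 384 px, the instrument
#' standard adopted throughout the package.
#' @return micrometres per pixel (scalar).
#' @export
ivcm_um_per_px <- function() 400 / 384

#' Construct a single IVCM frame object
#'
#' @param image numeric matrix, 8-bit intensity scale (0-255); row 1 is the
#'   top image row.
#' @param index acquisition index within the sequence.
#' @param um_per_px physical scale in micrometres per pixel.
#' @param label true tissue label if known (`"sbnp"`, `"epithelium"`,
#'   `"stroma"`) or `NA`.
#' @return an object of class `ivcm_frame`.
#' @export
ivcm_frame <- function(image, index = 1L, um_per_px = ivcm_um_per_px(),
                       label = NA_character_) {
  assert_image(image, "frame image")
  structure(list(image = image, index = as.integer(index),
                 um_per_px = um_per_px, label = label),
            class = "ivcm_frame")
}

#' @export
print.ivcm_frame <- function(x, ...) {
  cat(sprintf("<ivcm_frame #%d: %d x %d px, %.4f um/px, label %s>\n",
              x$index, nrow(x$image), ncol(x$image), x$um_per_px,
              ifelse(is.na(x$label), "?", x$label)))
  invisible(x)
}

# Resample a polyline (n x 2, columns x/y) at uniform arc-length spacing.
resample_polyline <- function(p, spacing) {
  if (nrow(p) < 2) return(p)
  seg <- sqrt(rowSums(diff(p)^2))
  cl <- c(0, cumsum(seg))
  total <- cl[length(cl)]
  if (total <= 0) return(p[1, , drop = FALSE])
  s <- seq(0, total, by = spacing)
  if (s[length(s)] < total) s <- c(s, total)
  cbind(stats::approx(cl, p[, 1], xout = s)$y,
        stats::approx(cl, p[, 2], xout = s)$y)
}

# Smoothed directed random walk from `start` towards `target` (micrometres).
walk_fiber <- function(start, target, step_um, n_max, heading_sd,
                       stop_fun = NULL) {
  pts <- matrix(NA_real_, n_max + 1, 2)
  pts[1, ] <- start
  heading <- atan2(target[2] - start[2], target[1] - start[1])
  n <- 1
  for (k in seq_len(n_max)) {
    to_target <- atan2(target[2] - pts[n, 2], target[1] - pts[n, 1])
    # steer gently towards the target with smooth angular noise
    dh <- ((to_target - heading + pi) %% (2 * pi)) - pi
    heading <- heading + 0.15 * dh + rnorm(1, 0, heading_sd)
    cand <- pts[n, ] + step_um * c(cos(heading), sin(heading))
    if (!is.null(stop_fun) && stop_fun(cand)) break
    n <- n + 1
    pts[n, ] <- cand
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Generate a ground-truth subbasal nerve plexus phantom
#'
#' Builds a wide-field SBNP phantom: an Archimedean-spiral whorl bundle plus
#' quasi-parallel radial nerve fibers converging toward the whorl, rendered
#' as bright lines with a Gaussian cross-sectional profile on a mid-gray
#' background. The full centerline geometry (polylines, branch points, total
#' length) is returned alongside the rendered 8-bit image, so downstream
#' stages can be validated against exact ground truth.
#'
#' @param canvas_um canvas size in micrometres, `c(width, height)`; at least
#'   1 x 1 mm.
#' @param fiber_count number of radial nerve fibers (>= 1). The default
#'   gives a total centerline density of roughly 9-10 mm/mm^2 on the
#'   default canvas, comparable to the corneal nerve fiber length
#'   densities reported for human subbasal plexus.
#' @param whorl_turns number of turns of the spiral whorl bundle (0 disables
#'   the whorl arms; the whorl centre is still defined).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param um_per_px physical scale of the phantom grid.
#' @param background,peak background and nerve-peak intensity (8-bit scale).
#' @param profile_sd_px Gaussian cross-profile standard deviation in px.
#' @param mottle_sd standard deviation of the smooth background texture
#'   (gray levels); real IVCM frames always carry low-frequency cellular
#'   background mottle, which is also what makes featureless regions
#'   registrable.
#' @param mottle_scale_px correlation length (Gaussian sigma, px) of the
#'   background mottle.
#' @param texture_sd,texture_scale_px standard deviation (gray levels) and
#'   correlation length (px) of the fine-scale scene texture superimposed
#'   on the background, emulating the basal epithelial cell texture that
#'   fills real IVCM frames; it is part of the scene (identical wherever
#'   two frames overlap), unlike the per-frame acquisition noise.
#' @param psf_sigma_px Gaussian sigma (px) of the optical point-spread
#'   function applied to the rendered scene. The default corresponds to
#'   roughly 2 micrometres FWHM, the lateral resolution limit of clinical
#'   confocal corneal microscopes; without it the phantom would claim
#'   finer detail than the instrument it emulates can image.
#' @return an object of class `sbnp_plexus` with elements `image` (numeric
#'   matrix, 0-255 integers), `um_per_px`, `centerlines` (list of n x 2
#'   micrometre polylines), `branch_points` (m x 2 matrix, micrometres),
#'   `crossing_points` (k x 2 matrix of fiber-fiber intersection points:
#'   in the rendered image these are junctions indistinguishable from
#'   bifurcations without continuity analysis), `whorl_center_um`, and
#'   `total_length_mm`.
#' @examples
#' px <- generate_plexus(canvas_um = c(1200, 1200), fiber_count = 5, seed = 1)
#' px$total_length_mm
#' @export
generate_plexus <- function(canvas_um = c(3000, 3000), fiber_count = 45,
                            whorl_turns = 3, seed = 1,
                            um_per_px = ivcm_um_per_px(),
                            background = 90, peak = 230,
                            profile_sd_px = 1.5, mottle_sd = 7,
                            mottle_scale_px = 20, texture_sd = 5,
                            texture_scale_px = 2.5, psf_sigma_px = 0.8) {
  if (length(canvas_um) != 2 || any(!is.finite(canvas_um)) ||
      any(canvas_um < 1000))
    stop("canvas_um must be two finite values of at least 1000 um (1 mm)",
         call. = FALSE)
  if (!is.finite(fiber_count) || fiber_count < 1)
    stop("fiber_count must be a positive integer", call. = FALSE)
  fiber_count <- as.integer(fiber_count)
  set.seed(as.integer(seed))

  margin <- 30
  center <- canvas_um / 2 + runif(2, -0.04, 0.04) * canvas_um
  lines <- list()
  branch_pts <- matrix(numeric(0), 0, 2)

  # spiral whorl bundle
  whorl_r <- min(300, 0.15 * min(canvas_um))
  if (whorl_turns > 0) {
    for (arm in 0:2) {
      th_max <- 2 * pi * whorl_turns
      th <- seq(0, th_max, length.out = max(40, round(60 * whorl_turns)))
      r <- 8 + (whorl_r - 8) * th / th_max
      phase <- 2 * pi * arm / 3 + runif(1, -0.2, 0.2)
      lines[[length(lines) + 1]] <-
        cbind(center[1] + r * cos(th + phase),
              center[2] + 0.92 * r * sin(th + phase))
    }
  }

  inside <- function(p) all(p >= margin) && p[1] <= canvas_um[1] - margin &&
    p[2] <= canvas_um[2] - margin
  near_whorl <- function(p) sqrt(sum((p - center)^2)) < 0.8 * whorl_r

  # radial fibers: start on an inset rectangle boundary, walk towards whorl
  fibers <- vector("list", fiber_count)
  for (f in seq_len(fiber_count)) {
    # perimeter position
    t <- runif(1)
    w <- canvas_um[1] - 2 * margin; h <- canvas_um[2] - 2 * margin
    per <- 2 * (w + h); s <- t * per
    start <- if (s < w) c(margin + s, margin)
      else if (s < w + h) c(canvas_um[1] - margin, margin + (s - w))
      else if (s < 2 * w + h) c(canvas_um[1] - margin - (s - w - h),
                                canvas_um[2] - margin)
      else c(margin, canvas_um[2] - margin - (s - 2 * w - h))
    target <- center + runif(2, -150, 150)
    fibers[[f]] <- walk_fiber(start, target, step_um = 8, n_max = 1200,
                              heading_sd = 0.045,
                              stop_fun = function(p) !inside(p) ||
                                near_whorl(p))
  }

  # deterministic number of branches placed on random fibers
  n_branch <- floor(0.5 * fiber_count)
  branches <- list()
  if (n_branch > 0) {
    host <- sample.int(fiber_count, n_branch, replace = TRUE)
    for (b in seq_len(n_branch)) {
      fp <- fibers[[host[b]]]
      if (nrow(fp) < 12) next
      i <- sample(seq(round(0.25 * nrow(fp)), round(0.75 * nrow(fp))), 1)
      at <- fp[i, ]
      local_dir <- fp[min(i + 1, nrow(fp)), ] - fp[max(i - 1, 1), ]
      ang <- atan2(local_dir[2], local_dir[1]) +
        sample(c(-1, 1), 1) * runif(1, 0.45, 0.8)
      tgt <- at + 600 * c(cos(ang), sin(ang))
      br <- walk_fiber(at, tgt, step_um = 8,
                       n_max = sample(30:60, 1), heading_sd = 0.05,
                       stop_fun = function(p) !inside(p))
      if (nrow(br) >= 4) {
        branches[[length(branches) + 1]] <- br
        branch_pts <- rbind(branch_pts, at)
      }
    }
  }

  lines <- c(lines, fibers, branches)
  total_mm <- sum(vapply(lines, polyline_length, numeric(1))) / 1000
  crossings <- polyline_crossings(lines)

  img <- render_centerlines(lines, canvas_um, um_per_px, background, peak,
                            profile_sd_px,
                            mottle_sd = mottle_sd,
                            mottle_scale_px = mottle_scale_px,
                            texture_sd = texture_sd,
                            texture_scale_px = texture_scale_px,
                            psf_sigma_px = psf_sigma_px)
  structure(list(image = img, um_per_px = um_per_px, centerlines = lines,
                 branch_points = branch_pts, crossing_points = crossings,
                 whorl_center_um = center,
                 total_length_mm = total_mm, canvas_um = canvas_um,
                 seed = as.integer(seed)),
            class = "sbnp_plexus")
}

#' @export
print.sbnp_plexus <- function(x, ...) {
  cat(sprintf(
    "<sbnp_plexus: %.1f x %.1f mm, %d centerlines, %.2f mm total, %d branch + %d crossing points>\n",
    x$canvas_um[1] / 1000, x$canvas_um[2] / 1000, length(x$centerlines),
    x$total_length_mm, nrow(x$branch_points), nrow(x$crossing_points)))
  invisible(x)
}

# Rasterize centerlines (micrometre polylines) onto the pixel grid and give
# them a Gaussian cross-profile by convolution with a Gaussian kernel.
render_centerlines <- function(lines, canvas_um, um_per_px, background,
                               peak, profile_sd_px, mottle_sd = 7,
                               mottle_scale_px = 20, texture_sd = 5,
                               texture_scale_px = 2.5,
                               psf_sigma_px = 0.8) {
  nr <- round(canvas_um[2] / um_per_px)
  nc <- round(canvas_um[1] / um_per_px)
  mask <- matrix(0, nr, nc)
  for (p in lines) {
    q <- resample_polyline(p / um_per_px, spacing = 0.4)
    rr <- round(q[, 2]) + 1L
    cc <- round(q[, 1]) + 1L
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    mask[cbind(rr[ok], cc[ok])] <- 1
  }
  k <- gaussian_kernel(profile_sd_px)
  resp <- EBImage::filter2(mask, k, boundary = 0)
  # response of an ideal straight pixel line = sum of the kernel centre row
  ref <- sum(k[ceiling(nrow(k) / 2), ])
  bg <- matrix(background, nr, nc)
  if (mottle_sd > 0) {
    # smooth cellular background mottle (uses the generator's RNG stream)
    m <- EBImage::gblur(matrix(rnorm(nr * nc), nr, nc),
                        sigma = mottle_scale_px)
    bg <- bg + m * (mottle_sd / sd(m))
  }
  if (texture_sd > 0) {
    # fine epithelial-cell texture: part of the scene, so overlapping
    # frames observe it identically (up to acquisition noise)
    tx <- EBImage::gblur(matrix(rnorm(nr * nc), nr, nc),
                         sigma = texture_scale_px)
    bg <- bg + tx * (texture_sd / sd(tx))
  }
  img <- bg + (peak - background) * pmin(resp / ref, 1)
  if (psf_sigma_px > 0) img <- EBImage::gblur(img, psf_sigma_px)
  round(clip8(img))
}

#' Serpentine raster scan plan over a plexus canvas
#'
#' Frame centres are laid out on a regular grid covering a centred region of
#' the canvas, visited in serpentine (boustrophedon) order so consecutive
#' frames overlap by `overlap` of the field size.
#'
#' @param canvas_um canvas size (micrometres) or an `sbnp_plexus`.
#' @param grid `c(rows, cols)` of scan tiles.
#' @param overlap fractional overlap between consecutive frames in each
#'   direction (0-1).
#' @param frame_px frame size in pixels (square).
#' @param field_um physical field size in micrometres (square).
#' @return an object of class `scan_plan`: tibble of frame origins plus scan
#'   parameters.
#' @export
scan_plan <- function(canvas_um, grid = c(5, 6), overlap = 0.5,
                      frame_px = 384L, field_um = 400) {
  if (inherits(canvas_um, "sbnp_plexus")) canvas_um <- canvas_um$canvas_um
  stopifnot(length(grid) == 2, overlap >= 0, overlap < 1)
  um_per_px <- field_um / frame_px
  step_um <- field_um * (1 - overlap)
  span <- (rev(grid) - 1) * step_um + field_um      # c(x span, y span)
  origin0 <- (canvas_um - span) / 2                 # top-left of scan region
  rows <- seq_len(grid[1]); cols <- seq_len(grid[2])
  pos <- do.call(rbind, lapply(rows, function(r) {
    cs <- if (r %% 2 == 1) cols else rev(cols)
    cbind(row = r, col = cs)
  }))
  x_um <- origin0[1] + (pos[, "col"] - 1) * step_um
  y_um <- origin0[2] + (pos[, "row"] - 1) * step_um
  # snap nominal origins to the pixel grid: without drift a frame is then
  # an exact pixel crop of the phantom
  x_px <- round(x_um / um_per_px)
  y_px <- round(y_um / um_per_px)
  structure(list(
    frames = tibble::tibble(
      plan_index = seq_len(nrow(pos)),
      tile_row = pos[, "row"], tile_col = pos[, "col"],
      x_um = x_px * um_per_px, y_um = y_px * um_per_px,
      x_px = x_px, y_px = y_px),
    frame_px = as.integer(frame_px), field_um = field_um,
    overlap = overlap, um_per_px = um_per_px, grid = as.integer(grid)),
    class = "scan_plan")
}

#' Smooth per-row motion distortion model
#'
#' Row offsets are Gaussian-filtered white noise, scaled so the largest
#' absolute offset equals `amplitude_px`, emulating the characteristic
#' motion-induced deformation of line-scanning confocal microscopes.
#'
#' @param amplitude_px maximum per-row offset in pixels (0 disables drift).
#' @param smoothness_rows correlation length (Gaussian sigma, in rows) of
#'   the offset path.
#' @param seed optional dedicated seed for the drift stream; when `NULL` the
#'   drift seed is derived from the `sample_frames()` seed.
#' @return an object of class `motion_model`.
#' @export
motion_model <- function(amplitude_px = 3, smoothness_rows = 64,
                         seed = NULL) {
  stopifnot(amplitude_px >= 0, smoothness_rows > 0)
  structure(list(amplitude_px = amplitude_px,
                 smoothness_rows = smoothness_rows, seed = seed),
            class = "motion_model")
}

# Draw one frame's per-row (dx, dy) drift path.
draw_drift <- function(n_rows, motion) {
  if (motion$amplitude_px == 0) return(matrix(0, n_rows, 2))
  d <- vapply(1:2, function(i) {
    v <- smooth_gauss1d(rnorm(n_rows), motion$smoothness_rows)
    v <- v - mean(v)
    m <- max(abs(v))
    if (m > 0) v * motion$amplitude_px / m else v
  }, numeric(n_rows))
  d
}

#' Sample an IVCM frame sequence from a plexus phantom
#'
#' Each SBNP frame is the plexus sampled (bilinearly) at its true per-row
#' positions — the frame's nominal raster position plus the smooth per-row
#' drift — with additive Gaussian noise clipped to the 8-bit range.
#' Non-SBNP frames (epithelium or stroma textures) are interleaved into the
#' acquisition stream at rate `insert_rate`: before emitting each planned
#' SBNP frame, inserts are drawn with probability `insert_rate` each until a
#' draw fails. The returned ground truth records, for every SBNP frame, the
#' exact global position of each image row, sufficient to reproduce the
#' noiseless frame bit-exactly and to compute exact sub-image positions.
#'
#' @param plexus an `sbnp_plexus`.
#' @param plan a `scan_plan`; its scale must match the plexus.
#' @param motion a `motion_model`.
#' @param noise_sd additive Gaussian noise standard deviation (8-bit
#'   intensity units).
#' @param insert_rate probability of a non-SBNP insert at each slot (0-1).
#' @param seed integer seed for noise and insertion draws.
#' @return list with `frames` (list of `ivcm_frame`) and `truth` (class
#'   `sbnp_truth`): a tibble of per-slot labels plus per-frame row-position
#'   matrices and the generating parameters.
#' @export
sample_frames <- function(plexus, plan, motion = motion_model(),
                          noise_sd = 4, insert_rate = 0, seed = 1) {
  stopifnot(inherits(plexus, "sbnp_plexus"), inherits(plan, "scan_plan"))
  if (abs(plan$um_per_px - plexus$um_per_px) > 1e-9)
    stop("scan plan scale does not match plexus scale", call. = FALSE)
  n_plan <- nrow(plan$frames)
  fpx <- plan$frame_px

  # drift paths for every planned frame, from the motion model's own stream
  drift_seed <- if (is.null(motion$seed)) derive_seed(seed, 1L)
                else as.integer(motion$seed)
  set.seed(drift_seed)
  drift <- lapply(seq_len(n_plan), function(f) draw_drift(fpx, motion))

  # footprint check (pre-condition): every sampled coordinate in canvas
  H <- nrow(plexus$image); W <- ncol(plexus$image)
  for (f in seq_len(n_plan)) {
    ox <- plan$frames$x_px[f] + drift[[f]][, 1]
    oy <- plan$frames$y_px[f] + (seq_len(fpx) - 1) + drift[[f]][, 2]
    if (min(ox) < 0 || max(ox) + (fpx - 1) > W - 1 ||
        min(oy) < 0 || max(oy) > H - 1)
      stop(sprintf("frame %d footprint falls outside the plexus canvas", f),
           call. = FALSE)
  }

  # insertion layout (replayable from `seed`)
  set.seed(as.integer(seed))
  labels <- character(0); plan_of <- integer(0)
  if (insert_rate > 0) {
    for (f in seq_len(n_plan)) {
      while (runif(1) < insert_rate) {
        labels <- c(labels, sample(c("epithelium", "stroma"), 1))
        plan_of <- c(plan_of, NA_integer_)
      }
      labels <- c(labels, "sbnp"); plan_of <- c(plan_of, f)
    }
  } else {
    labels <- rep("sbnp", n_plan); plan_of <- seq_len(n_plan)
  }

  n_slots <- length(labels)
  frames <- vector("list", n_slots)
  row_positions <- vector("list", n_slots)
  for (s in seq_len(n_slots)) {
    if (labels[s] == "sbnp") {
      f <- plan_of[s]
      rx <- plan$frames$x_px[f] + drift[[f]][, 1]
      ry <- plan$frames$y_px[f] + (seq_len(fpx) - 1) + drift[[f]][, 2]
      img <- cpp_sample_rows(plexus$image, rx, ry, fpx)
      if (noise_sd > 0) {
        set.seed(derive_seed(seed, 100L + s))
        img <- img + matrix(rnorm(length(img), 0, noise_sd),
                            nrow(img), ncol(img))
      }
      frames[[s]] <- ivcm_frame(round(clip8(img)), index = s,
                                um_per_px = plan$um_per_px, label = "sbnp")
      row_positions[[s]] <- cbind(x = rx, y = ry)
    } else {
      frames[[s]] <- make_nonsbnp_frame(labels[s], frame_px = fpx,
                                        seed = derive_seed(seed, 10000L + s))
      frames[[s]]$index <- s
    }
  }

  truth <- structure(list(
    frames = tibble::tibble(slot = seq_len(n_slots), label = labels,
                            plan_index = plan_of),
    row_positions = row_positions, drift = drift, plan = plan,
    motion = motion, noise_sd = noise_sd, insert_rate = insert_rate,
    seed = as.integer(seed), drift_seed = drift_seed),
    class = "sbnp_truth")
  list(frames = frames, truth = truth)
}

#' Synthetic non-SBNP (epithelium / stroma) frame
#'
#' Epithelium frames show a dense bright cellular tessellation with darker
#' cell boundaries; stroma frames show sparse bright keratocyte-like blobs
#' on a dark background. The two textures differ by construction in
#' bright-pixel fraction and granularity, which is what the tissue filter's
#' descriptors measure.
#'
#' @param kind `"epithelium"` or `"stroma"`.
#' @param frame_px frame size in pixels (square).
#' @param seed integer seed.
#' @return an `ivcm_frame` with the true label set.
#' @export
make_nonsbnp_frame <- function(kind, frame_px = 384L, seed = 1) {
  if (!is.character(kind) || length(kind) != 1 ||
      !kind %in% c("epithelium", "stroma"))
    stop("kind must be \"epithelium\" or \"stroma\"", call. = FALSE)
  set.seed(as.integer(seed))
  n <- as.integer(frame_px)
  if (kind == "epithelium") {
    v <- matrix(rnorm(n * n), n, n)
    v <- EBImage::gblur(v, sigma = 4)
    vn <- matrix(rank(v) / length(v), n, n)        # rank-normalize to [0,1]
    gx <- cbind(v[, -1] - v[, -ncol(v)], 0)
    gy <- rbind(v[-1, ] - v[-nrow(v), ], 0)
    g <- sqrt(gx^2 + gy^2)
    gn <- g / max(g)
    img <- 110 + 110 * vn - 90 * gn + matrix(rnorm(n * n, 0, 3), n, n)
  } else {
    img <- matrix(25 + rnorm(n * n, 0, 4), n, n)
    k <- gaussian_kernel(2)
    kr <- (nrow(k) - 1) / 2
    n_blob <- 40
    pos <- cbind(sample.int(n - 2 * kr, n_blob) + kr,
                 sample.int(n - 2 * kr, n_blob) + kr)
    amp <- 165 / max(k)
    for (b in seq_len(n_blob)) {
      rr <- (pos[b, 1] - kr):(pos[b, 1] + kr)
      cc <- (pos[b, 2] - kr):(pos[b, 2] + kr)
      img[rr, cc] <- img[rr, cc] + amp * k
    }
  }
  ivcm_frame(round(clip8(img)), index = 1L, label = kind)
}

# Intersection points between segments of different polylines (micrometre
# coordinates), found with a uniform grid hash; duplicate hits closer
# than 3 um merge into one point.
polyline_crossings <- function(lines, cell_um = 25, merge_um = 3) {
  segs <- do.call(rbind, lapply(seq_along(lines), function(i) {
    p <- lines[[i]]
    if (nrow(p) < 2) return(NULL)
    cbind(i, p[-nrow(p), 1], p[-nrow(p), 2], p[-1, 1], p[-1, 2])
  }))
  if (is.null(segs) || nrow(segs) < 2) return(matrix(numeric(0), 0, 2))
  cx <- floor((segs[, 2] + segs[, 4]) / 2 / cell_um)
  cy <- floor((segs[, 3] + segs[, 5]) / 2 / cell_um)
  key <- paste(cx, cy)
  pts <- list()
  for (cells in split(seq_len(nrow(segs)), key)) {
    if (length(cells) < 2) next
    for (a in seq_len(length(cells) - 1)) {
      for (b in (a + 1):length(cells)) {
        s1 <- segs[cells[a], ]; s2 <- segs[cells[b], ]
        if (s1[1] == s2[1]) next
        hit <- segment_intersection(s1[2:3], s1[4:5], s2[2:3], s2[4:5])
        if (!is.null(hit)) pts[[length(pts) + 1]] <- hit
      }
    }
  }
  if (!length(pts)) return(matrix(numeric(0), 0, 2))
  m <- do.call(rbind, pts)
  # merge near-duplicates (consecutive segments crossing the same line)
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    if (!keep[i]) next
    d <- sqrt((m[, 1] - m[i, 1])^2 + (m[, 2] - m[i, 2])^2)
    dup <- which(d < merge_um & seq_len(nrow(m)) > i)
    keep[dup] <- FALSE
  }
  m[keep, , drop = FALSE]
}

# intersection point of segments p1-p2 and q1-q2, or NULL
segment_intersection <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-12) return(NULL)
  t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
  if (t < 0 || t > 1 || u < 0 || u > 1) return(NULL)
  p1 + t * d1
}

#' Total centerline length inside a circular (or half-circular) region
#'
#' Ground-truth bookkeeping oracle: clips every centerline polyline of a
#' plexus against a disc (optionally its superior half) by exact
#' line-circle intersection and sums the inside portions.
#'
#' @param plexus an `sbnp_plexus`.
#' @param center_um circle centre, micrometres.
#' @param radius_um circle radius, micrometres.
#' @param half `"full"` or `"superior"` (rows above or at the centre row).
#' @return length in millimetres.
#' @export
plexus_length_in_disc <- function(plexus, center_um, radius_um,
                                  half = c("full", "superior")) {
  half <- match.arg(half)
  sum(vapply(plexus$centerlines, function(p)
    clipped_polyline_length(p, center_um, radius_um, half), numeric(1))) /
    1000
}

#' Write a synthetic eye folder of TIFF frames with ground-truth sidecars
#'
#' Writes numbered 8-bit grayscale TIFFs (`frame_001.tif`, ...) plus, when
#' ground truth is given, `frames.csv` (slot, label, plan index) and
#' `row_positions.csv` (slot, row, x, y in global pixel coordinates).
#'
#' @param frames list of `ivcm_frame`.
#' @param dir output directory (created if missing).
#' @param truth optional `sbnp_truth`.
#' @return `dir`, invisibly.
#' @export
write_eye_folder <- function(frames, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    tiff::writeTIFF(frames[[i]]$image / 255,
                    file.path(dir, sprintf("frame_%03d.tif", i)),
                    bits.per.sample = 8L, compression = "none")
  }
  if (!is.null(truth)) {
    write.csv(as.data.frame(truth$frames),
              file.path(dir, "frames.csv"), row.names = FALSE)
    rp <- do.call(rbind, lapply(seq_along(truth$row_positions), function(s) {
      m <- truth$row_positions[[s]]
      if (is.null(m)) return(NULL)
      data.frame(slot = s, row = seq_len(nrow(m)), x = m[, 1], y = m[, 2])
    }))
    write.csv(rp, file.path(dir, "row_positions.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read an eye folder of numbered TIFF frames
#'
#' @param dir folder containing `*.tif`/`*.tiff` files (read in sorted
#'   order); an optional `frames.csv` sidecar supplies true labels.
#' @param um_per_px physical scale to attach to each frame.
#' @return list of `ivcm_frame`.
#' @export
read_eye_folder <- function(dir, um_per_px = ivcm_um_per_px()) {
  files <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
  if (length(files) == 0)
    stop(sprintf("no TIFF frames found in %s", dir), call. = FALSE)
  labels <- rep(NA_character_, length(files))
  sc <- file.path(dir, "frames.csv")
  if (file.exists(sc)) {
    tab <- read.csv(sc)
    labels[tab$slot] <- tab$label
  }
  lapply(seq_along(files), function(i) {
    img <- tiff::readTIFF(files[i])
    if (length(dim(img)) == 3) img <- img[, , 1]
    ivcm_frame(round(img * 255), index = i, um_per_px = um_per_px,
               label = labels[i])
  })
}
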