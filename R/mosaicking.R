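# Mosaicking: 12-slice sub-image decomposition, pairwise correlation-based
# registration, regularized sparse least-squares global alignment, and
# feathered weighted-average rendering.
#
# Global positions p_i are 0-based pixel coordinates (x, y) of each
# sub-image's top-left pixel on a common canvas; d_ij = p_j - p_i.

#' Decompose a frame into horizontal sub-image slices
#'
#' The slices partition the frame's rows exactly: contiguous,
#' non-overlapping, top-to-bottom. When the row count is not divisible by
#' `n_slices`, the first `rows %% n_slices` slices receive one extra row.
#'
#' @param frame an `ivcm_frame` or a numeric matrix.
#' @param n_slices number of slices (default 12).
#' @return tibble with one row per slice: `slice`, `row_start`, `row_end`
#'   (0-based, half-open `[row_start, row_end)`).
#' @examples
#' decompose_frame(matrix(0, 384, 384))   # twelve 32-row slices
#' @export
decompose_frame <- function(frame, n_slices = 12L) {
  img <- if (inherits(frame, "ivcm_frame")) frame$image else frame
  assert_image(img, "frame")
  n_slices <- as.integer(n_slices)
  nr <- nrow(img)
  if (nr < n_slices)
    stop(sprintf("frame has %d rows; at least %d required", nr, n_slices),
         call. = FALSE)
  base <- nr %/% n_slices
  rem <- nr %% n_slices
  heights <- rep(base, n_slices) + c(rep(1L, rem), rep(0L, n_slices - rem))
  ends <- cumsum(heights)
  tibble::tibble(slice = seq_len(n_slices),
                 row_start = c(0L, ends[-n_slices]),
                 row_end = as.integer(ends))
}

# slice image rows of `img` for slice row range [r0, r1) (0-based)
slice_image <- function(img, r0, r1) img[(r0 + 1):r1, , drop = FALSE]

#' Pairwise registration of an SBNP frame sequence
#'
#' Full-frame phase correlation (at `scale_full`) is computed for all
#' unordered frame pairs; because the correlation is cyclic, the coarse
#' estimate is disambiguated among its cyclic representatives by the
#' normalized cross-correlation (NCC) of the actually overlapping pixels.
#' For pairs whose estimate implies at least `overlap_gate` fractional
#' area overlap and at least `ncc_gate` overlap correlation, the
#' individual sub-image slices with plausibly overlapping footprints are
#' registered at `scale_sub`, unwrapping the cyclic slice estimate to the
#' value nearest the coarse prediction and optionally refining it by a
#' +/- `scale_sub` px NCC search at full resolution. Sub-image offsets
#' deviating from the frame-level prediction by more than `slice_dev_px`
#' are discarded: the sub-images measure small row-wise motion
#' distortion, and a large deviation means the correlation locked onto a
#' different, similar-looking structure. Each registration's reported
#' `score` is the overlap NCC of the clamped high-pass residuals
#' (`hp_sigma`) at the final offset: smooth background correlates between
#' unrelated regions and bright fibers repeat across the plexus, so
#' scoring the bounded fine structure separates true from false matches
#' far more sharply than either the raw correlation peak height or the
#' plain-intensity NCC. Each unordered pair is computed once; registering
#' (j, i) is the negation of (i, j).
#'
#' @param frames list of `ivcm_frame` (or matrices), all the same size.
#' @param config an [alignment_config()].
#' @return tibble of sub-image pair registrations: global sub-image indices
#'   `i`, `j` (1-based, frame-major), their frame/slice coordinates, the
#'   translation `dx`, `dy` (`d_ij = p_j - p_i`, px) and correlation
#'   `score`. Attribute `full_pairs` holds the frame-level estimates.
#' @export
register_pairs <- function(frames, config = alignment_config()) {
  imgs <- lapply(frames, function(f)
    if (inherits(f, "ivcm_frame")) f$image else f)
  n <- length(imgs)
  if (n < 2) {
    warning("fewer than 2 frames; nothing to register")
    return(empty_pair_tbl())
  }
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("all frames must have identical dimensions", call. = FALSE)
  H <- dims[1, 1]; W <- dims[2, 1]
  slices <- decompose_frame(imgs[[1]], config$n_slices)
  ns <- nrow(slices)

  # clamped high-pass residuals for scoring, and downscaled copies for
  # cheap candidate evaluation
  hp <- lapply(imgs, function(x) clamp_hp(x, config$hp_sigma))
  ds <- lapply(imgs, downscale_block, factor = config$scale_full)
  full <- list(); k <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      pc <- phase_correlation(imgs[[a]], imgs[[b]], config$scale_full)
      d <- -pc$shift                     # d = p_b - p_a, c(dy, dx)
      # cyclic disambiguation: test all representatives by overlap NCC at
      # the downscaled resolution
      best <- disambiguate_shift(ds[[a]], ds[[b]], d / config$scale_full,
                                 c(H, W) %/% config$scale_full,
                                 min_px = 1500)
      d <- best$d * config$scale_full
      ov <- max(0, H - abs(d[1])) * max(0, W - abs(d[2])) / (H * W)
      # verification score: clamped high-pass NCC at full resolution
      ncc <- if (ov >= config$overlap_gate)
        overlap_ncc(hp[[a]], hp[[b]], d, min_px = 10000) else NA_real_
      k <- k + 1
      full[[k]] <- data.frame(frame_i = a, frame_j = b, dy = d[1],
                              dx = d[2], peak = pc$score, ncc = ncc,
                              overlap = ov)
    }
  }
  full <- do.call(rbind, full)

  out <- list(); k <- 0
  gated <- full[full$overlap >= config$overlap_gate &
                  !is.na(full$ncc) & full$ncc >= config$ncc_gate, ,
                drop = FALSE]
  for (g in seq_len(nrow(gated))) {
    a <- gated$frame_i[g]; b <- gated$frame_j[g]
    d_frame <- c(gated$dy[g], gated$dx[g])
    for (si in seq_len(ns)) {
      for (sj in seq_len(ns)) {
        # predicted d between slice origins
        d_pred <- d_frame + c(slices$row_start[sj] - slices$row_start[si], 0)
        hi <- slices$row_end[si] - slices$row_start[si]
        hj <- slices$row_end[sj] - slices$row_start[sj]
        h <- min(hi, hj)
        if (abs(d_pred[1]) >= h || abs(d_pred[2]) >= 0.85 * W) next
        A <- slice_image(imgs[[a]], slices$row_start[si],
                         slices$row_start[si] + h)
        B <- slice_image(imgs[[b]], slices$row_start[sj],
                         slices$row_start[sj] + h)
        Ah <- slice_image(hp[[a]], slices$row_start[si],
                          slices$row_start[si] + h)
        Bh <- slice_image(hp[[b]], slices$row_start[sj],
                          slices$row_start[sj] + h)
        pc <- phase_correlation(A, B, config$scale_sub)
        d_meas <- -pc$shift
        # unwrap cyclic estimate towards the prediction; the effective
        # period is the downscale-cropped extent at full resolution
        per <- if (config$scale_sub > 1)
          (c(h, W) %/% config$scale_sub) * config$scale_sub else c(h, W)
        d_meas <- d_meas + round((d_pred - d_meas) / per) * per
        # physical plausibility: sub-image offsets measure small row-wise
        # drift around the frame offset
        if (any(abs(d_meas - d_pred) > config$slice_dev_px)) next
        score <- overlap_ncc(Ah, Bh, d_meas, min_px = 3000)
        if (is.na(score)) score <- 0
        sharp <- NA_real_
        if (config$refine && config$scale_sub > 1 &&
            score >= config$tau / 2) {
          ref <- refine_offset(Ah, Bh, d_meas, config$refine_radius_px)
          d_meas <- ref$d
          score <- max(score, ref$ncc, na.rm = TRUE)
          sharp <- ref$sharp
        }
        k <- k + 1
        out[[k]] <- data.frame(
          frame_i = a, slice_i = si, frame_j = b, slice_j = sj,
          dy = d_meas[1], dx = d_meas[2], score = score, sharp = sharp)
      }
    }
  }
  res <- if (k > 0) do.call(rbind, out) else
    data.frame(frame_i = integer(0), slice_i = integer(0),
               frame_j = integer(0), slice_j = integer(0),
               dy = numeric(0), dx = numeric(0), score = numeric(0),
               sharp = numeric(0))
  res$i <- (res$frame_i - 1L) * ns + res$slice_i
  res$j <- (res$frame_j - 1L) * ns + res$slice_j
  res <- tibble::as_tibble(res[, c("i", "j", "frame_i", "slice_i",
                                   "frame_j", "slice_j", "dx", "dy",
                                   "score", "sharp")])
  attr(res, "full_pairs") <- tibble::as_tibble(full)
  attr(res, "n_frames") <- n
  attr(res, "n_slices") <- ns
  attr(res, "slices") <- slices
  res
}

# high-pass residual with robust clamping: removes smooth background and
# bounds the influence of isolated bright structures
clamp_hp <- function(img, sigma) {
  h <- img - EBImage::gblur(img, sigma)
  cl <- 3 * stats::mad(h)
  if (cl > 0) pmin(pmax(h, -cl), cl) else h
}

empty_pair_tbl <- function() {
  tibble::tibble(i = integer(0), j = integer(0), frame_i = integer(0),
                 slice_i = integer(0), frame_j = integer(0),
                 slice_j = integer(0), dx = numeric(0), dy = numeric(0),
                 score = numeric(0))
}

# local NCC search around an integer offset estimate (high-pass inputs),
# followed by a 3-point parabolic sub-pixel interpolation of the NCC
# optimum along each axis
refine_offset <- function(A, B, d, radius, min_px = 3000) {
  grid <- matrix(NA_real_, 2 * radius + 1, 2 * radius + 1)
  best <- c(0, 0); best_s <- -Inf
  for (ddy in -radius:radius) {
    for (ddx in -radius:radius) {
      s <- overlap_ncc(A, B, d + c(ddy, ddx), min_px = min_px)
      grid[ddy + radius + 1, ddx + radius + 1] <- s
      if (!is.na(s) && s > best_s) { best_s <- s; best <- c(ddy, ddx) }
    }
  }
  if (!is.finite(best_s))
    return(list(d = d, ncc = NA_real_, sharp = NA_real_))
  # worst-direction sharpness: drop of the NCC 2 px away from the optimum
  ring <- c()
  gi0 <- best + radius + 1
  for (ddy in -2:2) {
    for (ddx in -2:2) {
      if (max(abs(ddy), abs(ddx)) != 2) next
      r <- gi0[1] + ddy; c <- gi0[2] + ddx
      if (r >= 1 && r <= nrow(grid) && c >= 1 && c <= ncol(grid))
        ring <- c(ring, grid[r, c])
    }
  }
  sharp <- if (length(ring) && any(!is.na(ring)))
    best_s - max(ring, na.rm = TRUE) else NA_real_
  # sub-pixel optimum from a least-squares quadratic surface over the
  # whole grid; falls back to the integer optimum when the fitted surface
  # is not concave or its optimum leaves the search window
  sub <- c(0, 0)
  off <- seq(-radius, radius)
  ys <- rep(off, 2 * radius + 1)
  xs <- rep(off, each = 2 * radius + 1)
  z <- as.vector(grid)
  ok <- !is.na(z)
  if (sum(ok) >= 8) {
    X <- cbind(1, ys, xs, ys^2, xs^2, ys * xs)[ok, , drop = FALSE]
    fit <- tryCatch(qr.solve(X, z[ok]), error = function(e) NULL)
    if (!is.null(fit)) {
      Hm <- matrix(c(2 * fit[4], fit[6], fit[6], 2 * fit[5]), 2)
      ev <- eigen(Hm, only.values = TRUE)$values
      if (all(ev < 0)) {
        opt <- -solve(Hm, fit[2:3])          # (dy, dx)
        if (all(abs(opt) <= radius + 0.5)) sub <- opt - best
      }
    }
  }
  list(d = d + best + sub, ncc = best_s, sharp = sharp)
}

# choose among cyclic representatives d + k*period the one with the best
# overlap NCC (evaluated at the given, typically downscaled, resolution)
disambiguate_shift <- function(a, b, d, period, min_px = 32) {
  cands <- list()
  for (ky in -1:1) {
    for (kx in -1:1) {
      cand <- d + c(ky * period[1], kx * period[2])
      if (abs(cand[1]) < period[1] && abs(cand[2]) < period[2])
        cands[[length(cands) + 1]] <- cand
    }
  }
  best <- d; best_s <- NA_real_
  for (cand in cands) {
    s <- overlap_ncc(a, b, cand, min_px = min_px)
    if (!is.na(s) && (is.na(best_s) || s > best_s)) {
      best_s <- s; best <- cand
    }
  }
  list(d = best, ncc = best_s)
}

#' Build the regularized global-alignment linear system
#'
#' One equation per accepted sub-image registration, `p_j - p_i = d_ij`,
#' plus one absolute anchor `lambda1 * p_0 = 0` that removes the
#' translational degree of freedom, plus intra-frame smoothness equations
#' `lambda2 * (p_{i+1} - p_i) = 0` between consecutive sub-images of the
#' same frame. The x and y coordinates share the same system matrix and are
#' solved independently.
#'
#' @param pairs tibble of accepted registrations (columns `i`, `j`, `dx`,
#'   `dy`); pre-filter by score >= tau before calling.
#' @param n_sub total number of sub-images.
#' @param frame_of integer vector, frame membership of each sub-image.
#' @param config an [alignment_config()].
#' @param anchor sub-image index anchored at the origin (default 1).
#' @return list with sparse `A` and right-hand sides `bx`, `by`.
#' @export
build_system <- function(pairs, n_sub, frame_of,
                         config = alignment_config(), anchor = 1L) {
  if (n_sub <= 0) stop("no sub-images to align", call. = FALSE)
  np <- nrow(pairs)
  smooth_idx <- which(frame_of[-n_sub] == frame_of[-1])
  if (!config$smooth_all && np > 0) {
    reg <- unique(c(pairs$i, pairs$j))
    smooth_idx <- smooth_idx[!(smooth_idx %in% reg &
                                 (smooth_idx + 1L) %in% reg)]
  }
  nsm <- length(smooth_idx)
  nrows <- np + 1L + nsm

  ii <- c(seq_len(np), seq_len(np),                 # pair rows
          np + 1L,                                  # anchor row
          np + 1L + seq_len(nsm), np + 1L + seq_len(nsm))
  jj <- c(pairs$j, pairs$i, anchor, smooth_idx + 1L, smooth_idx)
  xx <- c(rep(1, np), rep(-1, np), config$lambda1,
          rep(config$lambda2, nsm), rep(-config$lambda2, nsm))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrows, n_sub))
  bx <- c(pairs$dx, 0, rep(0, nsm))
  by <- c(pairs$dy, 0, rep(0, nsm))
  list(A = A, bx = bx, by = by, n_pairs = np, anchor = anchor)
}

# least-squares solve of one coordinate via sparse normal equations
solve_ls <- function(A, b, w = NULL) {
  if (!is.null(w)) {
    A <- A * w          # row scaling (w recycled per column is wrong; use Diagonal)
  }
  AtA <- Matrix::crossprod(A)
  Atb <- Matrix::crossprod(A, b)
  as.numeric(Matrix::solve(AtA, Atb))
}

# robust (Huber IRLS) simultaneous x/y solve of one component's system;
# weights act on the pair rows only (starting from the supplied
# confidence weights), the anchor and smoothness rows keep weight 1.
# Returns the solution and the final per-pair residual norms.
solve_robust <- function(sys, n_pairs, conf = NULL, huber_px = 4,
                         iters = 3) {
  w <- rep(1, nrow(sys$A))
  if (!is.null(conf) && n_pairs > 0) w[seq_len(n_pairs)] <- conf
  for (it in seq_len(max(1, iters))) {
    W <- Matrix::Diagonal(x = w)
    sx <- solve_ls(W %*% sys$A, w * sys$bx)
    sy <- solve_ls(W %*% sys$A, w * sys$by)
    if (n_pairs == 0) break
    rx <- as.numeric(sys$A %*% sx) - sys$bx
    ry <- as.numeric(sys$A %*% sy) - sys$by
    res <- sqrt(rx^2 + ry^2)[seq_len(n_pairs)]
    w_new <- pmin(1, huber_px / pmax(res, 1e-9))
    if (!is.null(conf)) w_new <- w_new * conf
    if (it < iters) w[seq_len(n_pairs)] <- w_new
  }
  pair_res <- if (n_pairs > 0)
    sqrt((as.numeric(sys$A %*% sx) - sys$bx)^2 +
           (as.numeric(sys$A %*% sy) - sys$by)^2)[seq_len(n_pairs)]
  else numeric(0)
  list(sx = sx, sy = sy, pair_res = pair_res)
}

#' Solve the global alignment for a registered frame sequence
#'
#' Accepts the sub-image pair registrations, discards those with
#' correlation below `config$tau`, identifies connected components of the
#' registration graph (accepted pairs plus intra-frame consecutive-slice
#' edges, so a frame always stays in one piece), and solves the regularized
#' least-squares system of [build_system()] per component and coordinate.
#'
#' The unknowns are frame-anchored sub-image positions: each slice's
#' estimate of its parent frame's origin, i.e. the slice origin minus its
#' nominal in-frame row offset. Measured translations are reduced by the
#' nominal offsets before entering the system, so the intra-frame
#' smoothness equations `lambda2 * (p_{i+1} - p_i) = 0` express "no motion
#' distortion between consecutive slices" and supply alignment information
#' for slices without accepted registrations. The reported positions are
#' the actual slice origins (nominal offsets added back).
#'
#' @param pairs output of [register_pairs()].
#' @param config an [alignment_config()].
#' @return an `alignment_solution`: tibble with one row per sub-image
#'   (`sub`, `frame`, `slice`, `px`, `py`, `component`), plus attributes
#'   `residual_norm`, `n_accepted`, `n_components`.
#' @export
solve_alignment <- function(pairs, config = alignment_config()) {
  n_frames <- attr(pairs, "n_frames")
  ns <- attr(pairs, "n_slices")
  slices <- attr(pairs, "slices")
  if (is.null(n_frames))
    stop("pairs must come from register_pairs()", call. = FALSE)
  n_sub <- n_frames * ns
  frame_of <- rep(seq_len(n_frames), each = ns)
  slice_of <- rep(seq_len(ns), n_frames)
  acc <- pairs[pairs$score >= config$tau, , drop = FALSE]
  # frame-anchored parametrization: subtract nominal in-frame offsets
  acc$dy <- acc$dy - (slices$row_start[acc$slice_j] -
                        slices$row_start[acc$slice_i])

  intra <- cbind(seq_len(n_sub - 1), seq_len(n_sub)[-1])
  intra <- intra[frame_of[intra[, 1]] == frame_of[intra[, 2]], ,
                 drop = FALSE]

  for (iter in 0:config$reject_iters) {
    # component graph: accepted pairs + intra-frame chain edges
    edges <- rbind(cbind(acc$i, acc$j), intra)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n_sub - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_len(n_sub)]
    # relabel components by first member for determinism
    comp <- match(comp, unique(comp))

    px <- numeric(n_sub); py <- numeric(n_sub)
    resid2 <- 0
    acc$res <- NA_real_
    for (cid in sort(unique(comp))) {
      members <- which(comp == cid)
      local <- match(seq_len(n_sub), members)    # global -> local index
      in_comp <- acc$i %in% members & acc$j %in% members
      lp <- acc[in_comp, , drop = FALSE]
      lp$i <- local[lp$i]; lp$j <- local[lp$j]
      sys <- build_system(lp, length(members), frame_of[members], config,
                          anchor = 1L)
      conf <- pmax(0.15, (lp$score - config$tau) / (1 - config$tau)) *
        pmin(1, ifelse(is.na(lp$sharp), 1, lp$sharp) / config$sharp_soft)
      rob <- solve_robust(sys, nrow(lp), conf = conf)
      px[members] <- rob$sx
      py[members] <- rob$sy
      acc$res[in_comp] <- rob$pair_res
      resid2 <- resid2 +
        sum((as.numeric(sys$A %*% rob$sx) - sys$bx)^2) +
        sum((as.numeric(sys$A %*% rob$sy) - sys$by)^2)
    }

    if (iter == config$reject_iters || nrow(acc) == 0) break
    # residual-based outlier rejection of accepted registrations (the
    # robust solve keeps the solution near the consensus, so only truly
    # inconsistent registrations show large residuals)
    if (!any(acc$res > config$reject_px)) break
    acc <- acc[acc$res <= config$reject_px, , drop = FALSE]
  }

  # back to absolute slice origins
  py <- py + slices$row_start[slice_of]
  sol <- tibble::tibble(sub = seq_len(n_sub), frame = frame_of,
                        slice = slice_of,
                        px = px, py = py, component = comp)
  attr(sol, "residual_norm") <- sqrt(resid2)
  attr(sol, "n_accepted") <- nrow(acc)
  attr(sol, "n_components") <- length(unique(comp))
  attr(sol, "slices") <- slices
  class(sol) <- c("alignment_solution", class(sol))
  sol
}

#' Render a mosaic from aligned frames
#'
#' Row positions are linearly interpolated between the sub-image anchor
#' positions (each slice's position placed at its centre row; rows above
#' the first and below the last anchor extrapolate with the nearest
#' segment's slope). Every mosaic pixel gathers, from each frame covering
#' it, the bilinear sample of the frame at the exact inverse position, and
#' overlaps are combined by normalized weighted averaging with a
#' feathering weight equal to each pixel's distance to its frame's nearest
#' edge raised to `feather_power` (higher powers favour frame interiors,
#' reducing ghosting at small residual misalignments). Pixels that
#' received no data are invalid and rendered black.
#'
#' @param frames the frame list given to [register_pairs()].
#' @param solution an `alignment_solution`.
#' @param component which connected component to render (default 1).
#' @param um_per_px physical scale; taken from the first `ivcm_frame` if
#'   available.
#' @return an `sbnp_mosaic`: list with `image` (numeric matrix, 0-255),
#'   `mask` (logical validity matrix), `um_per_px`, `origin_px` (global
#'   coordinates of pixel [1,1]), `n_frames`, `component`.
#' @export
render_mosaic <- function(frames, solution, component = 1L,
                          um_per_px = NULL, feather_power = 2) {
  imgs <- lapply(frames, function(f)
    if (inherits(f, "ivcm_frame")) f$image else f)
  if (is.null(um_per_px)) {
    um_per_px <- if (inherits(frames[[1]], "ivcm_frame"))
      frames[[1]]$um_per_px else ivcm_um_per_px()
  }
  slices <- attr(solution, "slices")
  sel <- solution[solution$component == component, , drop = FALSE]
  if (nrow(sel) == 0) stop("component is empty", call. = FALSE)
  fr_ids <- unique(sel$frame)
  H <- nrow(imgs[[fr_ids[1]]]); W <- ncol(imgs[[fr_ids[1]]])

  # per-frame row positions by interpolation between slice anchors
  rowpos <- lapply(fr_ids, function(f) {
    s <- sel[sel$frame == f, , drop = FALSE]
    s <- s[order(s$slice), , drop = FALSE]
    centers <- (slices$row_start[s$slice] + slices$row_end[s$slice] - 1) / 2
    # global position of each slice's centre row
    ax <- s$px
    ay <- s$py + (centers - slices$row_start[s$slice])
    r <- seq_len(H) - 1
    list(x = interp_extrap(centers, ax, r),
         y = interp_extrap(centers, ay, r))
  })

  all_x <- unlist(lapply(rowpos, `[[`, "x"))
  all_y <- unlist(lapply(rowpos, `[[`, "y"))
  x0 <- floor(min(all_x)); x1 <- ceiling(max(all_x) + W - 1)
  y0 <- floor(min(all_y)); y1 <- ceiling(max(all_y))
  CW <- x1 - x0 + 2L; CH <- y1 - y0 + 2L
  acc <- matrix(0, CH, CW); wacc <- matrix(0, CH, CW)
  wmat <- feather_weights(H, W)^feather_power
  for (k in seq_along(fr_ids)) {
    cpp_gather_frame(acc, wacc, imgs[[fr_ids[k]]], wmat,
                     rowpos[[k]]$x - x0, rowpos[[k]]$y - y0)
  }
  eps <- 1e-9
  mask <- wacc > eps
  img <- matrix(0, CH, CW)
  img[mask] <- acc[mask] / wacc[mask]

  # tight crop to the validity bounding box
  rs <- range(which(rowSums(mask) > 0)); cs <- range(which(colSums(mask) > 0))
  img <- img[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE]
  mask <- mask[rs[1]:rs[2], cs[1]:cs[2], drop = FALSE]
  img[!mask] <- 0
  structure(list(image = img, mask = mask, um_per_px = um_per_px,
                 origin_px = c(x = x0 + cs[1] - 1, y = y0 + rs[1] - 1),
                 n_frames = length(fr_ids), component = component),
            class = "sbnp_mosaic")
}

interp_extrap <- function(x, y, xout) {
  if (length(x) == 1) return(rep(y, length(xout)))
  res <- stats::approx(x, y, xout = xout, rule = 2)$y
  # linear extrapolation with nearest segment's slope
  lo <- xout < x[1]; hi <- xout > x[length(x)]
  if (any(lo)) {
    sl <- (y[2] - y[1]) / (x[2] - x[1])
    res[lo] <- y[1] + sl * (xout[lo] - x[1])
  }
  if (any(hi)) {
    n <- length(x)
    sl <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    res[hi] <- y[n] + sl * (xout[hi] - x[n])
  }
  res
}

# feathering weight: normalized distance to the nearest frame edge
feather_weights <- function(H, W) {
  dr <- pmin(seq_len(H), rev(seq_len(H)))
  dc <- pmin(seq_len(W), rev(seq_len(W)))
  w <- outer(dr, dc, pmin)
  w / max(w)
}

#' @export
print.sbnp_mosaic <- function(x, ...) {
  cat(sprintf(
    "<sbnp_mosaic: %d x %d px, %.2f mm2 valid, %d frames, component %d>\n",
    nrow(x$image), ncol(x$image), mosaic_area(x), x$n_frames, x$component))
  invisible(x)
}

#' Render all components and pick the largest mosaic
#'
#' Components are ranked by valid-mask area (mm^2); ties are broken by frame
#' count, then by lowest component id. Frames that could not be integrated
#' into the largest mosaic still form the smaller, secondary mosaics.
#'
#' @param frames the frame list given to [register_pairs()].
#' @param solution an `alignment_solution`.
#' @param um_per_px physical scale override.
#' @return list with `largest` (an `sbnp_mosaic`) and `others` (list of the
#'   remaining mosaics in rank order).
#' @export
largest_mosaic <- function(frames, solution, um_per_px = NULL) {
  comps <- sort(unique(solution$component))
  mosaics <- lapply(comps, function(cid)
    render_mosaic(frames, solution, cid, um_per_px))
  area <- vapply(mosaics, mosaic_area, numeric(1))
  nfr <- vapply(mosaics, function(m) m$n_frames, numeric(1))
  ord <- order(-area, -nfr, comps)
  list(largest = mosaics[[ord[1]]],
       others = mosaics[ord[-1]])
}
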