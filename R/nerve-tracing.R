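# Automated nerve fiber tracing on SBNP mosaics: top-hat background
# equalization, log-Gabor line enhancement, pixel classification,
# skeletonization with spur pruning, and Dijkstra-based gap bridging.
#
# Graph coordinates are mosaic-local: pixel (x, y) 0-based as elsewhere;
# micrometre coordinates are px * um_per_px.

#' Enhance nerve-like structures in a mosaic
#'
#' White top-hat filtering (disc structuring element) equalizes the
#' background and isolates bright structures; a bank of log-Gabor filters
#' over several orientations and centre wavelengths then highlights linear
#' structures. The response is the maximum filter magnitude over the bank
#' (with the winning orientation in the `orientation` attribute); invalid
#' mosaic pixels carry response 0.
#'
#' @param mosaic an `sbnp_mosaic` (or plain matrix, treated as fully valid).
#' @param config a [tracer_config()].
#' @return numeric matrix of non-negative responses, same size as the
#'   mosaic.
#' @export
enhance <- function(mosaic, config = tracer_config()) {
  m <- as_mosaic(mosaic)
  if (!any(m$mask)) stop("mosaic validity mask is empty", call. = FALSE)
  img <- m$image / 255
  # neutralize invalid area so mosaic borders do not ring
  img[!m$mask] <- stats::median(img[m$mask])
  brush <- EBImage::makeBrush(2L * config$tophat_radius_px + 1L,
                              shape = "disc")
  th <- EBImage::whiteTopHat(img, brush)
  resp <- log_gabor_response(th, config$gabor_orientations,
                             config$gabor_wavelengths_px,
                             config$gabor_sigma_ratio)
  ori <- attr(resp, "orientation")
  resp[!m$mask] <- 0
  attr(resp, "orientation") <- ori
  resp
}

as_mosaic <- function(x) {
  if (inherits(x, "sbnp_mosaic")) return(x)
  assert_image(x, "mosaic")
  structure(list(image = x, mask = matrix(TRUE, nrow(x), ncol(x)),
                 um_per_px = ivcm_um_per_px(), origin_px = c(x = 0, y = 0),
                 n_frames = 1L, component = 1L), class = "sbnp_mosaic")
}

# candidate threshold on quantile-normalized responses: a fixed number in
# (0, 1) (the default; line responses are commensurate across top-hat
# equalized images), "robust" = median + 6 MAD, or "otsu"
candidate_threshold <- function(v, spec) {
  if (identical(spec, "robust"))
    return(stats::median(v) + 6 * stats::mad(v))
  if (identical(spec, "otsu")) return(otsu_threshold(v))
  spec
}

# Otsu threshold on a vector of values in [0, 1]
otsu_threshold <- function(v, n_bins = 256) {
  h <- tabulate(pmin(pmax(floor(v * n_bins) + 1, 1), n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b)) / n_bins
}

#' Classify pixels of a mosaic as nerve / other
#'
#' A threshold on the normalized enhancement response selects candidate
#' pixels; when a trained pixel classifier is configured, candidates are
#' additionally screened by it (the output is always a subset of the
#' candidate set). With the default `"threshold"` mode the candidate set is
#' returned as-is.
#'
#' @param mosaic an `sbnp_mosaic`.
#' @param response enhancement map from [enhance()] (computed when `NULL`).
#' @param config a [tracer_config()].
#' @return logical matrix: `TRUE` for nerve pixels.
#' @export
classify_pixels <- function(mosaic, response = NULL,
                            config = tracer_config()) {
  m <- as_mosaic(mosaic)
  cls <- config$classifier
  if (!inherits(cls, "sbnp_pixel_classifier") &&
      !identical(cls, "threshold")) {
    if (config$strict_classifier)
      stop("pixel classifier \"", cls, "\" requested but not trained",
           call. = FALSE)
    warning("no trained pixel classifier supplied; ",
            "falling back to threshold-only classification")
  }
  if (is.null(response)) response <- enhance(m, config)
  mx <- stats::quantile(response[m$mask], 0.999, names = FALSE)
  if (mx <= 0) return(matrix(FALSE, nrow(response), ncol(response)))
  # normalize by a high quantile (robust to isolated hot pixels); after
  # top-hat equalization nerve peak responses are comparable across images
  rn <- response / mx
  thr <- candidate_threshold(rn[m$mask], config$threshold)
  cand <- rn >= thr & m$mask
  # non-maximum suppression across the dominant orientation thins the
  # diffuse response envelope into ridge candidates
  ori <- attr(response, "orientation")
  if (isTRUE(config$nms) && !is.null(ori))
    cand <- cand & nms_response(rn, ori, config$gabor_orientations)

  if (inherits(cls, "sbnp_pixel_classifier")) {
    idx <- which(cand)
    if (length(idx)) {
      feats <- pixel_features(m, rn, idx)
      p <- as.numeric(predict(cls$fit, newdata = feats, type = "response"))
      keep <- p >= 0.5
      cand[idx[!keep]] <- FALSE
    }
  }
  cand
}

# feature table for candidate pixels: response, raw intensity, local mean,
# local sd, ridge strength (Hessian eigen-ratio proxy)
pixel_features <- function(m, rn, idx) {
  img <- m$image / 255
  k <- gaussian_kernel(2)
  mu <- EBImage::filter2(img, k, boundary = "replicate")
  mu2 <- EBImage::filter2(img^2, k, boundary = "replicate")
  s <- sqrt(pmax(mu2 - mu^2, 0))
  g <- EBImage::gblur(img, sigma = 1.5)
  hxx <- rbind(g[-1, ], g[nrow(g), ]) + rbind(g[1, ], g[-nrow(g), ]) - 2 * g
  hyy <- cbind(g[, -1], g[, ncol(g)]) + cbind(g[, 1], g[, -ncol(g)]) - 2 * g
  ridge <- pmax(-(hxx + hyy), 0)
  data.frame(resp = rn[idx], intensity = img[idx], local_mean = mu[idx],
             local_sd = s[idx], ridge = ridge[idx])
}

#' Train a logistic pixel classifier on synthetic ground truth
#'
#' Candidate pixels from each training mosaic are labelled positive when
#' they fall on the (dilated) ground-truth centerlines and negative
#' otherwise; a logistic regression on local response/intensity features is
#' fitted to the pooled sample.
#'
#' @param mosaics list of `sbnp_mosaic`.
#' @param truth_masks list of logical matrices marking true nerve pixels
#'   (dilated centerlines), same sizes as the mosaics.
#' @param config a [tracer_config()].
#' @param seed integer seed for pixel subsampling.
#' @param max_pixels_per_mosaic subsample cap per mosaic.
#' @return an object of class `sbnp_pixel_classifier`.
#' @export
train_pixel_classifier <- function(mosaics, truth_masks,
                                   config = tracer_config(), seed = 1,
                                   max_pixels_per_mosaic = 20000) {
  set.seed(as.integer(seed))
  feats <- list(); labs <- list()
  for (k in seq_along(mosaics)) {
    m <- as_mosaic(mosaics[[k]])
    resp <- enhance(m, config)
    rn <- resp / stats::quantile(resp[m$mask], 0.999, names = FALSE)
    thr <- candidate_threshold(rn[m$mask], config$threshold)
    idx <- which(rn >= thr & m$mask)
    if (length(idx) > max_pixels_per_mosaic)
      idx <- sort(sample(idx, max_pixels_per_mosaic))
    feats[[k]] <- pixel_features(m, rn, idx)
    labs[[k]] <- as.integer(truth_masks[[k]][idx])
  }
  df <- do.call(rbind, feats)
  df$y <- unlist(labs)
  fit <- stats::glm(y ~ resp + intensity + local_mean + local_sd + ridge,
                    family = binomial(), data = df)
  structure(list(fit = fit, n_pixels = nrow(df), seed = as.integer(seed)),
            class = "sbnp_pixel_classifier")
}

#' Skeletonize and segment a binary nerve map
#'
#' Morphological closing fuses small breaks, components smaller than
#' `min_segment_px` are removed, the map is thinned to a one-pixel-wide
#' skeleton, spurs shorter than `spur_px` are pruned, and the skeleton is
#' converted to polyline segments between endpoints and junctions.
#'
#' @param binary logical or 0/1 matrix of nerve pixels.
#' @param config a [tracer_config()].
#' @return list with `segments` (list of n x 2 polylines, 0-based px
#'   coordinates, columns x/y) and `skeleton` (logical matrix).
#' @export
postprocess <- function(binary, config = tracer_config()) {
  b <- matrix(as.integer(binary != 0), nrow(binary), ncol(binary))
  if (!any(b == 1))
    return(list(segments = list(),
                skeleton = matrix(FALSE, nrow(b), ncol(b))))
  # despeckle before closing, so isolated response specks are not glued
  # onto genuine ridges
  b <- drop_small_components(b, max(4L, config$min_segment_px %/% 2L))
  b <- EBImage::closing(b, EBImage::makeBrush(3, "box"))
  b <- matrix(as.integer(b > 0), nrow(b), ncol(b))
  # closing dotted ridges leaves small perforations; thinning would turn
  # every hole into a spurious loop, so fill the small ones first
  b <- fill_small_holes(b, 40L)
  b <- drop_small_components(b, config$min_segment_px)
  sk <- cpp_thin(b)
  chains <- skeleton_chains(sk)
  chains <- prune_spurs(chains, config$spur_px)
  # rebuild the skeleton from kept chains and re-extract so degrees are
  # consistent after pruning
  sk2 <- matrix(0L, nrow(b), ncol(b))
  for (ch in chains$chains) sk2[cbind(ch[, 2] + 1L, ch[, 1] + 1L)] <- 1L
  chains <- skeleton_chains(cpp_thin(sk2))
  keep <- vapply(chains$chains, nrow, integer(1)) >= 2
  segs <- extend_chain_ends(chains$chains[keep], b)
  list(segments = segs, skeleton = chains$skeleton)
}

# Thinning erodes roughly half the structure width from each free end of
# a segment; walk each free end outward through the binary map
# (8-connected, steepest along the local direction) to recover the lost
# tip length.
extend_chain_ends <- function(chains, b, max_steps = 4L) {
  if (!length(chains)) return(chains)
  ends <- do.call(rbind, lapply(chains, function(p)
    rbind(p[1, ], p[nrow(p), ])))
  key <- paste(ends[, 1], ends[, 2])
  shared <- names(which(table(key) > 1))
  H <- nrow(b); W <- ncol(b)
  off <- cbind(dx = c(-1, 0, 1, -1, 1, -1, 0, 1),
               dy = c(-1, -1, -1, 0, 0, 1, 1, 1))
  lapply(chains, function(p) {
    for (side in c(1, 2)) {
      n <- nrow(p)
      if (n < 2) next
      endpt <- if (side == 1) p[1, ] else p[n, ]
      if (paste(endpt[1], endpt[2]) %in% shared) next
      k <- min(5, n)
      dir <- if (side == 1) p[1, ] - p[k, ] else p[n, ] - p[n - k + 1, ]
      nm <- sqrt(sum(dir^2))
      if (nm == 0) next
      dir <- dir / nm
      cur <- endpt
      for (step in seq_len(max_steps)) {
        dots <- off[, "dx"] * dir[1] + off[, "dy"] * dir[2]
        cand <- NULL
        for (o in order(-dots)) {
          if (dots[o] < 0.5) break
          nx <- cur[1] + off[o, "dx"]; ny <- cur[2] + off[o, "dy"]
          if (nx < 0 || ny < 0 || nx >= W || ny >= H) next
          if (b[ny + 1, nx + 1] != 0) { cand <- c(nx, ny); break }
        }
        if (is.null(cand)) break
        p <- if (side == 1) rbind(cand, p) else rbind(p, cand)
        cur <- cand
      }
    }
    dimnames(p) <- list(NULL, c("x", "y"))
    p
  })
}

# fill background holes smaller than max_px that do not touch the border
fill_small_holes <- function(b, max_px) {
  inv <- matrix(as.integer(b == 0), nrow(b), ncol(b))
  lab <- EBImage::bwlabel(inv)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0])
  fill <- setdiff(which(sizes < max_px), border)
  if (length(fill)) b[lab %in% fill] <- 1L
  b
}

drop_small_components <- function(b, min_px) {
  lab <- EBImage::bwlabel(b)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_px)
  if (length(small)) b[lab %in% small] <- 0L
  b
}

# Extract polyline chains between nodes (endpoints / junctions) of a
# one-pixel-wide skeleton. Returns 0-based (x, y) polylines.
skeleton_chains <- function(sk) {
  H <- nrow(sk); W <- ncol(sk)
  skl <- sk != 0
  idx <- which(skl)
  if (!length(idx)) return(list(chains = list(), skeleton = skl))
  id_of <- matrix(0L, H, W); id_of[idx] <- seq_along(idx)
  rc <- arrayInd(idx, c(H, W))
  off <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
               c(1, -1), c(1, 0), c(1, 1))
  nbr <- lapply(seq_along(idx), function(k) {
    r <- rc[k, 1] + off[, 1]; c <- rc[k, 2] + off[, 2]
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    ids <- id_of[cbind(r[ok], c[ok])]
    ids[ids > 0L]
  })
  deg <- lengths(nbr)
  is_node <- deg != 2L
  chains <- list(); nc <- 0
  step_seen <- new.env(hash = TRUE, size = 4L * length(idx))
  mark <- function(a, b) assign(paste(a, b), TRUE, envir = step_seen)
  seen <- function(a, b) exists(paste(a, b), envir = step_seen)

  for (v in which(is_node)) {
    for (u in nbr[[v]]) {
      if (seen(v, u)) next
      path <- c(v, u); mark(v, u); mark(u, v)
      prev <- v; cur <- u
      while (!is_node[cur]) {
        nxt <- nbr[[cur]]
        nxt <- nxt[nxt != prev]
        if (length(nxt) == 0) break
        nxt <- nxt[1]
        mark(cur, nxt); mark(nxt, cur)
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      nc <- nc + 1
      chains[[nc]] <- path
    }
  }
  # pure cycles (all degree 2): walk each untouched component
  left <- which(!is_node & !vapply(seq_along(idx), function(k)
    any(vapply(nbr[[k]], function(u) seen(k, u), logical(1))),
    logical(1)))
  for (v in left) {
    if (any(vapply(nbr[[v]], function(u) seen(v, u), logical(1)))) next
    if (length(nbr[[v]]) == 0) next
    u <- nbr[[v]][1]
    path <- c(v, u); mark(v, u); mark(u, v)
    prev <- v; cur <- u
    while (cur != v) {
      nxt <- nbr[[cur]]; nxt <- nxt[nxt != prev]
      if (length(nxt) == 0) break
      nxt <- nxt[1]
      mark(cur, nxt); mark(nxt, cur)
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    nc <- nc + 1
    chains[[nc]] <- path
  }
  polys <- lapply(chains, function(p)
    cbind(x = rc[p, 2] - 1, y = rc[p, 1] - 1))
  # degree bookkeeping travels with the chains via attributes
  attr(polys, "deg") <- deg
  attr(polys, "rc") <- rc
  list(chains = polys, skeleton = skl,
       junctions = cbind(x = rc[deg >= 3L, 2] - 1, y = rc[deg >= 3L, 1] - 1))
}

# drop chains that dangle from a free end and are shorter than spur_px;
# a spur has at least one end not shared with any other chain
prune_spurs <- function(ch, spur_px) {
  if (!length(ch$chains)) return(ch)
  keep <- rep(TRUE, length(ch$chains))
  ends <- do.call(rbind, lapply(seq_along(ch$chains), function(i) {
    p <- ch$chains[[i]]
    rbind(cbind(i, p[1, 1], p[1, 2]), cbind(i, p[nrow(p), 1], p[nrow(p), 2]))
  }))
  key <- paste(ends[, 2], ends[, 3])
  cnt <- table(key)
  for (i in seq_along(ch$chains)) {
    p <- ch$chains[[i]]
    if (polyline_length(p) >= spur_px) next
    k1 <- paste(p[1, 1], p[1, 2])
    k2 <- paste(p[nrow(p), 1], p[nrow(p), 2])
    free1 <- cnt[k1] == 1
    free2 <- cnt[k2] == 1
    if (free1 || free2) keep[i] <- FALSE
  }
  ch$chains <- ch$chains[keep]
  ch
}

#' Bridge gaps between nerve segments
#'
#' Endpoint pairs of different segments closer than `max_gap_um` are
#' candidate connections, scored by
#' `w_dist * distance + w_angle * angular deviation + w_intensity * (1 -
#' mean normalized response along the straight path)`. Candidates are
#' realized cheapest-first (each endpoint used at most once) as
#' least-cost paths over the enhancement-derived cost field found with
#' Dijkstra's algorithm on the 8-connected pixel lattice (per-step cost =
#' step length * (1 + w_intensity * (1 - normalized response))). The
#' bridged skeleton is re-thinned and re-segmented, so the resulting graph
#' has no duplicate edges.
#'
#' @param segments output of [postprocess()].
#' @param response enhancement map from [enhance()].
#' @param config a [tracer_config()].
#' @param um_per_px physical scale.
#' @return a `nerve_graph`.
#' @export
bridge_gaps <- function(segments, response, config = tracer_config(),
                        um_per_px = ivcm_um_per_px()) {
  segs <- segments$segments
  sk <- segments$skeleton
  if (length(segs) == 0)
    return(new_nerve_graph(list(), sk, um_per_px, config))
  rn <- response / max(max(response), 1e-12)
  max_gap_px <- config$max_gap_um / um_per_px

  # endpoint table with outward tangents
  eps <- do.call(rbind, lapply(seq_along(segs), function(i) {
    p <- segs[[i]]
    n <- nrow(p)
    k <- min(5, n)
    t1 <- p[1, ] - p[k, ]                 # outward at start
    t2 <- p[n, ] - p[n - k + 1, ]         # outward at end
    rbind(data.frame(seg = i, end = 1L, x = p[1, 1], y = p[1, 2],
                     tx = t1[1], ty = t1[2]),
          data.frame(seg = i, end = 2L, x = p[n, 1], y = p[n, 2],
                     tx = t2[1], ty = t2[2]))
  }))

  cand <- list(); k <- 0
  for (a in seq_len(nrow(eps) - 1)) {
    for (b in (a + 1):nrow(eps)) {
      if (eps$seg[a] == eps$seg[b]) next
      dx <- eps$x[b] - eps$x[a]; dy <- eps$y[b] - eps$y[a]
      gap_px <- sqrt(dx^2 + dy^2)
      if (gap_px * um_per_px > config$max_gap_um || gap_px < 1) next
      cost <- bridge_cost(eps[a, ], eps[b, ], rn, um_per_px, config)
      k <- k + 1
      cand[[k]] <- data.frame(a = a, b = b, cost = cost)
    }
  }
  bridges <- matrix(0L, nrow(sk), ncol(sk))
  if (k > 0) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$cost), , drop = FALSE]
    used <- rep(FALSE, nrow(eps))
    for (r in seq_len(nrow(cand))) {
      a <- cand$a[r]; b <- cand$b[r]
      if (used[a] || used[b]) next
      path <- dijkstra_path(rn, c(eps$x[a], eps$y[a]),
                            c(eps$x[b], eps$y[b]), config)
      if (is.null(path)) next
      bridges[cbind(path[, 2] + 1L, path[, 1] + 1L)] <- 1L
      used[a] <- TRUE; used[b] <- TRUE
    }
  }
  full <- matrix(0L, nrow(sk), ncol(sk))
  for (p in segs) full[cbind(p[, 2] + 1L, p[, 1] + 1L)] <- 1L
  full[bridges == 1L] <- 1L
  ch <- skeleton_chains(cpp_thin(full))
  keep <- vapply(ch$chains, nrow, integer(1)) >= 2
  new_nerve_graph(ch$chains[keep], ch$skeleton, um_per_px, config,
                  junctions = ch$junctions)
}

# straight-path candidate cost (distance um, angular deviation rad,
# intensity deficit along the chord)
bridge_cost <- function(e1, e2, rn, um_per_px, config) {
  dx <- e2$x - e1$x; dy <- e2$y - e1$y
  gap_px <- sqrt(dx^2 + dy^2)
  dist_um <- gap_px * um_per_px
  ang <- function(tx, ty, ux, uy) {
    n1 <- sqrt(tx^2 + ty^2); n2 <- sqrt(ux^2 + uy^2)
    if (n1 == 0 || n2 == 0) return(0)
    acos(pmin(pmax((tx * ux + ty * uy) / (n1 * n2), -1), 1))
  }
  # deviation between each outward tangent and the connecting chord
  a1 <- ang(e1$tx, e1$ty, dx, dy)
  a2 <- ang(e2$tx, e2$ty, -dx, -dy)
  ts <- seq(0, 1, length.out = max(2, ceiling(gap_px)))
  xs <- round(e1$x + ts * dx) + 1L
  ys <- round(e1$y + ts * dy) + 1L
  ok <- ys >= 1 & ys <= nrow(rn) & xs >= 1 & xs <= ncol(rn)
  mi <- if (any(ok)) mean(rn[cbind(ys[ok], xs[ok])]) else 0
  config$w_dist * dist_um + config$w_angle * (a1 + a2) / 2 +
    config$w_intensity * (1 - mi)
}

# least-cost 8-connected lattice path between two pixels (0-based x/y),
# step cost = step length * (1 + w_intensity * (1 - normalized response))
dijkstra_path <- function(rn, from, to, config, pad = 6L) {
  x0 <- max(0L, min(from[1], to[1]) - pad)
  x1 <- min(ncol(rn) - 1L, max(from[1], to[1]) + pad)
  y0 <- max(0L, min(from[2], to[2]) - pad)
  y1 <- min(nrow(rn) - 1L, max(from[2], to[2]) + pad)
  w <- x1 - x0 + 1L; h <- y1 - y0 + 1L
  sub <- rn[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  vid <- function(x, y) (x - x0) * h + (y - y0) + 1L
  # edge list of the window lattice
  el <- list(); wt <- list(); k <- 0
  for (dd in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                  c(1L, -1L, sqrt(2)))) {
    ddx <- dd[1]; ddy <- dd[2]; sl <- dd[3]
    xs <- seq.int(x0, x1); ys <- seq.int(y0, y1)
    gx <- rep(xs, each = length(ys)); gy <- rep(ys, length(xs))
    ok <- gx + ddx >= x0 & gx + ddx <= x1 & gy + ddy >= y0 & gy + ddy <= y1
    gx <- gx[ok]; gy <- gy[ok]
    v1 <- vid(gx, gy); v2 <- vid(gx + ddx, gy + ddy)
    c1 <- sub[cbind(gy - y0 + 1L, gx - x0 + 1L)]
    c2 <- sub[cbind(gy + ddy - y0 + 1L, gx + ddx - x0 + 1L)]
    k <- k + 1
    el[[k]] <- cbind(v1, v2)
    wt[[k]] <- sl * (1 + config$w_intensity * (1 - (c1 + c2) / 2))
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, el), directed = FALSE)
  igraph::E(g)$weight <- pmax(unlist(wt), 1e-9)
  sp <- suppressWarnings(igraph::shortest_paths(
    g, from = vid(from[1], from[2]), to = vid(to[1], to[2]),
    weights = igraph::E(g)$weight, output = "vpath"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) < 2) return(NULL)
  cbind(x = (vp - 1L) %/% h + x0, y = (vp - 1L) %% h + y0)
}

new_nerve_graph <- function(polylines, skeleton, um_per_px, config,
                            junctions = NULL) {
  edges_um <- lapply(polylines, function(p) p * um_per_px)
  lens_um <- vapply(edges_um, polyline_length, numeric(1))
  bp <- if (is.null(junctions) || nrow(junctions) == 0)
    matrix(numeric(0), 0, 2) else merge_junctions(junctions,
                                                  config$merge_branch_px)
  bp <- filter_branch_points(bp, polylines, config)
  colnames(bp) <- c("x", "y")
  # endpoints: chain ends that are not branch points
  ep <- if (length(polylines)) do.call(rbind, lapply(polylines, function(p)
    rbind(p[1, ], p[nrow(p), ]))) else matrix(numeric(0), 0, 2)
  structure(list(edges_um = edges_um, edge_lengths_um = lens_um,
                 branch_points_um = bp * um_per_px,
                 endpoints_px = ep, skeleton = skeleton,
                 um_per_px = um_per_px,
                 total_length_mm = sum(lens_um) / 1000),
            class = "nerve_graph")
}

# Keep only junctions that look like true branchings or crossings: at
# least three incident chain directions, every pair separated by at least
# min_branch_angle. Junctions where two incident directions are nearly
# parallel arise from adjacent parallel fibers merging in the image, not
# from a branching.
filter_branch_points <- function(bp, polylines, config,
                                 min_branch_angle = 20 * pi / 180) {
  if (nrow(bp) == 0 || length(polylines) == 0) return(bp)
  reach <- config$merge_branch_px + 1.5
  ends <- do.call(rbind, lapply(seq_along(polylines), function(i) {
    p <- polylines[[i]]
    n <- nrow(p)
    k <- min(6, n)
    rbind(c(p[1, ], p[k, ] - p[1, ]), c(p[n, ], p[n - k + 1, ] - p[n, ]))
  }))
  keep <- logical(nrow(bp))
  for (j in seq_len(nrow(bp))) {
    d <- sqrt((ends[, 1] - bp[j, 1])^2 + (ends[, 2] - bp[j, 2])^2)
    inc <- ends[d <= reach, 3:4, drop = FALSE]
    nrm <- sqrt(rowSums(inc^2))
    inc <- inc[nrm > 0, , drop = FALSE] / nrm[nrm > 0]
    if (nrow(inc) < 3) next
    ang <- atan2(inc[, 2], inc[, 1])
    sep <- outer(ang, ang, function(a, b) {
      v <- abs(a - b) %% (2 * pi); pmin(v, 2 * pi - v)
    })
    diag(sep) <- Inf
    keep[j] <- all(apply(sep, 1, min) >= min_branch_angle)
  }
  bp[keep, , drop = FALSE]
}

# merge junction pixels closer than merge_px into centroid branch points
merge_junctions <- function(junctions, merge_px) {
  if (nrow(junctions) == 0) return(matrix(numeric(0), 0, 2))
  if (nrow(junctions) == 1) return(junctions)
  d <- as.matrix(stats::dist(junctions))
  g <- igraph::graph_from_adjacency_matrix(d <= merge_px, mode = "undirected",
                                           diag = FALSE)
  mem <- igraph::components(g)$membership
  t(vapply(sort(unique(mem)), function(k)
    colMeans(junctions[mem == k, , drop = FALSE]), numeric(2)))
}

#' @export
print.nerve_graph <- function(x, ...) {
  cat(sprintf(
    "<nerve_graph: %d edges, %.3f mm total, %d branch points>\n",
    length(x$edges_um), x$total_length_mm, nrow(x$branch_points_um)))
  invisible(x)
}

#' Trace nerves in a mosaic
#'
#' Deterministic composition of [enhance()], [classify_pixels()],
#' [postprocess()] and [bridge_gaps()].
#'
#' @param mosaic an `sbnp_mosaic`.
#' @param config a [tracer_config()].
#' @return a `nerve_graph` in mosaic-local coordinates (micrometres).
#' @export
trace_nerves <- function(mosaic, config = tracer_config()) {
  m <- as_mosaic(mosaic)
  resp <- enhance(m, config)
  binary <- classify_pixels(m, resp, config)
  segs <- postprocess(binary, config)
  bridge_gaps(segs, resp, config, um_per_px = m$um_per_px)
}

#' Serialize a nerve graph to CSV (and an optional overlay TIFF)
#'
#' Writes `<stem>_edges.csv` (edge id, vertex order, x/y in micrometres),
#' `<stem>_branch_points.csv`, and — when a mosaic is supplied —
#' `<stem>_overlay.tif` with the traced centerlines burned in at full
#' intensity for visual quality control.
#'
#' @param graph a `nerve_graph`.
#' @param stem output path stem (directories are created).
#' @param mosaic optional `sbnp_mosaic` for the overlay.
#' @return character vector of the files written, invisibly.
#' @export
write_nerve_graph <- function(graph, stem, mosaic = NULL) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  edges <- do.call(rbind, lapply(seq_along(graph$edges_um), function(i) {
    p <- graph$edges_um[[i]]
    data.frame(edge = i, vertex = seq_len(nrow(p)),
               x_um = p[, 1], y_um = p[, 2])
  }))
  if (is.null(edges))
    edges <- data.frame(edge = integer(0), vertex = integer(0),
                        x_um = numeric(0), y_um = numeric(0))
  f1 <- paste0(stem, "_edges.csv")
  write.csv(edges, f1, row.names = FALSE)
  bp <- graph$branch_points_um
  f2 <- paste0(stem, "_branch_points.csv")
  write.csv(data.frame(x_um = bp[, 1], y_um = bp[, 2]), f2,
            row.names = FALSE)
  files <- c(f1, f2)
  if (!is.null(mosaic)) {
    m <- as_mosaic(mosaic)
    ov <- m$image
    for (p in graph$edges_um) {
      q <- round(p / m$um_per_px) + 1L
      ok <- q[, 2] >= 1 & q[, 2] <= nrow(ov) & q[, 1] >= 1 &
        q[, 1] <= ncol(ov)
      ov[cbind(q[ok, 2], q[ok, 1])] <- 255
    }
    f3 <- paste0(stem, "_overlay.tif")
    tiff::writeTIFF(round(clip8(ov)) / 255, f3, bits.per.sample = 8L,
                    compression = "none")
    files <- c(files, f3)
  }
  invisible(files)
}
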