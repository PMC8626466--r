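# Quantitative SBNP parameters: mosaic area, enhancement factor, nerve
# fiber length density (CNFL) and branch density (CNBD) over the full
# mosaic and over circular whorl regions.

#' Valid mosaic area in mm^2
#'
#' Regions without image data (the invalid/black part of the canvas) are
#' excluded: area = valid-pixel count x (um/px)^2 x 1e-6.
#'
#' @param mosaic an `sbnp_mosaic`.
#' @return area in mm^2.
#' @export
mosaic_area <- function(mosaic) {
  m <- as_mosaic(mosaic)
  sum(m$mask) * m$um_per_px^2 * 1e-6
}

#' Mosaic enhancement factor
#'
#' Mosaic area divided by the area of a single 400 x 400 um IVCM frame
#' (0.16 mm^2): the equivalent number of single fields of view tiled by the
#' mosaic.
#'
#' @param area_mm2 mosaic area in mm^2 (or an `sbnp_mosaic`).
#' @return dimensionless factor.
#' @examples
#' enhancement_factor(0.16)   # 1
#' enhancement_factor(7.68)   # 48
#' @export
enhancement_factor <- function(area_mm2) {
  if (inherits(area_mm2, "sbnp_mosaic")) area_mm2 <- mosaic_area(area_mm2)
  stopifnot(area_mm2 >= 0)
  area_mm2 / 0.16
}

#' Whorl region specification
#'
#' @param center_um whorl centre `c(x, y)` in mosaic micrometre
#'   coordinates.
#' @param diameter_um region diameter in micrometres (800 or 400 by
#'   convention; any positive value accepted). Set `radius = TRUE` to
#'   interpret the value as a radius instead.
#' @param shape `"full"` circle or `"superior"` half (rows at or above the
#'   centre row, i.e. 9 to 3 o'clock through the top).
#' @param radius interpret `diameter_um` as a radius.
#' @return list of class `whorl_region`.
#' @export
whorl_region <- function(center_um, diameter_um = 800,
                         shape = c("full", "superior"), radius = FALSE) {
  shape <- match.arg(shape)
  structure(list(center_um = center_um,
                 radius_um = if (radius) diameter_um else diameter_um / 2,
                 shape = shape), class = "whorl_region")
}

#' Pixel mask of a whorl region intersected with mosaic validity
#'
#' @param mosaic an `sbnp_mosaic`.
#' @param region a [whorl_region()].
#' @return logical mask (same size as mosaic) with attribute `covered`:
#'   `TRUE` iff the full circle lies entirely within valid mosaic pixels.
#' @export
whorl_mask <- function(mosaic, region) {
  m <- as_mosaic(mosaic)
  s <- m$um_per_px
  H <- nrow(m$image); W <- ncol(m$image)
  cx <- region$center_um[1] / s; cy <- region$center_um[2] / s
  if (cx < 0 || cx > W - 1 || cy < 0 || cy > H - 1)
    stop("whorl centre lies outside the mosaic canvas", call. = FALSE)
  r_px <- region$radius_um / s
  xs <- (seq_len(W) - 1) - cx
  ys <- (seq_len(H) - 1) - cy
  disc <- outer(ys^2, xs^2, `+`) <= r_px^2
  full_inside <- all(m$mask[disc]) &&
    cx - r_px >= 0 && cx + r_px <= W - 1 &&
    cy - r_px >= 0 && cy + r_px <= H - 1
  mask <- disc
  if (region$shape == "superior") mask <- mask & (ys <= 0)
  mask <- mask & m$mask
  attr(mask, "covered") <- full_inside
  mask
}

# ---- polyline clipping against a disc / half-disc ------------------------

# parameter values t in [0,1] where segment p + t*(q-p) crosses the circle
segment_circle_roots <- function(p, q, center, r) {
  d <- q - p; f <- p - center
  a <- sum(d^2); b <- 2 * sum(f * d); cc <- sum(f^2) - r^2
  if (a == 0) return(numeric(0))
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(numeric(0))
  sq <- sqrt(disc)
  t <- c((-b - sq) / (2 * a), (-b + sq) / (2 * a))
  t[t > 0 & t < 1]
}

# length of the part of polyline `poly` (n x 2, same units as center/r)
# inside the disc (optionally its superior half: y <= center_y)
clipped_polyline_length <- function(poly, center, r,
                                    half = c("full", "superior")) {
  half <- match.arg(half)
  if (is.null(poly) || nrow(poly) < 2) return(0)
  inside <- function(pt) {
    sum((pt - center)^2) <= r^2 * (1 + 1e-12) &&
      (half == "full" || pt[2] <= center[2] + 1e-12)
  }
  total <- 0
  for (k in seq_len(nrow(poly) - 1)) {
    p <- poly[k, ]; q <- poly[k + 1, ]
    ts <- sort(unique(c(0, segment_circle_roots(p, q, center, r),
                        if (half == "superior" && q[2] != p[2])
                          (center[2] - p[2]) / (q[2] - p[2]), 1)))
    ts <- ts[ts >= 0 & ts <= 1]
    for (m in seq_len(length(ts) - 1)) {
      mid <- p + (ts[m] + ts[m + 1]) / 2 * (q - p)
      if (inside(mid))
        total <- total + (ts[m + 1] - ts[m]) * sqrt(sum((q - p)^2))
    }
  }
  total
}

# total traced length (mm) of a nerve graph inside a region mask (pixel
# mask) or a whorl_region (exact geometric clipping)
graph_length_in_region <- function(graph, region, um_per_px) {
  if (inherits(region, "whorl_region")) {
    if (region$shape == "superior") {
      sum(vapply(graph$edges_um, clipped_polyline_length,
                 numeric(1), center = region$center_um,
                 r = region$radius_um, half = "superior")) / 1000
    } else {
      sum(vapply(graph$edges_um, clipped_polyline_length,
                 numeric(1), center = region$center_um,
                 r = region$radius_um, half = "full")) / 1000
    }
  } else {
    # pixel mask: subdivide segments and count pieces whose midpoint is in
    # the mask
    total <- 0
    for (p in graph$edges_um) {
      q <- resample_polyline(p / um_per_px, 0.5)
      if (nrow(q) < 2) next
      mid <- (q[-1, , drop = FALSE] + q[-nrow(q), , drop = FALSE]) / 2
      seg <- sqrt(rowSums((diff(q))^2))
      rr <- round(mid[, 2]) + 1L; cc <- round(mid[, 1]) + 1L
      ok <- rr >= 1 & rr <= nrow(region) & cc >= 1 & cc <= ncol(region)
      ok[ok] <- region[cbind(rr[ok], cc[ok])]
      total <- total + sum(seg[ok]) * um_per_px
    }
    total / 1000
  }
}

#' Corneal nerve fiber length density
#'
#' Total centerline length inside the region divided by the region area:
#' mm of nerve per mm^2.
#'
#' @param graph a `nerve_graph`.
#' @param region a [whorl_region()] (exact geometric clipping) or a logical
#'   pixel mask.
#' @param area_mm2 region area in mm^2 (> 0).
#' @param um_per_px physical scale used to interpret a pixel-mask region.
#' @return density in mm/mm^2.
#' @export
cnfl <- function(graph, region, area_mm2,
                 um_per_px = graph$um_per_px) {
  if (!is.finite(area_mm2) || area_mm2 <= 0)
    stop("region area must be positive", call. = FALSE)
  graph_length_in_region(graph, region, um_per_px) / area_mm2
}

#' Corneal nerve branch density
#'
#' Number of branch points inside the region divided by the region area
#' (count per mm^2).
#'
#' @inheritParams cnfl
#' @return density in 1/mm^2.
#' @export
cnbd <- function(graph, region, area_mm2,
                 um_per_px = graph$um_per_px) {
  if (!is.finite(area_mm2) || area_mm2 <= 0)
    stop("region area must be positive", call. = FALSE)
  bp <- graph$branch_points_um
  if (nrow(bp) == 0) return(0)
  inside <- if (inherits(region, "whorl_region")) {
    d2 <- (bp[, 1] - region$center_um[1])^2 +
      (bp[, 2] - region$center_um[2])^2
    ok <- d2 <= region$radius_um^2
    if (region$shape == "superior")
      ok <- ok & bp[, 2] <= region$center_um[2]
    ok
  } else {
    rr <- round(bp[, 2] / um_per_px) + 1L
    cc <- round(bp[, 1] / um_per_px) + 1L
    ok <- rr >= 1 & rr <= nrow(region) & cc >= 1 & cc <= ncol(region)
    ok[ok] <- region[cbind(rr[ok], cc[ok])]
    ok
  }
  sum(inside) / area_mm2
}

#' Compute the full metrics record for a mosaic
#'
#' Mosaic area, enhancement factor, mCNFL and mCNBD over the valid mosaic,
#' and wCNFL/wCNBD for the four whorl configurations (800 and 400 um
#' diameter, full circle and superior half). Whorl entries are reported
#' only when the corresponding full circle contains image data everywhere;
#' otherwise they are `NA` and the coverage flag is `FALSE`.
#'
#' @param mosaic an `sbnp_mosaic`.
#' @param graph a `nerve_graph` traced on that mosaic.
#' @param whorl_center_um whorl centre `c(x, y)`, mosaic micrometre
#'   coordinates.
#' @param diameters_um whorl diameters analysed.
#' @return one-row tibble: `area_mm2`, `enhancement_factor`, `mcnfl`,
#'   `mcnbd`, then `wcnfl_<d>_full`, `wcnfl_<d>_sup`, `wcnbd_<d>_full`,
#'   `wcnbd_<d>_sup` and `whorl_covered_<d>` per diameter `<d>`.
#' @export
compute_metrics <- function(mosaic, graph, whorl_center_um,
                            diameters_um = c(800, 400)) {
  m <- as_mosaic(mosaic)
  area <- mosaic_area(m)
  if (area <= 0) stop("mosaic has zero valid area", call. = FALSE)
  out <- tibble::tibble(
    area_mm2 = area,
    enhancement_factor = enhancement_factor(area),
    mcnfl = cnfl(graph, m$mask, area, m$um_per_px),
    mcnbd = cnbd(graph, m$mask, area, m$um_per_px))
  for (d in diameters_um) {
    full <- whorl_region(whorl_center_um, d, "full")
    sup <- whorl_region(whorl_center_um, d, "superior")
    fm <- whorl_mask(m, full)
    covered <- attr(fm, "covered")
    tag <- as.character(round(d))
    if (covered) {
      a_full <- pi * (d / 2000)^2                 # mm^2
      a_sup <- a_full / 2
      out[[paste0("wcnfl_", tag, "_full")]] <- cnfl(graph, full, a_full)
      out[[paste0("wcnfl_", tag, "_sup")]] <- cnfl(graph, sup, a_sup)
      out[[paste0("wcnbd_", tag, "_full")]] <- cnbd(graph, full, a_full)
      out[[paste0("wcnbd_", tag, "_sup")]] <- cnbd(graph, sup, a_sup)
    } else {
      for (suffix in c("wcnfl_", "wcnbd_"))
        for (sh in c("_full", "_sup"))
          out[[paste0(suffix, tag, sh)]] <- NA_real_
    }
    out[[paste0("whorl_covered_", tag)]] <- covered
  }
  out
}
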