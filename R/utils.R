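# Shared internal helpers: 8-bit image conventions and small numerics.
#
# Images are plain numeric matrices on the 0..255 (8-bit) intensity scale,
# row 1 = top image row, column 1 = left. Continuous pixel coordinates are
# 0-based: (x, y) = (0, 0) is the centre of pixel [1, 1], x grows along
# columns, y grows downward along rows.

clip8 <- function(x) pmin(pmax(x, 0), 255)

#' @noRd
assert_image <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("%s must be a numeric matrix (grayscale)", what), call. = FALSE)
  invisible(img)
}

# Block-average downscaling by an integer factor; trailing rows/columns that
# do not fill a block are cropped.
downscale_block <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(img)
  nr <- (nrow(img) %/% factor) * factor
  nc <- (ncol(img) %/% factor) * factor
  img <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  # average over factor x factor blocks
  m <- matrix(0, nr %/% factor, nc %/% factor)
  for (dr in seq_len(factor)) {
    for (dc in seq_len(factor)) {
      m <- m + img[seq(dr, nr, by = factor), seq(dc, nc, by = factor),
                   drop = FALSE]
    }
  }
  m / factor^2
}

# Normalized 2-D Gaussian kernel (sums to 1).
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  ax <- seq(-radius, radius)
  g <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Gaussian smoothing of a vector with reflective boundaries.
smooth_gauss1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  radius <- ceiling(3 * sigma)
  g <- exp(-seq(-radius, radius)^2 / (2 * sigma^2))
  g <- g / sum(g)
  n <- length(x)
  xp <- c(rev(x[seq_len(min(radius, n))]), x,
          rev(x[seq(max(1, n - radius + 1), n)]))
  out <- stats::filter(xp, g, sides = 2)
  as.numeric(out[(length(xp) - n) / 2 + seq_len(n)])
}

# Polyline length (rows = vertices, cols = x, y), same units as coordinates.
polyline_length <- function(p) {
  if (is.null(p) || nrow(p) < 2) return(0)
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

# Round half away from zero to `digits` decimals (presentation rounding used
# for report tables; R's round() is half-to-even).
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# local integer RNG draw used to derive per-stage seeds from a master seed
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483629L
}
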