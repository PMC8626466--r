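# FFT-based phase correlation for translational registration.

#' Phase correlation between two equally sized images
#'
#' Estimates the circular shift `s` such that `b` equals `a` shifted by `s`
#' (rows down by `s[1]`... the returned value is `c(dy, dx)`), from the peak
#' of the normalized cross-power spectrum. With `scale > 1` both images are
#' block-average downscaled first and the coarse shift is multiplied back,
#' trading resolution (the estimate is then quantized to multiples of
#' `scale`) for speed.
#'
#' The score is the peak height of the normalized phase-correlation
#' surface; it approaches 1 for a pure shift and drops toward 0 for
#' unrelated content.
#'
#' @param a,b numeric matrices of identical dimensions.
#' @param scale integer downscale factor (>= 1).
#' @return list with `shift` (`c(dy, dx)`, full-resolution pixels; `b` is
#'   `a` circularly shifted by this amount) and `score` in `[0, 1]`.
#' @examples
#' a <- matrix(rnorm(64 * 64), 64, 64)
#' b <- a[c(53:64, 1:52), ]         # shift rows down by 12
#' phase_correlation(a, b)$shift    # c(12, 0)
#' @export
phase_correlation <- function(a, b, scale = 1L) {
  assert_image(a, "a"); assert_image(b, "b")
  if (!all(dim(a) == dim(b)))
    stop("phase correlation requires images of identical dimensions",
         call. = FALSE)
  scale <- as.integer(scale)
  stopifnot(scale >= 1L)
  if (scale > 1L) {
    a <- downscale_block(a, scale)
    b <- downscale_block(b, scale)
  }
  surf <- phase_corr_surface(a, b)
  pk <- which.max(surf)
  idx <- arrayInd(pk, dim(surf)) - 1L
  n <- dim(surf)
  sh <- ifelse(idx > n / 2, idx - n, idx)
  list(shift = as.numeric(sh) * scale,
       score = max(min(surf[pk], 1), 0))
}

# Normalized phase-correlation surface; entry [1,1] corresponds to zero
# shift, entry [1 + dy, 1 + dx] (cyclically) to b == shift(a, c(dy, dx)).
phase_corr_surface <- function(a, b) {
  Fa <- stats::fft(a)
  Fb <- stats::fft(b)
  cross <- Fb * Conj(Fa)
  m <- Mod(cross)
  m[m < 1e-12] <- 1e-12
  Re(stats::fft(cross / m, inverse = TRUE)) / length(a)
}

# Circular shift of a matrix by s = c(dy, dx): result[r, c] = x[r - dy, c - dx].
circshift <- function(x, s) {
  n <- dim(x)
  r <- ((seq_len(n[1]) - 1 - s[1]) %% n[1]) + 1
  c <- ((seq_len(n[2]) - 1 - s[2]) %% n[2]) + 1
  x[r, c, drop = FALSE]
}

# Pearson correlation of the overlapping region of image `a` and image `b`
# placed at integer offset d = c(dy, dx) (b's origin relative to a's).
# Returns NA when the overlap is smaller than min_px pixels.
overlap_ncc <- function(a, b, d, min_px = 64) {
  dy <- d[1]; dx <- d[2]
  r_lo <- max(1, 1 + dy); r_hi <- min(nrow(a), nrow(b) + dy)
  c_lo <- max(1, 1 + dx); c_hi <- min(ncol(a), ncol(b) + dx)
  if (r_hi - r_lo < 1 || c_hi - c_lo < 1 ||
      (r_hi - r_lo + 1) * (c_hi - c_lo + 1) < min_px) return(NA_real_)
  ra <- r_lo:r_hi
  ca <- c_lo:c_hi
  va <- a[ra, ca]
  vb <- b[ra - dy, ca - dx]
  if (sd(va) == 0 || sd(vb) == 0) return(NA_real_)
  cor(as.vector(va), as.vector(vb))
}
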