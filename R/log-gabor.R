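# Frequency-domain log-Gabor filter bank for curvilinear structure
# enhancement. Filters occupy one half-plane per orientation, so the
# inverse transform is an analytic (quadrature) signal whose magnitude is
# the local line-energy envelope.

# frequency coordinate along one axis, cycles per pixel
fft_freqs <- function(n) {
  k <- seq_len(n) - 1
  ifelse(k > n / 2, k - n, k) / n
}

# one log-Gabor transfer function on an H x W grid
log_gabor_filter <- function(H, W, wavelength, orientation, sigma_ratio,
                             theta_sigma) {
  fy <- fft_freqs(H)
  fx <- fft_freqs(W)
  r <- sqrt(outer(fy^2, fx^2, `+`))
  th <- atan2(outer(fy, rep(1, W)), outer(rep(1, H), fx))
  f0 <- 1 / wavelength
  radial <- exp(-(log(pmax(r, 1e-12) / f0))^2 / (2 * log(sigma_ratio)^2))
  radial[1, 1] <- 0                       # kill DC
  dth <- atan2(sin(th - orientation), cos(th - orientation))
  angular <- exp(-dth^2 / (2 * theta_sigma^2))
  radial * angular
}

# Maximum log-Gabor magnitude response over a bank of orientations and
# centre wavelengths. The returned matrix carries an `orientation`
# attribute: the index of the winning orientation per pixel, whose angle
# points across the local line (the direction for non-maximum
# suppression).
log_gabor_response <- function(img, orientations = 8,
                               wavelengths = c(8, 16),
                               sigma_ratio = 0.55) {
  H <- nrow(img); W <- ncol(img)
  Fimg <- stats::fft(img)
  theta_sigma <- pi / orientations / 1.3
  resp <- matrix(0, H, W)
  ori <- matrix(1L, H, W)
  for (wl in wavelengths) {
    for (o in seq_len(orientations)) {
      phi <- (o - 1) * pi / orientations
      filt <- log_gabor_filter(H, W, wl, phi, sigma_ratio, theta_sigma)
      e <- Mod(stats::fft(Fimg * filt, inverse = TRUE)) / length(img)
      upd <- e > resp
      resp[upd] <- e[upd]
      ori[upd] <- o
    }
  }
  attr(resp, "orientation") <- ori
  resp
}

# shift a matrix by (dy, dx) with edge replication
shift_replicate <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(seq_len(H) - dy, 1), H)
  c <- pmin(pmax(seq_len(W) - dx, 1), W)
  m[r, c, drop = FALSE]
}

# response sampled at a continuous offset (dy, dx) via bilinear
# combination of integer shifts
shift_bilinear <- function(m, dy, dx) {
  y0 <- floor(dy); x0 <- floor(dx)
  fy <- dy - y0; fx <- dx - x0
  (1 - fy) * (1 - fx) * shift_replicate(m, y0, x0) +
    (1 - fy) * fx * shift_replicate(m, y0, x0 + 1) +
    fy * (1 - fx) * shift_replicate(m, y0 + 1, x0) +
    fy * fx * shift_replicate(m, y0 + 1, x0 + 1)
}

# Non-maximum suppression across the locally dominant orientation: a pixel
# survives only if its response is a local maximum along the winning
# filter's angle (which points across the line). Neighbour responses are
# interpolated bilinearly at the exact unit offset, so ridges stay
# continuous at angles between the pixel-grid directions.
nms_response <- function(resp, ori, orientations) {
  keep <- matrix(FALSE, nrow(resp), ncol(resp))
  for (o in sort(unique(as.vector(ori)))) {
    phi <- (o - 1) * pi / orientations
    dx <- cos(phi); dy <- sin(phi)
    ge <- resp >= shift_bilinear(resp, dy, dx) &
      resp >= shift_bilinear(resp, -dy, -dx)
    keep <- keep | (ge & ori == o)
  }
  keep
}
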