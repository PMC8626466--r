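# Run configuration constructors. Every tunable of the pipeline lives here
# with its default and a short note on provenance: "method" marks values the
# underlying method prescribes, "choice" marks implementation-chosen
# defaults.

#' Alignment (mosaicking) configuration
#'
#' @param tau correlation acceptance threshold for sub-image registrations;
#'   registrations scoring below `tau` are discarded before the global
#'   solve (choice; the threshold is empirically predefined). The score is
#'   the normalized cross-correlation of the high-pass-filtered overlap
#'   (see [register_pairs()]), for which 0.5 separates true from false
#'   matches with a wide margin on synthetic data.
#' @param lambda1 weight of the absolute anchor equation `lambda1 * p0 = 0`
#'   that removes the translational degree of freedom (choice).
#' @param lambda2 weight of the intra-frame smoothness equations
#'   `lambda2 * (p_{i+1} - p_i) = 0` between consecutive sub-images of the
#'   same frame (choice).
#' @param scale_full integer downscale factor for full-frame correlations
#'   (method default 3).
#' @param scale_sub integer downscale factor for sub-image correlations
#'   (method default 2).
#' @param overlap_gate minimum estimated fractional frame overlap for
#'   attempting sub-image registration of a frame pair (choice).
#' @param ncc_gate minimum full-frame overlap correlation (clamped
#'   high-pass NCC at full resolution) for attempting sub-image
#'   registration of a frame pair; screens out frame pairs whose coarse
#'   estimate is spurious (choice).
#' @param hp_sigma Gaussian sigma (px) of the high-pass residual used for
#'   match scoring: scores are computed on `img - gblur(img, hp_sigma)`,
#'   clamped at 3 robust standard deviations, which suppresses smooth
#'   background (that correlates between unrelated regions) and bounds the
#'   influence of bright nerve fibers (whose near-parallel repeats would
#'   otherwise dominate the correlation) (choice).
#' @param slice_dev_px maximum deviation (px, per axis) of a sub-image
#'   offset from its frame-level prediction; sub-image registration
#'   measures the small row-wise motion distortion, so offsets deviating
#'   further than the plausible drift are discarded (choice).
#' @param sharp_soft sharpness soft-weighting scale: each registration's
#'   weight in the global solve is reduced in proportion to how much the
#'   drop of its NCC optimum (2 px away in the worst direction) falls
#'   short of this value. Direction-ambiguous matches (the aperture
#'   problem along a straight fiber) are thereby downweighted instead of
#'   hard-rejected (choice).
#' @param refine logical; refine scaled sub-image offsets by a local
#'   normalized cross-correlation search at full resolution with
#'   sub-pixel parabolic interpolation (choice, default on).
#' @param refine_radius_px radius (px) of that search; must cover the
#'   coarse-estimate quantization plus the largest plausible row drift
#'   (choice).
#' @param reject_px,reject_iters residual-based outlier rejection in the
#'   global solve: after solving, accepted registrations whose residual
#'   exceeds `reject_px` pixels are discarded and the system re-solved, up
#'   to `reject_iters` times (`0` disables). Guards the least-squares
#'   solution against occasional high-scoring false matches between
#'   self-similar nerve regions (choice).
#' @param smooth_all logical; if `TRUE` (default) smoothness equations are
#'   added for all intra-frame consecutive slice pairs; if `FALSE` only for
#'   slices without any accepted registration.
#' @param n_slices number of horizontal sub-images per frame (method: 12).
#' @return list of class `alignment_config`.
#' @export
alignment_config <- function(tau = 0.50, lambda1 = 1.0, lambda2 = 0.1,
                             scale_full = 3L, scale_sub = 2L,
                             overlap_gate = 0.15, ncc_gate = 0.25,
                             hp_sigma = 4, slice_dev_px = 8,
                             sharp_soft = 0.08, refine = TRUE,
                             refine_radius_px = 2L,
                             reject_px = 8, reject_iters = 2L,
                             smooth_all = TRUE, n_slices = 12L) {
  stopifnot(tau > 0, tau < 1, lambda1 > 0, lambda2 > 0,
            scale_full >= 1, scale_sub >= 1, n_slices >= 1)
  structure(list(tau = tau, lambda1 = lambda1, lambda2 = lambda2,
                 scale_full = as.integer(scale_full),
                 scale_sub = as.integer(scale_sub),
                 overlap_gate = overlap_gate, ncc_gate = ncc_gate,
                 hp_sigma = hp_sigma, slice_dev_px = slice_dev_px,
                 sharp_soft = sharp_soft, refine = isTRUE(refine),
                 refine_radius_px = as.integer(refine_radius_px),
                 reject_px = reject_px,
                 reject_iters = as.integer(reject_iters),
                 smooth_all = isTRUE(smooth_all),
                 n_slices = as.integer(n_slices)),
            class = "alignment_config")
}

#' Nerve tracer configuration
#'
#' @param tophat_radius_px structuring-element radius of the white top-hat
#'   background equalization (choice).
#' @param gabor_orientations number of log-Gabor orientations (choice; >= 4).
#' @param gabor_wavelengths_px centre wavelengths of the log-Gabor bank in
#'   pixels (choice; spans nerve widths of 1-4 px at ~1.04 um/px).
#' @param gabor_sigma_ratio ratio sigma_f / f0 of the radial log-Gaussian
#'   (choice).
#' @param threshold candidate threshold on the normalized nerve response
#'   (response divided by its 99.9th valid-pixel percentile): a fixed
#'   number in (0, 1) (default 0.55; nerve responses concentrate around
#'   0.6-1 after top-hat equalization while background texture stays
#'   below ~0.5), `"robust"` (median + 6 MAD), or `"otsu"` (choice).
#' @param nms apply non-maximum suppression across the locally dominant
#'   orientation, keeping only thin ridge candidates. Off by default: the
#'   skeletonization step thins the thresholded bands reliably, while
#'   suppression tends to fragment ridges at angles between the quantized
#'   orientations (choice).
#' @param classifier `"threshold"` (candidate set passed through), or a
#'   pixel classifier trained with [train_pixel_classifier()].
#' @param strict_classifier if `TRUE`, requesting a trained classifier that
#'   is not supplied is an error instead of a threshold-only fallback.
#' @param min_segment_px minimum skeleton segment length kept (px).
#' @param spur_px skeleton spurs shorter than this are pruned (px).
#' @param max_gap_um maximum endpoint gap bridged (micrometres).
#' @param w_dist,w_angle,w_intensity bridge candidate cost weights: cost =
#'   `w_dist` * distance (per um) + `w_angle` * angular deviation (per
#'   radian) + `w_intensity` * (1 - mean normalized intensity along the
#'   straight path).
#' @param merge_branch_px degree->=3 skeleton pixels closer than this merge
#'   into a single branch point (choice).
#' @return list of class `tracer_config`.
#' @export
tracer_config <- function(tophat_radius_px = 8L, gabor_orientations = 8L,
                          gabor_wavelengths_px = c(8, 16),
                          gabor_sigma_ratio = 0.55,
                          threshold = 0.55, nms = FALSE,
                          classifier = "threshold",
                          strict_classifier = FALSE,
                          min_segment_px = 10L, spur_px = 8L,
                          max_gap_um = 25, w_dist = 1, w_angle = 0.5,
                          w_intensity = 20, merge_branch_px = 3) {
  stopifnot(gabor_orientations >= 4, max_gap_um > 0)
  structure(list(tophat_radius_px = as.integer(tophat_radius_px),
                 gabor_orientations = as.integer(gabor_orientations),
                 gabor_wavelengths_px = gabor_wavelengths_px,
                 gabor_sigma_ratio = gabor_sigma_ratio,
                 threshold = threshold, nms = isTRUE(nms),
                 classifier = classifier,
                 strict_classifier = isTRUE(strict_classifier),
                 min_segment_px = as.integer(min_segment_px),
                 spur_px = as.integer(spur_px), max_gap_um = max_gap_um,
                 w_dist = w_dist, w_angle = w_angle,
                 w_intensity = w_intensity,
                 merge_branch_px = merge_branch_px),
            class = "tracer_config")
}

#' Full pipeline configuration
#'
#' @param alignment an [alignment_config()].
#' @param tracer a [tracer_config()].
#' @param tissue_model optional pre-trained [train_tissue_model()] model;
#'   when `NULL`, `run_eye()` trains one on synthetic textures.
#' @param skip_filter bypass the tissue filter (input known to be pure
#'   SBNP).
#' @param whorl_diameters_um whorl region diameters analysed (micrometres).
#' @return list of class `sbnp_config`.
#' @export
sbnp_config <- function(alignment = alignment_config(),
                        tracer = tracer_config(),
                        tissue_model = NULL, skip_filter = FALSE,
                        whorl_diameters_um = c(800, 400)) {
  structure(list(alignment = alignment, tracer = tracer,
                 tissue_model = tissue_model,
                 skip_filter = isTRUE(skip_filter),
                 whorl_diameters_um = whorl_diameters_um),
            class = "sbnp_config")
}
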