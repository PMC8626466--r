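# Tissue classification: epithelium / SBNP / stroma frame filtering before
# mosaicking. A bag-of-visual-words-style descriptor (grid-sampled local
# patch statistics quantized against a small learned vocabulary) feeds
# one-vs-rest support vector machines.

#' Texture descriptor configuration
#'
#' @param grid patches per side; a frame is divided into `grid x grid`
#'   patches.
#' @param vocab_size size of the learned patch-statistics vocabulary
#'   (k-means centres).
#' @return list of class `texture_config`.
#' @export
texture_config <- function(grid = 8L, vocab_size = 12L) {
  structure(list(grid = as.integer(grid), vocab_size = as.integer(vocab_size)),
            class = "texture_config")
}

# per-patch local-contrast descriptors: sd, mean |gradient|, robust range,
# bright-blob fraction relative to the patch median. All are invariant to
# global additive intensity shifts.
patch_descriptors <- function(img, grid) {
  H <- nrow(img); W <- ncol(img)
  rb <- floor(seq(0, H, length.out = grid + 1))
  cb <- floor(seq(0, W, length.out = grid + 1))
  out <- matrix(0, grid * grid, 4)
  k <- 0
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      p <- img[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1], drop = FALSE]
      g <- abs(p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])
      q <- quantile(p, c(0.05, 0.5, 0.95), names = FALSE)
      k <- k + 1
      out[k, ] <- c(sd(p), mean(g), q[3] - q[1],
                    mean(p > q[2] + 25))
    }
  }
  colnames(out) <- c("sd", "grad", "range", "bright")
  out
}

#' Extract a fixed-length texture feature vector from a frame
#'
#' Patch descriptors (local contrast statistics on a regular grid) are
#' summarized into a fixed-length vector: mean, standard deviation and
#' quartiles of each descriptor over the patches, plus — when a trained
#' vocabulary is supplied — the normalized histogram of nearest-vocabulary
#' assignments of the patches (the bag-of-visual-words part).
#'
#' @param frame an `ivcm_frame` or numeric grayscale matrix.
#' @param config a [texture_config()].
#' @param vocab optional vocabulary matrix (k-means centres of patch
#'   descriptors) as stored in a trained tissue model.
#' @return named numeric vector of fixed length.
#' @export
extract_texture_features <- function(frame, config = texture_config(),
                                     vocab = NULL) {
  img <- if (inherits(frame, "ivcm_frame")) frame$image else frame
  if (!is.matrix(img) || !is.numeric(img))
    stop("frame must be a single-channel grayscale image", call. = FALSE)
  d <- patch_descriptors(img, config$grid)
  summ <- unlist(lapply(seq_len(ncol(d)), function(j) {
    v <- d[, j]
    c(mean = mean(v), sd = sd(v),
      q25 = quantile(v, 0.25, names = FALSE),
      q75 = quantile(v, 0.75, names = FALSE))
  }))
  names(summ) <- as.vector(outer(c("mean", "sd", "q25", "q75"),
                                 colnames(d), function(a, b)
                                   paste(b, a, sep = "_")))
  if (!is.null(vocab)) {
    a <- vocab_assign(d, vocab)
    h <- tabulate(a, nrow(vocab)) / nrow(d)
    names(h) <- paste0("word_", seq_len(nrow(vocab)))
    summ <- c(summ, h)
  }
  summ
}

vocab_assign <- function(d, vocab) {
  # nearest centre in the vocabulary's standardized space
  ctr <- attr(vocab, "center"); scl <- attr(vocab, "scale")
  ds <- sweep(sweep(d, 2, ctr), 2, scl, "/")
  d2 <- outer(rowSums(ds^2), rowSums(vocab^2), "+") -
    2 * ds %*% t(vocab)
  max.col(-d2, ties.method = "first")
}

#' Train the tissue classification model
#'
#' Learns the patch-statistics vocabulary (k-means) from the training
#' frames, extracts bag-of-visual-words feature vectors, and fits one
#' linear support vector machine per class (one-vs-rest). Prediction takes
#' the class with the largest decision value, or `"unknown"` when all
#' decision values fall below `unknown_margin`.
#'
#' @param frames list of `ivcm_frame` (or matrices).
#' @param labels character vector of true labels (`"epithelium"`,
#'   `"sbnp"`, `"stroma"`), one per frame.
#' @param config a [texture_config()].
#' @param seed integer seed (k-means initialization).
#' @param unknown_margin decision-value margin below which a frame is
#'   labelled `"unknown"`; `NULL` (default) always assigns the argmax.
#' @return an object of class `tissue_model`.
#' @export
train_tissue_model <- function(frames, labels, config = texture_config(),
                               seed = 1, unknown_margin = NULL) {
  labels <- as.character(labels)
  classes <- c("epithelium", "sbnp", "stroma")
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0))
    stop("insufficient training data: all three tissue classes ",
         "(epithelium, sbnp, stroma) must be present", call. = FALSE)
  if (any(counts < 10))
    stop("insufficient training data: at least 10 frames per class required",
         call. = FALSE)
  imgs <- lapply(frames, function(f)
    if (inherits(f, "ivcm_frame")) f$image else f)

  set.seed(as.integer(seed))
  patches <- do.call(rbind, lapply(imgs, patch_descriptors,
                                   grid = config$grid))
  ctr <- colMeans(patches)
  scl <- apply(patches, 2, sd); scl[scl == 0] <- 1
  ps <- sweep(sweep(patches, 2, ctr), 2, scl, "/")
  km <- stats::kmeans(ps, centers = config$vocab_size, nstart = 5,
                      iter.max = 50)
  vocab <- km$centers
  attr(vocab, "center") <- ctr
  attr(vocab, "scale") <- scl

  X <- t(vapply(imgs, extract_texture_features, config = config,
                vocab = vocab,
                FUN.VALUE = numeric(16 + config$vocab_size)))
  fc <- colMeans(X)
  fs <- apply(X, 2, sd); fs[fs == 0] <- 1
  Xs <- sweep(sweep(X, 2, fc), 2, fs, "/")

  svms <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, "yes", "no"), levels = c("yes", "no"))
    e1071::svm(Xs, y, kernel = "linear", scale = FALSE, probability = FALSE)
  })
  names(svms) <- classes

  model <- structure(list(vocab = vocab, svms = svms, classes = classes,
                          feat_center = fc, feat_scale = fs,
                          config = config, seed = as.integer(seed),
                          unknown_margin = unknown_margin,
                          n_train = as.integer(counts)),
                     class = "tissue_model")
  model$train_accuracy <-
    mean(predict_tissue(model, frames)$label == labels)
  model
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf(
    "<tissue_model: %d-word vocabulary, 1-vs-rest linear SVMs, train acc %.3f>\n",
    nrow(x$vocab), x$train_accuracy))
  invisible(x)
}

#' Predict tissue classes for a frame sequence
#'
#' @param model a [train_tissue_model()] model.
#' @param frames list of `ivcm_frame` or matrices.
#' @return tibble: `index`, predicted `label`, `score` (winning decision
#'   value).
#' @export
predict_tissue <- function(model, frames) {
  X <- t(vapply(frames, extract_texture_features, config = model$config,
                vocab = model$vocab,
                FUN.VALUE = numeric(length(model$feat_center))))
  Xs <- sweep(sweep(X, 2, model$feat_center), 2, model$feat_scale, "/")
  dv <- vapply(model$classes, function(cl) {
    p <- predict(model$svms[[cl]], Xs, decision.values = TRUE)
    d <- attr(p, "decision.values")
    # orient so positive means "this class"
    if (colnames(d)[1] == "no/yes") -d[, 1] else d[, 1]
  }, numeric(nrow(Xs)))
  dv <- matrix(dv, nrow = nrow(Xs))
  best <- max.col(dv, ties.method = "first")
  score <- dv[cbind(seq_len(nrow(dv)), best)]
  label <- model$classes[best]
  if (!is.null(model$unknown_margin))
    label[score < model$unknown_margin] <- "unknown"
  tibble::tibble(index = seq_along(frames), label = label, score = score)
}

#' Filter a frame sequence down to SBNP frames
#'
#' @param frames list of `ivcm_frame`.
#' @param model a trained [train_tissue_model()] model.
#' @return list with `frames` (the kept SBNP frames, original acquisition
#'   indices preserved in each frame's `index`) and `report` (tibble with
#'   per-frame predicted `label`, `score` and `kept`).
#' @export
filter_sbnp <- function(frames, model) {
  if (length(frames) == 0)
    stop("empty frame sequence", call. = FALSE)
  if (!inherits(model, "tissue_model"))
    stop("model must be a trained tissue_model", call. = FALSE)
  rep <- predict_tissue(model, frames)
  rep$kept <- rep$label == "sbnp"
  list(frames = frames[rep$kept], report = rep)
}

#' Generate a labelled synthetic tissue-frame training/test set
#'
#' SBNP frames are noisy crops of a plexus phantom; epithelium and stroma
#' frames come from [make_nonsbnp_frame()].
#'
#' @param n_per_class frames per class.
#' @param seed integer seed.
#' @param plexus optional `sbnp_plexus` to crop SBNP frames from (a small
#'   one is generated when `NULL`).
#' @param frame_px frame size.
#' @param noise_sd additive noise on SBNP crops.
#' @return list with `frames` and `labels`.
#' @export
synth_tissue_frames <- function(n_per_class = 30, seed = 1, plexus = NULL,
                                frame_px = 384L, noise_sd = 4) {
  if (is.null(plexus))
    plexus <- generate_plexus(canvas_um = c(1500, 1500), fiber_count = 12,
                              whorl_turns = 2.5,
                              seed = derive_seed(seed, 77L))
  set.seed(as.integer(seed))
  H <- nrow(plexus$image); W <- ncol(plexus$image)
  wc <- round(plexus$whorl_center_um / plexus$um_per_px)
  frames <- list(); labels <- character(0)
  for (k in seq_len(n_per_class)) {
    if (runif(1) < 0.3) {
      # whorl-centred crops: the spiral bundle is a distinct SBNP texture
      # that uniform sampling would rarely include
      r0 <- min(max(1, wc[2] - frame_px %/% 2 + sample(-40:40, 1)),
                H - frame_px)
      c0 <- min(max(1, wc[1] - frame_px %/% 2 + sample(-40:40, 1)),
                W - frame_px)
    } else {
      r0 <- sample.int(H - frame_px, 1)
      c0 <- sample.int(W - frame_px, 1)
    }
    img <- plexus$image[r0:(r0 + frame_px - 1), c0:(c0 + frame_px - 1)]
    img <- round(clip8(img + matrix(rnorm(frame_px^2, 0, noise_sd),
                                    frame_px, frame_px)))
    frames[[length(frames) + 1]] <- ivcm_frame(img, label = "sbnp")
    labels <- c(labels, "sbnp")
  }
  for (kind in c("epithelium", "stroma")) {
    for (k in seq_len(n_per_class)) {
      frames[[length(frames) + 1]] <-
        make_nonsbnp_frame(kind, frame_px,
                           seed = derive_seed(seed, 1000L + k +
                                                1000L * (kind == "stroma")))
      labels <- c(labels, kind)
    }
  }
  list(frames = frames, labels = labels)
}

#' Save / load a tissue model
#'
#' The model is persisted to a single versioned file; loading verifies
#' the format version.
#'
#' @param model a [train_tissue_model()] model.
#' @param path file path.
#' @return `path` (save) or the restored `tissue_model` (load).
#' @export
save_tissue_model <- function(model, path) {
  stopifnot(inherits(model, "tissue_model"))
  saveRDS(list(format = "sbnpmosaic_tissue_model", version = 1L,
               model = model), path)
  invisible(path)
}

#' @rdname save_tissue_model
#' @export
load_tissue_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sbnpmosaic_tissue_model"))
    stop("not a tissue model file: ", path, call. = FALSE)
  obj$model
}
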