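# End-to-end per-eye and cohort orchestration: tissue filtering,
# registration, global alignment, mosaic rendering, nerve tracing and
# metric extraction, with per-stage wall-time logging and the dataset's
# file naming conventions (`<subjectID>_<RE|LE>.tif`, secondary mosaics
# suffixed `_m2`, `_m3`, ...).

stage_time <- function(timings, stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e)
    stop(sprintf("[%s stage] %s", stage, conditionMessage(e)),
         call. = FALSE))
  timings[[stage]] <- proc.time()[["elapsed"]] - t0
  list(value = value, timings = timings)
}

#' Run the full pipeline on one eye
#'
#' Stages: tissue filter (unless `config$skip_filter`), pairwise
#' registration, global alignment, mosaic rendering (largest plus
#' secondary mosaics), nerve tracing on the largest mosaic, and metric
#' extraction. Per-stage wall times are recorded in the result.
#'
#' @param input a folder of numbered TIFF frames (see
#'   [read_eye_folder()]) or a list of `ivcm_frame`.
#' @param config an [sbnp_config()].
#' @param whorl_center_um whorl centre in mosaic micrometre coordinates;
#'   when `NULL` the centre of the largest mosaic is used (the whorl
#'   centre is an input of the method, not detected automatically).
#' @param subject_id,eye identifiers used in output file names; `eye` is
#'   `"RE"` or `"LE"`.
#' @param output_dir when given, the largest mosaic is written as
#'   `<subjectID>_<eye>.tif`, secondary mosaics with `_m2`, `_m3`, ...
#'   suffixes, plus `<subjectID>_<eye>_alignment.csv` and
#'   `<subjectID>_<eye>_metrics.csv`.
#' @return list of class `eye_record`: `subject_id`, `eye`, `metrics`
#'   (one-row tibble), `mosaic` (largest), `other_mosaics`, `graph`,
#'   `filter_report`, `solution`, `timings`, `outputs` (file paths).
#' @export
run_eye <- function(input, config = sbnp_config(), whorl_center_um = NULL,
                    subject_id = "01", eye = c("RE", "LE"),
                    output_dir = NULL) {
  eye <- match.arg(eye)
  timings <- list()

  frames <- if (is.character(input)) read_eye_folder(input) else input
  if (length(frames) < 2)
    stop("[input stage] fewer than 2 readable frames", call. = FALSE)

  filter_report <- NULL
  if (!config$skip_filter) {
    model <- config$tissue_model
    st <- stage_time(timings, "filter", {
      if (is.null(model)) {
        tr <- synth_tissue_frames(n_per_class = 30, seed = 421L,
                                  frame_px = nrow(frames[[1]]$image))
        model <- train_tissue_model(tr$frames, tr$labels, seed = 421L)
      }
      filter_sbnp(frames, model)
    })
    timings <- st$timings
    filter_report <- st$value$report
    frames <- st$value$frames
    if (length(frames) < 2)
      stop("[filter stage] fewer than 2 SBNP frames after tissue filtering",
           call. = FALSE)
  }

  st <- stage_time(timings, "register",
                   register_pairs(frames, config$alignment))
  timings <- st$timings; pairs <- st$value

  st <- stage_time(timings, "align",
                   solve_alignment(pairs, config$alignment))
  timings <- st$timings; solution <- st$value

  st <- stage_time(timings, "render", largest_mosaic(frames, solution))
  timings <- st$timings
  mosaic <- st$value$largest
  others <- st$value$others

  st <- stage_time(timings, "trace", trace_nerves(mosaic, config$tracer))
  timings <- st$timings; graph <- st$value

  if (is.null(whorl_center_um))
    whorl_center_um <- c(ncol(mosaic$image), nrow(mosaic$image)) / 2 *
      mosaic$um_per_px
  st <- stage_time(timings, "metrics",
                   compute_metrics(mosaic, graph, whorl_center_um,
                                   config$whorl_diameters_um))
  timings <- st$timings
  metrics <- dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id, eye = eye), st$value)

  outputs <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(output_dir, paste0(subject_id, "_", eye))
    tiff::writeTIFF(round(clip8(mosaic$image)) / 255,
                    paste0(stem, ".tif"), bits.per.sample = 8L,
                    compression = "none")
    outputs <- paste0(stem, ".tif")
    for (k in seq_along(others)) {
      f <- paste0(stem, "_m", k + 1, ".tif")
      tiff::writeTIFF(round(clip8(others[[k]]$image)) / 255, f,
                      bits.per.sample = 8L, compression = "none")
      outputs <- c(outputs, f)
    }
    write.csv(as.data.frame(solution),
              paste0(stem, "_alignment.csv"), row.names = FALSE)
    write.csv(as.data.frame(metrics),
              paste0(stem, "_metrics.csv"), row.names = FALSE)
    outputs <- c(outputs, paste0(stem, "_alignment.csv"),
                 paste0(stem, "_metrics.csv"))
  }

  structure(list(subject_id = subject_id, eye = eye, metrics = metrics,
                 mosaic = mosaic, other_mosaics = others, graph = graph,
                 filter_report = filter_report, solution = solution,
                 timings = unlist(timings), outputs = outputs),
            class = "eye_record")
}

#' @export
print.eye_record <- function(x, ...) {
  cat(sprintf("<eye_record %s_%s: %.2f mm2, EF %.1f, mCNFL %.2f mm/mm2>\n",
              x$subject_id, x$eye, x$metrics$area_mm2,
              x$metrics$enhancement_factor, x$metrics$mcnfl))
  invisible(x)
}

#' Run the pipeline over a cohort manifest
#'
#' @param manifest data frame (or CSV path) with columns `subject_id`,
#'   `eye`, `path`, and optionally `whorl_x_um`, `whorl_y_um`.
#' @param config an [sbnp_config()].
#' @param observer_table optional long observer cell-density table (or CSV
#'   path) with columns `mosaic_id`, `observer`, `cell_type`, `density`;
#'   when given, a Bland-Altman agreement report is attached.
#' @param output_dir optional output folder passed to [run_eye()].
#' @return list of class `cohort_result`: `metrics` (tibble, one row per
#'   successful eye), `failures` (tibble of failed eyes with messages),
#'   `agreement` (tibble or `NULL`).
#' @export
run_cohort <- function(manifest, config = sbnp_config(),
                       observer_table = NULL, output_dir = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest)
  manifest <- tibble::as_tibble(manifest)
  rows <- list(); fails <- list()
  for (k in seq_len(nrow(manifest))) {
    m <- manifest[k, ]
    wc <- if (all(c("whorl_x_um", "whorl_y_um") %in% names(m)) &&
              is.finite(m$whorl_x_um) && is.finite(m$whorl_y_um))
      c(m$whorl_x_um, m$whorl_y_um) else NULL
    res <- tryCatch(
      run_eye(m$path, config, whorl_center_um = wc,
              subject_id = as.character(m$subject_id), eye = m$eye,
              output_dir = output_dir),
      error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("eye %s_%s failed: %s", m$subject_id, m$eye,
                      conditionMessage(res)))
      fails[[length(fails) + 1]] <-
        tibble::tibble(subject_id = as.character(m$subject_id),
                       eye = m$eye, error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res$metrics
    }
  }
  if (length(rows) == 0)
    stop("all eyes failed", call. = FALSE)
  agreement <- NULL
  if (!is.null(observer_table)) {
    if (is.character(observer_table))
      observer_table <- read.csv(observer_table)
    agreement <- agreement_report(observer_table)
  }
  structure(list(metrics = dplyr::bind_rows(rows),
                 failures = dplyr::bind_rows(fails),
                 agreement = agreement),
            class = "cohort_result")
}
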