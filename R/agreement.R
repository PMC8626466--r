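# Bland-Altman inter-observer agreement and observer/eye averaging for
# inflammatory (dendritic) cell density tables.

#' Bland-Altman agreement between two observers
#'
#' Differences `d = x - y` are summarized by their mean, sample standard
#' deviation (n - 1 denominator) and the 95% limits of agreement
#' `mean +/- 1.96 * SD`, together with Pearson's correlation of the paired
#' values.
#'
#' @param x,y paired density vectors (observer 1 and observer 2), equal
#'   length >= 2.
#' @return object of class `bland_altman`: list with `mean_diff`,
#'   `sd_diff`, `loa_lower`, `loa_upper`, `pearson_r` (`NA` with a warning
#'   when either input has zero variance), `n`, and the input vectors.
#' @examples
#' ba <- bland_altman(c(10, 12, 9, 14), c(11, 11, 10, 12))
#' glance(ba)
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must be paired vectors of equal length", call. = FALSE)
  if (length(x) < 2)
    stop("at least 2 paired observations are required", call. = FALSE)
  d <- x - y
  m <- mean(d)
  s <- sd(d)
  r <- if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance in one observer's values; Pearson's r undefined")
    NA_real_
  } else cor(x, y)
  structure(list(mean_diff = m, sd_diff = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 pearson_r = r, n = length(x), x = x, y = y),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman: n %d, mean diff %.2f, SD %.2f, 95%% LOA [%.2f, %.2f], r %s>\n",
    x$n, x$mean_diff, x$sd_diff, x$loa_lower, x$loa_upper,
    ifelse(is.na(x$pearson_r), "NA", sprintf("%.2f", x$pearson_r))))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a Bland-Altman analysis
#' @param x a [bland_altman()] object.
#' @param ... unused.
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 pearson_r = x$pearson_r, n = x$n)
}

#' Per-pair tidy table of a Bland-Altman analysis
#' @param x a [bland_altman()] object.
#' @param ... unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  obj <- x
  tibble::tibble(pair = seq_len(obj$n), x = obj$x, y = obj$y,
                 mean = (obj$x + obj$y) / 2, diff = obj$x - obj$y)
}

#' Table-style agreement report across cell types
#'
#' Runs [bland_altman()] per cell type on a long observer table and lays
#' the five agreement statistics out one row per cell type, optionally
#' rounded to one decimal (half away from zero) for presentation.
#'
#' @param table tibble/data.frame with columns `mosaic_id`, `observer`
#'   (exactly two distinct values), `cell_type`, `density`.
#' @param round round the statistics to 1 decimal for presentation.
#' @return tibble: `cell_type`, `mean_diff`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `pearson_r`, `n`.
#' @export
agreement_report <- function(table, round = FALSE) {
  obs <- sort(unique(table$observer))
  if (length(obs) != 2)
    stop("agreement report requires exactly two observers", call. = FALSE)
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(table[c("mosaic_id", "observer", "cell_type",
                              "density")]),
    names_from = "observer", values_from = "density")
  out <- wide |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::group_modify(function(df, key) {
      ok <- stats::complete.cases(df[[as.character(obs[1])]],
                                  df[[as.character(obs[2])]])
      glance(bland_altman(df[[as.character(obs[1])]][ok],
                          df[[as.character(obs[2])]][ok]))
    }) |>
    dplyr::ungroup()
  if (round) {
    num <- c("mean_diff", "sd_diff", "loa_lower", "loa_upper", "pearson_r")
    out[num] <- lapply(out[num], round_half_away, digits = 1)
  }
  out
}

#' Average cell densities across observers and eyes
#'
#' Per mosaic, densities are first averaged over observers; per subject,
#' the available eyes are then averaged (a single eye contributes its own
#' value).
#'
#' @param table tibble with columns `mosaic_id`, `observer`, `cell_type`,
#'   `density`.
#' @param eye_map tibble mapping `mosaic_id` to `subject` (and optionally
#'   `eye`).
#' @return tibble: `subject`, `cell_type`, `density`.
#' @export
average_densities <- function(table, eye_map) {
  missing_ids <- setdiff(unique(table$mosaic_id), eye_map$mosaic_id)
  if (length(missing_ids))
    stop("unknown mosaic id(s) in table: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  table |>
    dplyr::group_by(.data$mosaic_id, .data$cell_type) |>
    dplyr::summarise(density = mean(.data$density), .groups = "drop") |>
    dplyr::left_join(eye_map, by = "mosaic_id") |>
    dplyr::group_by(.data$subject, .data$cell_type) |>
    dplyr::summarise(density = mean(.data$density), .groups = "drop")
}
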