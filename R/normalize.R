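#' Cross-time-point normalization of signal matrices
#'
#' Two corrections for global per-time-point effects (antibody efficiency,
#' depth residuals) in peaks-by-time signal matrices:
#'
#' * **mean normalization** — divide each time point by the average signal
#'   over a large reference site set (e.g. the top 40,000 open-chromatin
#'   sites) at that time point;
#' * **ranking normalization** — a quantile normalization: each time-point
#'   column is replaced by the across-time average of the order statistics at
#'   its within-column ranks, making all columns share one distribution.
#'
#' Matrices travel in long format (`site_id`, `time`, `value`), one value per
#' (site, time).
#'
#' @name normalize
NULL

# long (site_id, time, value) -> numeric matrix sites x times; errors on
# ragged/duplicated cells
long_to_matrix <- function(data) {
  need <- c("site_id", "time", "value")
  if (!all(need %in% names(data))) abort("need columns site_id, time, value")
  wide <- tidyr::pivot_wider(data[, need], names_from = "time",
                             values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(m)) abort("ragged matrix: every site needs a value at every time point")
  rownames(m) <- as.character(wide$site_id)
  storage.mode(m) <- "double"
  m
}

matrix_to_long <- function(m) {
  tibble(
    site_id = rep(rownames(m), times = ncol(m)),
    time = rep(as.numeric(colnames(m)), each = nrow(m)),
    value = as.numeric(m)
  ) |>
    arrange(.data$site_id, .data$time)
}

#' Per-time-point reference profile
#'
#' The mean signal over a reference site set at each time point, the divisor
#' of [mean_normalize()].
#'
#' @param data Long signal tibble (`site_id`, `time`, `value`).
#' @param reference_ids Site ids forming the reference set (default: all).
#' @return Tibble `time`, `reference_mean`.
#' @export
reference_profile <- function(data, reference_ids = NULL) {
  if (!is.null(reference_ids)) {
    data <- data[data$site_id %in% reference_ids, , drop = FALSE]
    if (nrow(data) == 0) abort("no sites left after restricting to reference_ids")
  }
  data |>
    group_by(.data$time) |>
    summarise(reference_mean = mean(.data$value), .groups = "drop")
}

#' Mean normalization against a reference site set
#'
#' Divides every value at time `t` by `reference_mean(t)`. When the reference
#' profile is computed from the same matrix, the reference-set mean is exactly
#' 1 at every time point afterwards, removing any global per-time scaling.
#'
#' @param data Long signal tibble.
#' @param reference A [reference_profile()] tibble (`time`, `reference_mean`);
#'   every time point of `data` must be present with a positive mean.
#' @return Long tibble with normalized `value`.
#' @export
mean_normalize <- function(data, reference) {
  if (!all(c("time", "reference_mean") %in% names(reference))) {
    abort("reference needs columns time, reference_mean")
  }
  missing_t <- setdiff(unique(data$time), reference$time)
  if (length(missing_t) > 0) {
    abort(paste0("reference profile lacks time point(s): ",
                 paste(missing_t, collapse = ", ")))
  }
  bad <- reference$time[reference$reference_mean <= 0]
  if (length(bad) > 0) {
    abort(paste0("non-positive reference mean at time point(s): ",
                 paste(bad, collapse = ", ")))
  }
  data |>
    left_join(reference, by = "time") |>
    mutate(value = .data$value / .data$reference_mean) |>
    select(-"reference_mean")
}

#' Ranking (quantile) normalization across time points
#'
#' Sorts each time-point column, averages the sorted values across columns at
#' each rank, and maps every observation to the rank-average at its
#' within-column rank. Tied values receive the mean of their tied ranks'
#' reference values. Output columns share identical sorted values (hence
#' identical means); within-column rank order is preserved; the operation is
#' idempotent.
#'
#' @param data Long signal tibble (`site_id`, `time`, `value`), complete grid.
#' @return Long tibble with normalized `value`.
#' @export
rank_normalize <- function(data) {
  m <- long_to_matrix(data)
  ref <- rowMeans(matrix(apply(m, 2, sort), nrow = nrow(m)))  # rank averages
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # fractional (tied) ranks interpolate = mean of the tied ranks' refs
    stats::approx(seq_along(ref), ref, xout = r)$y
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m))
  dimnames(out) <- dimnames(m)
  matrix_to_long(out)
}
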