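#' Harmonic (Fourier) rhythm fitting
#'
#' A 24-h rhythm is modeled as the first harmonic
#' `x(t) = m + a * cos(2*pi*t/period) + b * sin(2*pi*t/period)`
#' fitted by least squares. The mesor is `m`, the amplitude
#' `A = sqrt(a^2 + b^2)` (half peak-to-trough), and the phase the clock time
#' of the fitted maximum, `(period / 2*pi) * atan2(b, a) mod period`,
#' reported in Zeitgeber-time hours. Significance of the harmonic is the
#' F-test of the two harmonic terms against the intercept-only model.
#'
#' @name rhythms
NULL

#' Fit the first 24-h harmonic to one circadian series
#'
#' @param times Sample times in hours, strictly increasing, equally spaced;
#'   at least 4 points spanning at least one period.
#' @param values Signal at each time.
#' @param period Period in hours (default 24; a 48-h series is fitted with a
#'   24-h period, i.e. two cycles).
#' @return An object of class `rhythm_fit` with elements `mesor`, `amplitude`,
#'   `phase_zt` (NA when the fitted amplitude is 0), `pvalue`, `period`,
#'   `coefficients` (m, a, b), `times`, `values`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' fourier_fit(seq(2, 22, by = 4), 3 + 2 * cos(2 * pi * (seq(2, 22, by = 4) - 6) / 24))
#' @export
fourier_fit <- function(times, values, period = 24) {
  check_series(times, values)
  f <- harmonic_stats(times, values, period)
  structure(
    c(f, list(period = period, times = times, values = values)),
    class = "rhythm_fit"
  )
}

check_series <- function(times, values) {
  if (length(times) != length(values)) abort("times and values differ in length")
  if (length(times) < 4) abort("need at least 4 time points to fit 3 parameters")
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  gaps <- diff(times)
  if (max(gaps) - min(gaps) > 1e-8 * max(gaps)) abort("times must be equally spaced")
  invisible(TRUE)
}

# closed-form least squares of the first harmonic for one series; shared by
# fourier_fit and the vectorized fit_rhythms
harmonic_stats <- function(times, values, period) {
  X <- cbind(1, cos(2 * pi * times / period), sin(2 * pi * times / period))
  cf <- qr.coef(qr(X), values)
  m <- cf[1]; a <- cf[2]; b <- cf[3]
  amp <- sqrt(a^2 + b^2)
  fitted <- drop(X %*% cf)
  sse <- sum((values - fitted)^2)
  sst <- sum((values - mean(values))^2)
  df2 <- length(values) - 3
  # F-test of the harmonic pair vs intercept-only; undefined for a constant
  # series (no variance to explain)
  pval <- if (sst <= 1e-12 * max(1, mean(values)^2)) {
    NA_real_
  } else if (df2 <= 0) {
    NA_real_
  } else {
    fstat <- ((sst - sse) / 2) / max(sse / df2, .Machine$double.xmin)
    pf(fstat, 2, df2, lower.tail = FALSE)
  }
  phase <- if (amp <= 1e-9 * max(1, abs(m))) NA_real_ else
    ((period / (2 * pi)) * atan2(b, a)) %% period
  list(mesor = unname(m), amplitude = unname(amp), phase_zt = unname(phase),
       pvalue = unname(pval),
       coefficients = c(mesor = unname(m), a = unname(a), b = unname(b)))
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat("Harmonic rhythm fit (period", x$period, "h)\n")
  cat(sprintf("  mesor %.4g  amplitude %.4g  phase ZT%.2f  p = %.3g\n",
              x$mesor, x$amplitude,
              if (is.na(x$phase_zt)) NA else x$phase_zt, x$pvalue))
  invisible(x)
}

#' @rdname fourier_fit
#' @param x,object A `rhythm_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rhythm_fit <- function(x, ...) {
  tibble(
    term = c("mesor", "amplitude", "phase_zt"),
    estimate = c(x$mesor, x$amplitude, x$phase_zt)
  )
}

#' @rdname fourier_fit
#' @exportS3Method generics::glance
glance.rhythm_fit <- function(x, ...) {
  tibble(
    mesor = x$mesor, amplitude = x$amplitude, phase_zt = x$phase_zt,
    p.value = x$pvalue, period = x$period, nobs = length(x$times)
  )
}

#' Fit rhythms across many series at once
#'
#' Data-frame-first companion to [fourier_fit()]: takes a long table of
#' circadian series, averages replicates per time point, and fits every
#' series. Series sharing the same time grid are fitted in one vectorized
#' least-squares solve, so thousands of series are cheap.
#'
#' @param data Long tibble with columns `series_id`, `time`, `value` and
#'   optionally `replicate`.
#' @param period Period in hours (default 24).
#' @return Tibble: `series_id`, `n_time`, `mean_level` (mean of the
#'   time-point means), `mesor`, `amplitude`, `phase_zt`, `pvalue`.
#' @export
fit_rhythms <- function(data, period = 24) {
  need <- c("series_id", "time", "value")
  if (!all(need %in% names(data))) {
    abort("data needs columns series_id, time, value")
  }
  avg <- data |>
    group_by(.data$series_id, .data$time) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    arrange(.data$series_id, .data$time)

  # group series by grid signature so each unique grid is solved once
  grids <- avg |>
    group_by(.data$series_id) |>
    summarise(grid = paste(signif(.data$time, 10), collapse = ","),
              .groups = "drop")
  out <- purrr::map_dfr(split(grids$series_id, grids$grid), function(ids) {
    sub <- avg[avg$series_id %in% ids, , drop = FALSE]
    times <- sort(unique(sub$time))
    check_series(times, times)  # spacing/size checks on the grid
    Y <- matrix(sub$value[order(match(sub$series_id, ids), sub$time)],
                nrow = length(times))
    X <- cbind(1, cos(2 * pi * times / period), sin(2 * pi * times / period))
    cf <- qr.coef(qr(X), Y)                      # 3 x n
    fitted <- X %*% cf
    sse <- colSums((Y - fitted)^2)
    sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
    df2 <- length(times) - 3
    fstat <- ((sst - sse) / 2) / pmax(sse / df2, .Machine$double.xmin)
    pval <- pf(fstat, 2, df2, lower.tail = FALSE)
    pval[sst <= 1e-12 * pmax(1, colMeans(Y)^2)] <- NA_real_
    amp <- sqrt(cf[2, ]^2 + cf[3, ]^2)
    phase <- ((period / (2 * pi)) * atan2(cf[3, ], cf[2, ])) %% period
    phase[amp <= 1e-9 * pmax(1, abs(cf[1, ]))] <- NA_real_
    tibble(
      series_id = ids, n_time = length(times), mean_level = colMeans(Y),
      mesor = cf[1, ], amplitude = amp, phase_zt = phase, pvalue = pval
    )
  })
  arrange(out, .data$series_id)
}

#' Call rhythmicity on circadian series
#'
#' A series is rhythmic when (1) the harmonic F-test p-value is below
#' `alpha`, (2) the fitted peak-to-trough fold change
#' `(mesor + amplitude) / (mesor - amplitude)` is at least `min_fold`
#' (infinite when the fitted trough is non-positive), and (3) the mean level
#' is at least `min_level` (reads/bp). Gates can be disabled by setting them
#' to 0 (`min_fold`, `min_level`) — the p-value criterion alone then controls
#' the type-I error at `alpha`.
#'
#' @inheritParams fit_rhythms
#' @param alpha Significance level for the harmonic F-test (default 0.05).
#' @param min_fold Minimum fitted peak/trough fold change (default 1.5).
#' @param min_level Minimum mean expression level (default 1 read/bp).
#' @return [fit_rhythms()] output plus `fold_change` and `is_rhythmic`.
#' @export
detect_rhythms <- function(data, period = 24, alpha = 0.05, min_fold = 1.5,
                           min_level = 1) {
  fits <- fit_rhythms(data, period = period)
  trough <- fits$mesor - fits$amplitude
  fold <- ifelse(trough <= 0, Inf, (fits$mesor + fits$amplitude) / trough)
  mutate(fits,
         fold_change = fold,
         is_rhythmic = !is.na(.data$pvalue) & .data$pvalue < alpha &
           fold >= min_fold & .data$mean_level >= min_level)
}

#' @rdname detect_rhythms
#' @param times,values A single series, as in [fourier_fit()].
#' @return `detect_rhythm()`: a `rhythm_fit` with added `fold_change` and
#'   `is_rhythmic` elements.
#' @export
detect_rhythm <- function(times, values, period = 24, alpha = 0.05,
                          min_fold = 1.5, min_level = 1) {
  fit <- fourier_fit(times, values, period = period)
  trough <- fit$mesor - fit$amplitude
  fit$fold_change <- if (trough <= 0) Inf else (fit$mesor + fit$amplitude) / trough
  fit$is_rhythmic <- !is.na(fit$pvalue) && fit$pvalue < alpha &&
    fit$fold_change >= min_fold && mean(values) >= min_level
  fit
}

#' Per-replicate extremes of a short circadian rhythm
#'
#' For each series/replicate, the maximum and minimum over the time points —
#' the raw material for comparing rhythm amplitudes between groups by two-way
#' ANOVA (group x extremum).
#'
#' @param data Long tibble with `time`, `value` and any identifying columns
#'   (`series_id`, `replicate`, `group`, ...).
#' @param ... Grouping columns (tidy-select), e.g. `series_id, replicate`.
#' @return Tibble with the grouping columns plus `max_value`, `min_value`.
#' @export
minmax_amplitude <- function(data, ...) {
  if (!"value" %in% names(data)) abort("data needs a 'value' column")
  data |>
    group_by(dplyr::pick(...)) |>
    summarise(max_value = max(.data$value), min_value = min(.data$value),
              .groups = "drop")
}

#' @rdname fourier_fit
#' @exportS3Method ggplot2::autoplot
autoplot.rhythm_fit <- function(object, ...) {
  grid <- seq(min(object$times), max(object$times), length.out = 200)
  cf <- object$coefficients
  curve <- tibble(
    time = grid,
    value = cf["mesor"] + cf["a"] * cos(2 * pi * grid / object$period) +
      cf["b"] * sin(2 * pi * grid / object$period)
  )
  pts <- tibble(time = object$times, value = object$values)
  ggplot2::ggplot(pts, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Zeitgeber time (h)", y = "signal",
      title = sprintf("mesor %.3g, amplitude %.3g, phase ZT%.1f, p = %.3g",
                      object$mesor, object$amplitude, object$phase_zt,
                      object$pvalue)
    ) +
    ggplot2::theme_minimal()
}
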