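#' Run the whole meta-analysis in one seeded, logged call
#'
#' Sequences the stages — co-bound peak intersection, gene assignment,
#' transcriptional-output classification, class counting, fraction reporting,
#' per-gene rhythm fits and (when signal is supplied) the TF variability
#' index — on in-memory tibbles, and optionally writes the report bundle as
#' tab-delimited tables plus a machine-readable manifest. Reruns with the
#' same inputs, config and seed are byte-identical.
#'
#' @param data Named list of inputs: `peaks_a`, `peaks_b` (interval tibbles),
#'   `genes` (gene tibble), `nascent` (long series tibble), optional `mrna`,
#'   optional `signal` (long tibble `site_id`/`window_id`, `time`, `value`
#'   keyed by peak name, for the variability index).
#' @param cfg A [classify_config()]; every threshold actually applied is
#'   echoed in the manifest.
#' @param seed Integer seed recorded in the manifest (the deterministic
#'   stages do not consume randomness; the seed is for provenance and any
#'   control-gene sampling downstream).
#' @param out_dir Optional directory; when given, all tables and
#'   `manifest.json` are written there.
#' @return List of class `circout_run`: `cobound` (intersected peaks),
#'   `classified` (peak table with gene, location, class), `class_counts`,
#'   `fractions` (see [fraction_report()]), `rhythm_fits`, `variability`
#'   (or NULL), `manifest`.
#' @export
run_all <- function(data, cfg = classify_config(), seed = 1L, out_dir = NULL) {
  need <- c("peaks_a", "peaks_b", "genes", "nascent")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("run_all inputs missing: ", paste(miss, collapse = ", ")))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  cobound <- stage("intersect", intersect_peaks(data$peaks_a, data$peaks_b))
  assigned <- stage("assign", assign_peaks(
    cobound, data$genes,
    upstream_bp = cfg$upstream_bp, downstream_bp = cfg$downstream_bp
  ))
  classified <- stage("classify",
                      classify_peaks(assigned, data$nascent, data$mrna, cfg))
  counts <- stage("count", class_counts(classified))
  fractions <- stage("fractions", fraction_report(counts))
  fits <- stage("rhythm", {
    ids <- unique(stats::na.omit(classified$gene_id))
    detect_rhythms(data$nascent[data$nascent$series_id %in% ids, , drop = FALSE],
                   period = cfg$period, alpha = cfg$alpha,
                   min_fold = cfg$min_fold, min_level = cfg$min_level)
  })
  variability <- NULL
  if (!is.null(data$signal)) {
    variability <- stage("varindex", {
      sig <- data$signal
      if ("window_id" %in% names(sig)) sig <- dplyr::rename(sig, site_id = "window_id")
      grouped <- sig |>
        group_by(.data$site_id) |>
        summarise(value = mean(.data$value), .groups = "drop") |>
        inner_join(select(classified, site_id = "name", group = "output_class"),
                   by = "site_id") |>
        filter(!is.na(.data$group))
      glance(variability_index(grouped))
    })
  }
  manifest <- list(
    package = "circout",
    version = as.character(utils::packageVersion("circout")),
    seed = as.integer(seed),
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    n_peaks_a = nrow(data$peaks_a), n_peaks_b = nrow(data$peaks_b),
    n_cobound = nrow(cobound), n_genes = nrow(data$genes),
    n_assigned = sum(!is.na(classified$gene_id)),
    n_intergenic = sum(is.na(classified$gene_id))
  )
  res <- structure(
    list(cobound = cobound, classified = classified, class_counts = counts,
         fractions = fractions, rhythm_fits = fits, variability = variability,
         manifest = manifest),
    class = "circout_run"
  )
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' @export
print.circout_run <- function(x, ...) {
  cat("circout run:", x$manifest$n_cobound, "co-bound peaks,",
      x$manifest$n_assigned, "assigned /", x$manifest$n_intergenic,
      "intergenic\n")
  print(x$class_counts)
  print(x$fractions)
  invisible(x)
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f), progress = FALSE)
  w(res$classified, "classified_peaks.tsv")
  w(res$class_counts, "class_counts.tsv")
  w(res$fractions, "fractions.tsv")
  w(res$rhythm_fits, "rhythm_fits.tsv")
  if (!is.null(res$variability)) w(res$variability, "variability_index.tsv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

# percentages are reported rounded half-up, matching conventional rounding
# of headline fractions
round_half_up <- function(x) floor(x + 0.5)

#' Headline fractions from output-class counts
#'
#' From the four headline class counts: the rhythmic fraction
#' `(RIN_PHI + RO_PHI) / (RIN_PHI + RO_PHI + AR + NE)` of analyzed peaks, and
#' the out-of-phase fraction `RO_PHI / (RIN_PHI + RO_PHI)` of the rhythmic
#' ones, each also as a half-up-rounded integer percentage.
#'
#' @param counts A [class_counts()] tibble (`output_class`, `n`) or a named
#'   numeric vector with entries RIN_PHI, RO_PHI, AR, NE.
#' @return One-row tibble: `rhythmic_fraction`, `out_of_phase_fraction`,
#'   `rhythmic_pct`, `out_of_phase_pct`.
#' @export
fraction_report <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$n, as.character(counts$output_class))
  }
  need <- c("RIN_PHI", "RO_PHI", "AR", "NE")
  if (!all(need %in% names(counts))) {
    abort(paste0("counts must include ", paste(need, collapse = ", ")))
  }
  counts <- counts[need]
  rhythmic_n <- counts[["RIN_PHI"]] + counts[["RO_PHI"]]
  total <- sum(counts)
  if (total == 0) abort("no peaks in the four headline classes")
  if (rhythmic_n == 0) {
    abort("no rhythmic peaks: out-of-phase fraction undefined")
  }
  tibble(
    rhythmic_fraction = rhythmic_n / total,
    out_of_phase_fraction = counts[["RO_PHI"]] / rhythmic_n,
    rhythmic_pct = round_half_up(100 * rhythmic_n / total),
    out_of_phase_pct = round_half_up(100 * counts[["RO_PHI"]] / rhythmic_n)
  )
}

#' Bar chart of output-class counts
#'
#' @param counts A [class_counts()] tibble.
#' @return A ggplot.
#' @export
plot_class_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(.data$output_class, .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", .data$pct)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "peaks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Phase histogram of rhythmic series
#'
#' @param fits A [detect_rhythms()] tibble.
#' @param binwidth Histogram bin width in hours.
#' @return A ggplot of fitted peak phases of the rhythmic series.
#' @export
plot_phase_distribution <- function(fits, binwidth = 1) {
  rh <- fits[fits$is_rhythmic & !is.na(fits$phase_zt), , drop = FALSE]
  ggplot2::ggplot(rh, ggplot2::aes(.data$phase_zt)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = seq(0, 24, by = 4)) +
    ggplot2::labs(x = "phase of fitted maximum (ZT h)", y = "series") +
    ggplot2::theme_minimal()
}
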