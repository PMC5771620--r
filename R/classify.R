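#' Transcriptional-output classification of TF-bound peaks
#'
#' Each peak assigned to a gene inherits the gene's transcriptional output,
#' decided from the gene's nascent-RNA and mRNA circadian series:
#'
#' * `NO_SIGNAL` — no expression record for the gene;
#' * `NE` (not expressed) — mean nascent signal over the samples below
#'   `ne_threshold` (1 read/bp);
#' * `LOW_EXPRESSION` — above the NE threshold but below the expression floor
#'   required to test rhythmicity;
#' * `RIN_PHI` — nascent transcription rhythmic with fitted peak phase inside
#'   the in-phase window (ZT02–ZT12, when clock-TF DNA binding peaks);
#' * `RO_PHI` — nascent transcription rhythmic, peak phase outside that
#'   window;
#' * `POST_TRANSCRIPTIONAL` — nascent arrhythmic but mRNA rhythmic (a guard
#'   against false arrhythmic calls);
#' * `AR` — nascent arrhythmic and mRNA not rhythmic.
#'
#' The seven classes are mutually exclusive and exhaustive over assigned
#' peaks.
#'
#' @name classify
NULL

output_classes <- function() {
  c("RIN_PHI", "RO_PHI", "AR", "NE", "POST_TRANSCRIPTIONAL",
    "LOW_EXPRESSION", "NO_SIGNAL")
}

#' Classification thresholds
#'
#' All tunables of the output classification in one list: the gene-assignment
#' windows, the not-expressed threshold, the in-phase window, and the
#' rhythm-call parameters (see [detect_rhythms()]).
#'
#' @param upstream_bp,downstream_bp Gene assignment window (bp).
#' @param ne_threshold Mean nascent level (reads/bp) below which a gene is
#'   called not expressed (default 1).
#' @param phase_window In-phase window `[lo, hi)` in ZT hours (default
#'   `c(2, 12)`).
#' @param alpha,min_fold,min_level Rhythm-call thresholds; `min_level` doubles
#'   as the expression floor below which rhythmicity is not tested
#'   (`LOW_EXPRESSION`).
#' @param period Fitting period, hours.
#' @return Named list of class `circout_config`.
#' @export
classify_config <- function(upstream_bp = 10000, downstream_bp = 1000,
                            ne_threshold = 1, phase_window = c(2, 12),
                            alpha = 0.05, min_fold = 1.5, min_level = 1,
                            period = 24) {
  if (length(phase_window) != 2 || phase_window[1] >= phase_window[2]) {
    abort("phase_window must be c(lo, hi) with lo < hi")
  }
  if (ne_threshold < 0 || min_level < 0) abort("thresholds must be non-negative")
  structure(
    list(upstream_bp = upstream_bp, downstream_bp = downstream_bp,
         ne_threshold = ne_threshold, phase_window = phase_window,
         alpha = alpha, min_fold = min_fold, min_level = min_level,
         period = period),
    class = "circout_config"
  )
}

#' @export
print.circout_config <- function(x, ...) {
  cat("Transcriptional-output classification config:\n")
  for (nm in names(x)) cat(sprintf("  %-13s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

#' Classify assigned peaks by their target gene's transcriptional output
#'
#' Applies the output-class decision tree (see [classify]) to every assigned
#' peak. Rhythm calls are made on the replicate-averaged nascent series with
#' [detect_rhythms()]; the mRNA series is consulted only for genes whose
#' nascent signal is testable but arrhythmic.
#'
#' @param assignments Output of [assign_peaks()] (peaks with `gene_id`);
#'   intergenic peaks pass through with class `NA`.
#' @param nascent Long tibble of nascent-RNA series: `series_id` (gene id),
#'   `time`, `value`, optional `replicate`. 12 points x 4 h over 48 h in the
#'   reference design.
#' @param mrna Same layout for the mRNA series; may omit genes.
#' @param cfg A [classify_config()].
#' @return `assignments` plus `mean_nascent_level`, `nascent_phase`,
#'   `nascent_pvalue`, `output_class` (factor over the seven classes, NA for
#'   intergenic peaks).
#' @export
classify_peaks <- function(assignments, nascent, mrna = NULL,
                           cfg = classify_config()) {
  if (!"gene_id" %in% names(assignments)) {
    abort("assignments must come from assign_peaks() (need gene_id)")
  }
  gene_class <- classify_genes(unique(stats::na.omit(assignments$gene_id)),
                               nascent, mrna, cfg)
  out <- left_join(assignments, gene_class, by = "gene_id")
  mutate(out, output_class = factor(.data$output_class, levels = output_classes()))
}

# per-gene decision tree; returns one row per requested gene id
classify_genes <- function(gene_ids, nascent, mrna, cfg) {
  if (length(gene_ids) == 0) {
    return(tibble(gene_id = character(), mean_nascent_level = numeric(),
                  nascent_phase = numeric(), nascent_pvalue = numeric(),
                  output_class = character()))
  }
  check_grid_consistency(nascent, mrna)
  nas <- nascent[nascent$series_id %in% gene_ids, , drop = FALSE]
  fits <- if (nrow(nas) > 0) {
    detect_rhythms(nas, period = cfg$period, alpha = cfg$alpha,
                   min_fold = cfg$min_fold, min_level = cfg$min_level)
  } else {
    tibble(series_id = character(), mean_level = numeric(), phase_zt = numeric(),
           pvalue = numeric(), is_rhythmic = logical())
  }
  mrna_rhythmic <- character(0)
  if (!is.null(mrna) && nrow(mrna) > 0) {
    mfits <- detect_rhythms(mrna[mrna$series_id %in% gene_ids, , drop = FALSE],
                            period = cfg$period, alpha = cfg$alpha,
                            min_fold = cfg$min_fold, min_level = cfg$min_level)
    mrna_rhythmic <- mfits$series_id[mfits$is_rhythmic]
  }
  lo <- cfg$phase_window[1]; hi <- cfg$phase_window[2]
  tb <- left_join(tibble(gene_id = gene_ids),
                  dplyr::rename(fits, gene_id = "series_id"), by = "gene_id")
  mutate(
    tb,
    output_class = dplyr::case_when(
      is.na(.data$mean_level) ~ "NO_SIGNAL",
      .data$mean_level < cfg$ne_threshold ~ "NE",
      .data$is_rhythmic & !is.na(.data$phase_zt) &
        .data$phase_zt >= lo & .data$phase_zt < hi ~ "RIN_PHI",
      .data$is_rhythmic ~ "RO_PHI",
      .data$mean_level < cfg$min_level ~ "LOW_EXPRESSION",
      .data$gene_id %in% mrna_rhythmic ~ "POST_TRANSCRIPTIONAL",
      TRUE ~ "AR"
    )
  ) |>
    select("gene_id", mean_nascent_level = "mean_level",
           nascent_phase = "phase_zt", nascent_pvalue = "pvalue",
           "output_class")
}

check_grid_consistency <- function(nascent, mrna) {
  if (is.null(mrna) || nrow(mrna) == 0 || nrow(nascent) == 0) return(invisible(TRUE))
  shared <- intersect(unique(nascent$series_id), unique(mrna$series_id))
  if (length(shared) == 0) return(invisible(TRUE))
  g <- shared[1]
  tn <- sort(unique(nascent$time[nascent$series_id == g]))
  tm <- sort(unique(mrna$time[mrna$series_id == g]))
  if (length(tn) != length(tm) || any(abs(tn - tm) > 1e-8)) {
    abort("nascent and mRNA series are on inconsistent time grids")
  }
  invisible(TRUE)
}

#' Tabulate output classes
#'
#' Counts (and percentages) of peaks per output class, optionally also broken
#' down by genomic location category. Counts always sum to the number of
#' classified peaks.
#'
#' @param classified Output of [classify_peaks()].
#' @param by_location Also cross-tabulate with the `location` column.
#' @return Tibble `output_class`, (`location`,) `n`, `pct`; every class level
#'   appears, zero-filled.
#' @export
class_counts <- function(classified, by_location = FALSE) {
  keep <- classified[!is.na(classified$output_class), , drop = FALSE]
  grp <- if (by_location) c("output_class", "location") else "output_class"
  out <- keep |>
    dplyr::count(across(dplyr::all_of(grp)), .drop = FALSE, name = "n") |>
    mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else 0)
  as_tibble(out)
}

#' Expression-matched control genes for each output class
#'
#' Samples `n_per_class` genes per output class from the non-target pool,
#' requiring that control expression levels are statistically
#' indistinguishable from target levels (Kruskal-Wallis p >= 0.05 within the
#' class); resamples up to `max_retry` times before failing for that class.
#'
#' @param gene_levels Tibble `gene_id`, `output_class`, `level` for the whole
#'   genome (targets and non-targets).
#' @param target_gene_ids Character vector of TF-target gene ids to exclude
#'   from the pool and to match against.
#' @param classes Classes to build controls for (default the four headline
#'   classes).
#' @param n_per_class Controls per class (default 125).
#' @param alpha Acceptance level for the match test (p >= alpha accepts).
#' @param max_retry Resampling attempts per class.
#' @param seed Optional integer; when given, sampling is reproducible.
#' @return Tibble of sampled control genes: `gene_id`, `output_class`,
#'   `level`, `match_pvalue`, `attempt`.
#' @export
select_matched_controls <- function(gene_levels, target_gene_ids,
                                    classes = c("RIN_PHI", "RO_PHI", "AR", "NE"),
                                    n_per_class = 125, alpha = 0.05,
                                    max_retry = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  need <- c("gene_id", "output_class", "level")
  if (!all(need %in% names(gene_levels))) {
    abort("gene_levels needs columns gene_id, output_class, level")
  }
  purrr::map_dfr(classes, function(cl) {
    pool <- gene_levels[gene_levels$output_class == cl &
                          !gene_levels$gene_id %in% target_gene_ids, , drop = FALSE]
    target <- gene_levels[gene_levels$output_class == cl &
                            gene_levels$gene_id %in% target_gene_ids, , drop = FALSE]
    if (nrow(pool) < n_per_class) {
      abort(paste0("control pool exhausted for class ", cl, " (",
                   nrow(pool), " < ", n_per_class, ")"))
    }
    if (nrow(target) == 0) abort(paste0("no target genes in class ", cl))
    for (attempt in seq_len(max_retry)) {
      take <- pool[sample.int(nrow(pool), n_per_class), , drop = FALSE]
      p <- kruskal.test(
        list(target = target$level, control = take$level)
      )$p.value
      if (is.na(p)) p <- 1  # all-tied levels: indistinguishable by construction
      if (p >= alpha) {
        return(mutate(take, match_pvalue = p, attempt = attempt))
      }
    }
    abort(paste0("no expression-matched control sample found for class ", cl,
                 " within ", max_retry, " attempts"))
  })
}
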