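#' Read-level signal extraction at peak-centered windows
#'
#' Reads are interval tibbles with a `strand` column; a read set is a reads
#' tibble plus a library size (total uniquely mapped, deduplicated reads).
#' Signal is reported throughout as reads/bp per 1e8 reads, the unit used for
#' cross-dataset comparison of ChIP-Seq, MNase-Seq and GRO-Seq coverage.
#'
#' @name signal
NULL

#' Assay-specific default window half-widths (bp)
#'
#' Transcription factors/coactivators/Pol II +/-250 bp, histone modifications
#' +/-1 kb, enhancer RNA +/-500 bp, nucleosome (MNase) signal +/-75 bp — wider
#' marks get wider windows to match the breadth of their signal.
#'
#' @return Named integer vector of half-widths.
#' @export
assay_halfwidths <- function() {
  c(tf = 250L, histone = 1000L, erna = 500L, nucleosome = 75L)
}

#' Remove duplicate reads
#'
#' Keeps at most one read per (chrom, start, strand) key, first occurrence
#' wins — the same collapsing as samtools rmdup for single-end data. Reads on
#' opposite strands at the same start are distinct.
#'
#' @param reads Read tibble with `chrom`, `start`, `end`, `strand`.
#' @return Deduplicated read tibble, original order preserved.
#' @export
remove_duplicates <- function(reads) {
  validate_intervals(reads, "read")
  if (!"strand" %in% names(reads)) abort("reads need a 'strand' column")
  distinct(reads, .data$chrom, .data$start, .data$strand, .keep_all = TRUE)
}

#' Extend reads from their 5' end
#'
#' Stretches each read to `length_bp` in the direction of its strand, from
#' the 5' end (start for `+`, end for `-`), clipping at chromosome position 0.
#' Used to restore fragment-length resolution, e.g. 50-nt reads to 147 bp to
#' match a mononucleosome.
#'
#' @param reads Read tibble with strand.
#' @param length_bp Target fragment length; must be positive.
#' @return Read tibble with adjusted coordinates.
#' @export
extend_reads <- function(reads, length_bp) {
  validate_intervals(reads, "read")
  if (!"strand" %in% names(reads)) abort("reads need a 'strand' column")
  if (length_bp <= 0) abort("length_bp must be positive")
  length_bp <- as.integer(length_bp)
  mutate(
    reads,
    start = ifelse(.data$strand == "-", pmax(0L, .data$end - length_bp), .data$start),
    end = ifelse(.data$strand == "-", .data$end, .data$start + length_bp)
  )
}

#' Normalized signal in peak-centered windows
#'
#' For each window of width `W = 2 * halfwidth_bp + 1` centered on the
#' interval midpoint, the signal is
#' `(read bases overlapping the window / W) / (library_size / 1e8)`,
#' i.e. mean per-base coverage scaled to a 100-million-read library. Windows
#' running off the chromosome start are clipped and their clipped width used.
#' `mode = "ends"` counts 5'-read-end landings instead of covered bases
#' (signal = ends in window / W / depth factor).
#'
#' @param reads Read tibble.
#' @param windows Interval tibble whose midpoints anchor the windows; a
#'   `name` column, when present, becomes the output `window_id`.
#' @param halfwidth_bp Window half-width in bp (> 0); see [assay_halfwidths()].
#' @param library_size Total reads for depth normalization (> 0).
#' @param mode `"coverage"` (default, per-base) or `"ends"` (5' end counting).
#' @return Tibble with `window_id` and `signal` (reads/bp per 1e8 reads),
#'   one row per window, input order.
#' @export
windowed_signal <- function(reads, windows, halfwidth_bp, library_size,
                            mode = c("coverage", "ends")) {
  mode <- match.arg(mode)
  validate_intervals(reads, "read")
  validate_intervals(windows, "window")
  if (halfwidth_bp <= 0) abort("halfwidth_bp must be positive")
  if (is.null(library_size) || library_size <= 0) abort("library_size must be positive")

  ctr <- peak_center(windows)
  win_start <- pmax(0L, ctr - as.integer(halfwidth_bp))
  win_end <- ctr + as.integer(halfwidth_bp) + 1L   # half-open
  width <- win_end - win_start                      # clipped width

  lv <- unique(c(reads$chrom, windows$chrom))
  if (mode == "ends") {
    pos5 <- ifelse("strand" %in% names(reads) & reads$strand == "-",
                   reads$end - 1L, reads$start)
    qry <- GenomicRanges::GRanges(factor(reads$chrom, levels = lv),
                                  IRanges::IRanges(pos5 + 1L, pos5 + 1L))
  } else {
    qry <- as_granges(reads, lv)
  }
  win_gr <- GenomicRanges::GRanges(factor(windows$chrom, levels = lv),
                                   IRanges::IRanges(win_start + 1L, win_end))
  bases <- numeric(nrow(windows))
  if (nrow(reads) > 0 && nrow(windows) > 0) {
    hits <- GenomicRanges::findOverlaps(win_gr, qry, ignore.strand = TRUE)
    if (length(hits) > 0) {
      ov <- IRanges::pintersect(
        IRanges::ranges(win_gr)[S4Vectors::queryHits(hits)],
        IRanges::ranges(qry)[S4Vectors::subjectHits(hits)]
      )
      w <- if (mode == "ends") rep(1, length(hits)) else IRanges::width(ov)
      agg <- tapply(w, S4Vectors::queryHits(hits), sum)
      bases[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  tibble(
    window_id = if ("name" %in% names(windows)) windows$name else
      as.character(seq_len(nrow(windows))),
    signal = (bases / width) / (library_size / 1e8)
  )
}

#' Build a peaks-by-time signal matrix from per-time-point read sets
#'
#' Convenience wrapper running [windowed_signal()] over a list of read sets
#' (one per time point, optionally per replicate) into the long-format signal
#' matrix consumed by normalization and rhythm fitting.
#'
#' @param read_sets Named list; each element a list with `reads` (tibble) and
#'   `library_size`. Names parsed as `"<time>"` or `"<time>_<replicate>"`.
#' @param windows Interval tibble of peaks.
#' @param halfwidth_bp Window half-width.
#' @param mode Passed to [windowed_signal()].
#' @return Long tibble: `window_id`, `time`, `replicate`, `signal` — a
#'   complete grid.
#' @export
signal_matrix <- function(read_sets, windows, halfwidth_bp, mode = "coverage") {
  if (is.null(names(read_sets)) || any(names(read_sets) == "")) {
    abort("read_sets must be a named list ('<time>' or '<time>_<replicate>')")
  }
  purrr::imap_dfr(read_sets, function(rs, nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    sig <- windowed_signal(rs$reads, windows, halfwidth_bp, rs$library_size,
                           mode = mode)
    mutate(sig,
           time = as.numeric(parts[1]),
           replicate = if (length(parts) > 1) parts[2] else "r1",
           .after = "window_id")
  })
}
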