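#' Genomic peaks, genes, and their tidy representation
#'
#' Peaks, DNase-hypersensitive sites and reads are plain tibbles with BED-style
#' 0-based half-open coordinates: columns `chrom`, `start`, `end`, and
#' optionally `name`, `score`, `strand`. Genes carry `strand` and `gene_id`.
#' All verbs in the package take such a tibble first and return a tibble, so
#' stages chain with the pipe (the same convention as valr-style tidy
#' genomics).
#'
#' @name interval-tibbles
NULL

# internal: check BED-style interval columns; returns the offending row
# indices in the error so malformed records are traceable
validate_intervals <- function(x, what = "interval") {
  if (!is.data.frame(x)) abort(paste0(what, " table must be a data frame"))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0(what, " table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!(x$start < x$end) | x$start < 0 | is.na(x$chrom) | x$chrom == "")
  if (length(bad) > 0) {
    abort(paste0(
      "malformed ", what, " record(s) (need 0 <= start < end, non-empty chrom) at row(s): ",
      paste(utils::head(bad, 10), collapse = ", ")
    ))
  }
  invisible(x)
}

validate_genes <- function(genes) {
  validate_intervals(genes, what = "gene")
  if (!all(c("strand", "gene_id") %in% names(genes))) {
    abort("gene table needs 'strand' and 'gene_id' columns")
  }
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(paste0("gene record(s) with unknown strand at row(s): ",
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  invisible(genes)
}

# internal: tibble (0-based half-open) -> GRanges (1-based closed); a shared
# seqlevels universe avoids spurious cross-object warnings
as_granges <- function(x, seqlevels = unique(x$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*"
  )
}

#' Read a BED file into a tidy interval tibble
#'
#' Accepts BED3/BED4/BED5/BED6 (name in column 4, score in column 5, strand in
#' column 6). Coordinates stay 0-based half-open, as in the file.
#'
#' @param path Path to a tab-delimited BED file (no header).
#' @return A tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 3) abort("BED file needs at least 3 columns")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(x)[seq_len(min(ncol(x), 6))] <- cols[seq_len(min(ncol(x), 6))]
  x <- x[, intersect(cols, names(x))]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  validate_intervals(x, what = "BED")
  as_tibble(x)
}

#' Write an interval tibble as BED
#'
#' Emits as many of the BED3..BED6 columns as the tibble carries.
#'
#' @param x Interval tibble (see [read_bed()]).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), names(x))
  # BED columns are positional: fill gaps (e.g. score without name) with "."
  upto <- max(match(cols, c("chrom", "start", "end", "name", "score", "strand")))
  out <- tibble(chrom = x$chrom, start = x$start, end = x$end)
  if (upto >= 4) out$name <- if ("name" %in% cols) x$name else "."
  if (upto >= 5) out$score <- if ("score" %in% cols) x$score else 0
  if (upto >= 6) out$strand <- if ("strand" %in% cols) x$strand else "."
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(x)
}

#' Read a gene model table
#'
#' Two layouts are understood: BED6 with the gene identifier in the name
#' column, or a tab-delimited file with header columns
#' `chrom, start, end, strand, gene_id` in any order. Gene spans are 0-based
#' half-open single intervals (no exon structure).
#'
#' @param path Path to the gene table.
#' @return Tibble with `chrom`, `start`, `end`, `strand`, `gene_id`, plus the
#'   derived strand-aware `tss` and `tts` base positions.
#' @export
read_genes <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  if (grepl("gene_id", first, fixed = TRUE)) {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    x <- read_bed(path)
    x <- dplyr::rename(x, gene_id = "name")
  }
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  validate_genes(x)
  add_tss_tts(as_tibble(x))
}

# derived TSS/TTS: for '+' genes tss = start, tts = end - 1 (last covered
# base); mirrored on '-' genes
add_tss_tts <- function(genes) {
  mutate(
    genes,
    tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
    tts = ifelse(.data$strand == "+", .data$end - 1L, .data$start)
  )
}

#' High-confidence co-bound peaks from two ChIP-Seq peak lists
#'
#' Keeps every interval of `list_b` that shares at least one base with an
#' interval of `list_a` — the convention used to call co-bound sites from two
#' factors' peak lists while retaining the second factor's coordinates.
#' Output is deduplicated and sorted by (chrom, start).
#'
#' @param list_a,list_b Interval tibbles; `list_b` coordinates are returned.
#' @param min_overlap Minimum shared bases to call an overlap (default 1).
#' @return Tibble of `list_b` rows overlapping `list_a`.
#' @export
intersect_peaks <- function(list_a, list_b, min_overlap = 1L) {
  validate_intervals(list_a, "list_a peak")
  validate_intervals(list_b, "list_b peak")
  if (nrow(list_a) == 0 || nrow(list_b) == 0) {
    return(arrange(distinct(list_b[0, ]), .data$chrom, .data$start))
  }
  lv <- unique(c(list_a$chrom, list_b$chrom))
  hits <- GenomicRanges::findOverlaps(as_granges(list_b, lv),
                                      as_granges(list_a, lv),
                                      minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  keep <- sort(unique(S4Vectors::queryHits(hits)))
  out <- distinct(list_b[keep, , drop = FALSE])
  arrange(out, .data$chrom, .data$start)
}

#' Peak reference position
#'
#' The anchor used for gene assignment and windowed signal: the integer
#' midpoint (floor) by default, or the summit when the tibble has a `summit`
#' column (absolute base position).
#'
#' @param peaks Interval tibble.
#' @param center `"midpoint"` or `"summit"`.
#' @return Integer vector of positions, one per peak.
#' @export
peak_center <- function(peaks, center = c("midpoint", "summit")) {
  center <- match.arg(center)
  if (center == "summit") {
    if (!"summit" %in% names(peaks)) abort("center = 'summit' needs a 'summit' column")
    return(as.integer(peaks$summit))
  }
  as.integer(floor((peaks$start + peaks$end) / 2))
}

#' Assign peaks to genes and categorize their location
#'
#' A peak is assigned to a gene when its center lies in the strand-aware
#' window from `upstream_bp` before the TSS to `downstream_bp` after the TTS;
#' with several candidates the gene with the nearest TSS wins (ties go to the
#' lexicographically smallest `gene_id`). The location category partitions
#' assigned peaks: `TSS` within +/-1 kb of the TSS, `EXTENDED_PROMOTER` in the
#' strand-aware \[-10 kb, -1 kb) window before the TSS, `GENE_BODY` otherwise;
#' unassigned peaks are `INTERGENIC`.
#'
#' @param peaks Interval tibble.
#' @param genes Gene tibble (see [read_genes()]); `tss`/`tts` derived if absent.
#' @param upstream_bp,downstream_bp Assignment window, bp (defaults 10000, 1000).
#' @param tss_halfwidth_bp Half-width of the TSS category window (default 1000).
#' @param center Peak anchor, see [peak_center()].
#' @return `peaks` with added columns `gene_id` (NA when intergenic),
#'   `location` (factor TSS/GENE_BODY/EXTENDED_PROMOTER/INTERGENIC) and
#'   `distance_to_tss` (signed bp in transcription direction; NA intergenic).
#' @export
assign_peaks <- function(peaks, genes, upstream_bp = 10000, downstream_bp = 1000,
                         tss_halfwidth_bp = 1000,
                         center = c("midpoint", "summit")) {
  validate_intervals(peaks, "peak")
  validate_genes(genes)
  if (nrow(genes) == 0) abort("gene table is empty")
  if (upstream_bp <= 0 || downstream_bp <= 0) abort("assignment windows must be positive")
  if (!all(c("tss", "tts") %in% names(genes))) genes <- add_tss_tts(genes)

  ctr <- peak_center(peaks, center)
  # strand-aware assignment window in genomic coordinates
  win_lo <- ifelse(genes$strand == "+", genes$tss - upstream_bp,
                   genes$tts - downstream_bp)
  win_hi <- ifelse(genes$strand == "+", genes$tts + downstream_bp,
                   genes$tss + upstream_bp)
  lv <- unique(c(peaks$chrom, genes$chrom))
  gene_gr <- GenomicRanges::GRanges(factor(genes$chrom, levels = lv),
                                    IRanges::IRanges(win_lo + 1L, win_hi + 1L))
  ctr_gr <- GenomicRanges::GRanges(factor(peaks$chrom, levels = lv),
                                   IRanges::IRanges(ctr + 1L, ctr + 1L))
  hits <- GenomicRanges::findOverlaps(ctr_gr, gene_gr, ignore.strand = TRUE)

  cand <- tibble(
    peak_idx = S4Vectors::queryHits(hits),
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    tss = genes$tss[S4Vectors::subjectHits(hits)],
    strand = genes$strand[S4Vectors::subjectHits(hits)]
  )
  cand$abs_d <- abs(ctr[cand$peak_idx] - cand$tss)
  cand <- arrange(cand, .data$peak_idx, .data$abs_d, .data$gene_id)
  best <- cand[!duplicated(cand$peak_idx), , drop = FALSE]

  gene_id <- rep(NA_character_, nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  gene_id[best$peak_idx] <- best$gene_id
  # signed distance in the direction of transcription: negative = upstream
  dist[best$peak_idx] <- ifelse(best$strand == "+",
                                ctr[best$peak_idx] - best$tss,
                                best$tss - ctr[best$peak_idx])
  location <- dplyr::case_when(
    is.na(gene_id) ~ "INTERGENIC",
    abs(dist) <= tss_halfwidth_bp ~ "TSS",
    dist >= -upstream_bp & dist < -tss_halfwidth_bp ~ "EXTENDED_PROMOTER",
    TRUE ~ "GENE_BODY"
  )
  mutate(
    peaks,
    peak_center = ctr,
    gene_id = gene_id,
    location = factor(location, levels = c("TSS", "GENE_BODY",
                                           "EXTENDED_PROMOTER", "INTERGENIC")),
    distance_to_tss = dist
  )
}

#' Partition peaks by overlap with a site list
#'
#' Flags each peak as inside (sharing >= 1 base with) or outside a set of
#' sites, e.g. DNase-hypersensitive sites.
#'
#' @param peaks Interval tibble.
#' @param sites Interval tibble of sites.
#' @return `peaks` with a logical `in_site` column; the TRUE/FALSE counts
#'   always sum to `nrow(peaks)`.
#' @export
overlap_with_sites <- function(peaks, sites) {
  validate_intervals(peaks, "peak")
  validate_intervals(sites, "site")
  in_site <- rep(FALSE, nrow(peaks))
  if (nrow(peaks) > 0 && nrow(sites) > 0) {
    lv <- unique(c(peaks$chrom, sites$chrom))
    hits <- GenomicRanges::findOverlaps(as_granges(peaks, lv),
                                        as_granges(sites, lv),
                                        ignore.strand = TRUE)
    in_site[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  mutate(peaks, in_site = in_site)
}

#' Keep the top-scoring sites
#'
#' Retains the `n` sites with the highest `score` (the whole list if shorter),
#' the filter used to restrict open-chromatin site lists to the strongest
#' signal before signal aggregation. Ties at the cutoff are broken by
#' (chrom, start).
#'
#' @param sites Interval tibble with a `score` column.
#' @param n Number of sites to keep (default 40000).
#' @return Tibble of at most `n` sites, sorted by descending score.
#' @export
top_sites_by_signal <- function(sites, n = 40000) {
  validate_intervals(sites, "site")
  if (!"score" %in% names(sites) || anyNA(sites$score)) {
    abort("every site needs a (non-missing) score")
  }
  out <- arrange(sites, dplyr::desc(.data$score), .data$chrom, .data$start)
  dplyr::slice_head(out, n = n)
}
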