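#' Seeded synthetic data with known ground truth
#'
#' Generators for gene models, co-bound peak pairs, circadian expression
#' series and read-interval files, each a pure function of its configuration
#' (including the seed): replays are identical. They emulate the statistical
#' structure the pipeline consumes — jittered co-binding of two factors near
#' target-gene promoters, cosine nascent-RNA rhythms with known
#' mesor/amplitude/phase and multiplicative log-normal noise, the headline
#' output classes in configurable proportions, and Poisson read coverage of
#' known depth — so every stage is testable without external downloads.
#'
#' @name synthetic
NULL

#' Simulation configuration
#'
#' Study-scale defaults: 2000 genes on one synthetic chromosome, the four
#' headline output classes in proportions 0.2/0.1/0.5/0.2
#' (in-phase : out-of-phase : arrhythmic : not expressed), relative rhythm
#' amplitudes 0.5–0.9, log-normal noise sigma 0.1, a 12-point x 4-h nascent
#' grid over 48 h and a 6-point x 4-h signal grid over 24 h.
#'
#' @param seed Integer seed; recorded and used by every generator.
#' @param n_genes Number of genes.
#' @param gene_length,gene_spacing Gene span and slot spacing, bp.
#' @param peak_width Co-bound peak width, bp.
#' @param jitter_bp Max offset between the two factors' peak coordinates
#'   (must stay below `peak_width` so co-bound pairs still overlap).
#' @param n_decoys Per-factor count of single-factor decoy peaks, placed in
#'   factor-specific regions that never intersect.
#' @param class_proportions Named proportions over the output classes
#'   (subset of the seven; must sum to 1).
#' @param mesor_range,mesor_range_ne Mesor draws (reads/bp) for expressed and
#'   not-expressed genes.
#' @param rel_amp_range Relative amplitude (amplitude/mesor) range for
#'   rhythmic genes; kept below 1 so expression stays positive.
#' @param sigma SD of the Gaussian noise on log signal.
#' @param phase_window In-phase window (ZT h); out-of-phase genes draw from
#'   its 24-h complement.
#' @param nascent_times,signal_times Sampling grids (h).
#' @param replicates Replicates per expression time point.
#' @param library_size Reads per simulated read set.
#' @param read_length,halfwidth_bp Read length and extraction half-width for
#'   [simulate_reads()].
#' @param background_reads Uniform background reads per read set.
#' @return Named list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 2000,
                              gene_length = 10000,
                              gene_spacing = 25000,
                              peak_width = 200,
                              jitter_bp = 50,
                              n_decoys = 200,
                              class_proportions = c(RIN_PHI = 0.2, RO_PHI = 0.1,
                                                    AR = 0.5, NE = 0.2),
                              mesor_range = c(2, 20),
                              mesor_range_ne = c(0.1, 0.7),
                              rel_amp_range = c(0.5, 0.9),
                              sigma = 0.1,
                              phase_window = c(2, 12),
                              nascent_times = seq(0, 44, by = 4),
                              signal_times = seq(0, 20, by = 4),
                              replicates = 1L,
                              library_size = 1e6,
                              read_length = 50L,
                              halfwidth_bp = 75L,
                              background_reads = 500L) {
  if (abs(sum(class_proportions) - 1) > 1e-8) abort("class_proportions must sum to 1")
  if (!all(names(class_proportions) %in% output_classes())) {
    abort("class_proportions names must be output classes")
  }
  if (sigma < 0) abort("sigma must be non-negative")
  if (max(rel_amp_range) >= 1) abort("relative amplitude must be < 1 (positive expression)")
  if (jitter_bp >= peak_width) abort("jitter_bp must be below peak_width to keep overlap")
  # genes, then two disjoint decoy regions, then margin
  chrom_size <- n_genes * gene_spacing + 2 * gene_spacing +
    8 * n_decoys * peak_width + 300000
  structure(
    list(seed = as.integer(seed), n_genes = n_genes, gene_length = gene_length,
         gene_spacing = gene_spacing, chrom = "chrS", chrom_size = chrom_size,
         peak_width = peak_width, jitter_bp = jitter_bp, n_decoys = n_decoys,
         class_proportions = class_proportions, mesor_range = mesor_range,
         mesor_range_ne = mesor_range_ne, rel_amp_range = rel_amp_range,
         sigma = sigma, phase_window = phase_window,
         nascent_times = nascent_times, signal_times = signal_times,
         replicates = as.integer(replicates), library_size = library_size,
         read_length = as.integer(read_length),
         halfwidth_bp = as.integer(halfwidth_bp),
         background_reads = as.integer(background_reads)),
    class = "sim_config"
  )
}

# draw a peak phase for a class: in-phase uniform on the window, out-of-phase
# uniform on its complement mod 24
draw_phase <- function(n, class, window) {
  lo <- window[1]; hi <- window[2]
  ifelse(class == "RIN_PHI",
         runif(n, lo, hi),
         (runif(n, hi, 24 + lo)) %% 24)
}

#' Simulate gene models and two factors' peak lists
#'
#' Places non-overlapping genes at regular slots (random strand), assigns
#' each a true output class, and plants a co-bound peak pair near each
#' gene's promoter: the factor-B peak inside the strand-aware assignment
#' window, the factor-A peak shifted by up to `jitter_bp`. Decoy peaks for
#' each factor alone sit in disjoint reserved regions, so intersecting the
#' two lists recovers exactly the planted co-bound peaks.
#'
#' @param cfg A [simulation_config()].
#' @return List: `genes` (gene tibble), `peaks_a`, `peaks_b` (interval
#'   tibbles; co-bound peaks first, then decoys), `truth` (tibble `peak_id`,
#'   `gene_id`, `class`, `phase`, `rel_amp`, `mesor`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$gene_length + 12000 >= cfg$gene_spacing) {
    abort("infeasible density: gene_spacing must exceed gene_length + 12 kb")
  }
  set.seed(cfg$seed)
  n <- cfg$n_genes
  slot <- (seq_len(n) - 1L) * cfg$gene_spacing + 11000L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genes <- tibble(
    chrom = cfg$chrom,
    start = as.integer(slot),
    end = as.integer(slot + cfg$gene_length),
    strand = strand,
    gene_id = sprintf("gene%04d", seq_len(n))
  ) |> add_tss_tts()

  classes <- sample(names(cfg$class_proportions), n, replace = TRUE,
                    prob = cfg$class_proportions)
  phase <- rep(NA_real_, n)
  rhy <- classes %in% c("RIN_PHI", "RO_PHI")
  phase[rhy] <- draw_phase(sum(rhy), classes[rhy], cfg$phase_window)
  rel_amp <- ifelse(rhy | classes == "POST_TRANSCRIPTIONAL",
                    runif(n, cfg$rel_amp_range[1], cfg$rel_amp_range[2]), 0)
  mesor <- ifelse(classes == "NE",
                  runif(n, cfg$mesor_range_ne[1], cfg$mesor_range_ne[2]),
                  runif(n, cfg$mesor_range[1], cfg$mesor_range[2]))

  # factor-B peak center near the TSS, inside the strand-aware window
  offset <- as.integer(runif(n, -2000, 500))            # signed, tx direction
  ctr <- ifelse(genes$strand == "+", genes$tss + offset, genes$tss - offset)
  half <- as.integer(cfg$peak_width / 2)
  peaks_b <- tibble(
    chrom = cfg$chrom,
    start = as.integer(ctr - half),
    end = as.integer(ctr - half + cfg$peak_width),
    name = sprintf("peak%04d", seq_len(n))
  )
  jit <- as.integer(runif(n, -cfg$jitter_bp, cfg$jitter_bp))
  peaks_a <- mutate(peaks_b, start = .data$start + jit, end = .data$end + jit,
                    name = sprintf("apeak%04d", seq_len(n)))

  # decoys: disjoint reserved regions beyond the gene block
  base_a <- n * cfg$gene_spacing + 2L * cfg$gene_spacing
  base_b <- base_a + 4L * cfg$n_decoys * cfg$peak_width + 100000L
  decoy <- function(base, tag) {
    s <- as.integer(base + (seq_len(cfg$n_decoys) - 1L) * 4L * cfg$peak_width)
    tibble(chrom = cfg$chrom, start = s, end = s + as.integer(cfg$peak_width),
           name = sprintf("%s%04d", tag, seq_len(cfg$n_decoys)))
  }
  list(
    genes = genes,
    peaks_a = bind_rows(peaks_a, decoy(base_a, "decoyA")),
    peaks_b = bind_rows(peaks_b, decoy(base_b, "decoyB")),
    truth = tibble(peak_id = peaks_b$name, gene_id = genes$gene_id,
                   class = classes, phase = phase, rel_amp = rel_amp,
                   mesor = mesor)
  )
}

#' Simulate nascent and mRNA circadian series from a truth table
#'
#' Rhythmic genes follow
#' `x(t) = mesor * (1 + rel_amp * cos(2*pi*(t - phase)/24)) * exp(eps)` with
#' `eps ~ N(0, sigma^2)`; arrhythmic and not-expressed genes are flat with
#' the same noise; post-transcriptional genes get a flat nascent series but
#' a rhythmic mRNA series; `NO_SIGNAL` genes are omitted from both tables.
#'
#' @param cfg A [simulation_config()].
#' @param truth Truth tibble from [simulate_annotation()].
#' @return List of long tibbles `nascent` and `mrna`
#'   (`series_id`, `time`, `replicate`, `value`).
#' @export
simulate_expression <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  tt <- truth[!duplicated(truth$gene_id), , drop = FALSE]
  tt <- tt[tt$class != "NO_SIGNAL", , drop = FALSE]
  # one mRNA phase per post-transcriptional gene, uniform over the day
  tt$pt_phase <- runif(nrow(tt), 0, 24)
  times <- cfg$nascent_times
  reps <- sprintf("r%d", seq_len(cfg$replicates))
  grid <- tidyr::expand_grid(gene_id = tt$gene_id, time = times,
                             replicate = reps)
  grid <- left_join(grid, tt, by = "gene_id")

  cos24 <- function(t, phase) cos(2 * pi * (t - phase) / 24)
  noise <- function(k) exp(rnorm(k, 0, cfg$sigma))
  k <- nrow(grid)

  nascent_mu <- ifelse(
    grid$class %in% c("RIN_PHI", "RO_PHI"),
    grid$mesor * (1 + grid$rel_amp * cos24(grid$time, grid$phase)),
    grid$mesor
  )
  # mRNA mirrors nascent rhythms; post-transcriptional genes are rhythmic in
  # mRNA only, with a phase drawn uniformly over the day
  pt <- grid$class == "POST_TRANSCRIPTIONAL"
  pt_phase <- grid$pt_phase
  mrna_mu <- ifelse(
    grid$class %in% c("RIN_PHI", "RO_PHI"),
    grid$mesor * (1 + grid$rel_amp * cos24(grid$time, grid$phase)),
    ifelse(pt, grid$mesor * (1 + grid$rel_amp * cos24(grid$time, pt_phase)),
           grid$mesor)
  )
  out <- function(mu) {
    tibble(series_id = grid$gene_id, time = grid$time,
           replicate = grid$replicate, value = mu * noise(k)) |>
      arrange(.data$series_id, .data$time, .data$replicate)
  }
  list(nascent = out(nascent_mu), mrna = out(mrna_mu))
}

#' Simulate read sets reproducing known window signal
#'
#' For each (peak, time) truth value `v` (reads/bp per 1e8 reads), draws
#' `Poisson(v * W * library_size / 1e8 / read_length)` reads placed uniformly
#' inside the extraction window of width `W = 2 * halfwidth_bp + 1`, so the
#' expected [windowed_signal()] equals `v`; uniform background reads are
#' added across the chromosome.
#'
#' @param cfg A [simulation_config()].
#' @param signal_truth Tibble `peak_id`, `chrom`, `start`, `end`, `time`,
#'   `value` — target signal per peak and time point.
#' @return Named list (one element per time point, name = time) of read sets:
#'   `list(reads = tibble, library_size = cfg$library_size)`.
#' @export
simulate_reads <- function(cfg, signal_truth) {
  stopifnot(inherits(cfg, "sim_config"))
  need <- c("peak_id", "chrom", "start", "end", "time", "value")
  if (!all(need %in% names(signal_truth))) {
    abort("signal_truth needs columns peak_id, chrom, start, end, time, value")
  }
  set.seed(cfg$seed + 2L)
  W <- 2 * cfg$halfwidth_bp + 1
  L <- cfg$read_length
  purrr::map(split(signal_truth, signal_truth$time), function(st) {
    ctr <- floor((st$start + st$end) / 2)
    lo <- ctr - cfg$halfwidth_bp
    n_planted <- rpois(nrow(st), st$value * W * cfg$library_size / 1e8 / L)
    starts <- purrr::map2(lo, n_planted, function(l, np) {
      as.integer(floor(runif(np, l, l + W - L)))
    })
    planted <- tibble(
      chrom = rep(st$chrom, n_planted),
      start = unlist(starts, use.names = FALSE)
    )
    bg_start <- as.integer(floor(runif(cfg$background_reads, 0,
                                       cfg$chrom_size - L)))
    reads <- bind_rows(
      planted,
      tibble(chrom = cfg$chrom, start = bg_start)
    ) |>
      mutate(end = .data$start + L,
             strand = sample(c("+", "-"), dplyr::n(), replace = TRUE))
    if (nrow(reads) > cfg$library_size) {
      abort("library_size smaller than simulated read count; raise it")
    }
    list(reads = reads, library_size = cfg$library_size)
  })
}

#' Cosine signal truth on a sampling grid
#'
#' Helper building the `signal_truth` input of [simulate_reads()]: each
#' peak's signal follows `mesor + amplitude * cos(2*pi*(t - phase)/24)`
#' (reads/bp per 1e8 reads), clamped at 0.
#'
#' @param peaks Interval tibble with `name`.
#' @param times Time grid, hours.
#' @param mesor,amplitude,phase Scalars or per-peak vectors.
#' @return Tibble `peak_id`, `chrom`, `start`, `end`, `time`, `value`.
#' @export
cosine_truth <- function(peaks, times, mesor, amplitude = 0, phase = 0) {
  tidyr::expand_grid(idx = seq_len(nrow(peaks)), time = times) |>
    mutate(
      peak_id = peaks$name[.data$idx],
      chrom = peaks$chrom[.data$idx],
      start = peaks$start[.data$idx],
      end = peaks$end[.data$idx],
      value = pmax(0, rep_len(mesor, nrow(peaks))[.data$idx] +
                     rep_len(amplitude, nrow(peaks))[.data$idx] *
                     cos(2 * pi * (.data$time -
                                     rep_len(phase, nrow(peaks))[.data$idx]) / 24))
    ) |>
    select("peak_id", "chrom", "start", "end", "time", "value")
}
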