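# Independent oracles and tiny fixture builders. These deliberately use
# nothing from the code paths they check: plain loops and base R only.

# all-pairs interval overlap: does row i of `a` share >= 1 base with any row
# of `b`? (0-based half-open)
bf_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# per-base pileup signal oracle: explicit coverage vector per chromosome
pileup_signal <- function(reads, windows, halfwidth, library_size) {
  vapply(seq_len(nrow(windows)), function(i) {
    ctr <- floor((windows$start[i] + windows$end[i]) / 2)
    lo <- max(0, ctr - halfwidth)
    hi <- ctr + halfwidth            # inclusive base positions lo..hi
    cov <- 0
    for (p in lo:hi) {
      cov <- cov + sum(reads$chrom == windows$chrom[i] &
                         reads$start <= p & reads$end > p)
    }
    (cov / (hi - lo + 1)) / (library_size / 1e8)
  }, numeric(1))
}

# grid-search least-squares phase oracle: for each candidate phase fit
# (mesor, amplitude) linearly and keep the phase minimizing SSE
grid_phase_oracle <- function(times, values, period = 24, step = 0.01) {
  phases <- seq(0, period - step, by = step)
  sse <- vapply(phases, function(ph) {
    X <- cbind(1, cos(2 * pi * (times - ph) / period))
    sum(lm.fit(X, values)$residuals^2)
  }, numeric(1))
  phases[which.min(sse)]
}

# smallest absolute circular difference on a 24-h clock
circ_diff <- function(a, b, period = 24) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

# random interval tibble on one chromosome set
rand_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                           max_len = 200) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE)
  )
}

# small deterministic gene model used across interval tests:
# '+' gene with TSS 100000, TTS 120000; '-' gene with TSS 320000, TTS 300000
toy_genes <- function() {
  tibble::tibble(
    chrom = "chr1",
    start = c(100000L, 300000L),
    end = c(120001L, 320001L),
    strand = c("+", "-"),
    gene_id = c("G", "H")
  )
}

# interval tibble from compact "chr:start-end" strings
iv <- function(...) {
  s <- c(...)
  m <- regmatches(s, regexec("^(.+):(\\d+)-(\\d+)$", s))
  tibble::tibble(
    chrom = vapply(m, `[`, "", 2),
    start = as.integer(vapply(m, `[`, "", 3)),
    end = as.integer(vapply(m, `[`, "", 4))
  )
}
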