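# circout

Circadian transcription factors such as the CLOCK:BMAL1 heterodimer bind
thousands of sites across the genome, yet rhythmic DNA binding does not
guarantee rhythmic transcription of the target gene. `circout` is an R
package for quantifying that disconnect: it takes ChIP-Seq peak lists,
gene models and circadian expression time series, and classifies every
high-confidence binding site by the transcriptional output of its target
gene, then compares chromatin and transcription-factor signal between the
output classes. It is written for computational biologists doing
regulatory-genomics meta-analysis of circadian datasets (ChIP-Seq,
MNase-Seq, GRO-Seq, Nascent-Seq), tibble-in / tibble-out so every stage
chains with the pipe.

## What it computes

* **Co-bound peaks** — `intersect_peaks()` keeps every peak of the second
  factor's list that shares ≥ 1 bp with a peak of the first, the standard
  way of deriving high-confidence heterodimer sites from two ChIP-Seq
  experiments.
* **Gene assignment and location** — `assign_peaks()` assigns a peak to a
  gene when its center falls in the strand-aware window from 10 kb
  upstream of the TSS to 1 kb past the TTS, nearest TSS winning, and
  categorizes the location (TSS ± 1 kb, gene body, extended promoter
  \[−10 kb, −1 kb), or intergenic).
* **Rhythm fitting** — `fourier_fit()` / `fit_rhythms()` fit the first
  24-h harmonic by least squares,

  x(t) = M + A·cos(2πt/T) + B·sin(2πt/T),

  reporting mesor M, amplitude √(A²+B²), phase as the ZT hour of the
  fitted maximum, and an F-test of the harmonic pair against the
  intercept-only model. `detect_rhythms()` adds the rhythmicity call
  (p < α, fitted peak/trough fold ≥ 1.5, mean level ≥ 1 read/bp; all
  configurable).
* **Output classification** — `classify_peaks()` maps each assigned peak
  to one of seven classes: rhythmic in phase with binding (nascent peak in
  ZT02–ZT12), rhythmic out of phase, arrhythmic, not expressed
  (mean < 1 read/bp), post-transcriptional (nascent flat, mRNA rhythmic),
  low expression, or no signal.
* **Signal extraction** — `windowed_signal()` turns read intervals into
  reads/bp per 10⁸ reads in assay-specific windows around peak centers
  (±250 bp for TFs and Pol II, ±1 kb for histone marks, ±500 bp for eRNA,
  ±75 bp for nucleosomes), after `remove_duplicates()` and
  `extend_reads()`.
* **Cross-time-point normalization** — `mean_normalize()` (ratio to the
  mean over a reference site set, e.g. the top 40,000 DNase sites by
  signal) and `rank_normalize()` (ranking/quantile normalization).
* **Group statistics** — `variability_index()` computes the decile-based
  TF DNA-binding variability index (sum over deciles 0.1–0.9 of the
  between-group SD of decile values divided by their mean);
  `kruskal_letters()` gives Kruskal-Wallis + Dunn post-hoc compact letter
  displays; `amplitude_anova()` compares rhythm extremes by two-way ANOVA.
* **Synthetic data** — `simulation_config()`, `simulate_annotation()`,
  `simulate_expression()`, `simulate_reads()` generate seeded cohorts with
  known ground truth so every stage is verifiable without downloads.

## Worked example

```r
library(circout)

cfg  <- simulation_config(seed = 42, n_genes = 500)
ann  <- simulate_annotation(cfg)
expr <- simulate_expression(cfg, ann$truth)
res  <- run_all(list(peaks_a = ann$peaks_a, peaks_b = ann$peaks_b,
                     genes = ann$genes, nascent = expr$nascent,
                     mrna = expr$mrna), seed = 42)
res
#> circout run: 500 co-bound peaks, 500 assigned / 0 intergenic
#> # A tibble: 7 × 3
#>   output_class             n   pct
#>   <fct>                <int> <dbl>
#> 1 RIN_PHI                 91  18.2
#> 2 RO_PHI                  56  11.2
#> 3 AR                     262  52.4
#> 4 NE                      91  18.2
#> 5 POST_TRANSCRIPTIONAL     0   0
#> 6 LOW_EXPRESSION           0   0
#> 7 NO_SIGNAL                0   0
#> # A tibble: 1 × 4
#>   rhythmic_fraction out_of_phase_fraction rhythmic_pct out_of_phase_pct
#>               <dbl>                 <dbl>        <dbl>            <dbl>
#> 1             0.294                 0.381           29               38
```

Every simulated co-bound peak is recovered and assigned; 29% of the
assigned peaks target rhythmically transcribed genes (the generator
planted 30%), and 38% of those rhythmic targets peak out of phase with
the in-phase window. A single series fit:

```r
fourier_fit(seq(2, 22, by = 4), c(4, 5, 4, 2, 1, 2))
#> Harmonic rhythm fit (period 24 h)
#>   mesor 3  amplitude 2  phase ZT6.00  p = 1.48e-46
```

`autoplot()` on a fit draws the data and fitted cosine;
`plot_class_counts()` and `plot_phase_distribution()` summarize a run;
`tidy()`/`glance()` return broom-style tibbles for fits and variability
results.

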