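---
title: "Methods: classifying circadian transcriptional output at TF binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying circadian transcriptional output at TF binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circout)
library(dplyr)
```

## The problem and the model

A circadian transcription-factor heterodimer binds its genomic sites
rhythmically, but the transcriptional response of the bound genes is
heterogeneous: some are transcribed in phase with binding, some out of
phase, many not rhythmically at all, and some not at all. `circout`
implements the analysis chain that quantifies this heterogeneity:
high-confidence co-bound sites from two factors' ChIP-Seq peak lists,
strand-aware assignment of sites to genes, harmonic-regression rhythm
calls on nascent-RNA time series, a decision tree mapping each site to a
transcriptional-output class, peak-centered signal aggregation for
chromatin readouts, two cross-time-point normalizations, and a
decile-based index of between-class differences in TF binding strength.

Rhythms are modeled by the first 24-h Fourier harmonic fitted by ordinary
least squares,

$$x(t) = m + a\cos\left(\tfrac{2\pi t}{T}\right) + b\sin\left(\tfrac{2\pi t}{T}\right),\qquad T = 24\,\mathrm{h},$$

with mesor $m$, amplitude $\sqrt{a^2+b^2}$ (half the fitted
peak-to-trough span), and phase $\tfrac{T}{2\pi}\operatorname{atan2}(b,a)
\bmod T$, the clock time of the fitted maximum. Significance is the
F-test of the harmonic pair against the intercept-only model. On a
uniform grid with at least four samples per period the harmonic basis is
orthogonal, so a noiseless first harmonic is recovered exactly; the test
has $(2, n-3)$ degrees of freedom and, under Gaussian noise, exact type-I
control — the package's white-noise simulation confirms the 5% level
empirically. A 48-h series is deliberately fitted with the 24-h period
(two cycles), which is what makes "arrhythmic over 48 h" a testable
statement. Replicates are averaged per time point before fitting.

The assumptions worth keeping in mind: a single sinusoid (no second
harmonic, so sharply peaked waveforms lose amplitude to the residual),
equally spaced samples, and homoscedastic noise for the F-test — count
data at very low expression violate the last point, which is one reason
the classification gates rhythm calls on a minimum expression level.

## The classification tree

Each peak assigned to a gene inherits the gene's class, decided in this
order:

1. no expression record at all → `NO_SIGNAL`;
2. mean nascent signal over the 12 samples < `ne_threshold`
   (1 read/bp) → `NE`, not expressed;
3. nascent series rhythmic — F-test p < `alpha` (0.05), fitted
   peak/trough fold ≥ `min_fold` (1.5), mean ≥ `min_level`
   (1 read/bp) — with fitted phase in `[2, 12)` ZT h → `RIN_PHI`,
   otherwise → `RO_PHI`;
4. expressed above `min_level` but arrhythmic: mRNA rhythmic →
   `POST_TRANSCRIPTIONAL` (a guard against calling a gene arrhythmic
   when its mRNA clearly cycles), otherwise → `AR`;
5. mean in `[ne_threshold, min_level)` → `LOW_EXPRESSION`, too low to
   test for rhythmicity but not "not expressed".

The classes partition the assigned peaks by construction; the rhythmic
ones split into exactly one of in-phase/out-of-phase. The in-phase window
`[ZT2, ZT12)` is half-open so that the categories partition the clock
face; the boundary convention is a package choice (the interval endpoints
are not dictated by the biology) and both it and the window are
configurable in `classify_config()`. The rhythm-call thresholds
themselves are stated defaults rather than inherited constants, because
the upstream nascent-RNA rhythm analyses this design mirrors do not
publish a complete threshold set; all of them are exposed and echoed in
the run manifest so no silent default participates in a result.

With the default `min_level = ne_threshold = 1` the `LOW_EXPRESSION`
branch is empty; it becomes populated when the rhythm-test floor is
raised above the not-expressed threshold, which is how a stricter
expression filter is expressed in this design.

## Gene assignment and location categories

A peak is attached to a gene when its center lies between 10 kb upstream
of the TSS and 1 kb downstream of the TTS, in the direction of
transcription. The peak "position" is the integer midpoint (floor) of the
interval — summit-based anchoring is available where summits exist. With
several candidate genes the nearest TSS wins, ties broken by the
lexicographically smallest gene identifier; this mirrors the default
behavior of the annotation tools commonly used for such assignments,
whose exact tie-breaking is not documented, so the rule is fixed and
stated rather than guessed. Locations are TSS (± 1 kb), extended promoter
(`[−10 kb, −1 kb)` upstream), gene body (the rest of the window), or
intergenic; the half-open promoter interval again makes the categories a
partition. Coordinates are 0-based half-open throughout (BED convention,
matching the input files); overlap anywhere in the package means at least
one shared base, the `intersectBed` default.

## Signal, units and normalization

Window signal is mean per-base read coverage scaled to a 100-million-read
library: for a window of width $W = 2h+1$ centered on the peak center,
$\mathrm{signal} = \frac{\text{read bases in window}}{W} \big/
\frac{\text{library size}}{10^8}$, in reads/bp per 10⁸ reads. The odd
width keeps the window symmetric around the center base. Coverage (read
bases) rather than read counts is the default because it is robust to
read-length differences between datasets; 5′-end counting is available as
`mode = "ends"`. Half-widths default per assay — ±250 bp for transcription
factors, coactivators and Pol II, ±1 kb for histone modifications,
±500 bp for eRNA, ±75 bp for nucleosome signal — reflecting the
characteristic breadth of each signal type. Duplicate removal keys on
(chromosome, start, strand), and reads can be extended from their 5′ end
to fragment length (e.g. 147 bp for a mononucleosome), clipped at
position 0.

Two normalizations correct global per-time-point effects:

* **mean normalization** divides each time point by the mean signal over
  a large reference site set (typically the top 40,000 open-chromatin
  sites by DNase signal) at that time point, after which the reference-set
  mean is exactly 1 everywhere;
* **ranking normalization** is a quantile normalization: each time-point
  column is replaced by the across-time average of the sorted values at
  its within-column ranks. Ties receive the mean of their tied ranks'
  reference values — the standard quantile-normalization convention,
  chosen because it keeps the output well-defined and idempotent. Rank
  averaging spans the time points of the matrix at hand; pooling several
  datasets into one reference is possible but not the default.

## The variability index

For a TF's signal at peaks grouped by the four headline classes, each
group's deciles 0.1–0.9 are computed with the linear-interpolation
quantile (R type 7, the common default; the definition is logged in the
result object). At each decile the sample standard deviation (n−1 form)
of the four group values is divided by their mean — a per-decile
coefficient of variation, since absolute dispersion grows with signal
level — and the nine ratios are summed. The index is 0 iff all groups
share identical decile vectors, and is invariant under global positive
scaling and group relabeling. The worked example in the test suite (three
groups `1..10` and one doubled) pins both conventions: each decile
contributes $0.5q/1.25q = 0.4$, so the index is 3.6. Deciles are computed
per group; a pooled-anchor variant is provided as a switch for
sensitivity analysis. Excluding a designated peak subset (e.g. peaks at
core clock genes, shipped as an editable list in
`inst/extdata/core_clock_genes.txt`) is a plain filter before recomputing.

Group comparisons use Kruskal-Wallis, with Dunn's z-tests on mean ranks
(tie-corrected) and Benjamini-Hochberg adjustment for the pairwise layer,
summarized as a compact letter display via the insert-and-absorb
algorithm; pairs are only declared different when the omnibus test itself
rejects. In the two-group case the Dunn p-value coincides with the
normal-approximation Mann-Whitney test, which the suite checks. Rhythm
amplitudes are compared as per-replicate maxima and minima in a
group × extremum two-way ANOVA; a table with zero total variance returns
p = 1 for all effects rather than the 0/0 F-statistics a raw fit would
produce.

## The synthetic cohort: what it emulates, and what it does not

The generator plants non-overlapping genes on one synthetic chromosome,
one co-bound peak pair near each promoter (the second factor's
coordinates jittered by up to 50 bp, always keeping ≥ 1 bp overlap),
single-factor decoys in disjoint regions, and expression series per the
gene's true class: cosine rhythms
$x(t) = m\,(1 + \rho\cos\tfrac{2\pi(t-\phi)}{24})\,e^{\varepsilon}$ with
$\varepsilon \sim N(0, \sigma^2)$ for rhythmic genes, flat series for
arrhythmic ones, mesors below 1 read/bp for not-expressed ones, and
flat-nascent/rhythmic-mRNA pairs for post-transcriptional ones. Reads are
placed uniformly inside extraction windows with Poisson counts calibrated
so the expected window signal equals the target value, plus uniform
background. Every generator is a pure function of its configuration and
seed.

The reference cohort is 2000 genes with class proportions
0.2/0.1/0.5/0.2 (in-phase/out-of-phase/arrhythmic/not expressed),
relative amplitudes 0.5–0.9, log-normal noise σ = 0.1, and a 12 × 4-h
nascent grid over 48 h — one gene-rich chromosome at roughly the class
balance and sampling design of the real analyses, at a size a laptop
fits in seconds. In-phase truth phases are uniform on `[2, 12)` and
out-of-phase ones uniform on the complement, mirroring the
classification windows. Multiplicative log-normal noise was chosen
because it keeps expression positive and makes noise proportional to
level, as in sequencing-derived signal.

What the generator does **not** emulate — and therefore what passing
recovery tests do not show about real data: overdispersed counts beyond
Poisson, correlated noise across time points, overlapping genes and
shared peaks, waveforms beyond a single harmonic, mappability and GC
structure, and replicate-level batch effects. Recovery rates on the
synthetic cohort are a check that the machinery is correct, not an
estimate of sensitivity on tissue data.

## Numerical choices and degenerate inputs

* Constant series: amplitude 0, phase flagged `NA`, p-value `NA` (there
  is no variance for the F-test to explain), never rhythmic.
* A fitted amplitude below $10^{-9}\max(1, |m|)$ flags the phase
  undefined rather than reporting noise-driven angles.
* Windows clipped at the chromosome start use the clipped width in the
  per-bp denominator.
* All-tied data in the Kruskal-Wallis wrapper return omnibus p = 1 and a
  single shared letter.
* A variability index with any zero decile mean is flagged `NA` rather
  than dividing by zero.
* Malformed intervals (start ≥ end, negative start, empty chromosome)
  are rejected with the offending row indices; unknown strands likewise.
* Percentages in reports are rounded half-up, so 25.8% prints as 26%.

## Problem sizes

The test suite and the acceptance script run the full chain at desk
scale, chosen as the smallest sizes at which the statistical checks are
well-powered: 2000-gene cohorts for class/phase recovery, 1000 series for
the type-I simulation, 10⁴ reads against the per-base pileup oracle,
counts-level examples for everything closed-form. The same code runs
unchanged on genome-scale inputs (tens of thousands of peaks, 10⁸ reads)
since the interval machinery is GenomicRanges-backed; only the read-level
pileup oracle in the tests is quadratic, and it exists purely as an
independent check.

## Known limitations

Single-harmonic fitting understates non-sinusoidal rhythms; the
assignment model treats genes as single spans (no isoforms or exon
structure); the classification inherits any bias in the rhythm thresholds
(the defaults are permissive on fold change and strict on expression);
Dunn + BH is one of several defensible post-hoc choices and is
configurable but not exhaustive; and the package does not perform read
mapping, motif discovery, or coordinate lift-over — it consumes their
outputs.
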