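---
title: "Allele-specific ddPCR quantification: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific ddPCR quantification: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropquant)
```

## The quantification model

Droplet digital PCR partitions a reaction into roughly 20,000 droplets of
volume $V_d$ (default 0.85 nL here, the common convention for the instrument
class this package emulates). If template molecules distribute independently
at concentration $C$ (copies/µL), the number of copies in one droplet is
Poisson with mean $\lambda = C \cdot V_d$, and a droplet is read as positive
whenever it holds at least one copy. From $k$ positive droplets out of $n$,

$$\hat p = k/n, \qquad \hat\lambda = -\ln(1 - \hat p), \qquad
  \hat C = \hat\lambda / V_d .$$

The log transform corrects for droplets that hold more than one copy; it is
what makes ddPCR absolute rather than relative quantification. The
assumptions are: independent partitioning (no template aggregation), equal
droplet volumes, and perfect binary readout of occupancy. `dropquant`
implements the estimator in `estimate_concentration()` and exposes the whole
per-well chain (thresholding, classification, estimation) as a fitted-model
object, `ddpcr_fit()`, with the usual `coef`/`confint`/`summary`/`plot`/
`simulate` methods.

**Confidence intervals.** The default 95% interval is the delta method on
$\hat\lambda$:
$\mathrm{SE}(\hat\lambda) = \sqrt{\hat p / (n(1-\hat p))}$, interval
$\hat\lambda \pm 1.96\,\mathrm{SE}$, floored at zero. It is transparent and
accurate at the droplet counts of a routine well; an exact alternative
(Clopper–Pearson on $\hat p$, transformed through $-\ln(1-p)$) is available
via `ci_method = "exact"`. Two degenerate cases are handled specially:

- $k = 0$: the delta interval collapses to a point, so the exact upper bound
  $-\ln\!\big((0.025)^{1/n}\big)$ is reported in either mode — an empty well
  still bounds the concentration from above.
- $k = n$: a saturated well carries no upper bound on $\lambda$ and is an
  error, never a number.

**Replicates.** Replicate wells of the same target are pooled by summing
$k$ and $n$ *before* the log transform (`merge_wells()`). Pooling counts is
not the same as averaging per-well concentrations when well sizes differ,
and is the statistically correct combination under the Poisson model.

## Allelic fractions and error propagation

A duplex SNP assay reads the WT allele on channel 1 and the MUT allele on
channel 2. The fractional abundance is

$$\hat f_{WT} = \frac{\hat C_{WT}}{\hat C_{WT} + \hat C_{MUT}}
             = \frac{\hat\lambda_{WT}}{\hat\lambda_{WT} + \hat\lambda_{MUT}},$$

with $f_{MUT} = 1 - f_{WT}$ exactly. Because the two channel counts are
estimated from the same droplets but independent Poisson draws, first-order
propagation gives

$$\mathrm{SE}(\hat f) = f(1-f)\sqrt{
  \left(\tfrac{\mathrm{SE}(\hat\lambda_{WT})}{\hat\lambda_{WT}}\right)^2 +
  \left(\tfrac{\mathrm{SE}(\hat\lambda_{MUT})}{\hat\lambda_{MUT}}\right)^2},$$

with the convention $\mathrm{SE}=0$ when either rate is zero (the fraction
is pinned at a boundary). A Monte-Carlo resampling check in the test suite
confirms the formula within 5% at typical counts. The fraction is invariant
to overall concentration scale — only the allele *ratio* matters — which the
tests assert directly. Replicate and cross-assay summaries
(`summarize_replicates()`) report per-assay means ± SD and a pooled mean
taken as the unweighted mean over all replicate values across assays, the
convention used when a sample is measured with several SNP assays and
reported as one number.

## Derived biological read-outs

- **Transcripts per diploid genome** (`copies_per_diploid_genome()`):
  $T = \phi \cdot s \cdot C_{cDNA} / C_{gDNA}$ from paired, same-assay cDNA
  and gDNA measurements. The diploid factor $\phi$ defaults to 2: a
  heterozygous SNP assay counts two gDNA amplicons per diploid genome, so
  the transcript-to-genome ratio must be doubled. The verbal description of
  this estimator ("divide transcript copies by gDNA amplicon copies") is
  ambiguous about the factor, so $\phi$ is an explicit, documented
  parameter rather than a constant. The recovery scaling $s$ (default 1)
  encodes the assumption that split-tube RNA/DNA isolations recover
  comparable per-cell material; users with measured recovery ratios can set
  it. CIs are delta-method intervals for a ratio of independent estimates.
- **Copy number** (`cnv()`): $CN = m \cdot C_{target}/C_{ref}$ with the
  reference at $m$ copies per genome (default 2, e.g. *Rpp30*). Homogeneous
  in the concentrations. `partition_cn()` splits the total by a
  gDNA-measured allelic fraction; continuous partitions always sum to the
  total, and integer reports round half away from zero (base `round()`
  rounds half to even, which would turn 2.5 copies into 2 — surprising in a
  copy-number report).
- **Knockdown** (`knockdown()`): expression normalized to a reference gene
  within each group, treated/control ratio per target (total, WT, MUT),
  knockdown = $100(1-\text{relative})$%. Reference normalization makes the
  read-out robust to loading differences between groups.

## What the generator emulates — and what it does not

`simulate_well()` inverts the quantification model: per droplet, WT and MUT
copy numbers are independent Poisson draws at $\lambda = C \cdot V_d$;
occupancy places the droplet in that channel's positive amplitude cluster,
and amplitudes are Gaussian around cluster means (defaults: negative 2,000,
positive 8,000, SD 300, in synthetic arbitrary units — the instrument's
amplitude physics is not being modeled, only well-separated clusters).
Optional features stress the classifier:

- **Rain** is modeled as *partial amplification*: per channel, a
  `rain_fraction` (default 1%) of the template-occupied droplets has its
  amplitude redrawn uniformly between the cluster means. Conditioning rain
  on occupancy matters: rain scales with the positive population, an empty
  well stays clean, and near-empty wells (gDNA at ~20 copies/µL,
  $\lambda \approx 0.017$) are not swamped by false positives. An
  unconditional rain model would add ~0.5% false positives per channel and
  bias such wells upward by tens of percent, destroying the ratio estimators
  downstream; under the partial-amplification model the residual bias is a
  ~0.5% *undercount* of positives per channel, which largely cancels in
  every ratio the package reports.
- **Crosstalk** adds a constant shift to the off-channel of positive
  droplets (default 0).
- **Saturation**: wells whose expected positive fraction exceeds 0.999 are
  flagged, not rejected.

Ground-truth occupancy and rain labels stay attached to simulated wells, so
tests can audit classification against labels rather than only end results.
All randomness flows through explicit seed arguments; the caller's RNG state
is saved and restored, and identical spec + seed gives bit-identical wells.

`simulate_experiment()` assembles the designs the analysis functions expect:
the seven-sample plasmid mixture series (WT fractions 1.0–0.0 at 400
copies/µL total), heterozygous-gDNA controls (100 + 100 copies/µL, 3
replicates), paired cDNA/gDNA wells (e.g. 540 or 370 vs 20 copies/µL, 3
replicate pairs), and control-vs-treated silencing designs (200/110 vs
100/55 copies/µL with an unchanged 500 copies/µL reference gene). These
defaults *are* the study conditions the package validates against; they are
parameters, not tuning knobs.

Not modeled: PCR chemistry and efficiency, droplet volume variability,
probe cross-hybridization, template aggregation. Passing tests on this
generator therefore show that the estimators are correct *under the Poisson
partitioning model with Gaussian amplitude clusters*; they cannot show
robustness to chemistry artifacts the model excludes.

## Thresholding: numerical choices

`auto_threshold()` splits one channel's amplitudes by 1-D two-means:
centers initialized at the 5th and 95th percentiles, Lloyd updates, at most
100 iterations, convergence tolerance $10^{-6}$; the threshold is the
midpoint of the final centers. Two deliberate guards:

- **Degenerate channels error.** If the final center gap is less than four
  times the largest within-cluster SD (a single Gaussian cloud split in half
  gives a gap of roughly $1.6\sigma$; genuine clusters here sit $20\sigma$
  apart), the channel has no cluster structure and the function refuses to
  pick a threshold. Silent nonsense thresholds on all-negative wells are the
  main failure mode this prevents.
- **Imbalanced wells converge.** With ~1% positives the initial centers both
  sit inside the negative cloud, but the mean updates chase the heavy upper
  tail and the split escapes to the true gap; this is asserted in the tests
  at a 1% positive fraction.

A consequence of the degenerate-channel guard: wells that genuinely lack one
cluster (the 100% WT mixture sample on the MUT channel) cannot be
auto-thresholded per well. `plate_thresholds()` pools amplitudes across all
wells of an assay and thresholds once — standard practice for a dilution or
mixture series — and is what the pipeline uses by default. Classification
uses strict inequality (`amplitude > threshold`), so droplets exactly at the
threshold count as negative: a deterministic tie-break. Rain droplets are
not excluded; whichever side of the threshold they land on is where they
count. This is a documented, stress-tested bias of roughly half the rain
fraction of a channel's positives.

## Pipeline and I/O conventions

One YAML configuration drives `run_pipeline()`; flags in the CLI wrapper
override it, and every run writes the resolved config and a log next to its
outputs. Amplitude CSVs use the header `Ch1 Amplitude,Ch2 Amplitude`
(case-insensitive, extra columns ignored with a warning) and round-trip at
full double precision; malformed cells are errors naming the file line —
readers reject rather than coerce. Result TSVs are deterministic: fixed
column order, 6 significant digits, stable row order. QC conditions (low
droplet count, saturation) flag wells and are logged; wells are never
silently dropped.

## RNA-seq cross-check

`per_snp_fraction()` computes per-SNP WT read fractions with Wilson score
intervals; `aggregate_fraction()` offers both `mean_of_snps` (default — the
convention when results are reported as an average over SNP regions) and
`pooled_counts` (sum reads first). The two differ whenever depths differ
across SNPs, and the across-SNP SD that `aggregate_fraction()` reports is
the quantity that makes shallow per-SNP RNA-seq estimates visibly noisier
than a ddPCR measurement at comparable molecule counts — the package's tests
demonstrate exactly that crossover (SD above the ddPCR SE at depth 1,000,
below it at depth $10^6$). Read alignment, strand subsetting and base-quality
filtering are upstream of this module; it starts from validated count
tables.

## Problem sizes and test design

The validation suite simulates wells at $n = 20{,}000$ droplets (the
generator's default) for all recovery checks: the 7-sample mixture series
(WT fraction recovered within 2 percentage points per sample), 3-replicate
heterozygous-gDNA controls (mean within 2 points of 50%), paired cDNA/gDNA
designs at 10–54 transcripts per diploid genome (within 10% relative with 3
replicate pairs pooled), and the 50% silencing design (within 3 points).
Calibration properties use 200 replicate wells per rate at
$\lambda \in \{0.05, 0.3, 1.5\}$ with a rain-free amplitude model — the CI
coverage band asserted is 90–98% — and 50-well batches for bias; these sizes
give Monte-Carlo error comfortably below the asserted tolerances while the
whole suite runs in well under a minute.

## Known limitations

- The delta-method allelic SE is first-order; at extreme fractions with few
  positive droplets on the minor channel it understates the uncertainty
  (the exact CI mode helps for single targets, not for the fraction).
- Two-means thresholding assumes two amplitude clusters per channel; heavy
  rain (approaching the 0.5 cap) or drifting clusters would need the manual
  threshold mode.
- `copies_per_diploid_genome()` inherits any systematic cDNA/gDNA recovery
  asymmetry unless `scaling` is measured and supplied; reverse-transcription
  efficiency is not modeled, so values are transcript *equivalents*.
- Copy-number partitioning assumes exactly two alleles and a correctly
  measured gDNA fraction; integer reports are conveniences, not calls.
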