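---
title: "Screening for coordinated ncRNA–mRNA regulation with windowed NB tests"
author: "ncoreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for coordinated ncRNA–mRNA regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncoreg)
```

## The biological question

ER-positive breast cancer cells adapted to long-term oestrogen deprivation
(LTED) up-regulate the oestrogen-receptor gene *ESR1*, and the locus starts
producing noncoding RNA from a broad region — introns, the gene body, and an
enhancer-like element ~40 kb upstream of the promoter — forming a
transcriptionally active chromatin domain of roughly 700 kb. Treatment with
resveratrol reverses both the mRNA and the ncRNA induction. `ncoreg`
implements the genome-wide screen behind that observation: find gene loci
whose mRNA **and** surrounding ncRNA are *coordinately* up-regulated on
adaptation (condition A → B) and down-regulated on treatment (B → C), from
nothing but aligned reads, an annotation, and a three-condition sample
sheet.

The screen is a pipeline of small, testable stages:

1. **Window counting** — reads are assigned by midpoint to 100-bp windows
   (per strand) and, separately, to exon unions per gene (the mRNA track).
2. **Differential testing** — median-of-ratios normalization and a
   conditioned negative-binomial exact test per feature; a feature is
   labelled `up` iff log2FC > 1 **and** P < 0.01 (strict), `down` for the
   mirror case.
3. **Region classification** — significant windows merge into regions,
   classified against the annotation as complete exon / exon–intron /
   intron / intergene. Everything except complete exons is an ncRNA
   candidate.
4. **The screen** — a gene is a *coordinated locus* iff its mRNA is up in
   A→B and down in B→C and it has at least one assigned ncRNA region up in
   A→B and one down in B→C. For each coordinated locus a contiguous
   chromatin domain is called by chaining its ncRNA regions to the gene
   span through gaps of at most `bridge_gap`.
5. **Pattern clustering** — FPKM profiles filtered by IQR > 10 and
   max FPKM > 5 are z-scored and k-means clustered; clusters whose centroid
   peaks in the middle condition give the induced-then-repressed gene set.

## The statistical model

Counts are modelled negative-binomially, variance = μ + αμ². Size factors
are median-of-ratios: for sample *j*,
*s*<sub>*j*</sub> = median<sub>*i*</sub>(*k*<sub>*ij*</sub>/geomean<sub>*i*</sub>),
over features positive in every sample, rescaled to geometric mean 1. The
two-condition test conditions on the total *N* = *K*<sub>A</sub> +
*K*<sub>B</sub>: the p-value is the summed conditional probability of all
splits (*a*, *N*−*a*) no more likely than the observed one, with per-side
means proportional to the summed size factors and a common dispersion α.
Ties (masses within a relative 10⁻⁸ of the observed mass) are included,
which keeps the rejection region reproducible across independently coded
enumerators. The masses are evaluated from cumulative logs of the rising
factorial with `log1p` for the size term — `dnbinom` itself drifts by ~10⁻⁹
relative at size 10⁸, which matters when you promise agreement with an
enumeration oracle to 10⁻⁹.

### Dispersion without replicates

The canonical design has one library per condition, which makes dispersion
estimation the load-bearing choice:

* `mode = "pooled"` (replicated designs): per-feature method-of-moments on
  normalized counts with within-condition variances pooled,
  α = max(floor, (v − m·m̄)/m²), m̄ the mean of 1/*s*<sub>*j*</sub>.
* `mode = "blind"`: the same estimator with all samples as one group. This
  is deliberately *self-masking*: a genuine fold change inflates its own
  feature's variance estimate, so blind estimates are sharply conservative —
  useful for null calibration (the no-effect suite runs blind and its
  false-positive fraction is far below nominal), useless for detection: the
  p-value of a planted effect is bounded away from any small threshold no
  matter the depth.
* `mode = "fixed"` (the pipeline default when any condition lacks
  replicates): every feature gets a prior dispersion `alpha0`, default 0.01
  — a squared biological CV of 0.1, the standard working assumption for
  libraries from the same cell line in no-replicate practice. This is an
  assumption, stated openly, not an estimate; it is what makes a
  no-replicate screen able to call anything at all.

Raw p-values gate the labels, reproducing the original selection; BH-adjusted
values are always reported alongside for modern use.

One caveat the package does not hide: the conditioned exact test
consumes **raw count sums**. Rescaling a sample's counts (together with its
size factor) leaves all normalized means and fold changes unchanged but
multiplies the evidence the test sees — counts are counts, and fabricating
more of them fabricates certainty. Only depth differences routed through
size factors are properly normalized away.

### Normalization in the pipeline

Median-of-ratios assumes most features are not differential. In the
synthetic genome (and in any strongly perturbed window track) nearly every
*expressed window* carries planted signal, so window-level factors would
absorb the fold change itself. The pipeline therefore estimates size
factors on the **gene-level** table — where flat null genes are the
majority — and applies them to the window tests as well.

## The synthetic study system

`sim_config()` defaults are the study conditions the acceptance suite runs
under; they are chosen once, on biological grounds, and not revisited:

| parameter | default | rationale |
|---|---|---|
| roster | 5 coordinated + 5 mRNA-only + 20 null (5 silent) | the screen's published scale: a handful of coordinated loci against a flat background |
| long-gene span | normal(280 kb, 30 kb), min 180 kb | coordinated loci are long genes (~280 kb average); 8 exons, ESR1-like |
| short-gene span | normal(17 kb, 3 kb), min 6 kb | the non-coordinated group averages ~17 kb |
| planted log2FC | +2 (A→B), −2 (B→C) | comfortably past the |log2FC| > 1 gate, as the headline loci are |
| ncRNA fraction | 0.25 of the exonic rate | intronic ncRNA is abundant but clearly below mRNA signal |
| upstream element | 2 kb, 40 kb upstream of the promoter | the enhancer-like upstream transcript sits ~40 kb out |
| exonic rate | 40 reads / 100-bp tile (baseline) | enough per-window counts for the exact test to resolve 4-fold at P < 0.01 |
| background | 0.05 reads/tile | low pervasive transcription everywhere |
| dispersion α | 0.1 | bulk RNA-seq between independently adapted cultures |
| design | 3 samples, one per condition | the no-replicate design of the original experiment |

Counts are drawn per 100-bp tile and materialised as reads whose
**midpoints** are uniform within the tile, so midpoint-based window
counting recovers exactly the drawn NB counts — the statistical truth is
decoupled from read placement. Gene and exon coordinates snap to the tile
grid; without that, tiles straddling exon boundaries of mRNA-only genes
spawn spurious exon–intron "ncRNA" regions and the planted classes are not
recoverable. Null genes are expressed-but-flat (they anchor
normalization); a configurable number are silent neighbours placed next to
coordinated genes, emulating the untouched gene beside the induced locus.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: splicing-aware coverage shapes, sequence
content and mappability, fragment-length effects, exon boundaries off the
window grid, overlapping genes, isoform switching, and genuine biological
replicate structure. The screen's perfect sensitivity here is a statement
about the pipeline's correctness under its own model, not about its power
on a real genome.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere inside the package; GTF I/O
  converts to/from 1-based inclusive at exactly one boundary, BED is native.
  Gene length is the genomic span (end − start), the convention under which
  the coordinated group averages hundreds of kb.
* Window grids start at every multiple of `step` below the chromosome
  length, last window truncated. The default `step = width` (tiling) makes
  each read count exactly once; overlapping windows are supported but
  warned about, since they are statistically dependent in testing.
* Merging joins same-direction significant windows within `max_gap` (default
  0: only touching windows); host-gene ties go to the lexicographically
  smallest id, logged.
* A region extending beyond its host's span but touching an exon is
  exon–intron; there is no mixed class. Window regions cannot see splice
  junctions, so this positional definition stands in for junction-based
  "exon–intron fusion" calls.
* `upstream_flank` defaults to 50 kb — covering the 40-kb upstream-element
  case with margin, since the biology gives an example distance, not a
  rule. `bridge_gap` defaults to 10 kb for domain chaining; the ~700-kb
  domain is visually contiguous but no gap tolerance is reported, so the
  called domain is the conservative chained interval.
* Quartiles for the IQR filter use linear interpolation (`quantile` type
  7); the IQR is computed across all three condition values on linear FPKM.
  Thresholds are strict (IQR exactly 10 fails).
* k-means runs on row-z-scored profiles (patterns, not magnitudes), with
  k-means++ seeding and the best of 50 restarts by within-cluster SS;
  pattern extraction is centroid-shape based because cluster numbering is
  arbitrary. On the toy genome the pipeline clamps k to the number of
  filtered profiles (a 30-gene genome cannot support 14 clusters).
* Degenerate inputs: empty read sets produce an empty screen, not an
  error; all-zero features are excluded from testing; an empty region set
  reports an undefined (NaN) ncRNA fraction rather than 0.

## Known limitations

FPKM is total-count normalized, so a strong global induction inflates the
denominator: on the toy genome condition B's library is ~4× deeper, which
flattens regulated genes' FPKM profiles and makes flat genes look
down-regulated. That composition effect is faithful to FPKM as practised —
and is why the differential stages use median-of-ratios factors instead.
The profile-clustering stage is therefore best read qualitatively on
strongly perturbed toy data.

The screen requires ncRNA regions to be gene-assigned in both contrasts but
not positionally identical between them; loci with ncRNA shifting along the
gene body between conditions still count as coordinated.

## Problem sizes

The shipped analyses and tests run a ~4.3-Mb genome (≈43,000 windows per
strand, ~0.9 M reads across three samples), ten simulation seeds for the
recovery study, 5,000 windows for null calibration, and all ~1.8 × 10⁵
count splits with totals ≤ 300 for the exact-test oracle — sizes chosen so
a complete run stays desk-scale while every stage is exercised at
non-trivial scale.
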