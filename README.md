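# ncoreg — windowed detection of coordinated ncRNA–mRNA regulation

`ncoreg` is an R package for a genome-wide screen that asks: **which gene
loci turn their messenger RNA and their surrounding noncoding RNA on and
off together** across a three-condition design — baseline (A), adapted
(B, e.g. long-term oestrogen deprivation of ER-positive breast cancer
cells), treated (C, e.g. resveratrol)? The motivating case is the *ESR1*
locus, where adaptation induces ncRNA across introns and an enhancer-like
element ~40 kb upstream, defining a ~700-kb transcriptionally active
chromatin domain that collapses again under treatment.

It is written for computational biologists who have aligned reads (BED6),
a GTF annotation and a sample sheet — or nobody's data at all: a
negative-binomial simulator with planted coordinated loci drives every
test, so the whole pipeline is verifiable offline.

## The method in brief

* reads → counts in 100-bp stranded windows (midpoint assignment) and in
  exon unions per gene;
* median-of-ratios size factors; per-feature NB exact test conditioned on
  the pairwise total, variance μ + αμ²; label `up` iff log2FC > 1 and
  P < 0.01 (strict), `down` mirrored;
* significant windows merge into regions classified as complete exon /
  exon–intron / intron / intergene; non-exonic regions are ncRNA
  candidates, assigned to their host gene or to a promoter ≤ 50 kb
  downstream;
* a **coordinated locus** has mRNA up (A→B) and down (B→C) *and* assigned
  ncRNA regions up (A→B) and down (B→C); its chromatin domain is the gene
  span chained with its ncRNA regions through gaps ≤ 10 kb;
* FPKM profiles (IQR > 10, max FPKM > 5) are z-scored and k-means
  clustered; clusters whose centroid peaks in B give the
  induced-then-repressed gene set.

See `vignettes/coordinated-ncrna-screen.Rmd` for the model, parameter
rationale and limitations.

## Worked example

The `analysis/` scripts run the whole study on the simulated genome; each
is a thin driver over package functions and writes under `results/`:

```sh
Rscript analysis/01_simulate.R      # toy genome + stranded reads
Rscript analysis/02_count.R         # 100-bp window + gene counts
Rscript analysis/03_diffexpr.R      # NB exact tests, both contrasts
Rscript analysis/04_classify.R      # regions + ncRNA candidates
Rscript analysis/05_screen.R        # the co-regulation screen + domains
Rscript analysis/06_cluster.R       # FPKM k-means patterns
```

What they printed on this machine (seed 1):

```
Simulated 30 genes on a 4,272,600 bp chromosome
Reads per sample:
   A_1    B_1    C_1
152157 585574 152198

A_B: 9737/17441 windows significant, 10/25 genes
B_C: 10071/17410 windows significant, 11/26 genes

A_B: 2954 regions (complete_exon=58, exon_intron=29, intergene=24,
     intron=2843); ncRNA candidates 98.0%

Verdicts:
coordinated   mrna_only       other
          5           5          15

Recovered 5/5 planted coordinated loci; 0 null genes miscalled
```

Reading it: condition B gains ~4× the reads because every planted locus is
induced there; ~10,000 windows per contrast pass the |log2FC| > 1, P < 0.01
gate; merged regions are overwhelmingly intronic (this toy genome is
ncRNA-rich by design, so its candidate fraction is far above what a real
genome shows); and the screen recovers exactly the five planted
coordinated long genes — with called domains overlapping the planted
domains at Jaccard ≥ 0.85 — while the five mRNA-only short genes are kept
out of the coordinated set and no flat gene is miscalled.

The same run from R:

```r
library(ncoreg)
report <- run_pipeline(pipeline_config(seed = 1))
report$recovery
#> $sensitivity                 [1] 1
#> $n_false_coordinated_null    [1] 0
#> $domain_jaccard_ge_0.8       [1] 1
```

Packaged reference data: `reference_gene_lengths()` returns the published
13 + 13 gene sets with/without coordinated transcription; their group
means recompute to 280,065 bp (coordinated; the source table prints
280,142 — a documented discrepancy of its printed column) and 16,839 bp
(non-coordinated, matching exactly).

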