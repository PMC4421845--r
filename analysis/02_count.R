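#!/usr/bin/env Rscript
# Stage 2 — count reads in 100-bp stranded windows (the ncRNA track) and
# over exon unions per gene (the mRNA track). Reads results/sim/, writes
# results/window_counts.tsv and results/gene_counts.tsv.

library(ncoreg)

ann <- read_annotation("results/sim/annotation.gtf", "results/sim/chrom.sizes")
sheet <- read.table("results/sim/samples.tsv", header = TRUE,
                    colClasses = "character")
reads <- lapply(setNames(sheet$sample, sheet$sample), function(s)
  read_bed6(file.path("results/sim", paste0(s, ".bed"))))

grid <- make_grid(ann, width = 100, strand_mode = "stranded_same")
wcm <- count_reads(reads, grid)
gcm <- count_genes(reads, ann)

write_counts(wcm, "results/window_counts.tsv")
write_counts(gcm, "results/gene_counts.tsv")

cat("Windows:", nrow(wcm$counts), " assigned reads:", sum(wcm$counts), "\n")
cat("Gene (exonic) reads:", sum(gcm$counts), "of", sum(gcm$totals), "\n")
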