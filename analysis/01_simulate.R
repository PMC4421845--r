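#!/usr/bin/env Rscript
# Stage 1 — simulate the study system: a toy genome with five ESR1-like long
# genes whose introns and an upstream element transcribe ncRNA that rises
# under hormone deprivation (A -> B) and falls under treatment (B -> C),
# five ERBB2-like short genes with mRNA-only regulation, flat null genes,
# and silent SYNE1-like neighbours. Writes GTF, per-sample BED6 reads, the
# truth table and a config echo under results/sim/.

library(ncoreg)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1

cfg <- sim_config(seed = seed)
ann <- simulate_annotation(cfg)
truth <- sim_truth(cfg, ann)
reads <- simulate_reads(cfg, ann)

dir.create("results", showWarnings = FALSE)
write_simulation(cfg, ann, truth, reads, "results/sim")

cat("Simulated", nrow(ann$genes), "genes on a",
    format(unname(ann$sizes[1]), big.mark = ","), "bp chromosome\n")
cat("Reads per sample:\n")
print(reads$totals)
cat("Outputs in results/sim/\n")
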