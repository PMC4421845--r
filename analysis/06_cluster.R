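#!/usr/bin/env Rscript
# Stage 6 — FPKM quantification, IQR>10 & FPKM>5 filtering, k-means pattern
# clustering of z-scored 3-condition profiles, and extraction of the
# induced-then-repressed (up-then-down) gene set. k is clamped to the
# number of filtered profiles on this desk-scale genome.

library(ncoreg)

ann <- read_annotation("results/sim/annotation.gtf", "results/sim/chrom.sizes")
gcm <- read_counts("results/gene_counts.tsv")
sheet <- read.table("results/sim/samples.tsv", header = TRUE,
                    colClasses = "character")

profiles <- fpkm_profiles(gcm, ann, sheet)
write.table(data.frame(gene_id = rownames(profiles), round(profiles, 3)),
            "results/fpkm.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

pass <- filter_genes(profiles)   # IQR > 10, max FPKM > 5
cat(sum(pass), "of", length(pass), "genes pass the variance/abundance filter\n")

filtered <- profiles[pass, , drop = FALSE]
k <- min(14, nrow(filtered))
cl <- kmeans_cluster(filtered, k = k, seed = 1)
write.table(data.frame(gene_id = names(cl$cluster), cluster = cl$cluster),
            "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(cluster = seq_len(cl$k), round(cl$centroids, 3)),
            "results/centroids.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

updown <- extract_pattern(cl, "up_then_down")
cat("k =", cl$k, "clusters;", length(updown),
    "genes follow the up-then-down pattern:\n")
print(updown)
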