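# Independent brute-force oracles. Each deliberately uses a different
# algorithm from the package path it checks.

# per-base interval overlap
bf_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  sum((seq(a$start, a$end - 1)) %in% seq(b$start, b$end - 1))
}

# NB exact-test p-value by multiplicative recurrence over all splits
bf_exact_p <- function(kA, kB, sA = 1, sB = 1, alpha = 1e-8) {
  N <- sum(kA) + sum(kB)
  if (N == 0) return(1)
  SA <- sum(sA); SB <- sum(sB)
  muA <- N * SA / (SA + SB); muB <- N - muA
  mass <- function(mu) {
    if (alpha < 1e-10) return(dpois(0:N, mu))
    r <- 1 / alpha
    v <- numeric(N + 1)
    v[1] <- exp(r * log1p(-mu / (r + mu)))
    for (x in 0:(N - 1)) v[x + 2] <- v[x + 1] * (x + r) / (x + 1) * mu / (r + mu)
    v
  }
  pr <- mass(muA) * rev(mass(muB))
  obs <- pr[sum(kA) + 1]
  sum(pr[pr <= obs * (1 + 1e-8)]) / sum(pr)
}

# all NB exact-test p-values for splits of a fixed total at once
bf_exact_p_all <- function(N, alpha, SA = 1, SB = 1) {
  if (N == 0) return(1)
  muA <- N * SA / (SA + SB); muB <- N - muA
  mass <- function(mu) {
    if (alpha < 1e-10) return(dpois(0:N, mu))
    r <- 1 / alpha
    v <- numeric(N + 1)
    v[1] <- exp(r * log1p(-mu / (r + mu)))
    for (x in 0:(N - 1)) v[x + 2] <- v[x + 1] * (x + r) / (x + 1) * mu / (r + mu)
    v
  }
  pr <- mass(muA) * rev(mass(muB))
  tot <- sum(pr)
  vapply(0:N + 1, function(i) sum(pr[pr <= pr[i] * (1 + 1e-8)]) / tot,
         numeric(1))
}

# brute-force midpoint window counting: loop reads x windows
bf_count <- function(reads, windows, stranded) {
  n <- integer(nrow(windows))
  for (i in seq_len(nrow(reads))) {
    mid <- floor((reads$start[i] + reads$end[i]) / 2)
    for (w in seq_len(nrow(windows))) {
      if (windows$chrom[w] != reads$chrom[i]) next
      if (stranded && windows$strand[w] != reads$strand[i]) next
      if (mid >= windows$start[w] && mid < windows$end[w])
        n[w] <- n[w] + 1L
    }
  }
  n
}

# brute-force merge: union-find over significant windows
bf_merge <- function(sig, max_gap) {
  n <- nrow(sig)
  if (!n) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- sig$chrom[i] == sig$chrom[j] && sig$strand[i] == sig$strand[j] &&
      sig$label[i] == sig$label[j]
    gap <- max(sig$start[i], sig$start[j]) - min(sig$end[i], sig$end[j])
    if (same && gap <= max_gap) parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), roots), function(ix)
    c(start = min(sig$start[ix]), end = max(sig$end[ix])))
}

# per-base region classification against an annotation
bf_classify <- function(region, ann, stranded = TRUE) {
  bases <- seq(region$start, region$end - 1)
  g <- ann$genes[ann$genes$chrom == region$chrom, , drop = FALSE]
  if (stranded && region$strand != "*")
    g <- g[g$strand == region$strand, , drop = FALSE]
  ov <- vapply(seq_len(nrow(g)), function(i)
    sum(bases >= g$start[i] & bases < g$end[i]), numeric(1))
  if (!length(ov) || max(ov) == 0)
    return(list(class = "intergene", host = NA_character_))
  host <- sort(g$gene_id[ov == max(ov)])[1]
  ex <- ann$exons[ann$exons$gene_id == host, , drop = FALSE]
  in_exon <- vapply(bases, function(b)
    any(b >= ex$start & b < ex$end), logical(1))
  hg <- ann$genes[host, ]
  in_span <- bases >= hg$start & bases < hg$end
  cls <- if (all(in_span) && all(in_exon)) "complete_exon"
  else if (any(in_exon)) "exon_intron"
  else "intron"
  list(class = cls, host = host)
}

# small hand-built annotation: one 3-exon gene + one single-exon gene
toy_annotation <- function() {
  sizes <- c(chrT = 10000)
  genes <- data.frame(
    gene_id = c("gA", "gB"),
    chrom = "chrT", start = c(1000, 6000), end = c(3000, 6500),
    strand = c("+", "-"), biotype = "gene")
  exons <- data.frame(
    gene_id = c("gA", "gA", "gA", "gB"),
    chrom = "chrT",
    start = c(1000, 1500, 2700, 6000), end = c(1200, 1800, 3000, 6500),
    strand = c("+", "+", "+", "-"))
  genome_annotation(genes, exons, sizes)
}

# count_matrix wrapper around a bare matrix
as_count_matrix <- function(k, prefix = "f") {
  ids <- paste0(prefix, seq_len(nrow(k)))
  rownames(k) <- ids
  structure(list(
    features = data.frame(feature_id = ids, chrom = "chrT",
                          start = (seq_len(nrow(k)) - 1) * 100,
                          end = seq_len(nrow(k)) * 100, strand = "*"),
    counts = k, totals = colSums(k),
    skipped = setNames(rep(0, ncol(k)), colnames(k))),
    class = "count_matrix")
}
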