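# Merge significant windows into regions and classify each region against
# the annotation into the four categories: complete_exon, exon_intron,
# intron, intergene. Regions not fully exonic are the ncRNA candidates.

#' Merge significant differential windows into regions
#'
#' Same-direction significant windows (label `up` or `down`) on the same
#' chromosome and strand merge when the gap between them is at most
#' `max_gap` bp (default 0: only touching/overlapping windows merge, so
#' adjacent tiling windows form one region). Merging is idempotent.
#'
#' @param diff a `diff_result` from one grid and one contrast.
#' @param max_gap maximum bridged gap in bp.
#' @return data.frame of regions: chrom, start, end, strand, direction,
#'   n_windows, log2fc (count-weighted mean), min_p.
#' @export
merge_windows <- function(diff, max_gap = 0) {
  sig <- diff[diff$label %in% c("up", "down"), , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      direction = character(), n_windows = integer(),
                      log2fc = numeric(), min_p = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  sig <- sig[order(sig$chrom, sig$strand, sig$label, sig$start), , drop = FALSE]
  grp <- paste(sig$chrom, sig$strand, sig$label)
  new_grp <- c(TRUE, grp[-1] != grp[-nrow(sig)])
  gap_break <- c(TRUE, sig$start[-1] - sig$end[-nrow(sig)] > max_gap)
  region_id <- cumsum(new_grp | gap_break)
  w <- sig$mean_a + sig$mean_b  # weight: total normalized signal
  out <- lapply(split(seq_len(nrow(sig)), region_id), function(ix) {
    data.frame(chrom = sig$chrom[ix[1]], start = min(sig$start[ix]),
               end = max(sig$end[ix]), strand = sig$strand[ix[1]],
               direction = sig$label[ix[1]], n_windows = length(ix),
               log2fc = sum(sig$log2fc[ix] * w[ix]) / sum(w[ix]),
               min_p = min(sig$pval[ix]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Classify regions against the annotation
#'
#' Decision rules, applied in order per region:
#' 1. no overlap with any (strand-compatible) gene span -> `intergene`;
#' 2. otherwise host = gene with maximal bp overlap (ties: lexicographically
#'    smallest gene id);
#' 3. region inside the host span and entirely exonic -> `complete_exon`;
#' 4. at least one exonic and one non-exonic base -> `exon_intron`;
#' 5. the region's intersection with the host entirely intronic -> `intron`.
#'
#' In stranded mode (`stranded = TRUE`) only genes on the region's strand
#' can host it; unstranded regions (`strand == "*"`) match any gene.
#'
#' @param regions data.frame of intervals (chrom, start, end, strand, ...),
#'   e.g. from [merge_windows()].
#' @param ann a `genome_annotation`.
#' @param stranded require region/host strand agreement (default TRUE).
#' @return `regions` with columns `class` and `host_gene` (NA for
#'   unassigned intergenic regions) appended.
#' @export
classify_regions <- function(regions, ann, stranded = TRUE) {
  g <- ann$genes
  cls <- character(nrow(regions)); host <- rep(NA_character_, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, , drop = FALSE]
    cand <- g[g$chrom == r$chrom, , drop = FALSE]
    if (stranded && r$strand != "*")
      cand <- cand[cand$strand == r$strand, , drop = FALSE]
    ov <- if (nrow(cand)) overlap_bp(cand, r) else numeric(0)
    if (!length(ov) || max(ov) == 0) { cls[i] <- "intergene"; next }
    best <- which(ov == max(ov))
    hg <- sort(cand$gene_id[best])[1]
    if (length(best) > 1)
      message("host-gene tie at ", r$chrom, ":", r$start, "-", r$end,
              "; choosing ", hg)
    host[i] <- hg
    ex <- ann$exons[ann$exons$gene_id == hg, , drop = FALSE]
    exonic <- sum(overlap_bp(ex, r))
    hg_row <- g[hg, , drop = FALSE]
    inside <- r$start >= hg_row$start && r$end <= hg_row$end
    nonexonic_bp <- (r$end - r$start) - exonic  # intronic or past the span
    if (inside && nonexonic_bp == 0) cls[i] <- "complete_exon"
    else if (exonic > 0) cls[i] <- "exon_intron"
    else cls[i] <- "intron"
  }
  regions$class <- cls
  regions$host_gene <- host
  regions
}

#' ncRNA candidate regions
#'
#' Regions whose class is not `complete_exon` (exon-intron, intron and
#' intergene regions) are the ncRNA candidates.
#'
#' @param regions classified regions (from [classify_regions()]).
#' @return list: `candidates` (the subset), `fraction_pct` (percentage of
#'   all regions; `NaN` for empty input).
#' @export
ncrna_candidates <- function(regions) {
  sub <- regions[regions$class != "complete_exon", , drop = FALSE]
  list(candidates = sub,
       fraction_pct = if (nrow(regions)) 100 * nrow(sub) / nrow(regions)
                      else NaN)
}

#' Write classified regions as BED6+
#'
#' name = class, score = -log10(min p), extra columns host gene and
#' direction.
#'
#' @param regions classified regions.
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  df <- data.frame(chrom = regions$chrom, start = as.integer(regions$start),
                   end = as.integer(regions$end), name = regions$class,
                   score = round(-log10(pmax(regions$min_p, 1e-300)), 3),
                   strand = regions$strand,
                   host_gene = ifelse(is.na(regions$host_gene), ".",
                                      regions$host_gene),
                   direction = regions$direction)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
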