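# The headline screen: intersect mRNA and ncRNA differential calls across
# the two contrasts (baseline -> deprived -> treated), extract coordinated
# loci, call the contiguous ncRNA chromatin domain, summarize gene lengths.

#' Assign classified regions to gene loci
#'
#' Genic regions (intron, exon_intron, complete_exon) belong to their host
#' gene. Intergenic regions are assigned to the nearest gene whose
#' transcription start lies downstream of the region on the same strand
#' within `upstream_flank` bp (the upstream-ncRNA rule: an enhancer-like
#' transcript ~40 kb before the promoter belongs to the locus); otherwise
#' they stay unassigned.
#'
#' @param regions classified regions (from [classify_regions()]).
#' @param ann a `genome_annotation`.
#' @param upstream_flank maximum promoter distance in bp (default 50000).
#' @return `regions` with an `assigned_gene` column (NA when unassigned).
#' @export
assign_regions <- function(regions, ann, upstream_flank = 50000) {
  g <- ann$genes
  assigned <- regions$host_gene
  inter <- which(regions$class == "intergene")
  for (i in inter) {
    r <- regions[i, , drop = FALSE]
    cand <- g[g$chrom == r$chrom, , drop = FALSE]
    if (r$strand != "*")
      cand <- cand[cand$strand == r$strand, , drop = FALSE]
    if (!nrow(cand)) next
    # distance from region to the promoter it could lie upstream of
    d <- ifelse(cand$strand == "-", r$start - cand$end, cand$start - r$end)
    ok <- d >= 0 & d <= upstream_flank
    if (!any(ok)) next
    assigned[i] <- cand$gene_id[ok][which.min(d[ok])]
  }
  regions$assigned_gene <- assigned
  regions
}

#' Four-way Venn pattern counts
#'
#' Counts every element of the union of four sets into exactly one of the 15
#' non-empty membership patterns.
#'
#' @param sets named list of four character vectors.
#' @return named integer vector over patterns like `"A"`, `"A+B"`, ...,
#'   using the set names joined by `+`.
#' @export
four_way_venn <- function(sets) {
  stopifnot(length(sets) == 4)
  nm <- names(sets)
  if (is.null(nm)) nm <- names(sets) <- LETTERS[1:4]
  sets <- lapply(sets, unique)
  u <- unique(unlist(sets))
  member <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1) member <- matrix(member, nrow = 1,
                                       dimnames = list(NULL, nm))
  pats <- unlist(lapply(1:4, function(k)
    utils::combn(nm, k, paste, collapse = "+")))
  counts <- setNames(integer(length(pats)), pats)
  key <- apply(member, 1, function(m) paste(nm[m], collapse = "+"))
  tab <- table(key)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Call the contiguous ncRNA chromatin domain of a locus
#'
#' The minimal interval covering the gene span plus every assigned ncRNA
#' region chainable to it through gaps of at most `bridge_gap` bp; regions
#' beyond an unbridged gap are excluded. Iterates to a fixed point so chains
#' of regions extend the domain stepwise.
#'
#' @param gene_interval one-row data.frame (chrom, start, end).
#' @param regions data.frame of ncRNA region intervals assigned to the gene.
#' @param bridge_gap maximum bridged gap in bp (default 10000).
#' @return list(start, end) of the called domain.
#' @export
call_domain <- function(gene_interval, regions, bridge_gap = 10000) {
  lo <- gene_interval$start; hi <- gene_interval$end
  regions <- regions[regions$chrom == gene_interval$chrom, , drop = FALSE]
  repeat {
    gap <- pmax(regions$start - hi, lo - regions$end)  # <= 0 when touching
    take <- gap <= bridge_gap
    if (!any(take)) break
    new_lo <- min(lo, regions$start[take]); new_hi <- max(hi, regions$end[take])
    regions <- regions[!take, , drop = FALSE]
    if (new_lo == lo && new_hi == hi) break
    lo <- new_lo; hi <- new_hi
  }
  list(start = lo, end = hi)
}

#' Screen for coordinated ncRNA-mRNA loci
#'
#' A gene is `coordinated` iff its mRNA is up in the first contrast and down
#' in the second AND at least one assigned ncRNA region (class other than
#' complete_exon) is up in the first contrast and at least one is down in
#' the second. Genes meeting only the mRNA criterion are `mrna_only`;
#' everything else is `other`. For coordinated loci the ncRNA chromatin
#' domain is called with [call_domain()].
#'
#' @param mrna_ab,mrna_bc gene-level `diff_result`s for the two contrasts
#'   (feature_id = gene id).
#' @param ncrna_ab,ncrna_bc classified + assigned window regions for the two
#'   contrasts (from [assign_regions()]).
#' @param ann a `genome_annotation`.
#' @param bridge_gap domain-chaining gap in bp.
#' @return data.frame of class `coreg_screen`: gene_id, length_bp, mrna
#'   labels, ncRNA region counts, verdict, domain coordinates (NA when no
#'   domain), sorted by gene length descending.
#' @export
coregulation_screen <- function(mrna_ab, mrna_bc, ncrna_ab, ncrna_bc, ann,
                                bridge_gap = 10000) {
  de_genes <- union(mrna_ab$feature_id, mrna_bc$feature_id)
  unknown <- setdiff(de_genes, ann$genes$gene_id)
  if (length(unknown))
    stop("gene id(s) in DE results absent from annotation: ",
         paste(unknown, collapse = ", "))
  seen <- unique(c(de_genes,
                   ncrna_ab$assigned_gene[!is.na(ncrna_ab$assigned_gene)],
                   ncrna_bc$assigned_gene[!is.na(ncrna_bc$assigned_gene)]))
  ids <- ann$genes$gene_id[ann$genes$gene_id %in% seen]
  lab <- function(de, id) {
    m <- de$label[match(id, de$feature_id)]
    ifelse(is.na(m), "ns", m)
  }
  mlab_ab <- lab(mrna_ab, ids); mlab_bc <- lab(mrna_bc, ids)
  nc_ab <- ncrna_ab[ncrna_ab$class != "complete_exon" &
                    !is.na(ncrna_ab$assigned_gene) &
                    ncrna_ab$direction == "up", , drop = FALSE]
  nc_bc <- ncrna_bc[ncrna_bc$class != "complete_exon" &
                    !is.na(ncrna_bc$assigned_gene) &
                    ncrna_bc$direction == "down", , drop = FALSE]
  n_up <- table(factor(nc_ab$assigned_gene, levels = ids))
  n_dn <- table(factor(nc_bc$assigned_gene, levels = ids))
  mrna_ok <- mlab_ab == "up" & mlab_bc == "down"
  coord <- mrna_ok & n_up >= 1 & n_dn >= 1
  verdict <- ifelse(coord, "coordinated",
                    ifelse(mrna_ok, "mrna_only", "other"))
  dom_s <- dom_e <- rep(NA_real_, length(ids))
  for (i in which(coord)) {
    gi <- ann$genes[ids[i], , drop = FALSE]
    reg <- rbind(nc_ab[nc_ab$assigned_gene == ids[i],
                       c("chrom", "start", "end"), drop = FALSE],
                 nc_bc[nc_bc$assigned_gene == ids[i],
                       c("chrom", "start", "end"), drop = FALSE])
    d <- call_domain(gi, reg, bridge_gap)
    dom_s[i] <- d$start; dom_e[i] <- d$end
  }
  out <- data.frame(gene_id = ids,
                    length_bp = ann$genes[ids, "end"] - ann$genes[ids, "start"],
                    mrna_ab = unname(mlab_ab), mrna_bc = unname(mlab_bc),
                    ncrna_up_ab = as.integer(n_up),
                    ncrna_down_bc = as.integer(n_dn),
                    verdict = unname(verdict),
                    domain_start = dom_s, domain_end = dom_e,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$length_bp, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coreg_screen", class(out))
  out
}

#' Mean gene length per group
#'
#' Arithmetic mean of the genomic lengths, rounded half-up to the nearest
#' integer bp. Empty groups report `n = 0` and an undefined (NA) mean.
#'
#' @param groups named list of numeric length vectors (bp).
#' @return data.frame: group, n, mean_length_bp.
#' @export
length_summary <- function(groups) {
  out <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(group = g, n = length(x),
               mean_length_bp = if (length(x)) floor(mean(x) + 0.5) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Published gene sets with and without coordinated ncRNA-mRNA regulation
#'
#' The 13 + 13 genes reported in the LTED breast-cancer adaptation model:
#' genes whose mRNA and surrounding ncRNA are coordinately up- (deprivation)
#' then down-regulated (treatment), and genes whose mRNA shows the same
#' pattern without ncRNA co-regulation, with their genomic lengths in bp.
#'
#' @return data.frame: gene, group (`coordinated` / `non_coordinated`),
#'   length_bp.
#' @export
reference_gene_lengths <- function() {
  path <- system.file("extdata", "coordinated_gene_lengths.tsv",
                      package = "ncoreg", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "numeric"))
}
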