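#' @importFrom data.table data.table fread fwrite setorder rbindlist :=
#' @importFrom stats median quantile rnbinom rpois runif setNames
#' @importFrom utils head tail
NULL

# Internal coordinate convention: 0-based half-open [start, end), as in BED.
# GTF I/O converts to/from 1-based inclusive at the boundary; nothing else
# ever shifts a coordinate.

#' Construct a table of genomic intervals
#'
#' Intervals are plain data.frames with columns `chrom`, `start`, `end`,
#' `strand`, in 0-based half-open coordinates. `strand` is one of
#' `"+"`, `"-"`, `"*"` (unstranded).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-valued positions, `0 <= start < end`.
#' @param strand strand characters, recycled.
#' @param sizes optional named vector of chromosome lengths; when given,
#'   every `chrom` must be present and `end` must not exceed its length.
#' @return data.frame with columns chrom, start, end, strand.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*", sizes = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  validate_intervals(df, sizes)
  df
}

validate_intervals <- function(df, sizes = NULL) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$start >= df$end)) stop("interval must satisfy start < end")
  if (!all(df$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  if (!is.null(sizes)) {
    bad <- setdiff(unique(df$chrom), names(sizes))
    if (length(bad))
      stop("chromosome(s) absent from size table: ", paste(bad, collapse = ", "))
    if (any(df$end > sizes[df$chrom]))
      stop("interval end exceeds chromosome length")
  }
  invisible(df)
}

#' Overlap in base pairs between two intervals
#'
#' Vectorised over rows; intervals on different chromosomes overlap by 0 bp.
#' Half-open semantics: `(0,100)` and `(100,200)` are adjacent, overlap 0.
#'
#' @param a,b interval data.frames (columns chrom, start, end), recycled to
#'   a common length.
#' @return numeric vector of overlap widths in bp.
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  same <- a$chrom[ai] == b$chrom[bi]
  ov <- pmax(0, pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]))
  ov * same
}

#' Build a genome annotation object
#'
#' The annotation bundles chromosome sizes with one flattened gene model per
#' gene id: the gene interval is the union span of its exons, and exons of a
#' gene are sorted, non-overlapping, and tile the span boundaries (first exon
#' starts at the gene start, last ends at the gene end).
#'
#' @param genes data.frame with columns gene_id, chrom, start, end, strand
#'   and optionally biotype.
#' @param exons data.frame with columns gene_id, chrom, start, end, strand.
#' @param sizes named numeric vector of chromosome lengths.
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, exons, sizes) {
  genes <- as.data.frame(genes); exons <- as.data.frame(exons)
  if (!"biotype" %in% names(genes)) genes$biotype <- "gene"
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  validate_intervals(genes, sizes)
  validate_intervals(exons, sizes)
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(genes) <- genes$gene_id
  for (g in genes$gene_id) {
    ex <- exons[exons$gene_id == g, , drop = FALSE]
    if (!nrow(ex)) stop("gene ", g, " has no exons")
    if (any(ex$chrom != genes[g, "chrom"]) || any(ex$strand != genes[g, "strand"]))
      stop("exons of gene ", g, " disagree with gene chrom/strand")
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)]))
      stop("exons of gene ", g, " overlap")
    if (ex$start[1] != genes[g, "start"] || ex$end[nrow(ex)] != genes[g, "end"])
      stop("exon span of gene ", g, " does not match gene interval")
  }
  structure(list(sizes = sizes, genes = genes, exons = exons),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      length(x$sizes), "chromosome(s),",
      format(sum(x$sizes), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Genomic span length of a gene
#'
#' Gene length is the genomic span `end - start` (introns included), the
#' convention used for reporting lengths of ncRNA-coordinated loci.
#'
#' @param ann a `genome_annotation`.
#' @param gene_id one or more gene ids.
#' @return numeric vector of lengths in bp.
#' @export
gene_length <- function(ann, gene_id) {
  missing <- setdiff(gene_id, ann$genes$gene_id)
  if (length(missing)) stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  ann$genes[gene_id, "end"] - ann$genes[gene_id, "start"]
}

#' Introns of a gene
#'
#' Gaps between consecutive exons, in genomic order. A single-exon gene has
#' no introns.
#'
#' @param ann a `genome_annotation`.
#' @param gene_id a single gene id.
#' @return interval data.frame with 0 or more rows.
#' @export
introns_of <- function(ann, gene_id) {
  if (!gene_id %in% ann$genes$gene_id) stop("unknown gene id: ", gene_id)
  ex <- ann$exons[ann$exons$gene_id == gene_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  if (nrow(ex) < 2)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  data.frame(chrom = ex$chrom[1],
             start = ex$end[-nrow(ex)],
             end = ex$start[-1],
             strand = ex$strand[1],
             stringsAsFactors = FALSE)
}

#' Read a chromosome-size table
#'
#' @param path two-column TSV: chromosome name, length in bp (no header).
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  setNames(df$length, df$chrom)
}

#' Read a GTF annotation
#'
#' Parses exon features carrying `gene_id` attributes (via rtracklayer) and
#' flattens overlapping exons of each gene into an exon union; the gene
#' interval is the union span. GTF 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention.
#'
#' @param path GTF file.
#' @param sizes_path chromosome-size TSV (name, length).
#' @return a `genome_annotation`.
#' @export
read_annotation <- function(path, sizes_path) {
  sizes <- read_chrom_sizes(sizes_path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nf < 9)) {
    bad <- which(keep)[which(nf < 9)[1]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("exon features must carry gene_id attributes")
  ex <- data.frame(gene_id = as.character(gr$gene_id),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,  # 1-based -> 0-based
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  ex$strand[ex$strand == "."] <- "*"
  bt <- if (!is.null(gr$gene_biotype)) as.character(gr$gene_biotype) else "gene"
  ex$biotype <- bt
  flat <- flatten_exons(ex)
  genes <- do.call(rbind, lapply(split(flat, flat$gene_id), function(e) {
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               start = min(e$start), end = max(e$end), strand = e$strand[1],
               biotype = e$biotype[1], stringsAsFactors = FALSE)
  }))
  genome_annotation(genes, flat[, c("gene_id", "chrom", "start", "end", "strand")],
                    sizes)
}

# union of possibly overlapping exons, per gene
flatten_exons <- function(ex) {
  out <- lapply(split(ex, ex$gene_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    st <- e$start; en <- e$end
    ks <- st[1]; ke <- en[1]; us <- numeric(); ue <- numeric()
    if (nrow(e) > 1) for (i in 2:nrow(e)) {
      if (st[i] <= ke) ke <- max(ke, en[i]) else {
        us <- c(us, ks); ue <- c(ue, ke); ks <- st[i]; ke <- en[i]
      }
    }
    us <- c(us, ks); ue <- c(ue, ke)
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1], start = us, end = ue,
               strand = e$strand[1], biotype = e$biotype[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write a genome annotation as GTF (plus chromosome sizes)
#'
#' One exon feature per flattened exon, `gene_id`/`transcript_id` set to the
#' gene id. Coordinates convert back to 1-based inclusive; a round trip
#' through [read_annotation()] preserves all coordinates exactly.
#'
#' @param ann a `genome_annotation`.
#' @param path output GTF path.
#' @param sizes_path optional path for the chromosome-size TSV.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, sizes_path = NULL) {
  ex <- ann$exons
  bt <- ann$genes[ex$gene_id, "biotype"]
  lines <- sprintf(
    '%s\tncoreg\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    ex$chrom, as.integer(ex$start + 1), as.integer(ex$end),
    ifelse(ex$strand == "*", ".", ex$strand), ex$gene_id, ex$gene_id, bt)
  writeLines(lines, path)
  if (!is.null(sizes_path))
    utils::write.table(data.frame(names(ann$sizes), unname(ann$sizes)),
                       sizes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write BED6 interval files
#'
#' BED is native 0-based half-open; no coordinate shift is applied.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed6 <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end",
                                        "name", "score", "strand"),
                          colClasses = list(character = c(1, 4, 6)))
  as.data.frame(df)
}

#' @rdname read_bed6
#' @param x data.frame with at least chrom, start, end; name/score/strand
#'   filled with defaults when absent.
#' @export
write_bed6 <- function(x, path) {
  df <- data.frame(chrom = x$chrom, start = as.integer(x$start),
                   end = as.integer(x$end),
                   name = if ("name" %in% names(x)) x$name else ".",
                   score = if ("score" %in% names(x)) x$score else 0,
                   strand = if ("strand" %in% names(x)) x$strand else "*")
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
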