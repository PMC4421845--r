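# Fixed-width window counting across the genome (the 100-bp window track).

#' Build a window grid over the genome
#'
#' Windows start at every multiple of `step` below the chromosome length and
#' are truncated at the chromosome end. The default `step = width` gives a
#' non-overlapping tiling; `step < width` gives overlapping sliding windows
#' (supported, but overlapping windows are statistically dependent in
#' differential testing, so a warning is emitted).
#'
#' @param sizes named numeric vector of chromosome lengths, or a
#'   `genome_annotation` (its size table is used).
#' @param width window width w in bp (default 100).
#' @param step step s in bp, `1 <= s <= w` (default `width`).
#' @param strand_mode `"stranded_same"` (count per strand, windows duplicated
#'   per strand) or `"unstranded"`.
#' @return an object of class `window_grid`.
#' @export
make_grid <- function(sizes, width = 100, step = width,
                      strand_mode = c("stranded_same", "unstranded")) {
  strand_mode <- match.arg(strand_mode)
  if (inherits(sizes, "genome_annotation")) sizes <- sizes$sizes
  if (width < 1) stop("window width must be >= 1")
  if (step < 1 || step > width)
    stop("step must satisfy 1 <= step <= width (gaps would drop reads)")
  if (step < width)
    warning("overlapping windows (step < width): adjacent windows share reads")
  win <- data.table::rbindlist(lapply(names(sizes), function(ch) {
    L <- sizes[[ch]]
    st <- seq(0, max(L - 1, 0), by = step)
    data.table::data.table(chrom = ch, start = st, end = pmin(st + width, L))
  }))
  structure(list(windows = as.data.frame(win), width = width, step = step,
                 strand_mode = strand_mode, sizes = sizes),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat("window_grid: w =", x$width, "s =", x$step, "(", x$strand_mode, "),",
      nrow(x$windows), "windows per strand set\n")
  invisible(x)
}

#' Count reads in windows
#'
#' A read is assigned by its midpoint `floor((start+end)/2)` to every window
#' containing that midpoint, so with a tiling grid each read is counted
#' exactly once and column sums equal library sizes. In `stranded_same` mode
#' windows are duplicated per strand and a read only counts towards windows
#' on its own strand. Reads on chromosomes absent from the grid are skipped
#' with a warning and tallied.
#'
#' @param reads named list of read data.frames (BED6-style: chrom, start,
#'   end, strand), one per sample, or a single data.frame.
#' @param grid a [make_grid()] result.
#' @return object of class `count_matrix`: `features` (window intervals),
#'   `counts` (integer matrix windows x samples), `totals` (mapped reads per
#'   sample), `skipped` (skipped reads per sample).
#' @export
count_reads <- function(reads, grid) {
  if (is.data.frame(reads)) reads <- list(sample = reads)
  stranded <- grid$strand_mode == "stranded_same"
  win <- grid$windows
  feats <- if (stranded) {
    rbind(transform(win, strand = "+"), transform(win, strand = "-"))
  } else transform(win, strand = "*")
  feats$feature_id <- sprintf("%s:%d-%d:%s", feats$chrom,
                              as.integer(feats$start), as.integer(feats$end),
                              feats$strand)
  counts <- matrix(0L, nrow = nrow(feats), ncol = length(reads),
                   dimnames = list(feats$feature_id, names(reads)))
  totals <- skipped <- setNames(numeric(length(reads)), names(reads))
  # index windows by (chrom, start-offset): for step s, a midpoint m falls in
  # windows with start in (m - width, m], i.e. starts s*k for k in a range
  for (j in seq_along(reads)) {
    rd <- reads[[j]]
    known <- rd$chrom %in% names(grid$sizes)
    skipped[j] <- sum(!known)
    if (skipped[j] > 0)
      warning(sum(!known), " read(s) on unknown chromosome(s) skipped in ",
              names(reads)[j])
    rd <- rd[known, , drop = FALSE]
    totals[j] <- nrow(rd)
    if (!nrow(rd)) next
    mid <- floor((rd$start + rd$end) / 2)
    if (grid$step == grid$width) {   # tiling: direct arithmetic indexing
      chroms <- names(grid$sizes)
      nwin <- ceiling(unname(grid$sizes) / grid$step)
      off <- setNames(cumsum(c(0, head(nwin, -1))), chroms)
      nw <- setNames(nwin, chroms)
      k <- floor(mid / grid$step)
      ok <- k < nw[rd$chrom]         # midpoints beyond chrom end can't occur
      hit <- off[rd$chrom] + k + 1
      if (stranded) hit <- hit + nrow(win) * (rd$strand == "-")
      tab <- tabulate(hit[ok], nbins = nrow(feats))
    } else {                         # sliding: every window containing mid
      k_hi <- floor(mid / grid$step)
      k_lo <- pmax(0, floor((mid - grid$width) / grid$step) + 1)
      n_k <- k_hi - k_lo + 1
      ridx <- rep(seq_along(mid), n_k)
      k <- unlist(lapply(seq_along(mid),
                         function(i) k_lo[i]:k_hi[i]), use.names = FALSE)
      key <- paste0(rd$chrom[ridx], ":", k * grid$step)
      wkey <- paste0(feats$chrom, ":", feats$start)
      if (stranded) {
        key <- paste0(key, ":", rd$strand[ridx])
        wkey <- paste0(wkey, ":", feats$strand)
      }
      hit <- match(key, wkey)
      ok <- !is.na(hit)  # k beyond the truncated tail of the chromosome
      tab <- tabulate(hit[ok], nbins = nrow(feats))
    }
    counts[, j] <- counts[, j] + as.integer(tab)
  }
  structure(list(features = feats[, c("feature_id", "chrom", "start",
                                      "end", "strand")],
                 counts = counts, totals = totals, skipped = skipped),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples;", sum(x$counts), "assigned reads\n")
  invisible(x)
}

#' Gene-level counts over exon unions
#'
#' Reads are assigned by midpoint to the exon union of each gene (the mRNA
#' signal); midpoints in introns or intergenic space are not counted. In
#' stranded mode only reads on the gene's strand count.
#'
#' @param reads named list of read data.frames, one per sample.
#' @param ann a `genome_annotation`.
#' @param stranded match read strand to gene strand (default TRUE).
#' @return a `count_matrix` whose features are genes (feature_id = gene id,
#'   interval = gene span).
#' @export
count_genes <- function(reads, ann, stranded = TRUE) {
  if (is.data.frame(reads)) reads <- list(sample = reads)
  ex <- ann$exons
  g <- ann$genes
  counts <- matrix(0L, nrow = nrow(g), ncol = length(reads),
                   dimnames = list(g$gene_id, names(reads)))
  totals <- setNames(numeric(length(reads)), names(reads))
  exo <- ex[order(ex$chrom, ex$start), , drop = FALSE]
  for (j in seq_along(reads)) {
    rd <- reads[[j]]
    totals[j] <- nrow(rd)
    if (!nrow(rd)) next
    mid <- floor((rd$start + rd$end) / 2)
    for (ch in unique(exo$chrom)) {
      e <- exo[exo$chrom == ch, , drop = FALSE]
      sel <- rd$chrom == ch
      if (!any(sel)) next
      m <- mid[sel]
      # locate the exon (if any) containing each midpoint
      pos <- findInterval(m, e$start)
      inside <- pos >= 1 & m < e$end[pmax(pos, 1)]
      if (stranded)
        inside <- inside & rd$strand[sel] == e$strand[pmax(pos, 1)]
      hit <- match(e$gene_id[pos[inside]], g$gene_id)
      tab <- tabulate(hit, nbins = nrow(g))
      counts[, j] <- counts[, j] + as.integer(tab)
    }
  }
  structure(list(features = data.frame(feature_id = g$gene_id,
                                       chrom = g$chrom, start = g$start,
                                       end = g$end, strand = g$strand,
                                       stringsAsFactors = FALSE),
                 counts = counts, totals = totals,
                 skipped = setNames(rep(0, length(reads)), names(reads))),
            class = "count_matrix")
}

#' Write / read a window-count TSV
#'
#' Columns: feature_id, chrom, start, end, strand, then one count column per
#' sample; per-sample totals are stored in `# totals:` header comments so the
#' matrix round-trips.
#'
#' @param cm a `count_matrix`.
#' @param path output TSV.
#' @export
write_counts <- function(cm, path) {
  hdr <- paste0("# totals: ",
                paste(names(cm$totals), cm$totals, sep = "=", collapse = " "))
  con <- file(path, "w"); writeLines(hdr, con); close(con)
  df <- cbind(cm$features, as.data.frame(cm$counts))
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_counts
#' @param path TSV written by [write_counts()].
#' @export
read_counts <- function(path) {
  hdr <- readLines(path, n = 1)
  df <- data.table::fread(path, sep = "\t", skip = 1, header = TRUE,
                          data.table = FALSE)
  meta <- c("feature_id", "chrom", "start", "end", "strand")
  counts <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  rownames(counts) <- df$feature_id
  tot <- sub("^# totals: ", "", hdr)
  kv <- strsplit(strsplit(tot, " ", fixed = TRUE)[[1]], "=", fixed = TRUE)
  totals <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                     vapply(kv, `[`, "", 1))
  structure(list(features = df[, meta], counts = counts,
                 totals = totals[colnames(counts)],
                 skipped = setNames(rep(0, ncol(counts)), colnames(counts))),
            class = "count_matrix")
}
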