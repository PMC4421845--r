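# Synthetic genome + stranded read simulator with planted coordinated loci.
# The toy genome emulates the three-condition adaptation design: an ESR1-like
# long gene carries broad intronic + upstream ncRNA signal that rises in the
# hormone-deprived condition (B) and falls under treatment (C); ERBB2-like
# short genes regulate their mRNA only; flat "null" genes anchor
# normalization; silent SYNE1-like neighbours sit next to the long genes.

#' Simulation configuration
#'
#' Defaults are the study conditions the rest of the package is tested
#' against; see the methods vignette for the rationale behind each value.
#'
#' @param seed integer; every randomised stage derives its own stream from it.
#' @param n_coordinated,n_mrna_only,n_null gene roster: long genes with
#'   coordinated mRNA + ncRNA regulation, short genes with mRNA-only
#'   regulation, and unregulated genes.
#' @param n_null_silent how many of the null genes are transcriptionally
#'   silent neighbours (background-level counts in every condition), placed
#'   immediately downstream of coordinated genes.
#' @param long_span_mean,long_span_sd,long_span_min genomic span distribution
#'   (bp) of coordinated genes (normal, truncated below).
#' @param short_span_mean,short_span_sd,short_span_min span distribution (bp)
#'   of the short genes.
#' @param exonic_rate expected reads per 100-bp exonic tile in the baseline
#'   condition (10x this value = expected reads/kb).
#' @param ncrna_fraction intronic/upstream ncRNA tile rate as a fraction of
#'   `exonic_rate`.
#' @param background_rate expected reads per tile anywhere in the genome.
#' @param lfc_ab,lfc_bc planted log2 fold changes for the A->B and B->C
#'   contrasts (applied to mRNA and ncRNA of coordinated genes; mRNA only for
#'   mrna_only genes; never to null genes).
#' @param dispersion negative-binomial dispersion alpha (variance =
#'   mean + alpha * mean^2); 0 gives Poisson counts.
#' @param upstream_offset distance (bp) from the promoter to the planted
#'   upstream ncRNA element (u-Eleanor-like).
#' @param upstream_length length (bp) of the upstream ncRNA element.
#' @param depth per-sample depth multiplier applied to all rates.
#' @param read_length simulated read length (bp).
#' @param tile width (bp) of the generation tile; counts are drawn per tile
#'   and materialised as reads whose midpoints are uniform within the tile.
#' @param spacing minimum gap (bp) between consecutive gene spans; must be at
#'   least twice `upstream_offset` so upstream elements never collide.
#' @param n_chroms number of chromosomes; genes are placed round-robin.
#' @param chrom_len chromosome length (bp); `NULL` auto-sizes to fit the
#'   roster.
#' @param conditions condition names, in temporal order.
#' @param replicates samples per condition (1 = the canonical no-replicate
#'   design).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_coordinated = 5, n_mrna_only = 5, n_null = 20,
                       n_null_silent = 5,
                       long_span_mean = 280000, long_span_sd = 30000,
                       long_span_min = 180000,
                       short_span_mean = 17000, short_span_sd = 3000,
                       short_span_min = 6000,
                       exonic_rate = 40, ncrna_fraction = 0.25,
                       background_rate = 0.05,
                       lfc_ab = 2, lfc_bc = -2,
                       dispersion = 0.1,
                       upstream_offset = 40000, upstream_length = 2000,
                       depth = 1, read_length = 50, tile = 100,
                       spacing = 2 * upstream_offset,
                       n_chroms = 1, chrom_len = NULL,
                       conditions = c("A", "B", "C"), replicates = 1) {
  cfg <- as.list(environment())
  stopifnot(exonic_rate > 0, ncrna_fraction > 0, background_rate > 0,
            depth >= 0, dispersion >= 0, is.finite(lfc_ab), is.finite(lfc_bc),
            tile >= 1, read_length >= 1, replicates >= 1,
            n_null_silent <= n_null, spacing >= 2 * upstream_offset,
            length(conditions) >= 2)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-stage seed fan-out (31-bit string hash, exact in doubles)
stage_seed <- function(seed, stage) {
  h <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

trunc_norm <- function(n, mean, sd, min) pmax(min, round(stats::rnorm(n, mean, sd)))

# exon layout inside a span: exons of 200-400 bp, first at the span start,
# last ending at the span end, gaps split randomly. All coordinates snap to
# the generation tile so exonic signal tiles are fully exonic and the
# window stage sees exactly the planted exon/intron structure.
place_exons <- function(start, end, n_ex, tile = 100) {
  span <- end - start
  if (n_ex == 1) return(data.frame(start = start, end = end))
  len <- sample(seq(2 * tile, 4 * tile, by = tile), n_ex, replace = TRUE)
  if (sum(len) + (n_ex - 1) * tile > span)   # degenerate small span
    len <- rep(tile, n_ex)
  gaps_total <- span - sum(len)
  w <- stats::runif(n_ex - 1); w <- w / sum(w)
  gaps <- pmax(tile, floor(gaps_total * w / tile) * tile)
  gaps[1] <- gaps[1] + (gaps_total - sum(gaps))  # absorb rounding
  if (gaps[1] < tile) {  # degenerate: split evenly instead
    gaps <- rep(max(tile, floor(gaps_total / (n_ex - 1) / tile) * tile),
                n_ex - 1)
    gaps[1] <- gaps_total - sum(gaps[-1])
  }
  st <- start + cumsum(c(0, head(len, -1) + gaps))
  data.frame(start = st, end = st + len)
}

#' Simulate a toy genome annotation with planted gene roles
#'
#' Genes are placed non-overlapping with at least `spacing` bp between
#' spans; coordinated genes get 8 exons, short genes 2-5. The gene role is
#' recorded in the `biotype` column (`coordinated`, `mrna_only`, `null`,
#' `null_silent`). Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `genome_annotation`.
#' @export
simulate_annotation <- function(config) {
  set.seed(stage_seed(config$seed, "annotation"))
  n_co <- config$n_coordinated; n_mo <- config$n_mrna_only
  n_nu <- config$n_null; n_si <- config$n_null_silent
  roles <- c(rep("coordinated", n_co), rep("null_silent", n_si),
             rep("mrna_only", n_mo), rep("null", n_nu - n_si))
  # interleave silent neighbours right after coordinated genes
  ord <- c(rbind(seq_len(min(n_co, n_si)),
                 n_co + seq_len(min(n_co, n_si))))
  ord <- c(ord, setdiff(seq_along(roles), ord))
  roles <- roles[ord]
  n <- length(roles)
  if (!n) stop("empty gene roster")
  spans <- numeric(n)
  long <- roles == "coordinated"
  spans[long] <- trunc_norm(sum(long), config$long_span_mean,
                            config$long_span_sd, config$long_span_min)
  spans[!long] <- trunc_norm(sum(!long), config$short_span_mean,
                             config$short_span_sd, config$short_span_min)
  spans <- round(spans / config$tile) * config$tile  # snap to the tile grid
  strands <- sample(c("+", "-"), n, replace = TRUE)
  chrom_of <- rep(seq_len(config$n_chroms), length.out = n)
  starts <- numeric(n)
  cursor <- rep(ceiling(config$spacing / config$tile) * config$tile,
                config$n_chroms)
  for (i in seq_len(n)) {
    k <- chrom_of[i]
    starts[i] <- cursor[k]
    cursor[k] <- starts[i] + spans[i] + config$spacing
  }
  need <- max(cursor)
  if (!is.null(config$chrom_len) && config$chrom_len < need)
    stop("genome too small for the roster: need chromosomes of at least ",
         need, " bp")
  L <- if (is.null(config$chrom_len)) need else config$chrom_len
  sizes <- setNames(rep(L, config$n_chroms),
                    paste0("chrS", seq_len(config$n_chroms)))
  ids <- sprintf("G%03d_%s", seq_len(n), roles)
  exl <- vector("list", n)
  for (i in seq_len(n)) {
    n_ex <- if (long[i]) 8L else sample(2:5, 1)
    ex <- place_exons(starts[i], starts[i] + spans[i], n_ex, config$tile)
    exl[[i]] <- data.frame(gene_id = ids[i], chrom = names(sizes)[chrom_of[i]],
                           start = ex$start, end = ex$end,
                           strand = strands[i], stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, c(exl, list(make.row.names = FALSE)))
  genes <- data.frame(gene_id = ids, chrom = names(sizes)[chrom_of],
                      start = starts, end = starts + spans, strand = strands,
                      biotype = roles, stringsAsFactors = FALSE)
  genome_annotation(genes, exons, sizes)
}

#' Ground truth for a simulated annotation
#'
#' Per-gene role label, planted condition multipliers, and the planted
#' ncRNA-domain interval of each coordinated gene (upstream element through
#' the far end of the gene span).
#'
#' @param config a [sim_config()].
#' @param ann annotation from [simulate_annotation()].
#' @return list with elements `genes` (data.frame: gene_id, label,
#'   domain_start, domain_end) and `config`.
#' @export
sim_truth <- function(config, ann) {
  g <- ann$genes
  lab <- ifelse(g$biotype == "null_silent", "null", g$biotype)
  up <- upstream_element(config, g)
  dom_s <- ifelse(g$strand == "+", up$start, g$start)
  dom_e <- ifelse(g$strand == "+", g$end, up$end)
  co <- lab == "coordinated"
  list(genes = data.frame(gene_id = g$gene_id, label = lab,
                          domain_start = ifelse(co, dom_s, NA),
                          domain_end = ifelse(co, dom_e, NA),
                          stringsAsFactors = FALSE),
       config = config)
}

# upstream ncRNA element coordinates for each gene (strand-aware)
upstream_element <- function(config, g) {
  s <- ifelse(g$strand == "+",
              g$start - config$upstream_offset - config$upstream_length,
              g$end + config$upstream_offset)
  data.frame(start = pmax(0, s), end = pmax(0, s) + config$upstream_length)
}

# per-tile expected means for every signal tile (exonic, intronic of
# coordinated genes, upstream elements); background is handled separately.
# Returns data.table: chrom, start, end, strand, one mean column per condition.
expected_tile_means <- function(config, ann) {
  conds <- config$conditions
  mult <- cumprod(c(1, 2^config$lfc_ab, 2^config$lfc_bc))[seq_along(conds)]
  flat <- rep(1, length(conds))
  g <- ann$genes
  rows <- list()
  tile_range <- function(start, end, chrom, strand, rate, m) {
    t0 <- floor(start / config$tile); t1 <- ceiling(end / config$tile)
    if (t1 <= t0) return(NULL)
    ts <- (t0:(t1 - 1)) * config$tile
    te <- pmin(ts + config$tile, ann$sizes[[chrom]])
    frac <- (pmin(te, end) - pmax(ts, start)) / (te - ts)  # partial tiles
    dt <- data.table::data.table(chrom = chrom, start = ts, end = te,
                                 strand = strand)
    for (j in seq_along(conds))
      dt[[paste0("mean_", conds[j])]] <- rate * frac * m[j]
    dt
  }
  up <- upstream_element(config, g)
  for (i in seq_len(nrow(g))) {
    role <- g$biotype[i]
    if (role == "null_silent") next
    m_mrna <- if (role %in% c("coordinated", "mrna_only")) mult else flat
    ex <- ann$exons[ann$exons$gene_id == g$gene_id[i], , drop = FALSE]
    for (k in seq_len(nrow(ex)))
      rows[[length(rows) + 1]] <- tile_range(ex$start[k], ex$end[k],
                                             g$chrom[i], g$strand[i],
                                             config$exonic_rate, m_mrna)
    if (role == "coordinated") {
      nc_rate <- config$exonic_rate * config$ncrna_fraction
      intr <- introns_of(ann, g$gene_id[i])
      for (k in seq_len(nrow(intr)))
        rows[[length(rows) + 1]] <- tile_range(intr$start[k], intr$end[k],
                                               g$chrom[i], g$strand[i],
                                               nc_rate, mult)
      rows[[length(rows) + 1]] <- tile_range(up$start[i], up$end[i],
                                             g$chrom[i], g$strand[i],
                                             nc_rate, mult)
    }
  }
  dt <- data.table::rbindlist(rows)
  # a tile can host two features (e.g. exon boundary tile): sum the means
  dt[, lapply(.SD, sum), by = c("chrom", "start", "end", "strand")]
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

# materialise per-tile counts as reads; midpoints uniform in the tile so
# midpoint-based window counting recovers the drawn counts exactly
tiles_to_reads <- function(counts, tile_start, tile_end, chrom, strand,
                           chrom_len, read_length) {
  keep <- counts > 0
  if (!any(keep)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  idx <- rep(which(keep), counts[keep])
  w <- tile_end[idx] - tile_start[idx]
  mid <- tile_start[idx] + floor(stats::runif(length(idx)) * w)
  half <- floor(read_length / 2)
  st <- pmax(0, mid - half)
  en <- pmin(chrom_len[idx], st + read_length)
  st <- pmax(0, pmin(st, en - 1))
  data.frame(chrom = chrom[idx], start = st, end = en, name = ".",
             score = 0, strand = strand[idx], stringsAsFactors = FALSE)
}

#' Simulate stranded reads for every sample
#'
#' Counts per tile are drawn NB(mean = depth-scaled planted mean, dispersion
#' alpha) for signal tiles and at the background rate elsewhere, then
#' materialised as BED6-style reads. Signal reads take the gene strand;
#' background reads take a random strand. Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @param ann annotation from [simulate_annotation()].
#' @return list with `samples` (named list of read data.frames), `sample_sheet`
#'   (data.frame: sample, condition) and `totals` (reads per sample).
#' @export
simulate_reads <- function(config, ann) {
  means <- expected_tile_means(config, ann)
  sheet <- data.frame(
    sample = paste(rep(config$conditions, each = config$replicates),
                   seq_len(config$replicates), sep = "_"),
    condition = rep(config$conditions, each = config$replicates),
    stringsAsFactors = FALSE)
  # genome-wide background tiles
  bg <- data.table::rbindlist(lapply(names(ann$sizes), function(ch) {
    L <- ann$sizes[[ch]]
    ts <- seq(0, L - 1, by = config$tile)
    data.table::data.table(chrom = ch, start = ts,
                           end = pmin(ts + config$tile, L))
  }))
  samples <- list()
  for (i in seq_len(nrow(sheet))) {
    set.seed(stage_seed(config$seed, paste0("reads_", sheet$sample[i])))
    mu_sig <- means[[paste0("mean_", sheet$condition[i])]] * config$depth
    n_sig <- rnb(nrow(means), mu_sig, config$dispersion)
    sig <- tiles_to_reads(n_sig, means$start, means$end, means$chrom,
                          means$strand, ann$sizes[means$chrom],
                          config$read_length)
    n_bg <- rnb(nrow(bg), config$background_rate * config$depth,
                config$dispersion)
    bgr <- tiles_to_reads(n_bg, bg$start, bg$end, bg$chrom,
                          sample(c("+", "-"), nrow(bg), replace = TRUE),
                          ann$sizes[bg$chrom], config$read_length)
    rd <- rbind(sig, bgr)
    samples[[sheet$sample[i]]] <- rd[order(rd$chrom, rd$start), , drop = FALSE]
  }
  list(samples = samples, sample_sheet = sheet,
       totals = vapply(samples, nrow, numeric(1)))
}

#' Simulate a flat (no-effect) window-count matrix
#'
#' Every feature has the same expected mean in every sample; used for null
#' calibration of the differential test.
#'
#' @param n_features number of windows/features.
#' @param mu expected count per feature per sample.
#' @param dispersion NB dispersion alpha (0 = Poisson).
#' @param n_samples number of samples.
#' @param seed RNG seed.
#' @return integer matrix, features x samples.
#' @export
simulate_counts <- function(n_features, mu, dispersion, n_samples, seed = 1) {
  set.seed(stage_seed(seed, "flat_counts"))
  matrix(rnb(n_features * n_samples, mu, dispersion),
         nrow = n_features, ncol = n_samples,
         dimnames = list(NULL, paste0("S", seq_len(n_samples))))
}

#' Write simulation outputs to disk
#'
#' GTF + chromosome sizes, one BED6 per sample, truth table TSV, sample
#' sheet TSV, and a JSON echo of the configuration.
#'
#' @param config,ann,truth,reads outputs of the simulate functions.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(config, ann, truth, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(ann, file.path(dir, "annotation.gtf"),
                   file.path(dir, "chrom.sizes"))
  for (s in names(reads$samples))
    write_bed6(reads$samples[[s]], file.path(dir, paste0(s, ".bed")))
  utils::write.table(truth$genes, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(reads$sample_sheet, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- config; class(cfg) <- NULL
  cfg$chrom_len <- if (is.null(cfg$chrom_len)) NA else cfg$chrom_len
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}
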