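# End-to-end orchestration: simulate -> count -> test -> classify -> screen
# -> cluster, with a single global seed fanned out per stage and a run
# report that is byte-identical for identical configs.

#' Pipeline configuration
#'
#' Either `sim` (a [sim_config()]; the annotation and reads are simulated)
#' or `annotation`/`sizes`/`reads`/`sample_sheet` paths must be supplied.
#' Stage parameters default to the values documented in each stage.
#'
#' @param sim a [sim_config()] or NULL.
#' @param annotation,sizes GTF and chromosome-size paths (ignored when `sim`
#'   is given).
#' @param reads named list of BED6 paths per sample.
#' @param sample_sheet path to a sample/condition TSV.
#' @param contrasts list of length-2 condition vectors, in temporal order.
#' @param window,step window grid parameters (bp).
#' @param stranded stranded counting and classification.
#' @param lfc_thr,p_thr,pseudocount,alpha0 differential-test parameters.
#' @param max_gap window-merge gap (bp).
#' @param upstream_flank,bridge_gap screen parameters (bp).
#' @param k,iqr_min,fpkm_min,restarts clustering parameters.
#' @param seed global seed; per-stage seeds derive from it.
#' @param out_dir output directory, or NULL to skip writing.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), annotation = NULL,
                            sizes = NULL, reads = NULL, sample_sheet = NULL,
                            contrasts = list(c("A", "B"), c("B", "C")),
                            window = 100, step = window, stranded = TRUE,
                            lfc_thr = 1.0, p_thr = 0.01, pseudocount = 0.5,
                            alpha0 = 0.01, max_gap = 0,
                            upstream_flank = 50000, bridge_gap = 10000,
                            k = 14, iqr_min = 10, fpkm_min = 5,
                            restarts = 50, seed = 1, out_dir = NULL) {
  cfg <- as.list(environment())
  if (is.null(cfg$sim) &&
      (is.null(annotation) || is.null(sizes) || is.null(reads) ||
       is.null(sample_sheet)))
    stop("provide either `sim` or annotation/sizes/reads/sample_sheet paths")
  class(cfg) <- "pipeline_config"
  cfg
}

interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  uni <- pmax(e1, e2) - pmin(s1, s2)
  ifelse(uni > 0, inter / uni, NA_real_)
}

#' Run the full screen pipeline
#'
#' Executes every stage and returns (and optionally writes) a run report:
#' parameter echo, per-stage feature counts, ncRNA-candidate fractions per
#' contrast, the coordinated-locus table with called domains, gene-length
#' summaries per verdict, cluster assignments, and — when the input was
#' simulated — recovery metrics against the planted truth.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report` (invisibly when writing).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- stage_seed(config$seed, "simulate")
    ann <- simulate_annotation(sim)
    truth <- sim_truth(sim, ann)
    rd <- simulate_reads(sim, ann)
    reads <- rd$samples; sheet <- rd$sample_sheet
  } else {
    ann <- read_annotation(config$annotation, config$sizes)
    reads <- lapply(config$reads, read_bed6)
    sheet <- utils::read.table(config$sample_sheet, sep = "\t", header = TRUE,
                               colClasses = "character")
  }
  for (ct in config$contrasts) {
    bad <- setdiff(ct, sheet$condition)
    if (length(bad))
      stop("contrast condition(s) missing from sample sheet: ",
           paste(bad, collapse = ", "))
  }
  grid <- make_grid(ann, config$window, config$step,
                    if (config$stranded) "stranded_same" else "unstranded")
  wcm <- count_reads(reads, grid)
  gcm <- count_genes(reads, ann, stranded = config$stranded)
  # size factors come from the gene table: the flat majority of genes
  # anchors median-of-ratios, which window-level signal would distort
  sf <- if (sum(gcm$counts) == 0) rep(1, ncol(gcm$counts))
        else estimate_size_factors(gcm)
  names(sf) <- colnames(gcm$counts)

  per_contrast <- list()
  for (ci in seq_along(config$contrasts)) {
    ct <- config$contrasts[[ci]]
    wde <- diff_regions(wcm, sheet, ct, lfc_thr = config$lfc_thr,
                        p_thr = config$p_thr,
                        pseudocount = config$pseudocount,
                        size_factors = sf, alpha0 = config$alpha0)
    gde <- diff_regions(gcm, sheet, ct, lfc_thr = config$lfc_thr,
                        p_thr = config$p_thr,
                        pseudocount = config$pseudocount,
                        size_factors = sf, alpha0 = config$alpha0)
    reg <- merge_windows(wde, max_gap = config$max_gap)
    reg <- classify_regions(reg, ann, stranded = config$stranded)
    reg <- assign_regions(reg, ann, upstream_flank = config$upstream_flank)
    nc <- ncrna_candidates(reg)
    per_contrast[[paste(ct, collapse = "_")]] <-
      list(contrast = ct, window_de = wde, gene_de = gde, regions = reg,
           ncrna_fraction_pct = nc$fraction_pct)
  }
  pc <- per_contrast
  screen <- coregulation_screen(pc[[1]]$gene_de, pc[[2]]$gene_de,
                                pc[[1]]$regions, pc[[2]]$regions, ann,
                                bridge_gap = config$bridge_gap)
  lens <- split(screen$length_bp, screen$verdict)
  lsum <- length_summary(lens)
  venn <- four_way_venn(list(
    mrna_up_ab = pc[[1]]$gene_de$feature_id[pc[[1]]$gene_de$label == "up"],
    ncrna_up_ab = unique(stats::na.omit(
      pc[[1]]$regions$assigned_gene[pc[[1]]$regions$class != "complete_exon" &
                                    pc[[1]]$regions$direction == "up"])),
    mrna_down_bc = pc[[2]]$gene_de$feature_id[pc[[2]]$gene_de$label == "down"],
    ncrna_down_bc = unique(stats::na.omit(
      pc[[2]]$regions$assigned_gene[pc[[2]]$regions$class != "complete_exon" &
                                    pc[[2]]$regions$direction == "down"]))))

  if (all(gcm$totals > 0)) {
    profiles <- fpkm_profiles(gcm, ann, sheet,
                              conditions = unique(sheet$condition))
    pass <- filter_genes(profiles, config$iqr_min, config$fpkm_min)
    filtered <- profiles[pass, , drop = FALSE]
  } else {  # empty libraries: FPKM undefined, nothing to cluster
    filtered <- matrix(numeric(0), 0, length(unique(sheet$condition)))
  }
  clust <- NULL; pattern_genes <- character()
  if (nrow(filtered) >= 2) {
    k_use <- min(config$k, nrow(filtered))  # toy genomes have few genes
    clust <- kmeans_cluster(filtered, k = k_use,
                            seed = stage_seed(config$seed, "cluster"),
                            restarts = config$restarts)
    if (ncol(filtered) == 3) pattern_genes <- extract_pattern(clust)
  }

  recovery <- NULL
  if (!is.null(truth)) {
    tg <- truth$genes
    called_coord <- screen$gene_id[screen$verdict == "coordinated"]
    co <- tg$gene_id[tg$label == "coordinated"]
    nulls <- tg$gene_id[tg$label == "null"]
    jac <- vapply(intersect(called_coord, co), function(g) {
      i <- match(g, screen$gene_id); j <- match(g, tg$gene_id)
      interval_jaccard(screen$domain_start[i], screen$domain_end[i],
                       tg$domain_start[j], tg$domain_end[j])
    }, numeric(1))
    recovery <- list(
      sensitivity = length(intersect(called_coord, co)) / length(co),
      n_false_coordinated_null = length(intersect(called_coord, nulls)),
      domain_jaccard = jac,
      domain_jaccard_ge_0.8 = if (length(jac)) mean(jac >= 0.8) else NA_real_)
  }

  echo <- config; class(echo) <- NULL
  echo$out_dir <- NULL   # not part of the analysis; keeps reports comparable
  echo$sim <- if (!is.null(config$sim)) unclass(config$sim) else NULL
  report <- list(
    params = echo,
    n_windows = nrow(wcm$counts), n_genes = nrow(gcm$counts),
    totals = as.list(wcm$totals),
    size_factors = as.list(round(sf, 6)),
    per_contrast = lapply(pc, function(x) list(
      contrast = x$contrast,
      n_tested_windows = nrow(x$window_de),
      n_sig_windows = sum(x$window_de$label != "ns"),
      n_regions = nrow(x$regions),
      class_counts = as.list(table(x$regions$class)),
      ncrna_fraction_pct = x$ncrna_fraction_pct)),
    venn = as.list(venn),
    screen = screen,
    length_summary = lsum,
    n_filtered_profiles = nrow(filtered),
    clusters = if (!is.null(clust)) as.list(table(clust$cluster)) else NULL,
    pattern_genes = pattern_genes,
    recovery = recovery)
  class(report) <- "pipeline_report"

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(truth))
      write_simulation(sim, ann, truth,
                       list(samples = reads, sample_sheet = sheet), d)
    write_counts(wcm, file.path(d, "window_counts.tsv"))
    write_counts(gcm, file.path(d, "gene_counts.tsv"))
    for (nm in names(pc)) {
      write_diff(pc[[nm]]$window_de,
                 file.path(d, paste0("de_windows_", nm, ".tsv")))
      write_diff(pc[[nm]]$gene_de,
                 file.path(d, paste0("de_genes_", nm, ".tsv")))
      write_regions(pc[[nm]]$regions,
                    file.path(d, paste0("regions_", nm, ".bed")))
    }
    utils::write.table(screen, file.path(d, "screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dom <- screen[!is.na(screen$domain_start), , drop = FALSE]
    if (nrow(dom))
      write_bed6(data.frame(chrom = ann$genes[dom$gene_id, "chrom"],
                            start = dom$domain_start, end = dom$domain_end,
                            name = dom$gene_id, score = 0,
                            strand = ann$genes[dom$gene_id, "strand"]),
                 file.path(d, "domains.bed"))
    if (!is.null(lsum))
      utils::write.table(lsum, file.path(d, "length_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    rep_json <- report
    rep_json$screen <- NULL  # written as TSV above
    rep_json$length_summary <- NULL
    jsonlite::write_json(rep_json, file.path(d, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE, null = "null")
    return(invisible(report))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("ncoreg pipeline report\n")
  cat("  windows:", x$n_windows, " genes:", x$n_genes, "\n")
  for (nm in names(x$per_contrast)) {
    p <- x$per_contrast[[nm]]
    cat(sprintf("  %s: %d regions, ncRNA fraction %.1f%%\n",
                paste(p$contrast, collapse = "->"), p$n_regions,
                p$ncrna_fraction_pct))
  }
  cat("  coordinated loci:",
      sum(x$screen$verdict == "coordinated"), "\n")
  if (!is.null(x$recovery))
    cat(sprintf("  recovery: sensitivity %.2f, false-coordinated nulls %d\n",
                x$recovery$sensitivity,
                x$recovery$n_false_coordinated_null))
  invisible(x)
}
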