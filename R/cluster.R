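# Gene-level expression quantification (FPKM), variance/abundance
# filtering, and k-means pattern clustering of condition profiles.

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM = count / (length/1000 * mapped/1e6)`; linear in counts at fixed
#' length and depth.
#'
#' @param count read count(s) for the feature.
#' @param length_bp exonic length in bp (> 0).
#' @param mapped total mapped reads of the sample (> 0).
#' @return numeric FPKM.
#' @export
compute_fpkm <- function(count, length_bp, mapped) {
  if (any(length_bp <= 0)) stop("feature length must be positive")
  if (any(mapped <= 0)) stop("zero mapped reads: FPKM undefined")
  count / (length_bp / 1000 * mapped / 1e6)
}

#' FPKM profiles per gene and condition
#'
#' Gene counts are averaged within condition after per-sample FPKM
#' conversion (exonic length = sum of exon widths).
#'
#' @param gene_counts a `count_matrix` from [count_genes()].
#' @param ann a `genome_annotation`.
#' @param sample_sheet data.frame: sample, condition.
#' @param conditions condition order for the profile columns (default: order
#'   of first appearance in the sheet).
#' @return matrix genes x conditions of FPKM values.
#' @export
fpkm_profiles <- function(gene_counts, ann, sample_sheet,
                          conditions = unique(sample_sheet$condition)) {
  ex <- ann$exons
  exlen <- tapply(ex$end - ex$start, ex$gene_id, sum)
  ids <- rownames(gene_counts$counts)
  fp <- sweep(gene_counts$counts, 1, as.numeric(exlen[ids]) / 1000, "/")
  fp <- sweep(fp, 2, gene_counts$totals[colnames(fp)] / 1e6, "/")
  out <- vapply(conditions, function(cond) {
    s <- sample_sheet$sample[sample_sheet$condition == cond]
    rowMeans(fp[, s, drop = FALSE])
  }, numeric(nrow(fp)))
  rownames(out) <- ids
  out
}

#' Variance/abundance gene filter
#'
#' A profile passes iff its interquartile range across the condition values
#' exceeds `iqr_min` AND its maximum exceeds `fpkm_min` (strict
#' inequalities). Quartiles use linear interpolation (the common default of
#' scientific stacks, `stats::quantile` type 7).
#'
#' @param profiles matrix genes x conditions (e.g. [fpkm_profiles()]).
#' @param iqr_min IQR threshold (default 10).
#' @param fpkm_min abundance threshold on the max value (default 5).
#' @return logical vector named by gene: passes filter.
#' @export
filter_genes <- function(profiles, iqr_min = 10, fpkm_min = 5) {
  stopifnot(ncol(profiles) >= 2)
  iqr <- apply(profiles, 1, function(x)
    diff(quantile(x, c(0.25, 0.75), names = FALSE, type = 7)))
  mx <- apply(profiles, 1, max)
  setNames(iqr > iqr_min & mx > fpkm_min, rownames(profiles))
}

# k-means++ seeding: spread initial centres with probability proportional
# to squared distance from the nearest chosen centre
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1, prob = prob)
    centers[j + 1, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(x[i, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' K-means clustering of z-scored expression profiles
#'
#' Rows are z-scored (mean 0, sd 1 across conditions) so clusters capture
#' the *pattern*, not the magnitude; constant rows (sd 0) become all-zero.
#' Initialisation is k-means++; the best of `restarts` runs by total
#' within-cluster sum of squares is kept. Deterministic under `seed`.
#'
#' @param profiles matrix genes x conditions (already filtered).
#' @param k number of clusters (default 14).
#' @param seed RNG seed.
#' @param restarts independent k-means++ starts (default 50).
#' @return list of class `cluster_assignment`: `cluster` (named integer in
#'   1..k), `centroids` (k x conditions, z-scored), `withinss`, `k`, `seed`.
#' @export
kmeans_cluster <- function(profiles, k = 14, seed = 1, restarts = 50) {
  if (nrow(profiles) < k)
    stop("fewer profiles (", nrow(profiles), ") than clusters (", k,
         "); choose a smaller k")
  z <- t(apply(profiles, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  set.seed(stage_seed(seed, "kmeans"))
  best <- NULL
  for (r in seq_len(restarts)) {
    cen <- kmeanspp_centers(z, k)
    cen <- cen[!duplicated(cen), , drop = FALSE]
    fit <- suppressWarnings(
      stats::kmeans(z, centers = cen, iter.max = 100, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  structure(list(cluster = setNames(best$cluster, rownames(profiles)),
                 centroids = best$centers, withinss = best$tot.withinss,
                 k = nrow(best$centers), seed = seed),
            class = "cluster_assignment")
}

#' Extract genes in clusters matching an expression pattern
#'
#' For 3-condition profiles, `"up_then_down"` selects clusters whose
#' centroid peaks in the middle condition (`centroid[2] > centroid[1]` and
#' `centroid[2] > centroid[3]`) — induction on adaptation, repression on
#' treatment. Selection is centroid-shape based; cluster indices are
#' arbitrary.
#'
#' @param assignment a `cluster_assignment`.
#' @param pattern currently `"up_then_down"`.
#' @return character vector of gene ids (union of member genes of matching
#'   clusters).
#' @export
extract_pattern <- function(assignment, pattern = "up_then_down") {
  pattern <- match.arg(pattern)
  cen <- assignment$centroids
  stopifnot(ncol(cen) == 3)
  pick <- which(cen[, 2] > cen[, 1] & cen[, 2] > cen[, 3])
  names(assignment$cluster)[assignment$cluster %in% pick]
}
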