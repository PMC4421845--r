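# Normalization, dispersion, and negative-binomial exact testing of window
# and gene counts between two conditions, with the regulation-labelling
# thresholds |log2FC| > 1 and P < 0.01.

#' Median-of-ratios size factors
#'
#' For each sample j, `s_j = median_i(k_ij / geomean_i(k_i.))` over features
#' positive in every sample, rescaled so the geometric mean of the factors is
#' 1. When no feature is positive in all samples, library-size ratios are
#' used instead (with a warning).
#'
#' @param counts integer matrix (features x samples) or a `count_matrix`.
#' @return numeric vector of positive size factors, geometric mean 1.
#' @export
estimate_size_factors <- function(counts) {
  k <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  pos <- rowSums(k > 0) == ncol(k)
  if (!any(pos)) {
    warning("no feature positive in all samples; using library-size ratios")
    s <- colSums(k)
    if (any(s <= 0)) stop("cannot normalize: a sample has zero total counts")
  } else {
    logk <- log(k[pos, , drop = FALSE])
    loggm <- rowMeans(logk)
    s <- apply(exp(logk - loggm), 2, median)
  }
  s / exp(mean(log(s)))
}

#' Per-feature NB dispersion
#'
#' Method-of-moments on normalized counts `q_ij = k_ij / s_j`:
#' `alpha_i = max(floor, (var_i - mean_i * mbar) / mean_i^2)` with `mbar` the
#' mean of `1/s_j` over the samples used (the NB variance model is
#' `var = mean + alpha * mean^2`).
#'
#' Modes:
#' * `"pooled"` — within-condition variances pooled across conditions;
#'   requires at least 2 samples per condition.
#' * `"blind"` — all samples treated as one group; works without replicates
#'   but a genuine fold change inflates its own feature's estimate, so blind
#'   estimates are deliberately conservative for differential testing.
#' * `"fixed"` — every feature gets the supplied `alpha0`; the standard
#'   choice for no-replicate designs, where `alpha0` encodes the assumed
#'   squared biological coefficient of variation (default 0.01, i.e. BCV
#'   0.1, appropriate for libraries from the same cell line).
#'
#' @param counts matrix or `count_matrix`.
#' @param size_factors from [estimate_size_factors()].
#' @param mode `"blind"`, `"pooled"` or `"fixed"`.
#' @param conditions condition per sample (required for `"pooled"`).
#' @param alpha0 dispersion used by `"fixed"` mode.
#' @param floor lower bound on every estimate (default 1e-8).
#' @return list of class `dispersion_model`: `alpha` (per feature), `mode`,
#'   `floor`.
#' @export
estimate_dispersion <- function(counts, size_factors,
                                mode = c("blind", "pooled", "fixed"),
                                conditions = NULL, alpha0 = 0.01,
                                floor = 1e-8) {
  mode <- match.arg(mode)
  k <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  s <- size_factors
  stopifnot(length(s) == ncol(k), all(s > 0))
  q <- sweep(k, 2, s, "/")
  if (mode == "fixed") {
    alpha <- rep(max(floor, alpha0), nrow(k))
  } else if (mode == "blind") {
    mbar <- mean(1 / s)
    m <- rowMeans(q)
    v <- apply(q, 1, stats::var)
    alpha <- ifelse(m > 0, pmax(floor, (v - m * mbar) / m^2), floor)
  } else {
    if (is.null(conditions) || length(conditions) != ncol(k))
      stop("pooled mode needs a condition per sample")
    tab <- table(conditions)
    if (any(tab < 2)) stop("pooled mode requires >= 2 samples per condition")
    groups <- split(seq_len(ncol(k)), conditions)
    ss <- Reduce(`+`, lapply(groups, function(ix) {
      qc <- q[, ix, drop = FALSE]
      rowSums((qc - rowMeans(qc))^2)
    }))
    v <- ss / (ncol(k) - length(groups))   # pooled within-condition variance
    m <- rowMeans(q)
    mbar <- mean(1 / s)
    alpha <- ifelse(m > 0, pmax(floor, (v - m * mbar) / m^2), floor)
  }
  structure(list(alpha = alpha, mode = mode, floor = floor),
            class = "dispersion_model")
}

# log NB masses for counts 0..n with mean mu, dispersion alpha (size =
# 1/alpha). Built from cumulative logs of the rising factorial plus log1p,
# which stays accurate at the tiny dispersions where dnbinom's saddlepoint
# evaluation drifts (relative error ~1e-9 at size 1e8). Poisson limit below
# alpha = 1e-10.
nb_log_mass_upto <- function(n, mu, alpha) {
  a <- 0:n
  if (alpha < 1e-10) return(stats::dpois(a, mu, log = TRUE))
  r <- 1 / alpha
  lgr <- c(0, cumsum(log(r + a[-length(a)])))   # lgamma(a + r) - lgamma(r)
  lgr - lgamma(a + 1) + r * log1p(-mu / (r + mu)) + a * log(mu / (r + mu))
}

#' Conditioned NB exact test for one feature
#'
#' With `K_A = sum(kA)`, `K_B = sum(kB)`, `N = K_A + K_B`, the two-sided
#' p-value is the total conditional probability of all splits `(a, N - a)`
#' at most as likely as the observed one:
#' `p = sum_{Pr(a) <= Pr(K_A)} Pr(a) / sum_a Pr(a)`, where
#' `Pr(a) = f_A(a) * f_B(N - a)` and `f_A`, `f_B` are NB masses with means
#' proportional to the summed size factors of each condition
#' (`mu_A = N * S_A / (S_A + S_B)`) and common dispersion `alpha`. Masses
#' within a relative 1e-8 of the observed mass count as ties and are
#' included, keeping the sum reproducible across implementations.
#' `N = 0` returns p = 1 by definition.
#'
#' @param kA,kB non-negative integer counts per sample in each condition.
#' @param sA,sB size factors of the samples in each condition.
#' @param alpha NB dispersion.
#' @return p-value in (0, 1].
#' @export
nb_exact_test <- function(kA, kB, sA = rep(1, length(kA)),
                          sB = rep(1, length(kB)), alpha = 1e-8) {
  KA <- sum(kA); KB <- sum(kB); N <- KA + KB
  if (N == 0) return(1)
  SA <- sum(sA); SB <- sum(sB)
  pr <- split_masses(N, SA, SB, alpha)
  sum(pr[pr <= pr[KA + 1] * (1 + 1e-8)]) / sum(pr)
}

# probability mass of every split (a, N - a), a = 0..N
split_masses <- function(N, SA, SB, alpha) {
  muA <- N * SA / (SA + SB); muB <- N - muA
  exp(nb_log_mass_upto(N, muA, alpha) +
        rev(nb_log_mass_upto(N, muB, alpha)))
}

# p-values for every split at once (O(N^2); used on small totals)
p_of_split <- function(N, SA, SB, alpha) {
  pr <- split_masses(N, SA, SB, alpha)
  tot <- sum(pr)
  vapply(seq_along(pr), function(i) sum(pr[pr <= pr[i] * (1 + 1e-8)]) / tot,
         numeric(1))
}

#' Differential testing of a count matrix between two conditions
#'
#' Features with all-zero counts across the samples used are excluded.
#' `log2FC = log2((meanB + c) / (meanA + c))` on normalized condition means
#' with pseudocount `c` (default 0.5); the regulation label is `up` iff
#' `log2FC > lfc_thr` and `p < p_thr` (strict inequalities), `down` for the
#' mirror case, otherwise `ns`. Raw p-values gate the labels (reproducing
#' the original selection); BH-adjusted values are reported alongside.
#'
#' @param counts a `count_matrix` (windows or genes).
#' @param sample_sheet data.frame with columns sample, condition.
#' @param contrast length-2 character vector `(condA, condB)`; `up` means
#'   higher in `condB` (the later state).
#' @param lfc_thr,p_thr label thresholds (defaults 1.0 and 0.01).
#' @param pseudocount added to normalized means before the ratio.
#' @param size_factors optional precomputed size factors named by sample
#'   (e.g. estimated from a gene-level table); default: median-of-ratios on
#'   the samples used here.
#' @param dispersion optional `dispersion_model` for the used samples, or a
#'   single fixed alpha; default: `"fixed"` with `alpha0` when either
#'   condition has a single sample, else `"pooled"`.
#' @param alpha0 fixed dispersion for no-replicate contrasts.
#' @return data.frame of class `diff_result`: feature_id, interval columns,
#'   normalized condition means, log2fc, pval, padj, label.
#' @export
diff_regions <- function(counts, sample_sheet, contrast,
                         lfc_thr = 1.0, p_thr = 0.01, pseudocount = 0.5,
                         size_factors = NULL, dispersion = NULL,
                         alpha0 = 0.01) {
  stopifnot(inherits(counts, "count_matrix"), length(contrast) == 2)
  missing <- setdiff(contrast, sample_sheet$condition)
  if (length(missing))
    stop("condition(s) not in sample sheet: ", paste(missing, collapse = ", "))
  sheet <- sample_sheet[sample_sheet$condition %in% contrast, , drop = FALSE]
  k <- counts$counts[, sheet$sample, drop = FALSE]
  if (is.null(size_factors)) {
    s <- estimate_size_factors(k)
  } else {
    s <- size_factors[sheet$sample]
    if (anyNA(s)) stop("size_factors must be named by sample")
  }
  use <- rowSums(k) > 0
  k <- k[use, , drop = FALSE]
  feats <- counts$features[use, , drop = FALSE]
  inA <- sheet$condition == contrast[1]
  if (is.null(dispersion)) {
    n_per <- table(sheet$condition)
    disp <- if (any(n_per < 2))
      estimate_dispersion(k, s, mode = "fixed", alpha0 = alpha0)
    else
      estimate_dispersion(k, s, mode = "pooled", conditions = sheet$condition)
    alpha <- disp$alpha
  } else if (inherits(dispersion, "dispersion_model")) {
    alpha <- dispersion$alpha[use]
  } else {
    alpha <- rep(dispersion, nrow(k))
  }
  q <- sweep(k, 2, s, "/")
  meanA <- rowMeans(q[, inA, drop = FALSE])
  meanB <- rowMeans(q[, !inA, drop = FALSE])
  log2fc <- log2((meanB + pseudocount) / (meanA + pseudocount))
  KA <- rowSums(k[, inA, drop = FALSE]); KB <- rowSums(k[, !inA, drop = FALSE])
  SA <- sum(s[inA]); SB <- sum(s[!inA])
  N <- KA + KB
  pval <- numeric(nrow(k))
  if (nrow(k) > 0 && length(unique(alpha)) == 1) {
    # common dispersion: the split distribution depends only on N, so
    # compute it once per distinct total
    a1 <- alpha[1]
    for (n in unique(N)) {
      sel <- which(N == n)
      if (n == 0) { pval[sel] <- 1; next }
      pr <- split_masses(n, SA, SB, a1)
      tot <- sum(pr)
      pval[sel] <- vapply(KA[sel] + 1,
                          function(i) sum(pr[pr <= pr[i] * (1 + 1e-8)]) / tot,
                          numeric(1))
    }
  } else {
    for (i in seq_len(nrow(k))) {
      if (N[i] == 0) { pval[i] <- 1; next }
      pr <- split_masses(N[i], SA, SB, alpha[i])
      pval[i] <- sum(pr[pr <= pr[KA[i] + 1] * (1 + 1e-8)]) / sum(pr)
    }
  }
  padj <- stats::p.adjust(pval, method = "BH")
  label <- rep("ns", nrow(k))
  label[log2fc > lfc_thr & pval < p_thr] <- "up"
  label[log2fc < -lfc_thr & pval < p_thr] <- "down"
  out <- cbind(feats,
               data.frame(mean_a = meanA, mean_b = meanB, log2fc = log2fc,
                          pval = pval, padj = padj, label = label,
                          stringsAsFactors = FALSE))
  attr(out, "contrast") <- contrast
  attr(out, "size_factors") <- s
  class(out) <- c("diff_result", class(out))
  rownames(out) <- NULL
  out
}

#' Write a differential-test table
#'
#' @param de a `diff_result`.
#' @param path output TSV.
#' @export
write_diff <- function(de, path) {
  data.table::fwrite(as.data.frame(de), path, sep = "\t")
  invisible(path)
}
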