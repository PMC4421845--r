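# Normalization, dispersion estimation, NB exact test, region labelling.

test_that("identical samples get unit size factors", {
  k <- matrix(c(5, 9, 20, 5, 9, 20), ncol = 2)
  expect_equal(estimate_size_factors(k), c(1, 1))
})

test_that("a uniformly doubled sample splits the factor symmetrically", {
  k1 <- c(4, 10, 50, 7)
  k <- cbind(k1, 2 * k1)
  expect_equal(estimate_size_factors(k), c(1 / sqrt(2), sqrt(2)),
               ignore_attr = TRUE)
})

test_that("median-of-ratios matches a literal per-definition loop", {
  set.seed(21)
  k <- matrix(rnbinom(500 * 4, size = 5, mu = 80), ncol = 4)
  s <- estimate_size_factors(k)
  # independent re-implementation, looping feature by feature
  pos <- apply(k, 1, function(r) all(r > 0))
  gm <- apply(k[pos, ], 1, function(r) prod(r)^(1 / length(r)))
  s2 <- vapply(1:4, function(j) median(k[pos, j] / gm), numeric(1))
  s2 <- s2 / prod(s2)^(1 / 4)
  expect_equal(s, s2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(prod(s)^(1 / 4), 1, tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(4)
  k <- matrix(rnbinom(400 * 3, size = 8, mu = 60), ncol = 3)
  s <- estimate_size_factors(k)
  ref <- DESeq2::estimateSizeFactorsForMatrix(k)
  ref <- ref / exp(mean(log(ref)))   # same geometric-mean-1 scaling
  # DESeq2 takes the median on the log scale; with an even number of usable
  # rows the two medians differ in the 6th decimal, not beyond
  expect_equal(unname(s), unname(ref), tolerance = 1e-4)
})

test_that("without an all-positive feature, library sizes take over", {
  k <- matrix(c(0, 10, 5, 0), ncol = 2)   # no row positive everywhere
  expect_warning(s <- estimate_size_factors(k), "library-size")
  # totals 10 and 5, rescaled to geometric mean 1
  expect_equal(s, c(sqrt(2), 1 / sqrt(2)), ignore_attr = TRUE)
})

test_that("constant counts give floor dispersion", {
  k <- matrix(10, nrow = 3, ncol = 4)
  d <- estimate_dispersion(k, rep(1, 4), mode = "blind")
  expect_equal(d$alpha, rep(1e-8, 3))
})

test_that("Poisson data gives near-floor median dispersion", {
  set.seed(6)
  k <- matrix(rpois(1000 * 4, 50), ncol = 4)
  d <- estimate_dispersion(k, rep(1, 4), mode = "blind")
  expect_lt(median(d$alpha), 0.01)
})

test_that("pooled estimation recovers a planted dispersion", {
  set.seed(14)
  k <- matrix(rnbinom(2000 * 10, size = 1 / 0.2, mu = 100), ncol = 10)
  d <- estimate_dispersion(k, rep(1, 10), mode = "pooled",
                           conditions = rep(c("A", "B"), each = 5))
  expect_gt(median(d$alpha), 0.1)
  expect_lt(median(d$alpha), 0.3)
  expect_error(estimate_dispersion(k[, 1:2], rep(1, 2), mode = "pooled",
                                   conditions = c("A", "B")),
               ">= 2 samples")
})

test_that("balanced splits are not significant", {
  expect_gte(nb_exact_test(15, 15, alpha = 0.1), 0.99)
  expect_equal(nb_exact_test(0, 0), 1)   # N = 0 by definition
})

test_that("the exact test equals an independently coded enumeration", {
  set.seed(9)
  for (alpha in c(1e-8, 0.05, 0.4)) {
    for (rep in 1:40) {
      kA <- sample(0:80, 1); kB <- sample(0:80, 1)
      sA <- runif(1, 0.5, 2); sB <- runif(1, 0.5, 2)
      expect_equal(nb_exact_test(kA, kB, sA, sB, alpha),
                   bf_exact_p(kA, kB, sA, sB, alpha), tolerance = 1e-9)
    }
  }
})

test_that("p decreases monotonically as the split grows more extreme", {
  for (alpha in c(1e-8, 0.1)) {
    p <- vapply(0:30, function(a) nb_exact_test(a, 60 - a, alpha = alpha),
                numeric(1))
    expect_true(all(diff(p) >= -1e-12))   # towards the balanced split
  }
})

test_that("all-zero features are excluded from testing", {
  k <- rbind(c(0, 0), c(5, 9))
  cm <- as_count_matrix(k)
  sheet <- data.frame(sample = c("s1", "s2"), condition = c("A", "B"))
  colnames(cm$counts) <- c("s1", "s2")
  de <- diff_regions(cm, sheet, c("A", "B"))
  expect_equal(nrow(de), 1)
  expect_equal(de$feature_id, "f2")
})

test_that("planted four-fold windows are labelled up at high depth", {
  set.seed(101)
  mu <- 60
  kA <- rnbinom(20, size = 1 / 0.01, mu = mu)
  kB <- rnbinom(20, size = 1 / 0.01, mu = 4 * mu)
  flat <- matrix(rnbinom(200 * 2, size = 1 / 0.01, mu = mu), ncol = 2)
  k <- rbind(cbind(kA, kB), flat)
  colnames(k) <- c("s1", "s2")
  cm <- as_count_matrix(k)
  sheet <- data.frame(sample = c("s1", "s2"), condition = c("A", "B"))
  de <- diff_regions(cm, sheet, c("A", "B"),
                     size_factors = c(s1 = 1, s2 = 1), alpha0 = 0.01)
  expect_gte(sum(de$label[1:20] == "up"), 18)
  expect_equal(sum(de$label[21:220] != "ns"), 0,
               tolerance = 0)   # flat windows stay ns at these settings
})

test_that("a log2 fold change of exactly 1 is not called up", {
  # normalized means 2.5 and 5.5: (5.5 + 0.5)/(2.5 + 0.5) = 2 exactly
  k <- rbind(c(2, 3, 5, 6), c(2, 3, 40, 45))
  colnames(k) <- paste0("s", 1:4)
  cm <- as_count_matrix(k)
  sheet <- data.frame(sample = paste0("s", 1:4),
                      condition = c("A", "A", "B", "B"))
  de <- diff_regions(cm, sheet, c("A", "B"),
                     size_factors = setNames(rep(1, 4), paste0("s", 1:4)),
                     dispersion = 1e-8)
  expect_equal(de$log2fc[1], 1)
  expect_equal(de$label[1], "ns")       # strict inequality at the boundary
  expect_equal(de$label[2], "up")       # well past it
})

test_that("normalized means and fold changes ignore count rescaling", {
  set.seed(33)
  k <- matrix(rnbinom(100 * 2, size = 10, mu = 50), ncol = 2,
              dimnames = list(NULL, c("s1", "s2")))
  sheet <- data.frame(sample = c("s1", "s2"), condition = c("A", "B"))
  de1 <- diff_regions(as_count_matrix(k), sheet, c("A", "B"),
                      size_factors = c(s1 = 1, s2 = 1), dispersion = 0.05)
  k2 <- k; k2[, 2] <- k2[, 2] * 3
  de2 <- diff_regions(as_count_matrix(k2), sheet, c("A", "B"),
                      size_factors = c(s1 = 1, s2 = 3), dispersion = 0.05)
  expect_equal(de1$mean_a, de2$mean_a)
  expect_equal(de1$mean_b, de2$mean_b)
  expect_equal(de1$log2fc, de2$log2fc)
})

test_that("null windows with known dispersion keep valid p-values", {
  k <- simulate_counts(2000, mu = 50, dispersion = 0.1, n_samples = 2,
                       seed = 55)
  colnames(k) <- c("s1", "s2")
  cm <- as_count_matrix(k)
  sheet <- data.frame(sample = c("s1", "s2"), condition = c("A", "B"))
  de <- diff_regions(cm, sheet, c("A", "B"),
                     size_factors = c(s1 = 1, s2 = 1), dispersion = 0.1)
  expect_lte(mean(de$pval < 0.05), 0.08)
})

test_that("an unknown contrast condition is a configuration error", {
  k <- matrix(1:4, ncol = 2, dimnames = list(NULL, c("s1", "s2")))
  sheet <- data.frame(sample = c("s1", "s2"), condition = c("A", "B"))
  expect_error(diff_regions(as_count_matrix(k), sheet, c("A", "Z")),
               "not in sample sheet")
})
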