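# Merging significant windows and classifying regions against genes.

fake_diff <- function(chrom, start, end, label, strand = "+",
                      log2fc = 2, pval = 1e-4) {
  data.frame(feature_id = paste0("w", seq_along(start)), chrom = chrom,
             start = start, end = end, strand = strand,
             mean_a = 10, mean_b = 40, log2fc = log2fc, pval = pval,
             padj = pval, label = label, stringsAsFactors = FALSE)
}

test_that("no significant windows merge to an empty region list", {
  d <- fake_diff("c", c(0, 100), c(100, 200), c("ns", "ns"))
  expect_equal(nrow(merge_windows(d)), 0)
})

test_that("adjacent same-direction windows merge into one region", {
  d <- fake_diff("c", c(0, 100), c(100, 200), c("up", "up"))
  m <- merge_windows(d)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 200))
  expect_equal(m$n_windows, 2)
})

test_that("direction, strand, chromosome and gaps all break merges", {
  d <- rbind(fake_diff("c", c(0, 100), c(100, 200), c("up", "down")),
             fake_diff("c", 300, 400, "up"),
             fake_diff("c", 400, 500, "up", strand = "-"),
             fake_diff("d", 500, 600, "up"))
  m <- merge_windows(d)
  expect_equal(nrow(m), 5)
  m2 <- merge_windows(rbind(fake_diff("c", 0, 100, "up"),
                            fake_diff("c", 150, 250, "up")), max_gap = 50)
  expect_equal(nrow(m2), 1)   # gap of 50 bridged when allowed
})

test_that("merging matches a union-find oracle on random inputs", {
  set.seed(12)
  for (rep in 1:30) {
    n <- sample(5:25, 1)
    starts <- sort(sample(seq(0, 3000, by = 100), n))
    d <- fake_diff(sample(c("c", "d"), n, replace = TRUE),
                   starts, starts + 100,
                   sample(c("up", "down"), n, replace = TRUE),
                   strand = sample(c("+", "-"), n, replace = TRUE))
    gap <- sample(c(0, 100, 300), 1)
    m <- merge_windows(d, max_gap = gap)
    oracle <- bf_merge(d, gap)
    expect_equal(nrow(m), length(oracle))
    got <- sort(paste(m$start, m$end))
    want <- sort(unname(vapply(oracle, function(r)
      paste(r["start"], r["end"]), "")))
    expect_equal(got, want)
  }
})

test_that("merging is idempotent", {
  d <- fake_diff("c", c(0, 100, 300), c(100, 200, 400),
                 c("up", "up", "up"))
  m1 <- merge_windows(d)
  # re-feed the merged regions as pseudo-windows
  d2 <- fake_diff("c", m1$start, m1$end, m1$direction)
  m2 <- merge_windows(d2)
  expect_equal(m2[, c("start", "end")], m1[, c("start", "end")],
               ignore_attr = TRUE)
})

test_that("regions are classified by the positional rules", {
  ann <- toy_annotation()   # gA: exons (1000,1200),(1500,1800),(2700,3000)
  reg <- data.frame(chrom = "chrT",
                    start = c(1250, 1050, 1100, 4000, 900),
                    end = c(1450, 1150, 1600, 4100, 1100),
                    strand = "+",
                    direction = "up", stringsAsFactors = FALSE)
  cls <- classify_regions(reg, ann)
  expect_equal(cls$class,
               c("intron", "complete_exon", "exon_intron", "intergene",
                 "exon_intron"))   # last: extends past the gene span
  expect_equal(cls$host_gene, c("gA", "gA", "gA", NA, "gA"))
})

test_that("strand matching is enforced only in stranded mode", {
  ann <- toy_annotation()
  reg <- data.frame(chrom = "chrT", start = 1250, end = 1450, strand = "-",
                    direction = "up")
  expect_equal(classify_regions(reg, ann, stranded = TRUE)$class, "intergene")
  expect_equal(classify_regions(reg, ann, stranded = FALSE)$class, "intron")
})

test_that("classification matches the per-base oracle on random regions", {
  ann <- simulate_annotation(sim_config(
    seed = 42, n_coordinated = 2, n_mrna_only = 3, n_null = 3,
    n_null_silent = 0))
  set.seed(88)
  L <- unname(ann$sizes[1])
  n <- 250
  starts <- sample(seq(0, L - 600, by = 50), n, replace = TRUE)
  reg <- data.frame(chrom = names(ann$sizes)[1], start = starts,
                    end = starts + sample(c(100, 300, 500), n, replace = TRUE),
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    direction = "up", stringsAsFactors = FALSE)
  cls <- classify_regions(reg, ann)
  for (i in seq_len(n)) {
    o <- bf_classify(reg[i, ], ann)
    expect_equal(cls$class[i], o$class)
    expect_equal(cls$host_gene[i], o$host)
  }
  # classification is invariant to gene order in the annotation
  ann2 <- ann
  ord <- rev(seq_len(nrow(ann2$genes)))
  ann2$genes <- ann2$genes[ord, ]
  expect_equal(classify_regions(reg, ann2)$class, cls$class)
})

test_that("every region gets exactly one of the four classes", {
  ann <- simulate_annotation(sim_config(seed = 4, n_coordinated = 1,
                                        n_mrna_only = 1, n_null = 1,
                                        n_null_silent = 0))
  set.seed(5)
  starts <- sample(seq(0, unname(ann$sizes[1]) - 300, by = 100), 100)
  reg <- data.frame(chrom = names(ann$sizes)[1], start = starts,
                    end = starts + 200, strand = "*", direction = "up")
  cls <- classify_regions(reg, ann, stranded = FALSE)
  expect_true(all(cls$class %in% c("complete_exon", "exon_intron",
                                   "intron", "intergene")))
})

test_that("ncRNA candidates are the non-exonic classes", {
  reg <- data.frame(class = c(rep("complete_exon", 3), rep("intron", 2),
                              "intergene", rep("exon_intron", 2)))
  nc <- ncrna_candidates(reg)
  expect_equal(nrow(nc$candidates), 5)
  expect_equal(nc$fraction_pct, 62.5)
  all_ex <- data.frame(class = rep("complete_exon", 4))
  expect_equal(ncrna_candidates(all_ex)$fraction_pct, 0)
  expect_true(is.nan(ncrna_candidates(reg[0, , drop = FALSE])$fraction_pct))
})
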