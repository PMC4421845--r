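# Region-to-locus assignment, the four-way screen, domains, length means.

classified <- function(chrom, start, end, strand, class, host = NA,
                       direction = "up") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             direction = direction, n_windows = 1, log2fc = 2, min_p = 1e-4,
             class = class, host_gene = host, stringsAsFactors = FALSE)
}

gene_de <- function(ids, labels) {
  n <- length(ids)
  data.frame(feature_id = ids, chrom = rep("chrT", n), start = rep(0, n),
             end = rep(1, n), strand = rep("+", n), mean_a = rep(1, n),
             mean_b = rep(1, n), log2fc = rep(0, n), pval = rep(1, n),
             padj = rep(1, n), label = labels, stringsAsFactors = FALSE)
}

test_that("genic regions go to their host, upstream intergenics to the promoter", {
  ann <- toy_annotation()   # gA: (1000,3000) +, gB: (6000,6500) -
  reg <- rbind(
    classified("chrT", 1250, 1450, "+", "intron", "gA"),
    classified("chrT", 400, 600, "+", "intergene"),      # 400 bp upstream gA
    classified("chrT", 6800, 6900, "-", "intergene"),    # 300 bp upstream gB
    classified("chrT", 6800, 6900, "+", "intergene"),    # wrong strand
    classified("chrT", 3500, 3600, "+", "intergene"))    # downstream of gA
  a <- assign_regions(reg, ann, upstream_flank = 50000)
  expect_equal(a$assigned_gene, c("gA", "gA", "gB", NA, NA))
})

test_that("the upstream flank bounds promoter assignment", {
  ann <- toy_annotation()
  sizes <- c(chrU = 300000)
  genes <- data.frame(gene_id = "g", chrom = "chrU", start = 100000,
                      end = 120000, strand = "+", biotype = "gene")
  exons <- data.frame(gene_id = "g", chrom = "chrU",
                      start = c(100000, 119000), end = c(100500, 120000),
                      strand = "+")
  ann <- genome_annotation(genes, exons, sizes)
  near <- classified("chrU", 59000, 60000, "+", "intergene")  # 40 kb upstream
  far <- classified("chrU", 30000, 40000, "+", "intergene")   # 60 kb upstream
  expect_equal(assign_regions(near, ann, 50000)$assigned_gene, "g")
  expect_true(is.na(assign_regions(far, ann, 50000)$assigned_gene))
})

test_that("four-way venn covers every element exactly once", {
  same <- list(a = letters[1:5], b = letters[1:5], c = letters[1:5],
               d = letters[1:5])
  v <- four_way_venn(same)
  expect_equal(unname(v["a+b+c+d"]), 5)
  expect_equal(sum(v), 5)
  disj <- list(a = "w", b = "x", c = "y", d = "z")
  v2 <- four_way_venn(disj)
  expect_equal(unname(v2[c("a", "b", "c", "d")]), rep(1L, 4))
  expect_equal(sum(v2), 4)
  set.seed(19)
  for (rep in 1:20) {
    sets <- lapply(1:4, function(i) sample(letters, sample(0:15, 1)))
    names(sets) <- c("A", "B", "C", "D")
    v3 <- four_way_venn(sets)
    u <- unique(unlist(sets))
    expect_equal(sum(v3), length(u))
    # exhaustive per-element membership tabulation
    pats <- vapply(u, function(el)
      paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
            collapse = "+"), "")
    want <- table(pats)
    expect_equal(unname(v3[names(want)]), unname(as.integer(want)))
    expect_equal(sum(v3[setdiff(names(v3), names(want))]), 0)
  }
})

test_that("domains cover the gene plus chainable ncRNA regions", {
  gene <- data.frame(chrom = "c", start = 100000, end = 300000)
  intronic <- data.frame(chrom = "c", start = 150000, end = 160000)
  expect_equal(call_domain(gene, intronic),
               list(start = 100000, end = 300000))
  upstream <- data.frame(chrom = "c", start = 58000, end = 60000)  # 40 kb gap
  expect_equal(call_domain(gene, upstream, bridge_gap = 50000),
               list(start = 58000, end = 300000))
  expect_equal(call_domain(gene, upstream, bridge_gap = 10000),
               list(start = 100000, end = 300000))   # unbridged: excluded
  # stepwise chaining: the middle region brings the far one in reach
  chain <- data.frame(chrom = "c", start = c(85000, 60000),
                      end = c(92000, 70000))
  expect_equal(call_domain(gene, chain, bridge_gap = 16000),
               list(start = 60000, end = 300000))
})

test_that("screen verdicts follow the four-way intersection logic", {
  ann <- toy_annotation()
  m_ab <- gene_de(c("gA", "gB"), c("up", "up"))
  m_bc <- gene_de(c("gA", "gB"), c("down", "down"))
  nc_ab <- classified("chrT", 1250, 1450, "+", "intron", "gA")
  nc_ab$assigned_gene <- "gA"
  nc_bc <- classified("chrT", 1250, 1450, "+", "intron", "gA",
                      direction = "down")
  nc_bc$assigned_gene <- "gA"
  sc <- coregulation_screen(m_ab, m_bc, nc_ab, nc_bc, ann)
  expect_equal(sc$verdict[sc$gene_id == "gA"], "coordinated")
  expect_equal(sc$verdict[sc$gene_id == "gB"], "mrna_only")
  # brute-force set logic gives the same verdicts
  up_ab <- m_ab$feature_id[m_ab$label == "up"]
  dn_bc <- m_bc$feature_id[m_bc$label == "down"]
  co <- intersect(intersect(up_ab, dn_bc),
                  intersect(nc_ab$assigned_gene, nc_bc$assigned_gene))
  expect_setequal(sc$gene_id[sc$verdict == "coordinated"], co)
  # coordinated loci get a called domain covering the gene span
  expect_equal(sc$domain_start[sc$gene_id == "gA"], 1000)
  expect_equal(sc$domain_end[sc$gene_id == "gA"], 3000)
  expect_true(is.na(sc$domain_start[sc$gene_id == "gB"]))
})

test_that("empty inputs give an empty screen", {
  ann <- toy_annotation()
  empty_de <- gene_de(character(), character())
  empty_nc <- classified("c", 1, 2, "+", "intron")[0, ]
  empty_nc$assigned_gene <- character()
  sc <- coregulation_screen(empty_de, empty_de, empty_nc, empty_nc, ann)
  expect_equal(nrow(sc), 0)
})

test_that("screen output is ordered by length and invariant to input order", {
  ann <- toy_annotation()
  m_ab <- gene_de(c("gB", "gA"), c("up", "up"))
  m_bc <- gene_de(c("gA", "gB"), c("down", "down"))
  sc1 <- coregulation_screen(m_ab, m_bc,
                             {x <- classified("c", 1, 2, "+", "intron")[0, ]
                              x$assigned_gene <- character(); x},
                             {x <- classified("c", 1, 2, "+", "intron")[0, ]
                              x$assigned_gene <- character(); x}, ann)
  sc2 <- coregulation_screen(m_ab[2:1, ], m_bc[2:1, ],
                             {x <- classified("c", 1, 2, "+", "intron")[0, ]
                              x$assigned_gene <- character(); x},
                             {x <- classified("c", 1, 2, "+", "intron")[0, ]
                              x$assigned_gene <- character(); x}, ann)
  expect_equal(sc1, sc2)
  expect_equal(sc1$gene_id, c("gA", "gB"))   # gA is longer
  # mRNA labels never contradict the verdict
  expect_true(all(sc1$verdict[sc1$mrna_ab == "up" &
                                sc1$mrna_bc == "down"] != "other"))
})

test_that("unknown DE gene ids are an error", {
  ann <- toy_annotation()
  expect_error(
    coregulation_screen(gene_de("nope", "up"), gene_de("gA", "down"),
                        {x <- classified("c", 1, 2, "+", "intron")[0, ]
                         x$assigned_gene <- character(); x},
                        {x <- classified("c", 1, 2, "+", "intron")[0, ]
                         x$assigned_gene <- character(); x}, ann),
    "nope")
})

test_that("group length means reproduce the published table", {
  tbl <- reference_gene_lengths()
  ls <- length_summary(split(tbl$length_bp, tbl$group))
  expect_equal(ls$mean_length_bp[ls$group == "non_coordinated"], 16839)
  expect_equal(ls$n, c(13, 13))
  expect_equal(length_summary(list(one = 412778))$mean_length_bp, 412778)
  empty <- length_summary(list(none = numeric()))
  expect_equal(empty$n, 0)
  expect_true(is.na(empty$mean_length_bp))
})
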