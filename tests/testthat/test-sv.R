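sv_row <- function(spanning, split, ca = 30, cb = 30, id = "x") {
  data.frame(id = id, sample = "S", sv_type = "TRA",
             chrom_a = "chr1", pos_a = 100L, orient_a = "tail",
             chrom_b = "chr2", pos_b = 200L, orient_b = "head",
             spanning = spanning, split = split,
             concordant_a = ca, concordant_b = cb, mh_len = NA_integer_)
}

test_that("read-support filter enforces 8 spanning AND 3 split, inclusively", {
  calls <- rbind(sv_row(8, 3, id = "keep"), sv_row(7, 10, id = "drop1"),
                 sv_row(20, 2, id = "drop2"), sv_row(9, 5, id = "keep2"))
  kept <- filter_sv_calls(calls)
  expect_identical(kept$id, c("keep", "keep2"))
  expect_identical(filter_sv_calls(kept), kept)   # idempotent
  empty <- calls[0, ]
  expect_equal(nrow(filter_sv_calls(empty)), 0L)
})

test_that("allele frequency follows S/(S + mean concordant) and is scale-invariant", {
  expect_equal(allele_frequency(sv_row(7, 3, 30, 30)), 0.25)
  expect_equal(allele_frequency(sv_row(5, 5, 0, 0)), 1)
  expect_true(is.na(allele_frequency(sv_row(0, 0, 0, 0))))
  r <- sv_row(6, 4, 12, 20)
  r10 <- sv_row(60, 40, 120, 200)
  expect_equal(allele_frequency(r), allele_frequency(r10))
  # sum-mode option halves the AF relative to mean when counts are equal
  expect_equal(allele_frequency(sv_row(10, 0, 30, 30), "sum"), 10 / 70)
})

test_that("AF filter boundary is inclusive at 10%", {
  at <- sv_row(10, 0, 90, 90)       # AF = 10/100 = 0.10
  below <- sv_row(999, 0, 9000.09, 9000.09)
  below$spanning <- 999L
  calls <- rbind(at, sv_row(1, 0, 200, 200))   # second AF ~ 0.005
  expect_equal(nrow(af_filter(calls, 0.10)), 1L)
  expect_equal(af_filter(calls, 0.10)$id[1], "x")
  expect_equal(nrow(af_filter(calls, 0)), 2L)   # min_af = 0 is identity
  just_below <- sv_row(999, 0, 9004, 9004)     # AF = 999/10003 < 0.0999
  expect_equal(nrow(af_filter(just_below, 0.10)), 0L)
})

test_that("simulated allele fractions are recovered near-unbiasedly", {
  set.seed(91)
  ev <- simulate_read_evidence(300, rep(0.3, 500))
  est <- allele_frequency(ev)
  expect_gt(mean(est), 0.28)
  expect_lt(mean(est), 0.32)
})

test_that("breakpoint-vs-gene classification matches the all-pairs oracle", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chrom = c("c1", "c1", "c2"),
                      strand = c("+", "-", "+"),
                      start = c(100L, 500L, 0L), end = c(200L, 800L, 300L))
  exons <- data.frame(gene_id = genes$gene_id, exon_number = 1L,
                      start = genes$start, end = genes$end)
  gm <- gene_models(genes, exons)
  set.seed(8)
  calls <- data.frame(id = sprintf("s%d", 1:20), sample = "S",
                      sv_type = "TRA",
                      chrom_a = sample(c("c1", "c2"), 20, replace = TRUE),
                      pos_a = sample(0:1000, 20), orient_a = "tail",
                      chrom_b = sample(c("c1", "c2"), 20, replace = TRUE),
                      pos_b = sample(0:1000, 20), orient_b = "head",
                      spanning = 10L, split = 5L, concordant_a = 10L,
                      concordant_b = 10L, mh_len = NA_integer_)
  got <- classify_breakpoints(calls, gm)
  expect_identical(got$classes$category,
                   oracle_breakpoint_classes(calls, gm))
  expect_equal(sum(got$fractions$gene), 1)
})

test_that("gene-body containment is half-open at both boundaries", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", strand = "+",
                      start = 100L, end = 200L)
  gm <- gene_models(genes, data.frame(gene_id = "g1", exon_number = 1L,
                                      start = 100L, end = 200L))
  mk <- function(p) data.frame(id = "x", sample = "S", sv_type = "TRA",
                               chrom_a = "c1", pos_a = p, orient_a = "tail",
                               chrom_b = "c9", pos_b = 5L, orient_b = "head",
                               spanning = 1L, split = 1L,
                               concordant_a = 1L, concordant_b = 1L,
                               mh_len = NA_integer_)
  expect_equal(classify_breakpoints(mk(100L), gm)$classes$category,
               "intragenic-one")   # start coordinate is inside
  expect_equal(classify_breakpoints(mk(200L), gm)$classes$category,
               "intergenic-both")  # end coordinate is outside
})

test_that("expression categories and fusion flag are assigned", {
  genes <- data.frame(gene_id = c("gE", "gF"), chrom = c("c1", "c2"),
                      strand = c("+", "+"), start = c(0L, 0L),
                      end = c(1000L, 1000L))
  gm <- gene_models(genes, data.frame(gene_id = c("gE", "gF"),
                                      exon_number = 1L, start = c(0L, 0L),
                                      end = c(1000L, 1000L)))
  expr <- data.frame(gene_id = c("gE", "gF"), S = c(50, 30))
  call <- data.frame(id = "x", sample = "S", sv_type = "TRA",
                     chrom_a = "c1", pos_a = 500L, orient_a = "tail",
                     chrom_b = "c2", pos_b = 500L, orient_b = "head",
                     spanning = 9L, split = 9L, concordant_a = 1L,
                     concordant_b = 1L, mh_len = NA_integer_)
  fus <- data.frame(gene5 = "gE", gene3 = "gF")
  got <- classify_breakpoints(call, gm, expression = expr, fusions = fus)
  expect_equal(got$classes$expression_category, "both-expressed")
  expect_true(got$classes$yields_fusion)
})

test_that("intragenic fraction counts overlapping genes once (bitmap oracle)", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chrom = "c1", strand = "+",
                      start = c(0L, 30000L, 40000L),
                      end = c(50000L, 60000L, 45000L))
  exons <- data.frame(gene_id = genes$gene_id, exon_number = 1L,
                      start = genes$start, end = genes$end)
  gm <- gene_models(genes, exons)
  lens <- c(c1 = 100000L)
  expect_equal(intragenic_genome_fraction(gm, lens),
               oracle_intragenic_fraction(gm, lens))
  expect_equal(intragenic_genome_fraction(gm, lens), 0.6)
  one <- gene_models(genes[1, ], exons[1, ])
  expect_equal(intragenic_genome_fraction(one, lens), 0.5)
  none <- gene_models(genes[0, ], exons[0, ])
  expect_equal(intragenic_genome_fraction(none, lens), 0)
})
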