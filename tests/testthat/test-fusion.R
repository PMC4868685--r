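rand_ctx <- function(n = 200, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mk_fusion <- function(id = "f1", gene5 = "gA", gene3 = "gB", pos5 = 100L,
                      pos3 = 500L, spanning = 10L, split = 5L,
                      context = rand_ctx(), sample = "S1") {
  data.frame(id = id, sample = sample, gene5 = gene5, gene3 = gene3,
             exon5 = NA_integer_, exon3 = NA_integer_,
             chrom5 = "c1", pos5 = pos5, chrom3 = "c2", pos3 = pos3,
             spanning = spanning, split = split, context = context)
}

test_that("caller merge applies the coordinate tolerance rule", {
  a <- mk_fusion("a1")
  cases <- list(c(0L, 0L, TRUE), c(5L, 0L, TRUE), c(10L, 10L, TRUE),
                c(11L, 0L, FALSE), c(0L, 25L, FALSE))
  for (cs in cases) {
    b <- mk_fusion("b1", pos5 = 100L + cs[[1]], pos3 = 500L + cs[[2]])
    m <- merge_caller_outputs(a, b)
    if (cs[[3]]) {
      expect_equal(nrow(m), 1L)
      expect_equal(m$provenance, "both")
    } else {
      expect_equal(nrow(m), 2L)
      expect_setequal(m$provenance, c("A", "B"))
    }
  }
  disjoint <- merge_caller_outputs(mk_fusion("a1"),
                                   mk_fusion("b2", gene5 = "gX"))
  expect_equal(nrow(disjoint), 2L)
})

test_that("normal-panel filtering is order-sensitive on the gene pair", {
  fus <- rbind(mk_fusion("f1", "gA", "gB"), mk_fusion("f2", "gB", "gA"),
               mk_fusion("f3", "gC", "gD"))
  out <- normal_panel_filter(fus, "gA>gB")
  expect_setequal(out$id, c("f2", "f3"))   # reciprocal pair survives
  expect_equal(nrow(normal_panel_filter(fus, character(0))), 3L)
})

test_that("junction complexity filter removes low-entropy and repeat contexts", {
  polyA <- mk_fusion("pa", context = strrep("A", 200))
  expect_equal(junction_entropy(polyA$context), 0)
  ac <- mk_fusion("ac", context = strrep("AC", 100))
  expect_gt(tandem_repeat_coverage(ac$context), 0.5)
  rnd <- mk_fusion("ok", context = rand_ctx(200, 7))
  expect_gt(junction_entropy(rnd$context), 3.5)
  kept <- junction_complexity_filter(rbind(polyA, ac, rnd))
  expect_equal(kept$id, "ok")
  shorty <- mk_fusion("sh", context = rand_ctx(80, 3))
  out <- junction_complexity_filter(shorty)
  expect_true(out$context_truncated)
})

test_that("uniform random 200-mers pass the complexity filter at > 99.9%", {
  # expected dinucleotide entropy of an i.i.d. 200-mer is ~ 3.94 bits,
  # far above the 1.5-bit threshold
  set.seed(12)
  ctx <- vapply(1:500, function(i) rand_ctx(200, i), character(1))
  ent <- vapply(ctx, junction_entropy, numeric(1))
  rep_cov <- vapply(ctx, tandem_repeat_coverage, numeric(1))
  expect_true(all(ent > 1.5))
  expect_true(all(rep_cov <= 0.5))
})

test_that("read-support filter boundaries match the 8/3 rule", {
  fus <- rbind(mk_fusion("k", spanning = 8L, split = 3L),
               mk_fusion("d1", spanning = 8L, split = 2L),
               mk_fusion("d2", spanning = 7L, split = 9L))
  expect_equal(read_support_filter(fus)$id, "k")
  expect_equal(nrow(read_support_filter(fus[0, ])), 0L)
})

test_that("the filter cascade is order-independent", {
  set.seed(5)
  fus <- do.call(rbind, lapply(1:30, function(i)
    mk_fusion(paste0("f", i),
              gene5 = sample(c("gA", "gB", "gC"), 1),
              gene3 = sample(c("gD", "gE"), 1),
              spanning = sample(0:20, 1), split = sample(0:6, 1),
              context = if (i %% 7 == 0) strrep("AT", 100)
                        else rand_ctx(200, i))))
  cfg <- fusion_filter_config(normal_panel = c("gA>gD", "gC>gE"))
  o1 <- filter_fusions(fus, cfg)
  o2 <- junction_complexity_filter(
          read_support_filter(normal_panel_filter(fus, cfg$normal_panel),
                              cfg), cfg)
  o2 <- o2[, names(o1)]
  expect_equal(o1$id, o2$id)
})

test_that("matcher labels planted provenance classes correctly", {
  cfg <- sim_config(seed = 31, trans_splice_fraction = 0.4,
                    normal_panel_fraction = 0.1,
                    read_through_fraction = 0.1)
  g <- simulate_genome(cfg)
  fus <- simulate_fusion_calls(g, cfg, n_fusions = 40)
  conc <- concordance_summary(fus$fusions, fus$rearrangements, g$models)
  truth <- fus$truth[match(conc$results$id, fus$truth$id), ]
  # genomic fusions: found, with the right rearrangement id
  gsel <- truth$class == "genomic"
  expect_true(all(conc$results$status[gsel] == "genomic-direct"))
  expect_identical(conc$results$matched[gsel], truth$rearrangement[gsel])
  # read-through: matched via the neighbor gene
  rsel <- truth$class == "read-through"
  expect_true(all(conc$results$status[rsel] == "genomic-read-through"))
  # trans-splice-only and panel artifacts: never genomic-direct
  usel <- truth$class %in% c("trans-splice", "normal-panel")
  expect_true(all(conc$results$status[usel] == "unsupported"))
  # summary counts agree with the truth table
  expect_equal(conc$summary$supported,
               sum(truth$genomically_supported))
})

test_that("a missing partner gene yields unsupported with a warning", {
  g <- shared_genome()
  fus <- mk_fusion("f1", gene5 = "NOT_A_GENE",
                   gene3 = g$models$genes$gene_id[1])
  expect_warning(res <- match_fusion_to_genome(fus, data.frame(), g$models),
                 "absent")
  expect_equal(res$status, "unsupported")
})

test_that("partner genes drawn from the top expression decile are enriched", {
  set.seed(44)
  expr <- data.frame(gene_id = sprintf("g%04d", 1:1000),
                     S1 = rlnorm(1000, 2, 1))
  top <- expr$gene_id[order(-expr$S1)][1:100]
  partners <- sample(top, 40)
  fus <- do.call(rbind, lapply(seq(1, 40, 2), function(i)
    mk_fusion(paste0("f", i), gene5 = partners[i],
              gene3 = partners[i + 1])))
  got <- partner_expression_enrichment(fus, expr)
  expect_lt(got$p_value, 1e-4)
  expect_gt(got$median_partner, got$median_other)
  few <- partner_expression_enrichment(fus[1, ], expr)
  expect_true(few$degenerate)
})
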