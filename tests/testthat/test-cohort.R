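test_that("aberration descriptors classify by size and kind", {
  recs <- data.frame(type = c("Small del (10 bp)", "Del (7.5 Mb)", "Trans",
                              "High level Ampl", "SNV", "Inv (50.3 Mb)",
                              "Del (9 kb)"))
  got <- classify_aberration(recs)
  expect_equal(got$class, c("indel", "rearrangement", "rearrangement",
                            "amplification", "snv", "rearrangement",
                            "rearrangement"))
  expect_equal(got$size_bp[2], 7.5e6)
  expect_equal(got$size_bp[7], 9000)
  expect_error(classify_aberration(data.frame(type = "mystery event")),
               "unparseable")
})

test_that("the tumor cohort fixture parses completely and reproduces the counts", {
  tum <- classify_aberration(load_tumor_tp53())
  expect_equal(nrow(tum), 24L)    # 22 TP53 events + 2 MDM2 amplifications
  expect_equal(length(unique(tum$sample)), 18L)
  ps <- pathway_status(tum, samples = c(unique(tum$sample),
                                        sprintf("unaffected%02d", 1:7)))
  expect_equal(sum(ps$status == "TP53-rearranged"), 10L)
  expect_equal(sum(ps$status == "TP53-mutated"), 6L)
  expect_equal(sum(ps$status == "MDM2-amplified"), 2L)
  expect_equal(sum(ps$status != "none"), 18L)
  freqs <- cohort_frequencies(ps$status, n_samples = 25)
  expect_equal(unname(freqs[c("rearrangement", "mutation_indel",
                              "mdm2_amplification")]), c(40, 24, 8))
  expect_lte(abs(sum(freqs) - 100), 1)
})

test_that("pathway precedence puts rearrangement above mutation above MDM2", {
  recs <- data.frame(sample = c("s1", "s1", "s2"),
                     gene = c("TP53", "MDM2", "MDM2"),
                     type = c("Trans", "High level Ampl", "High level Ampl"))
  ps <- pathway_status(classify_aberration(recs))
  expect_equal(ps$status[ps$sample == "s1"], "TP53-rearranged")
  expect_equal(ps$status[ps$sample == "s2"], "MDM2-amplified")
  expect_equal(pathway_status(recs[0, ], samples = "s9")$status, "none")
})

test_that("wild-type allele statistics reproduce the cohort range and median", {
  tum <- load_tumor_tp53()
  wt <- wt_allele_stats(tum[tum$gene == "TP53", ])
  expect_equal(wt$min, 0.15)
  expect_equal(wt$median, 0.30)
  expect_equal(wt$max, 0.80)
  expect_equal(wt$n, 16L)
})

test_that("wt allele stats equal a sort-based oracle on random vectors", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(3:15, 1)
    v <- round(runif(n), 2)
    recs <- data.frame(sample = sprintf("s%d", 1:n), wt_af = v)
    got <- wt_allele_stats(recs)
    s <- sort(v)
    med <- if (n %% 2 == 1) s[(n + 1) / 2]
           else mean(s[n / 2 + 0:1])
    expect_equal(got$min, s[1])
    expect_equal(got$max, s[n])
    expect_equal(got$median, med)
  }
  single <- wt_allele_stats(data.frame(sample = "a", wt_af = 0.4))
  expect_equal(c(single$min, single$median, single$max), rep(0.4, 3))
  expect_true(wt_allele_stats(data.frame(sample = "a",
                                         wt_af = NA_real_))$degenerate)
})

test_that("intron hotspots count samples, not events", {
  tum <- classify_aberration(load_tumor_tp53())
  hs <- hotspot_detection(tum[tum$gene == "TP53" &
                              tum$class == "rearrangement", ])
  expect_equal(hs$samples[hs$intron == 1], 5L)   # PD7193 counted once
  expect_equal(hs$samples[hs$intron == 9], 2L)
  expect_true(all(hs$hotspot))
  expect_true(hs$top[hs$intron == 1])
  cells <- load_cellline_tp53()
  chs <- hotspot_detection(cells[cells$mechanism == "rearrangement", ])
  expect_equal(chs$samples[chs$intron == 1], 4L)
  none <- hotspot_detection(data.frame(sample = character(),
                                       position = character()))
  expect_equal(nrow(none), 0L)
})

test_that("cell-line mechanisms give the 64% rearrangement share", {
  cells <- load_cellline_tp53()
  expect_equal(nrow(cells), 11L)
  freqs <- cohort_frequencies(cells$mechanism, n_samples = 11)
  expect_equal(unname(freqs["rearrangement"]), 64)
  expect_true(all(cells$p53_functional == "deficient"))
})

test_that("protein consequences follow the domain table", {
  dom <- load_tp53_domains()
  trunc306 <- protein_consequence(dom, c(1, 306))
  expect_equal(trunc306$lost_aa, 87L)
  expect_true("NLS" %in% trunc306$disrupted)   # most of the NLS is lost
  expect_setequal(trunc306$lost, c("OD", "BR"))
  nterm <- protein_consequence(dom, c(126, 393))
  expect_equal(nterm$lost_aa, 125L)
  expect_setequal(nterm$lost, c("TAD1", "TAD2"))
  expect_equal(nterm$disrupted, "DBD")   # first 25 aa of the DBD lost
  full <- protein_consequence(dom, c(1, 393))
  expect_equal(full$lost_aa, 0L)
  expect_equal(length(full$lost) + length(full$disrupted), 0L)
  ctrunc331 <- protein_consequence(dom, c(1, 331))
  expect_setequal(ctrunc331$lost, c("OD", "BR"))
  expect_error(protein_consequence(dom, c(0, 400)))
})

test_that("validation rate and recurrence arithmetic", {
  panel <- load_fusion_validation()
  expect_equal(nrow(panel), 17L)
  expect_equal(validation_rate(panel), 76)
  expect_equal(validation_rate(data.frame(sanger = rep("+", 5))), 100)
  expect_error(validation_rate(data.frame(sanger = character())), "tested")
  expect_equal(recurrence_frequency(7, c(49, 25)), 9)
  expect_equal(recurrence_frequency(character(0), c(49, 25)), 0)
  # overlapping cohorts deduplicate by id: set-union oracle
  c1 <- sprintf("s%02d", 1:30); c2 <- sprintf("s%02d", 21:50)
  pos <- c("s01", "s25", "s45")
  expect_equal(recurrence_frequency(pos, list(c1, c2)),
               round(100 * length(unique(pos)) /
                       length(union(c1, c2))))
  expect_equal(recurrence_frequency(pos, list(c1, c2)), 6)
})

test_that("the supported-fusion fixture carries the 19 genome-backed records", {
  t2 <- load_supported_fusions()
  expect_equal(nrow(t2), 19L)
  expect_equal(sum(t2$sample == "IOR/OS15"), 11L)
  expect_equal(sum(t2$sample == "MG-63"), 6L)
  expect_equal(sum(t2$sample == "ZK-58"), 2L)
  expect_equal(sum(t2$read_through == "yes"), 1L)
})
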