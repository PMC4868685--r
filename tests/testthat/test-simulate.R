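test_that("simulation is byte-identical for a fixed seed", {
  cfg <- sim_config(seed = 12, n_chromosomes = 2, chrom_length_bp = 50000L,
                    sv_counts = c(DEL = 10L, DUP = 2L, INV = 2L, TRA = 3L))
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1$reference, g2$reference)
  expect_identical(g1$models$exons, g2$models$exons)
  s1 <- simulate_rearrangements(g1, cfg)
  s2 <- simulate_rearrangements(g2, cfg)
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$calls, s2$calls)
  f1 <- write_fasta(s1$reference, tempfile(fileext = ".fa"))
  f2 <- write_fasta(s2$reference, tempfile(fileext = ".fa"))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("gene tiling makes the intragenic fraction controllable", {
  half <- simulate_genome(sim_config(seed = 3, n_chromosomes = 1,
                                     chrom_length_bp = 100000L,
                                     gene_fraction = 0.5))
  expect_equal(intragenic_genome_fraction(half$models,
                                          c(chr1 = 100000L)), 0.5)
  human_like <- simulate_genome(sim_config(seed = 3, n_chromosomes = 2,
                                           chrom_length_bp = 200000L,
                                           gene_fraction = 0.4))
  frac <- intragenic_genome_fraction(human_like$models,
                                     c(chr1 = 200000L, chr2 = 200000L))
  expect_equal(frac, 0.4, tolerance = 0.02)
})

test_that("planted microhomology mixtures are recovered within binomial bounds", {
  mix <- c(none = 0.2, short = 0.25, long = 0.55)
  cfg <- sim_config(seed = 21, n_chromosomes = 4,
                    chrom_length_bp = 1000000L,
                    sv_counts = c(DEL = 400L, DUP = 0L, INV = 0L, TRA = 0L),
                    microhomology_mixture = list(
                      del_lt5kb = mix, del_5to10kb = mix,
                      del_ge10kb = mix, other = mix))
  g <- simulate_genome(cfg)
  sim <- simulate_rearrangements(g, cfg)
  m <- measure_microhomology(sim$calls, sim$reference)
  cat3 <- table(categorize_microhomology(m$mh_len))
  n <- sum(cat3)
  obs <- as.numeric(cat3) / n
  for (i in 1:3) {
    ci <- stats::binom.test(cat3[i], n, mix[i])$conf.int
    # observed fraction within the exact binomial 95% interval around the
    # observation, which must cover the planted probability
    expect_true(mix[i] >= ci[1] && mix[i] <= ci[2])
    expect_lt(abs(obs[i] - mix[i]), 0.05)
  }
})

test_that("read-evidence counts behave at the allele-fraction extremes", {
  set.seed(1)
  hom <- simulate_read_evidence(100, rep(1, 20))
  expect_true(all(hom$concordant_a == 0 & hom$concordant_b == 0))
  absent <- simulate_read_evidence(100, rep(0, 20))
  expect_true(all(absent$spanning == 0 & absent$split == 0))
})

test_that("allele-fraction estimator is unbiased over replicates", {
  set.seed(33)
  ev <- simulate_read_evidence(200, rep(0.25, 500))
  est <- allele_frequency(ev)
  expect_gt(mean(est), 0.23)
  expect_lt(mean(est), 0.27)
  # within 2 standard errors of the planted fraction
  expect_lt(abs(mean(est) - 0.25), 2 * stats::sd(est) / sqrt(500))
})

test_that("coverage simulation plants detectable amplification", {
  lens <- c(chr1 = 500000L, chr2 = 500000L)
  flat <- simulate_coverage(lens, NULL, fold = 1, depth = 60,
                            window_bp = 10000L, seed = 4)
  expect_equal(coverage_fold_change(list(chrom = "chr1", start = 0,
                                         end = 200000), flat), 1,
               tolerance = 0.1)
  amp <- data.frame(chrom = "chr2", start = 100000, end = 300000)
  track <- simulate_coverage(lens, amp, fold = 7, depth = 60,
                             window_bp = 10000L, seed = 4)
  fc <- coverage_fold_change(list(chrom = "chr2", start = 100000,
                                  end = 300000), track)
  expect_gt(fc, 6)
  expect_equal(fc, 7, tolerance = 0.15)
  again <- simulate_coverage(lens, amp, fold = 7, depth = 60,
                             window_bp = 10000L, seed = 4)
  expect_identical(track, again)
})

test_that("damage assay plants exact folds at zero noise", {
  tab <- simulate_damage_assay("deficient", ct_noise_sd = 0, seed = 9)
  folds <- delta_delta_ct(tab)
  expect_equal(folds$fold, c(1, 1))
  tab4 <- simulate_damage_assay("functional", planted_fold = 4,
                                ct_noise_sd = 0, seed = 9)
  expect_equal(delta_delta_ct(tab4)$fold, c(4, 4))
  status <- sample(c("functional", "deficient"), 100, replace = TRUE)
  big <- simulate_damage_assay(status, ct_noise_sd = 0, seed = 10)
  calls <- p53_functional_call(delta_delta_ct(big))
  expect_identical(calls$call, status)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(chrom_length_bp = 5000L), "10 kb")
  expect_error(sim_config(microhomology_mixture = list(
    del_lt5kb = c(0.5, 0.5, 0.5), del_5to10kb = c(1, 0, 0),
    del_ge10kb = c(1, 0, 0), other = c(1, 0, 0))), "summing to 1")
  expect_error(sim_config(allele_fraction_range = c(0.2, 1.4)), "within")
  expect_error(sim_config(trans_splice_fraction = 0.8,
                          normal_panel_fraction = 0.3), "exceed")
  expect_error(sim_config(sv_counts = c(DEL = -1L)), ">= 0")
})

test_that("fusion provenance truth matches construction", {
  cfg <- sim_config(seed = 55, trans_splice_fraction = 0,
                    normal_panel_fraction = 0, read_through_fraction = 0)
  g <- simulate_genome(cfg)
  fus <- simulate_fusion_calls(g, cfg, n_fusions = 15)
  expect_true(all(fus$truth$genomically_supported))
  expect_true(all(fus$truth$rearrangement %in% fus$rearrangements$id))
  expect_equal(nchar(fus$fusions$context), rep(200L, 15))
})
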