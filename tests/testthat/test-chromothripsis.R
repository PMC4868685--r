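test_that("inter-breakpoint distances are gaps of sorted unique positions", {
  expect_equal(interbreakpoint_distances(c(10, 20, 40)), c(10, 20))
  expect_message(d <- interbreakpoint_distances(c(10, 10, 20, 40)),
                 "duplicate")
  expect_equal(d, c(10, 20))
  expect_error(interbreakpoint_distances(c(10, 20)), ">= 3")
})

test_that("KS statistic against the fitted exponential matches hand computation", {
  x <- c(1, 2, 4)   # mean 7/3
  m <- mean(x)
  fx <- stats::pexp(sort(x), 1 / m)
  d_hand <- max(max((1:3) / 3 - fx), max(fx - (0:2) / 3))
  got <- exponential_gof_test(c(x, 8, 16), bootstrap = 10, seed = 1)
  # recompute on the 5-point sample the function actually used
  x5 <- c(1, 2, 4, 8, 16)
  f5 <- stats::pexp(sort(x5), 1 / mean(x5))
  d5 <- max(max((1:5) / 5 - f5), max(f5 - (0:4) / 5))
  expect_equal(got$statistic, d5)
  expect_true(d_hand > 0)
})

test_that("clustering test keeps nominal type-I error and flags regular spacing", {
  set.seed(40)
  rej <- 0; nsim <- 150
  for (i in 1:nsim) {
    gaps <- rexp(80, 1 / 5000)
    p <- exponential_gof_test(gaps, bootstrap = 250, seed = i)$p_value
    if (p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / nsim, 0.01)
  expect_lt(rej / nsim, 0.10)
  regular <- exponential_gof_test(rep(1000, 60), bootstrap = 500, seed = 2)
  expect_lt(regular$p_value, 0.01)
})

test_that("two tight clusters are called clustered at p < 0.005", {
  set.seed(11)
  pos <- c(runif(50, 1e6, 1.02e6), runif(50, 2e6, 2.02e6))
  gaps <- interbreakpoint_distances(pos)
  got <- exponential_gof_test(gaps, bootstrap = 1000, seed = 5)
  expect_lt(got$p_value, 0.005)
})

test_that("too few distances or negative input are rejected", {
  expect_warning(out <- exponential_gof_test(c(1, 2, 3, 4)), "5")
  expect_true(is.na(out$p_value))
  expect_error(exponential_gof_test(c(1, -2, 3, 4, 5, 6)), "negative")
})

test_that("orientation chi-square matches the closed-form CDF", {
  even <- join_orientation_test(c(10, 10, 10, 10))
  expect_equal(even$p_value, 1)
  skew <- join_orientation_test(c(40, 0, 0, 0))
  expect_equal(skew$statistic, 120)
  expect_equal(skew$p_value, stats::pchisq(120, 3, lower.tail = FALSE))
  expect_lt(skew$p_value, 1e-6)
  for (cnt in list(c(12, 8, 15, 9), c(30, 22, 28, 20))) {
    got <- join_orientation_test(cnt)
    stat <- sum((cnt - sum(cnt) / 4)^2 / (sum(cnt) / 4))
    expect_equal(got$statistic, stat)
    expect_equal(got$p_value, stats::pchisq(stat, 3, lower.tail = FALSE))
  }
})

test_that("small orientation totals use the exact multinomial fallback", {
  got <- join_orientation_test(c(5, 0, 0, 0))
  expect_equal(got$method, "exact multinomial")
  # exact p of the most extreme outcome classes: all 4^5 sequences whose
  # probability <= that of (5,0,0,0)
  expect_equal(got$p_value, 4 * (1 / 4)^5, tolerance = 1e-9)
})

test_that("orientation p-values are calibrated under uniform joins", {
  set.seed(9)
  ps <- replicate(300, {
    cnt <- as.integer(stats::rmultinom(1, 60, rep(1 / 4, 4)))
    join_orientation_test(cnt)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("coverage fold change and cluster classification follow thresholds", {
  starts <- seq(0, 950000, 50000)
  track <- data.frame(chrom = "c1", start = starts, end = starts + 50000,
                      depth = 30)
  expect_equal(coverage_fold_change(list(chrom = "c1", start = 0,
                                         end = 5e5), track), 1)
  expect_error(coverage_fold_change(list(chrom = "c2", start = 0,
                                         end = 1e5), track), "no coverage")
  expect_equal(classify_cluster(0.5, 0.9, 7), "not-clustered")
  expect_equal(classify_cluster(1e-4, 0.95, 1.1), "clustered-copy-neutral")
  expect_equal(classify_cluster(1e-4, 0.95, 7), "clustered-amplified")
  expect_equal(classify_cluster(0.005, 0.95, 7), "not-clustered")  # boundary
  expect_equal(classify_cluster(1e-4, 0.95, 6), "clustered-copy-neutral")
})

test_that("the per-chromosome scan flags a planted MMBIR-like cluster", {
  cfg <- sim_config(seed = 19, n_chromosomes = 2,
                    clustered_fraction = 0.95, cluster_width_bp = 40000L,
                    sv_counts = c(DEL = 10L, DUP = 5L, INV = 10L, TRA = 40L),
                    amplified_fold = 7, depth = 40)
  g <- simulate_genome(cfg)
  sim <- simulate_rearrangements(g, cfg)
  cl <- sim$truth$cluster[!is.na(sim$truth$cluster)]
  amp_chrom <- sub("cluster_", "", cl[1])
  pos <- c(sim$calls$pos_a[sim$calls$chrom_a == amp_chrom],
           sim$calls$pos_b[sim$calls$chrom_b == amp_chrom])
  amp <- data.frame(chrom = amp_chrom, start = min(pos), end = max(pos))
  track <- simulate_coverage(c(chr1 = 1e6, chr2 = 1e6), amp, fold = 7,
                             depth = 40, window_bp = 10000L, seed = 3)
  rep <- chromothripsis_scan(sim$calls, track, bootstrap = 500, seed = 4)
  row <- rep[rep$chrom == amp_chrom, ]
  expect_lt(row$gof_p, 0.005)
  expect_gt(row$coverage_fold, 6)
  expect_equal(row$call, "clustered-amplified")
})
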