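#' Successive inter-breakpoint distances on one chromosome
#'
#' Positions are deduplicated (with a message) and sorted; the n-1
#' successive gaps are returned. Fewer than 3 unique breakpoints is an
#' error: no clustering statistic is defined.
#'
#' @param positions numeric vector of breakpoint positions on one
#'   chromosome.
#' @return numeric vector of gaps.
#' @export
interbreakpoint_distances <- function(positions) {
  u <- sort(unique(positions))
  if (length(u) < length(positions))
    message(length(positions) - length(u), " duplicate position(s) removed")
  if (length(u) < 3) stop("need >= 3 unique breakpoints")
  diff(u)
}

# Two-sided KS distance between sorted sample x and Exponential(rate)
.ks_stat_exp <- function(x_sorted, rate) {
  n <- length(x_sorted)
  fx <- stats::pexp(x_sorted, rate)
  i <- seq_len(n)
  max(max(i / n - fx), max(fx - (i - 1) / n))
}

#' Exponential goodness-of-fit test for inter-breakpoint distances
#'
#' Null model: breakpoints placed at random, so successive distances are
#' exponential with the mean of all observed distances. Because the mean
#' is estimated from the data, the Kolmogorov-Smirnov statistic is
#' calibrated by parametric bootstrap (Lilliefors-style: each resample is
#' drawn from the fitted exponential and the rate re-estimated before
#' computing its KS distance).
#'
#' @param distances non-negative gaps (>= 5 required; fewer gives an
#'   `NA` p with a warning).
#' @param bootstrap number of bootstrap resamples (default 2000).
#' @param seed integer seed.
#' @return list `statistic` (KS D), `p_value`, `n`, `mean_distance`.
#' @export
exponential_gof_test <- function(distances, bootstrap = 2000L, seed = 1L) {
  if (any(distances < 0)) stop("negative distance")
  n <- length(distances)
  if (n < 5) {
    warning("fewer than 5 distances; p undefined")
    return(list(statistic = NA_real_, p_value = NA_real_, n = n,
                mean_distance = mean(distances)))
  }
  m <- mean(distances)
  d_obs <- .ks_stat_exp(sort(distances), 1 / m)
  set.seed(.sub_seed(seed, "background"))
  d_null <- vapply(seq_len(bootstrap), function(b) {
    x <- stats::rexp(n, 1 / m)
    .ks_stat_exp(sort(x), 1 / mean(x))
  }, numeric(1))
  p <- (1 + sum(d_null >= d_obs)) / (bootstrap + 1)
  list(statistic = d_obs, p_value = p, n = n, mean_distance = m)
}

#' Join-orientation class of a rearrangement
#'
#' Interchromosomal joins use the two breakend orientations directly;
#' intrachromosomal types map to their standard join semantics
#' (DEL tail-head, DUP head-tail, INV head-head or tail-tail).
#'
#' @param calls rearrangement data.frame.
#' @return `JoinOrientationCounts`: named counts over the four classes
#'   head-head, head-tail, tail-head, tail-tail.
#' @export
join_orientation_counts <- function(calls) {
  cls <- paste(calls$orient_a, calls$orient_b, sep = "-")
  lv <- c("head-head", "head-tail", "tail-head", "tail-tail")
  tab <- table(factor(cls, levels = lv))
  stats::setNames(as.integer(tab), lv)
}

# Exact multinomial goodness-of-fit p (equal cell probabilities) by
# enumeration of all compositions; used as small-sample fallback.
.exact_multinomial_p <- function(counts, p = rep(1 / 4, 4)) {
  n <- sum(counts)
  obs <- stats::dmultinom(counts, prob = p)
  total <- 0
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    d <- n - a - b - cc
    pr <- stats::dmultinom(c(a, b, cc, d), prob = p)
    if (pr <= obs + 1e-12) total <- total + pr
  }
  min(total, 1)
}

#' Chi-square test of join-orientation randomness
#'
#' Goodness-of-fit of the four join-class counts against equal
#' probabilities (1/4 each, 3 df). Random joins give large p-values;
#' totals below 8 fall back to an exact multinomial test.
#'
#' @param counts named or plain vector of 4 join-class counts.
#' @return list `p_value`, `statistic` (chi-square, `NA` for the exact
#'   fallback), `method`.
#' @export
join_orientation_test <- function(counts) {
  stopifnot(length(counts) == 4, all(counts >= 0))
  n <- sum(counts)
  if (n < 8) {
    return(list(p_value = .exact_multinomial_p(as.integer(counts)),
                statistic = NA_real_, method = "exact multinomial"))
  }
  ct <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / 4, 4)))
  list(p_value = ct$p.value, statistic = unname(ct$statistic),
       method = "chi-square")
}

#' Coverage fold change of a region relative to the genome-wide median
#'
#' Median depth of the coverage windows whose midpoint falls in the
#' region, divided by the genome-wide median window depth.
#'
#' @param region list or data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param track coverage data.frame (`chrom`, `start`, `end`, `depth`).
#' @return positive fold change.
#' @export
coverage_fold_change <- function(region, track) {
  mid <- (track$start + track$end) / 2
  sel <- track$chrom == region$chrom & mid >= region$start &
    mid < region$end
  if (!any(sel)) stop("region contains no coverage windows")
  gm <- stats::median(track$depth)
  if (gm == 0) stop("genome-wide median depth is 0")
  stats::median(track$depth[sel]) / gm
}

#' Classify a per-chromosome breakpoint cluster
#'
#' `clustered` iff the exponential goodness-of-fit p is below `alpha`
#' (default 0.005); clustered chromosomes are `clustered-amplified`
#' (MMBIR-like) when the coverage fold change exceeds `fold_threshold`
#' (default 6), else `clustered-copy-neutral` (chromothripsis-like). The
#' orientation p is reported alongside but does not gate the call.
#'
#' @param gof_p clustering p-value.
#' @param orientation_p join-orientation p-value (reported only).
#' @param fold coverage fold change.
#' @param alpha clustering significance threshold.
#' @param fold_threshold amplification threshold.
#' @return one of `"not-clustered"`, `"clustered-copy-neutral"`,
#'   `"clustered-amplified"`.
#' @export
classify_cluster <- function(gof_p, orientation_p = NA, fold = 1,
                             alpha = 0.005, fold_threshold = 6) {
  if (is.na(gof_p) || gof_p >= alpha) return("not-clustered")
  if (fold > fold_threshold) "clustered-amplified"
  else "clustered-copy-neutral"
}

#' Per-chromosome chromothripsis scan
#'
#' For every chromosome with enough breakpoints, computes the exponential
#' goodness-of-fit clustering p, the join-orientation randomness p, the
#' coverage fold change of the minimal breakpoint-covering cluster region
#' (single-linkage with gap threshold `gap_mult` x median gap) and the
#' resulting call.
#'
#' @param calls rearrangement data.frame (both breakends contribute
#'   breakpoints to their chromosomes).
#' @param track coverage data.frame or `NULL` (fold reported as `NA`,
#'   copy-neutral assumed).
#' @param bootstrap,seed passed to [exponential_gof_test()].
#' @param alpha,fold_threshold passed to [classify_cluster()].
#' @param gap_mult single-linkage gap threshold multiplier.
#' @return `ChromothripsisReport` data.frame: one row per chromosome with
#'   `chrom`, `n_breakpoints`, `gof_p`, `orientation_p`, `coverage_fold`,
#'   `call`.
#' @export
chromothripsis_scan <- function(calls, track = NULL, bootstrap = 2000L,
                                seed = 1L, alpha = 0.005,
                                fold_threshold = 6, gap_mult = 10) {
  bp <- rbind(data.frame(chrom = calls$chrom_a, pos = calls$pos_a),
              data.frame(chrom = calls$chrom_b, pos = calls$pos_b))
  out <- list()
  for (ch in unique(bp$chrom)) {
    pos <- sort(unique(bp$pos[bp$chrom == ch]))
    if (length(pos) < 6) next
    gaps <- diff(pos)
    gof <- exponential_gof_test(gaps, bootstrap = bootstrap, seed = seed)
    on_ch <- calls$chrom_a == ch | calls$chrom_b == ch
    orient <- join_orientation_test(join_orientation_counts(calls[on_ch, ]))
    fold <- NA_real_
    if (!is.null(track)) {
      thr <- gap_mult * stats::median(gaps)
      grp <- cumsum(c(1, gaps > thr))
      sizes <- table(grp)
      main <- as.integer(names(sizes)[which.max(sizes)])
      reg <- list(chrom = ch, start = min(pos[grp == main]),
                  end = max(pos[grp == main]) + 1)
      fold <- tryCatch(coverage_fold_change(reg, track),
                       error = function(e) NA_real_)
    }
    call <- classify_cluster(gof$p_value, orient$p_value,
                             if (is.na(fold)) 1 else fold,
                             alpha, fold_threshold)
    out[[ch]] <- data.frame(chrom = ch, n_breakpoints = length(pos),
                            gof_p = gof$p_value,
                            orientation_p = orient$p_value,
                            coverage_fold = fold, call = call)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), n_breakpoints = integer(),
                      gof_p = numeric(), orientation_p = numeric(),
                      coverage_fold = numeric(), call = character())
  rownames(res) <- NULL
  res
}
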