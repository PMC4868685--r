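# Independent brute-force oracles used across the suite. These are
# deliberately written with their own string arithmetic (no package
# internals): the microhomology oracle tests junction-shift invariance of
# the derived sequence directly, instead of common-prefix scans.

o_rc <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Retained-side flank of the left partner ending at the (shifted)
# junction, and the right partner's first n bases after it. 0-based pos.
o_a_flank <- function(ref, ch, pos, orient, t, n) {
  if (orient == "tail") substr(ref[[ch]], pos + t - n + 1, pos + t)
  else o_rc(substr(ref[[ch]], pos - t + 1, pos - t + n))
}
o_b_flank <- function(ref, ch, pos, orient, t, n) {
  if (orient == "head") substr(ref[[ch]], pos + t + 1, pos + t + n)
  else o_rc(substr(ref[[ch]], pos - t - n + 1, pos - t))
}

# Junction ambiguity: number of shifts t != 0 (contiguous from 0) whose
# derived sequence, anchored W bases before and after the original
# junction, is identical to the unshifted one.
oracle_mh <- function(ref, ch_a, pos_a, or_a, ch_b, pos_b, or_b,
                      max_scan = 25) {
  W <- max_scan + 2
  derived <- function(t) {
    paste0(o_a_flank(ref, ch_a, pos_a, or_a, t, W + t),
           o_b_flank(ref, ch_b, pos_b, or_b, t, W - t))
  }
  d0 <- derived(0)
  r <- 0
  while (r < max_scan && identical(derived(r + 1), d0)) r <- r + 1
  l <- 0
  while (l < max_scan && identical(derived(-(l + 1)), d0)) l <- l + 1
  min(l + r, max_scan)
}

# Per-base bitmap oracle for the intragenic genome fraction.
oracle_intragenic_fraction <- function(models, genome_lengths) {
  covered <- 0
  for (ch in names(genome_lengths)) {
    bits <- logical(genome_lengths[[ch]])
    g <- models$genes[models$genes$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(g)))
      if (g$end[i] > g$start[i])
        bits[(g$start[i] + 1):g$end[i]] <- TRUE
    covered <- covered + sum(bits)
  }
  covered / sum(unlist(genome_lengths))
}

# Quadratic all-pairs oracle for breakend-in-gene classification.
oracle_breakpoint_classes <- function(calls, models) {
  in_gene <- function(ch, p) {
    hits <- 0
    for (i in seq_len(nrow(models$genes))) {
      g <- models$genes[i, ]
      if (g$chrom == ch && p >= g$start && p < g$end) hits <- hits + 1
    }
    hits > 0
  }
  vapply(seq_len(nrow(calls)), function(i) {
    na <- in_gene(calls$chrom_a[i], calls$pos_a[i])
    nb <- in_gene(calls$chrom_b[i], calls$pos_b[i])
    c("intergenic-both", "intragenic-one", "intragenic-both")[na + nb + 1]
  }, character(1))
}

# Shared small simulated genomes (built once per test run)
shared_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_genome(sim_config(seed = 424, n_chromosomes = 2,
                                           chrom_length_bp = 100000L))
    cache
  }
})
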