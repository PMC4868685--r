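#' Simulation configuration for the synthetic genome generator
#'
#' Bundles every knob of the synthetic-data module. Defaults emulate the
#' regimes observed in chaotic osteosarcoma-like genomes: deletions are the
#' dominant type and short deletions carry mostly long (6-25 bp)
#' junction microhomology, while translocations, inversions, duplications
#' and long deletions mostly carry 5 bp or less; interchromosomal allele
#' fractions span 1-50%; a fraction of breakpoints fall into one dense
#' cluster per chromosome.
#'
#' @param seed integer seed for the run's random stream.
#' @param n_chromosomes,chrom_length_bp toy genome shape.
#' @param gc GC content of the random genome.
#' @param gene_fraction fraction of each chromosome tiled by gene bodies.
#' @param gene_length_bp,exons_per_gene gene model geometry.
#' @param sv_counts named counts per SV type (DEL, DUP, INV, TRA).
#' @param microhomology_mixture list of probability vectors over the
#'   categories `c(none, short, long)` = \{0, 1-5, 6-25\} bp, one per
#'   stratum: `del_lt5kb`, `del_5to10kb`, `del_ge10kb`, `other`.
#' @param clustered_fraction fraction of breakpoints placed inside a single
#'   cluster window per chromosome (the chromothripsis-like alternative).
#' @param cluster_width_bp width of that window.
#' @param amplified_fold coverage fold change planted in amplified regions.
#' @param depth mean read pairs per breakpoint window / coverage window.
#' @param coverage_window_bp window size of the simulated coverage track.
#' @param allele_fraction_range interval the planted allele fractions are
#'   drawn from.
#' @param trans_splice_fraction,normal_panel_fraction,read_through_fraction
#'   mixture of fusion-call provenance classes; the remainder is
#'   genomically supported.
#' @param ct_noise_sd Gaussian noise on simulated qPCR Ct values (cycles).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L,
                       chrom_length_bp = 1000000L,
                       gc = 0.5,
                       gene_fraction = 0.4,
                       gene_length_bp = 5000L,
                       exons_per_gene = 4L,
                       sv_counts = c(DEL = 200L, DUP = 30L, INV = 30L, TRA = 40L),
                       microhomology_mixture = list(
                         del_lt5kb  = c(none = 0.15, short = 0.25, long = 0.60),
                         del_5to10kb = c(none = 0.35, short = 0.45, long = 0.20),
                         del_ge10kb = c(none = 0.40, short = 0.47, long = 0.13),
                         other      = c(none = 0.40, short = 0.47, long = 0.13)),
                       clustered_fraction = 0,
                       cluster_width_bp = 50000L,
                       amplified_fold = 1,
                       depth = 30,
                       coverage_window_bp = 50000L,
                       allele_fraction_range = c(0.01, 0.5),
                       trans_splice_fraction = 0.55,
                       normal_panel_fraction = 0.15,
                       read_through_fraction = 0.05,
                       ct_noise_sd = 0.15) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.integer(chrom_length_bp),
              gc = gc, gene_fraction = gene_fraction,
              gene_length_bp = as.integer(gene_length_bp),
              exons_per_gene = as.integer(exons_per_gene),
              sv_counts = sv_counts,
              microhomology_mixture = microhomology_mixture,
              clustered_fraction = clustered_fraction,
              cluster_width_bp = as.integer(cluster_width_bp),
              amplified_fold = amplified_fold,
              depth = depth,
              coverage_window_bp = as.integer(coverage_window_bp),
              allele_fraction_range = allele_fraction_range,
              trans_splice_fraction = trans_splice_fraction,
              normal_panel_fraction = normal_panel_fraction,
              read_through_fraction = read_through_fraction,
              ct_noise_sd = ct_noise_sd)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  # structured-config files (YAML) deliver nested lists; flatten them
  cfg$sv_counts <- unlist(cfg$sv_counts)
  cfg$allele_fraction_range <- unlist(cfg$allele_fraction_range)
  cfg$microhomology_mixture <- lapply(cfg$microhomology_mixture, unlist)
  if (cfg$chrom_length_bp < 10000L)
    stop("chromosome length < 10 kb: too small to plant junctions")
  if (any(cfg$sv_counts < 0)) stop("sv_counts must be >= 0")
  if (is.null(names(cfg$sv_counts)) ||
      !all(names(cfg$sv_counts) %in% c("DEL", "DUP", "INV", "TRA")))
    stop("sv_counts must be named with SV types DEL/DUP/INV/TRA")
  for (nm in names(cfg$microhomology_mixture)) {
    p <- cfg$microhomology_mixture[[nm]]
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("microhomology_mixture[['", nm,
           "']] must be 3 non-negative probabilities summing to 1")
  }
  afr <- cfg$allele_fraction_range
  if (length(afr) != 2L || afr[1] < 0 || afr[2] > 1 || afr[1] > afr[2])
    stop("allele_fraction_range must be an interval within [0, 1]")
  if (cfg$clustered_fraction < 0 || cfg$clustered_fraction > 1)
    stop("clustered_fraction must be a probability")
  if (cfg$amplified_fold < 1) stop("amplified_fold must be >= 1")
  if (cfg$trans_splice_fraction + cfg$normal_panel_fraction +
      cfg$read_through_fraction > 1)
    stop("fusion provenance fractions exceed 1")
  if (cfg$gene_fraction < 0 || cfg$gene_fraction > 1)
    stop("gene_fraction must be in [0, 1]")
  cfg
}

# One global stream per run; sub-streams derived per operation so results
# are reproducible under reordering of the simulation calls.
.sub_seed <- function(seed, op) {
  offs <- c(genome = 11, sv = 23, evidence = 37, fusion = 41,
            coverage = 53, damage = 67, background = 71)
  as.integer((as.numeric(seed) * 101 + offs[[op]]) %% 2147483647)
}
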