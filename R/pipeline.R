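#' Run the full genomic-chaos analysis on a simulated study
#'
#' End-to-end driver tying the modules together: simulates a toy genome
#' and rearrangement truth set, filters the calls on read support and
#' allele fraction, builds the microhomology profile and compares each
#' group to the random background, scans chromosomes for
#' chromothripsis-like clustering against the coverage track, runs the
#' fusion filter cascade and RNA-DNA concordance, summarizes the bundled
#' aberration cohort fixtures, and quantifies a simulated damage-response
#' assay. Deterministic given the seed.
#'
#' @param config a [sim_config()] object, a YAML file path, or a list of
#'   `sim_config()` arguments.
#' @param out_dir optional directory; when given, TSV tables and a
#'   `summary.json` are written there.
#' @param background_n random junctions for the background profile.
#' @param fisher_replicates Monte-Carlo replicates for the profile tests.
#' @param bootstrap bootstrap resamples for the clustering test.
#' @return (invisibly) a list with all stage results and a `summary`
#'   list mirroring the JSON output.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         background_n = 500L,
                         fisher_replicates = 100000L,
                         bootstrap = 1000L) {
  if (is.character(config))
    config <- do.call(sim_config, yaml::read_yaml(config))
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, config)
  genome <- simulate_genome(config)
  sim <- simulate_rearrangements(genome, config)

  thr <- filter_thresholds()
  calls <- filter_sv_calls(sim$calls, thr)
  calls <- af_filter(calls, thr$min_allele_fraction)
  calls <- measure_microhomology(calls, sim$reference)

  profile <- build_mh_profile(calls)
  background <- random_background_profile(sim$reference, n = background_n,
                                          seed = config$seed)
  occupied <- profile[profile$n > 0, ]
  mh_tests <- lapply(split(occupied, droplevels(factor(occupied$group))),
                     function(pg)
    compare_to_background(pg, background, replicates = fisher_replicates,
                          seed = config$seed)$p_value)

  lens <- stats::setNames(rep(config$chrom_length_bp, config$n_chromosomes),
                          names(genome$reference))
  amp <- NULL
  if (config$amplified_fold > 1 && config$clustered_fraction > 0) {
    # amplify the cluster windows (MMBIR-like regime)
    cl <- sim$truth$cluster[!is.na(sim$truth$cluster)]
    amp_chroms <- unique(sub("cluster_", "", cl))
    amp <- do.call(rbind, lapply(amp_chroms, function(ch) {
      pos <- c(sim$calls$pos_a[sim$calls$chrom_a == ch],
               sim$calls$pos_b[sim$calls$chrom_b == ch])
      data.frame(chrom = ch, start = max(0, min(pos) - 1),
                 end = max(pos) + 1)
    }))
  }
  track <- simulate_coverage(lens, amp, fold = config$amplified_fold,
                             depth = config$depth,
                             window_bp = config$coverage_window_bp,
                             seed = config$seed)
  ct_report <- chromothripsis_scan(calls, track, bootstrap = bootstrap,
                                   seed = config$seed)

  # never ask for more fusions than the gene pool supports (each planted
  # fusion consumes its partner genes plus an occasional neighbor)
  n_fus <- min(40L, nrow(genome$models$genes) %/% 3L)
  fus <- simulate_fusion_calls(genome, config, n_fusions = n_fus)
  fcfg <- fusion_filter_config(normal_panel = fus$panel)
  kept <- filter_fusions(fus$fusions, fcfg)
  conc <- concordance_summary(kept, fus$rearrangements, genome$models)

  expr <- simulate_expression(genome$models, seed = config$seed)
  enrich <- partner_expression_enrichment(kept, expr)

  tumor <- classify_aberration(load_tumor_tp53())
  ps <- pathway_status(tumor, samples = c(unique(tumor$sample),
                                          sprintf("PDneg%02d", 1:7)))
  freqs <- cohort_frequencies(ps$status, n_samples = 25)
  wt <- wt_allele_stats(tumor[tumor$gene == "TP53", ])
  hs <- hotspot_detection(tumor[tumor$gene == "TP53" &
                                tumor$class == "rearrangement", ])

  ct_tab <- simulate_damage_assay(c("functional", "deficient"),
                                  samples = c("CTRL", "OS1"),
                                  seed = config$seed)
  folds <- delta_delta_ct(ct_tab)
  calls53 <- p53_functional_call(folds)

  summary <- list(
    seed = config$seed,
    thresholds = thr,
    sv = list(n_simulated = nrow(sim$calls), n_filtered = nrow(calls)),
    microhomology = list(profile_p_vs_background = mh_tests),
    chromothripsis = ct_report,
    concordance = conc$summary,
    partner_expression_p = enrich$p_value,
    cohort = list(frequencies = as.list(freqs),
                  wt_allele = wt[c("min", "median", "max")],
                  hotspots = hs),
    damage_response = stats::setNames(as.list(calls53$call), calls53$sample))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sv_bedpe(calls, file.path(out_dir, "sv_filtered.bedpe"))
    utils::write.table(profile, file.path(out_dir, "mh_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ct_report, file.path(out_dir, "chromothripsis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(conc$summary, file.path(out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(list(genome = genome, sim = sim, calls = calls,
                 profile = profile, background = background,
                 mh_tests = mh_tests, chromothripsis = ct_report,
                 fusions = fus, kept_fusions = kept, concordance = conc,
                 expression = expr, enrichment = enrich,
                 damage = list(folds = folds, calls = calls53),
                 summary = summary))
}
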