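# svforensics

Forensics of structural-variant junctions in chaotic cancer genomes —
junction microhomology profiling, chromothripsis/MMBIR cluster
statistics, SV allele-fraction estimation, fusion-transcript filtering
with RNA–DNA concordance, gene-centric aberration cohort summaries, and
2^−ΔΔCt quantification of the p53 damage response.

## The problem

Osteosarcoma-like genomes carry hundreds of rearrangements and no single
pathognomonic translocation. What *is* informative is the forensic
signature of each junction and the genome-wide geometry of the
breakpoints:

* **Microhomology at junctions.** The breakpoint of a rearrangement is
  ambiguous over the bases shared by its two flanks. We report this
  junction ambiguity L + R (capped at 25 bp; reverse-complement-aware
  for inversion-type joins) and group it into three categories — none,
  1–5 bp, 6–25 bp. Under a random genome E[L + R] = 2·Σₖ(¼)ᵏ = 2/3 bp
  and homology ≥ 6 bp is ≪ 1%, so enrichment of the 6–25 bp class
  (typically in short deletions) is the fingerprint of
  microhomology-mediated end joining (MMEJ). Profiles are tested against
  a 500-junction random background with Fisher's exact test for count
  data using simulated p-values (10⁵ replicates).
* **Breakpoint clustering.** Random breakpoints have exponential
  inter-breakpoint distances with the observed mean; a Kolmogorov–
  Smirnov test with a parametric bootstrap (the mean being estimated)
  flags chromothripsis-like clusters at p < 0.005. Join-orientation
  randomness is a χ² test of the four join classes against ¼ each, and
  > 6-fold coverage gain over the genome median separates MMBIR-like
  amplified clusters from copy-neutral chromothripsis.
* **Allele fraction.** AF = S/(S + C̄), with S the spanning + split reads
  and C̄ the mean concordant count across the two breakends in a 500-bp
  window; calls are kept at ≥ 8 spanning, ≥ 3 split, AF ≥ 10%.
* **RNA–DNA concordance.** Fusion transcripts pass a read-support /
  normal-panel / junction-complexity cascade and are then matched to
  genomic rearrangements as direct fusions, read-through events (the
  breakend sits in the gene next to the reported partner), or —
  usually — unsupported, the hallmark of trans-splicing.
* **Cohorts and function.** Gene-level aberration tables are classified
  (rearrangement / snv / indel / amplification, 50-bp SV boundary),
  summarized into per-mechanism frequencies, intron hotspots and
  wild-type allele statistics, and protein-domain consequences; p53
  function is called from 2^−ΔΔCt induction of CDKN1A and BAX after
  irradiation.

A synthetic-genome simulator plants every one of these quantities
(microhomology per junction, cluster membership, allele fraction,
coverage fold, fusion provenance, Ct shifts), so the entire pipeline is
exercised end-to-end with no external data. Small plain-text fixtures
encode the published cohort tables the summaries reproduce.

## Worked example

```r
library(svforensics)

cfg    <- sim_config(seed = 7, sv_counts = c(DEL = 300L, DUP = 60L,
                                             INV = 60L, TRA = 80L))
genome <- simulate_genome(cfg)
sim    <- simulate_rearrangements(genome, cfg)

calls <- filter_sv_calls(sim$calls, filter_thresholds())   # 8 spanning, 3 split
calls <- af_filter(calls, 0.10)                            # AF >= 10%
calls <- measure_microhomology(calls, sim$reference)
prof  <- build_mh_profile(calls)
subset(prof, group %in% c("DEL_lt5kb", "TRA"))
#>      group category count  fraction  n
#>        TRA     none     6 0.3750000 16
#>        TRA      1-5     7 0.4375000 16
#>        TRA     6-25     3 0.1875000 16
#>  DEL_lt5kb     none     4 0.1176471 34
#>  DEL_lt5kb      1-5     7 0.2058824 34
#>  DEL_lt5kb     6-25    23 0.6764706 34

bg <- random_background_profile(sim$reference, n = 500, seed = 7)
compare_to_background(subset(prof, group == "DEL_lt5kb"), bg,
                      replicates = 1e5, seed = 7)$p_value
#> [1] 1e-05
length_homology_association(calls)[c("rho", "p_value")]
#> $rho: -0.3   $p_value: 0.04
```

Of 496 simulated calls, 90 pass the read-support and allele-fraction
filters. Short deletions show 68% long (6–25 bp) microhomology versus
19% for translocations — the planted MMEJ regime — and differ from the
random-junction background at the Monte-Carlo floor (p = 1e-05, i.e.
none of 10⁵ resampled tables was as extreme). The negative Spearman
correlation says longer deletions carry shorter junction homology.

`run_pipeline(cfg, out_dir = "out")` drives every stage (SV filtering,
microhomology vs background, chromothripsis scan, fusion cascade and
concordance, cohort fixtures, damage-response calls) and writes TSV
tables plus a `summary.json`; it also accepts a YAML config file.

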