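---
title: "Dissecting chaotic tumor genomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting chaotic tumor genomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svforensics)
```

Osteosarcoma and similarly unstable tumors carry hundreds of structural
variants (SVs) per genome, produced largely by microhomology-mediated
repair (MMEJ) and replication-based mechanisms (MMBIR) rather than by a
few recurrent driver translocations. `svforensics` implements the
statistics used to characterize such genomes — junction microhomology
profiling, chromothripsis-style clustering tests, SV allele-fraction
estimation, fusion-transcript filtering and RNA–DNA concordance, cohort
summarization of gene-level aberrations, and 2^-ddCt quantification of
the p53 damage response — together with a synthetic-genome simulator that
plants every quantity the analyses estimate, so the whole pipeline is
testable without sequencing data.

## Junction microhomology

A rearrangement junction glues the retained flank of one breakend to the
retained flank of the other; flanks retained on the far side for their
role in the join are reverse-complemented. We define the microhomology of
a junction as its **placement ambiguity**: the breakpoint can be slid
left by $L$ and right by $R$ bases without changing the derived sequence,
and the reported length is $L + R$, capped at a 25 bp scan (longer
homologies are flagged as capped; they fall outside the three-category
system used downstream). This is the standard MMEJ-oriented definition.
For an i.i.d. random genome each directional shift is geometric with
success probability $1/4$, so the expected ambiguity of a random junction
is $2\sum_{k\ge1}4^{-k} = 2/3$ bp, and homologies of 6 bp or more occur
well below the 1% level — which is what makes the observed enrichment in
tumor junctions informative. A single-direction scan (expectation $1/3$)
is sometimes used in the literature; we use the two-sided definition
because it is the one under which the junction is genuinely ambiguous.

Lengths are grouped into three categories — none, 1–5 bp, 6–25 bp — and
profiled per SV type with deletions further stratified at 5 kb and 10 kb
(the 10 kb stratum nested inside the 5 kb one, mirroring how such results
are usually presented). Each group is compared against a background of
500 random junctions measured identically on the same reference, with
Fisher's exact test for count data using simulated p-values (10^5
Monte-Carlo replicates conditioned on the table margins). The
Monte-Carlo estimate is validated in the test suite against the exact
network-algorithm p on the same 2×3 tables. The deletion-length /
homology-length association is summarized by a Spearman rank correlation.

The simulator *plants* microhomology by copying flank bases across the
junction and then forcing a mismatch at both extension points, so the
measured ambiguity equals the planted length exactly, for every length in
0–25 bp and all four SV types — a round-trip property the suite checks
exhaustively. An independent brute-force oracle re-derives the ambiguity
by explicitly shifting breakend coordinates and comparing anchored
derived-sequence windows.

## Chromothripsis and MMBIR statistics

Clustering of breakpoints on a chromosome is tested against the null of
random placement, under which successive inter-breakpoint distances are
exponential with the observed mean. Because the mean is estimated from
the same data, the Kolmogorov–Smirnov statistic is calibrated by
parametric bootstrap (Lilliefors-style: each resample is drawn from the
fitted exponential and the rate re-estimated; 2000 resamples by
default). The suite verifies a type-I error within [0.03, 0.07] at
$\alpha = 0.05$ (1000 simulations, 100 gaps each) and power above 0.95
against a two-cluster alternative. A chromosome is called clustered at
p < 0.005.

Join-orientation randomness — the second chromothripsis hallmark — is a
chi-square goodness-of-fit of the four join classes (head-head,
head-tail, tail-head, tail-tail) against equal probabilities ¼ (3 df),
with an exact multinomial fallback below 8 joins. Equal class
probabilities are used; deriving them from genome composition would
change nothing for the four-class system. Intrachromosomal types map to
their standard join semantics (DEL tail–head, DUP head–tail, INV
head-head/tail-tail).

Copy-number state separates chromothripsis-like (copy-neutral) clusters
from MMBIR-like amplified ones: the median depth of 50-kb coverage
windows in the cluster region, divided by the genome-wide median, with a
6-fold threshold. Cluster regions are the minimal interval covering the
breakpoints assigned by single-linkage with a gap threshold of 10× the
median gap; the threshold is exposed because no standard definition
exists. The orientation p is reported alongside the call but does not
gate it — a skewed orientation spectrum is informative, not
disqualifying.

## SV read support and allele fraction

Calls are kept when they have at least 8 spanning and 3 split
(breakpoint-covering) reads. The allele fraction is
$\mathrm{AF} = S/(S+\bar C)$ with $S$ the supporting reads and $\bar C$
the *mean* of the two per-breakend concordant counts measured in a
500-bp window; the mean (rather than the sum) makes the estimator
symmetric in the breakends and reduces it to the read fraction at a
single junction. The sum variant is exposed as an option since either
reading of "comparing concordant and supporting reads" is defensible.
AF filtering at ≥ 10% is inclusive at the boundary. With evidence counts
simulated as a binomial split of Poisson window depths, the estimator
recovers planted fractions to within sampling error (a small
ratio-estimator bias of order 1/depth remains; at 200× it is ~0.001 and
ignored).

Breakpoints are classified against gene bodies with half-open containment
(`[start, end)`), so a breakend exactly at a gene start is intragenic. A
gene counts as expressed above 1 FPKM-equivalent — the threshold is a
design choice, exposed as a parameter, since expression units are
consumed as given.

## Fusion transcripts and RNA–DNA concordance

The RNA-side cascade mirrors standard fusion post-processing: (i) read
support ≥ 8 spanning and ≥ 3 split reads; (ii) removal of pairs seen in a
normal-tissue panel, matched **order-sensitively** on (5′ gene, 3′ gene)
because chimeric transcripts are directional; (iii) removal of junctions
whose 200-bp context is low-complexity or repetitive. No standard
complexity metric exists, so we use dinucleotide Shannon entropy
(threshold 1.5 bits — uniform random 200-mers score ≈ 3.94 bits and pass
at > 99.9%) plus a tandem-repeat rule (longest exact repeat tract of
period ≤ 8 covering > 50% of the window). The three filters are
independent predicates, so the cascade is order-independent.

A fusion is **genomic-direct** when one rearrangement breakend lies in
the 5′ partner's body oriented to retain its upstream part and the other
lies in the 3′ partner's body oriented to retain its downstream part (a
collinear 5′→3′ chimera; fused-exon indices tighten the interval when
present). It is **genomic-read-through** when the breakend instead falls
in a same-strand neighbor (≤ 1 Mb) of a partner — the pattern produced
when a translocation into one gene yields a second transcript involving
the gene next door. Everything else is unsupported; on this kind of data
the large unsupported majority is the signature of trans-splicing.
Caller outputs are merged by gene pair with a ±10 bp junction-coordinate
tolerance (the exact tolerance between callers is tool-dependent, so it
is a parameter). Partner-gene expression enrichment uses a two-sided
Wilcoxon rank-sum test of fusion partners against all other genes.

## Cohort summarization

Free-text aberration descriptors are classified with a 50 bp size
boundary between indels and structural rearrangements — the standard SV
convention; the source tables distinguish "small" deletions from kb–Mb
events without stating a cutoff. Pathway status per sample applies the
precedence TP53 rearrangement > TP53 snv/indel > MDM2 amplification.
Hotspots count *samples* per intron, not events, so a sample with two
intron-1 events contributes once (whether such a pair is one complex
event or two independent ones is not resolvable from a table, and
counting samples is conservative either way). Wild-type allele statistics
take one known fraction per sample; an even count medians the central
pair. Protein consequences are computed against a shipped, explicitly
synthetic p53 domain coordinate table whose boundaries are consistent
with the documented consequences of the cohort's truncations; it is a
plain TSV and editable. Recurrence across cohorts deduplicates sample ids
by set union when ids are available and sums sizes when cohorts are known
disjoint.

## Damage response

Relative induction is quantified as $2^{-\Delta\Delta C_t}$ with
technical replicates averaged per condition before differencing and a
TBP-like endogenous reference. A sample is p53-functional when both
CDKN1A and BAX are induced ≥ 2-fold at 8 h (inclusive). The 2-fold
cutoff is a design choice — reports of this assay call "no significant
increase" without a number — and is exposed, along with an optional
"partial" category for samples inducing exactly one target.

## The simulator: what it emulates, and what it does not

The generator's defaults encode the study conditions the analyses
target: deletions as the dominant SV type; short (< 5 kb) deletions drawn
with 60% long (6–25 bp) homology versus 13% for other types and long
deletions (so the MMEJ signature — > 55% long homology in short
deletions, 80–93% at ≤ 5 bp elsewhere — is reproduced); interchromosomal
allele fractions uniform on 1–50%; clustered breakpoints placed uniformly
inside one cluster window per chromosome (the alternative the
exponential test targets); optional 7-fold amplification of the cluster
(the MMBIR-like regime against the > 6-fold rule); fusion calls mixed as
~25% genomically supported, 5% read-through, 55% trans-splice-only and
15% normal-panel artifacts, emulating the observed ~90% unsupported
majority; and qPCR Ct values with 0.15-cycle Gaussian noise and a 4-fold
planted induction for p53-functional samples.

Toy genomes are i.i.d. A/C/G/T at configurable GC; genes tile a
configurable fraction of each chromosome (default 40%, matching the
genome-wide intragenic fraction) in equal-length bodies with equal-length
exons. Read evidence is simulated at the count level (binomial splits of
Poisson depths) — no reads, no FASTQ/BAM. Real data differ in ways the
simulator deliberately ignores: non-uniform base composition and repeats
(which would raise the random-junction homology background), mappability
artifacts, overdispersed read counts (the binomial/Poisson choice is an
assumption, exposed in the evidence model), aneuploidy-driven coverage
waves, and gene-length/expression correlations. Passing tests therefore
demonstrate the correctness of the statistics under their stated models,
not robustness to every artifact of sequencing data.

One global stream is seeded per run and sub-streams are derived per
operation, so individual stages are reproducible under reordering.
Problem sizes in the test suite (toy chromosomes of 0.1–1 Mb, hundreds of
junctions, 300-resample bootstraps in the calibration loops, 2×10^4-
replicate Monte-Carlo Fisher checks) were chosen so the full suite runs
in a few minutes while keeping every interval assertion at least two
standard errors wide; the acceptance script uses the full stated
defaults (10^5 Fisher replicates, 2000 bootstrap resamples, 500
background junctions).

## Known limitations

* Microhomology is measured against the provided reference, so somatic
  SNVs at the junction would truncate the homology; callers that emit
  consensus contigs avoid this, count-level tables cannot.
* The read-through window (1 Mb, one intervening gene allowed implicitly
  via the same-strand neighbor rule) is generous on toy genomes; on
  gene-dense regions it can over-call read-through when gene assignments
  collide, which is why the simulator never reuses genes across planted
  fusions.
* The exponential null treats breakpoints as one-dimensional points;
  reference gaps and unmappable regions would inflate clustering signal
  on real chromosomes.
* No derivative-chromosome reconstruction and no oscillating
  copy-number-state segmentation are attempted; the cluster call is a
  screen, not a proof of chromothripsis.
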