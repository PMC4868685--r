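# Gene-centric aberration cohort summarization: classification of raw
# aberration descriptors, p53-pathway status with precedence, cohort
# frequencies, intron hotspots, protein-domain consequences and
# validation/recurrence arithmetic. Ships small TSV fixtures encoding the
# published cohort tables.

.extdata <- function(name) {
  p <- system.file("extdata", name, package = "svforensics")
  if (p == "") p <- file.path("inst", "extdata", name)  # pre-install use
  p
}

.generic_fixture <- function(name, int_cols = character(0)) {
  tv <- .read_tsv_hash(.extdata(name))
  rows <- strsplit(tv$body, "\t", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, lapply(rows, function(r) {
    length(r) <- length(tv$cols); r
  })), stringsAsFactors = FALSE)
  names(out) <- tv$cols
  for (cc in intersect(int_cols, names(out)))
    out[[cc]] <- suppressWarnings(as.numeric(out[[cc]]))
  out
}

#' Bundled cohort fixtures
#'
#' Small plain-text tables encoding the published osteosarcoma cohort
#' results: the 17-candidate fusion validation panel, the 19 genomically
#' supported fusion transcripts, the TP53/MDM2 aberrations of the
#' 25-tumor WGS cohort (allele frequencies as fractions), the p53 status
#' of the 11 sequenced cell lines, and a synthetic p53 domain coordinate
#' table (documented in the file header).
#'
#' @return data.frames; `load_tp53_domains()` returns a list with
#'   `protein_length` and `domains`.
#' @export
load_fusion_validation <- function() .generic_fixture("fusion_validation_panel.tsv")

#' @rdname load_fusion_validation
#' @export
load_supported_fusions <- function() .generic_fixture("genomic_supported_fusions.tsv")

#' @rdname load_fusion_validation
#' @export
load_tumor_tp53 <- function() {
  out <- .generic_fixture("tumor_tp53_aberrations.tsv",
                          c("aberrant_af_pct", "wt_af_pct", "copy_number"))
  out$aberrant_af <- out$aberrant_af_pct / 100
  out$wt_af <- out$wt_af_pct / 100
  out
}

#' @rdname load_fusion_validation
#' @export
load_cellline_tp53 <- function() {
  out <- .generic_fixture("cellline_tp53_status.tsv")
  out$tp53_intron <- suppressWarnings(as.integer(out$tp53_intron))
  out
}

#' @rdname load_fusion_validation
#' @export
load_tp53_domains <- function() {
  tv <- .read_tsv_hash(.extdata("tp53_domains.tsv"))
  plen_line <- grep("^#protein_length\t", tv$comments, value = TRUE)
  plen <- as.integer(strsplit(plen_line, "\t")[[1]][2])
  rows <- strsplit(tv$body, "\t", fixed = TRUE)
  domains <- data.frame(domain = vapply(rows, `[`, "", 1),
                        start_aa = as.integer(vapply(rows, `[`, "", 2)),
                        end_aa = as.integer(vapply(rows, `[`, "", 3)))
  stopifnot(all(domains$start_aa >= 1), all(domains$end_aa <= plen),
            all(domains$start_aa <= domains$end_aa))
  list(protein_length = plen, domains = domains)
}

.parse_size_bp <- function(type) {
  m <- regmatches(type, regexec("\\(([0-9.]+) ?(bp|kb|Mb)\\)", type))[[1]]
  if (length(m) < 3) return(NA_real_)
  as.numeric(m[2]) * c(bp = 1, kb = 1e3, Mb = 1e6)[[m[3]]]
}

#' Classify a raw aberration descriptor
#'
#' Maps free-text aberration types ("Trans", "Del (7.5 Mb)",
#' "Small del (10 bp)", "SNV", "Inv (50.3 Mb)", "High level Ampl") to the
#' class system: interchromosomal events and intrachromosomal events of
#' at least `sv_min_bp` (default 50 bp, the standard SV size convention)
#' are structural `rearrangement`s; smaller deletions/insertions are
#' `indel`; single-nucleotide changes `snv`; high-level amplifications
#' `amplification`.
#'
#' @param records data.frame with at least a `type` column (vectorized).
#' @param sv_min_bp indel / rearrangement size boundary.
#' @return `records` with added `class`, `subtype`, `size_bp` columns;
#'   unparseable type strings are an error naming the record.
#' @export
classify_aberration <- function(records, sv_min_bp = 50) {
  n <- nrow(records)
  class <- character(n); subtype <- character(n); size <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ty <- records$type[i]
    tl <- tolower(ty)
    size[i] <- .parse_size_bp(ty)
    if (grepl("ampl", tl)) {
      class[i] <- "amplification"; subtype[i] <- "high-level-ampl"
    } else if (grepl("snv|c\\.[0-9]+", tl)) {
      class[i] <- "snv"; subtype[i] <- "snv"
    } else if (grepl("trans", tl)) {
      class[i] <- "rearrangement"; subtype[i] <- "tra"
    } else if (grepl("inv", tl)) {
      class[i] <- "rearrangement"; subtype[i] <- "inv"
    } else if (grepl("dup", tl)) {
      class[i] <- "rearrangement"; subtype[i] <- "dup"
    } else if (grepl("del", tl)) {
      if (!is.na(size[i]) && size[i] < sv_min_bp) {
        class[i] <- "indel"; subtype[i] <- "del"
      } else {
        class[i] <- "rearrangement"; subtype[i] <- "del"
      }
    } else {
      stop("unparseable aberration type in record ", i, ": '", ty, "'")
    }
  }
  records$class <- class
  records$subtype <- subtype
  records$size_bp <- size
  records
}

#' Per-sample p53-pathway status
#'
#' Precedence: a structural TP53 rearrangement dominates, then TP53
#' snv/indel, then MDM2 amplification; samples with none of these (or
#' absent from the records) are `"none"`.
#'
#' @param records classified aberration records (see
#'   [classify_aberration()]) with `sample` and `gene` columns.
#' @param samples full cohort sample ids (so unaffected samples are
#'   counted); defaults to the samples present in `records`.
#' @return data.frame `sample`, `status` with status in
#'   `TP53-rearranged`, `TP53-mutated`, `MDM2-amplified`, `none`.
#' @export
pathway_status <- function(records, samples = NULL) {
  if (is.null(samples)) samples <- unique(records$sample)
  status <- vapply(samples, function(s) {
    rs <- records[records$sample == s, , drop = FALSE]
    if (nrow(rs) == 0) return("none")
    if (any(rs$gene == "TP53" & rs$class == "rearrangement"))
      return("TP53-rearranged")
    if (any(rs$gene == "TP53" & rs$class %in% c("snv", "indel")))
      return("TP53-mutated")
    if (any(rs$gene == "MDM2" & rs$class == "amplification"))
      return("MDM2-amplified")
    "none"
  }, character(1))
  data.frame(sample = samples, status = unname(status))
}

#' Cohort frequencies of p53-inactivation mechanisms
#'
#' @param labels per-sample mechanism labels; accepts the
#'   [pathway_status()] statuses or raw mechanism names
#'   (`rearrangement`, `mutation`/`snv`, `indel`,
#'   `mdm2_amplification`/`amplification`). Unlisted cohort members are
#'   covered by `n_samples`.
#' @param n_samples cohort size (default `length(labels)`).
#' @return named integer percentages (`rearrangement`, `mutation_indel`,
#'   `mdm2_amplification`, `none`), each rounded to whole percent; they
#'   sum to 100 +- rounding.
#' @export
cohort_frequencies <- function(labels, n_samples = length(labels)) {
  stopifnot(n_samples >= length(labels))
  map <- function(x) {
    x <- tolower(x)
    ifelse(grepl("rearrang", x), "rearrangement",
    ifelse(grepl("mutat|snv|indel", x), "mutation_indel",
    ifelse(grepl("ampl", x), "mdm2_amplification", "none")))
  }
  m <- map(labels)
  counts <- c(rearrangement = sum(m == "rearrangement"),
              mutation_indel = sum(m == "mutation_indel"),
              mdm2_amplification = sum(m == "mdm2_amplification"))
  counts <- c(counts, none = n_samples - sum(counts))
  round(100 * counts / n_samples)
}

#' Wild-type allele-fraction statistics
#'
#' Min, median and max of the known wild-type allele fractions, one per
#' sample (continuation rows without a value are ignored). Even counts
#' take the mean of the central pair.
#'
#' @param records data.frame with `sample` and `wt_af` columns.
#' @return list `min`, `median`, `max`, `n`; all `NA` with a flag when no
#'   fractions are known.
#' @export
wt_allele_stats <- function(records) {
  per_sample <- tapply(records$wt_af, records$sample,
                       function(v) v[!is.na(v)][1])
  v <- unname(per_sample[!is.na(per_sample)])
  if (length(v) == 0)
    return(list(min = NA_real_, median = NA_real_, max = NA_real_, n = 0,
                degenerate = TRUE))
  list(min = min(v), median = stats::median(v), max = max(v),
       n = length(v), degenerate = FALSE)
}

#' Intron hotspot detection
#'
#' Counts distinct samples with an intragenic breakpoint per intron
#' (samples with several events in one intron count once) and flags
#' introns reaching `hotspot_min` samples; the maximal count is labelled
#' the hotspot.
#'
#' @param records data.frame with `sample` and either an `intron` column
#'   or a `position` column containing "Intron N" descriptors.
#' @param hotspot_min minimum samples for a hotspot flag (default 2).
#' @return data.frame `intron`, `samples`, `hotspot`, `top`.
#' @export
hotspot_detection <- function(records, hotspot_min = 2L) {
  if (!"sample" %in% names(records) && "cell_line" %in% names(records))
    records$sample <- records$cell_line
  if (!"intron" %in% names(records) && "tp53_intron" %in% names(records))
    records$intron <- records$tp53_intron
  if (!"intron" %in% names(records)) {
    pos <- records$position %||% character(0)
    m <- regmatches(pos, regexec("[Ii]ntron ?([0-9]+)", pos))
    records$intron <- vapply(m, function(x)
      if (length(x) >= 2) as.integer(x[2]) else NA_integer_, integer(1))
  }
  rec <- records[!is.na(records$intron), , drop = FALSE]
  if (nrow(rec) == 0)
    return(data.frame(intron = integer(), samples = integer(),
                      hotspot = logical(), top = logical()))
  counts <- tapply(rec$sample, rec$intron,
                   function(s) length(unique(s)))
  out <- data.frame(intron = as.integer(names(counts)),
                    samples = as.integer(counts))
  out <- out[order(-out$samples, out$intron), ]
  out$hotspot <- out$samples >= hotspot_min
  out$top <- seq_len(nrow(out)) == 1 & out$hotspot
  rownames(out) <- NULL
  out
}

#' Protein consequence of a truncating aberration
#'
#' Given the retained amino-acid interval, reports how many residues are
#' lost and which domains are lost (disjoint from the retained interval)
#' or disrupted (partially overlapping).
#'
#' @param annotation list with `protein_length` and `domains`
#'   (`domain`, `start_aa`, `end_aa`), e.g. [load_tp53_domains()].
#' @param retained length-2 integer vector `c(start_aa, end_aa)` of the
#'   retained interval (1-based, inclusive).
#' @return list `lost_aa`, `lost` (domain names), `disrupted`.
#' @export
protein_consequence <- function(annotation, retained) {
  plen <- annotation$protein_length
  stopifnot(length(retained) == 2, retained[1] >= 1,
            retained[2] <= plen, retained[1] <= retained[2])
  lost_aa <- plen - (retained[2] - retained[1] + 1L)
  d <- annotation$domains
  overlap_lo <- pmax(d$start_aa, retained[1])
  overlap_hi <- pmin(d$end_aa, retained[2])
  ov <- pmax(0L, overlap_hi - overlap_lo + 1L)
  dlen <- d$end_aa - d$start_aa + 1L
  list(lost_aa = as.integer(lost_aa),
       lost = d$domain[ov == 0],
       disrupted = d$domain[ov > 0 & ov < dlen])
}

#' Validation rate of a candidate panel
#'
#' Fraction of tested candidates confirmed by Sanger sequencing, as a
#' whole percent.
#'
#' @param panel data.frame with a `sanger` column (`"+"` confirmed).
#' @return integer percent.
#' @export
validation_rate <- function(panel) {
  if (nrow(panel) == 0) stop("no candidates tested")
  round(100 * sum(panel$sanger == "+") / nrow(panel))
}

#' Recurrence frequency across cohorts
#'
#' Positives over the union of the screened cohorts, as a whole percent.
#' Cohorts given as id vectors are deduplicated by set union; numeric
#' cohort sizes are summed (assumed disjoint).
#'
#' @param positives ids (or count) of positive samples.
#' @param cohorts list of sample-id vectors, or numeric sizes.
#' @return integer percent.
#' @export
recurrence_frequency <- function(positives, cohorts) {
  total <- if (is.numeric(cohorts)) sum(cohorts)
           else length(unique(unlist(cohorts)))
  npos <- if (is.numeric(positives) && length(positives) == 1) positives
          else length(unique(positives))
  if (total == 0) stop("empty cohorts")
  round(100 * npos / total)
}
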