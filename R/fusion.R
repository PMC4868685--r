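#' Fusion filter configuration
#'
#' @param min_spanning,min_split minimum read support (defaults 8 / 3).
#' @param context_window junction context window in bp (even, default 200).
#' @param complexity_threshold minimum dinucleotide Shannon entropy of the
#'   junction context, bits per symbol (default 1.5; uniform random
#'   200-mers score close to 4 bits and pass at > 99.9%).
#' @param repeat_coverage_max maximum fraction of the window a single
#'   exact tandem repeat may cover (default 0.5).
#' @param normal_panel character vector of order-sensitive
#'   `"GENE5>GENE3"` keys observed in normal tissues.
#' @return named list of settings.
#' @export
fusion_filter_config <- function(min_spanning = 8L, min_split = 3L,
                                 context_window = 200L,
                                 complexity_threshold = 1.5,
                                 repeat_coverage_max = 0.5,
                                 normal_panel = character(0)) {
  stopifnot(min_spanning >= 0, min_split >= 0, context_window %% 2 == 0)
  list(min_spanning = min_spanning, min_split = min_split,
       context_window = context_window,
       complexity_threshold = complexity_threshold,
       repeat_coverage_max = repeat_coverage_max,
       normal_panel = normal_panel)
}

.fusion_key <- function(g5, g3) paste0(g5, ">", g3)

#' Merge fusion calls from two callers
#'
#' Fusions are keyed by (gene5, gene3) with junction coordinates matched
#' within `tolerance_bp`; matched pairs collapse to one record with
#' provenance `"both"` (coordinates and read support taken from caller A),
#' the rest keep provenance `"A"` or `"B"`.
#'
#' @param calls_a,calls_b fusion data.frames.
#' @param tolerance_bp coordinate tolerance (default 10).
#' @return unioned fusion data.frame with a `provenance` column.
#' @export
merge_caller_outputs <- function(calls_a, calls_b, tolerance_bp = 10L) {
  calls_a$provenance <- "A"; calls_b$provenance <- "B"
  if (nrow(calls_a) == 0) return(calls_b)
  if (nrow(calls_b) == 0) return(calls_a)
  used_b <- rep(FALSE, nrow(calls_b))
  for (i in seq_len(nrow(calls_a))) {
    j <- which(!used_b &
               calls_b$gene5 == calls_a$gene5[i] &
               calls_b$gene3 == calls_a$gene3[i] &
               abs(calls_b$pos5 - calls_a$pos5[i]) <= tolerance_bp &
               abs(calls_b$pos3 - calls_a$pos3[i]) <= tolerance_bp)
    if (length(j) > 0) {
      used_b[j[1]] <- TRUE
      calls_a$provenance[i] <- "both"
    }
  }
  rbind(calls_a, calls_b[!used_b, , drop = FALSE])
}

#' Remove fusions seen in the normal-tissue panel
#'
#' Matching is order-sensitive on (gene5, gene3): chimeric transcripts are
#' directional, so the reciprocal pair is kept unless itself listed.
#'
#' @param fusions fusion data.frame.
#' @param panel character vector of `"GENE5>GENE3"` keys.
#' @return subset of `fusions`.
#' @export
normal_panel_filter <- function(fusions, panel) {
  if (nrow(fusions) == 0 || length(panel) == 0) return(fusions)
  keep <- !(.fusion_key(fusions$gene5, fusions$gene3) %in% panel)
  fusions[keep, , drop = FALSE]
}

#' Shannon entropy of a sequence over overlapping dinucleotides
#'
#' @param context DNA string.
#' @return entropy in bits per dinucleotide symbol (max 4 bits).
#' @export
junction_entropy <- function(context) {
  n <- nchar(context)
  if (n < 2) return(0)
  di <- substring(context, 1:(n - 1), 2:n)
  p <- table(di) / (n - 1)
  -sum(p * log2(p))
}

#' Fraction of a window covered by its longest exact tandem repeat
#'
#' Scans periods 1..`max_period` for the longest run where each base
#' equals the base `p` positions earlier; the repeat tract length is run
#' + period.
#'
#' @param context DNA string.
#' @param max_period largest repeat unit considered (default 8).
#' @return covered fraction in `[0, 1]`.
#' @export
tandem_repeat_coverage <- function(context, max_period = 8L) {
  n <- nchar(context)
  if (n < 2) return(0)
  x <- utf8ToInt(context)
  best <- 0L
  for (p in seq_len(min(max_period, n - 1))) {
    eq <- x[(p + 1):n] == x[1:(n - p)]
    r <- rle(eq)
    runs <- r$lengths[r$values]
    if (length(runs) > 0) best <- max(best, max(runs) + p)
  }
  best / n
}

#' Remove fusions with low-complexity or repetitive junction context
#'
#' A fusion is removed when the dinucleotide Shannon entropy of its
#' junction context falls below `complexity_threshold` OR the longest
#' exact tandem repeat covers more than `repeat_coverage_max` of the
#' window. Contexts shorter than the configured window are evaluated on
#' the available bases and flagged in the `context_truncated` column.
#'
#' @param fusions fusion data.frame with a `context` column.
#' @param config a [fusion_filter_config()] list.
#' @return subset of `fusions`.
#' @export
junction_complexity_filter <- function(fusions,
                                       config = fusion_filter_config()) {
  if (nrow(fusions) == 0) return(fusions)
  ent <- vapply(fusions$context, junction_entropy, numeric(1),
                USE.NAMES = FALSE)
  rep_cov <- vapply(fusions$context, tandem_repeat_coverage, numeric(1),
                    USE.NAMES = FALSE)
  fusions$context_truncated <- nchar(fusions$context) < config$context_window
  keep <- ent >= config$complexity_threshold &
    rep_cov <= config$repeat_coverage_max
  fusions[keep, , drop = FALSE]
}

#' Remove fusions with insufficient read support
#'
#' Kept iff `spanning >= min_spanning` and `split >= min_split`.
#'
#' @inheritParams junction_complexity_filter
#' @return subset of `fusions`.
#' @export
read_support_filter <- function(fusions, config = fusion_filter_config()) {
  if (nrow(fusions) == 0) return(fusions)
  keep <- fusions$spanning >= config$min_spanning &
    fusions$split >= config$min_split
  fusions[keep, , drop = FALSE]
}

#' Full fusion filter cascade
#'
#' Applies the read-support, normal-panel and junction-complexity filters;
#' the filters are independent predicates, so the output does not depend
#' on their order.
#'
#' @inheritParams junction_complexity_filter
#' @return filtered fusion data.frame.
#' @export
filter_fusions <- function(fusions, config = fusion_filter_config()) {
  fusions <- read_support_filter(fusions, config)
  fusions <- normal_panel_filter(fusions, config$normal_panel)
  junction_complexity_filter(fusions, config)
}

# Orientation a breakend must have to contribute the 5' (upstream) or 3'
# (downstream) part of a collinear chimera from a gene on this strand.
.required_orient <- function(strand, side) {
  if (side == "5") { if (strand == "+") "tail" else "head" }
  else             { if (strand == "+") "head" else "tail" }
}

# Does breakend (chrom,pos,orient) support gene g contributing `side`?
# When the fused exon index is known, the breakend must also lie past the
# last retained exon (5' side) / before the first retained exon (3' side).
.breakend_supports <- function(chrom, pos, orient, grow, side, models,
                               exon = NA) {
  if (chrom != grow$chrom || pos < grow$start || pos >= grow$end)
    return(FALSE)
  if (orient != .required_orient(grow$strand, side)) return(FALSE)
  if (!is.na(exon)) {
    ex <- models$exons[models$exons$gene_id == grow$gene_id, ]
    ex <- ex[order(ex$start), ]
    # exon numbers are in genomic order for the simulator's models
    if (side == "5" && grow$strand == "+" && pos < ex$end[exon]) return(FALSE)
    if (side == "5" && grow$strand == "-" && pos >= ex$start[nrow(ex) - exon + 1])
      return(FALSE)
    if (side == "3" && grow$strand == "+" && pos >= ex$start[exon]) return(FALSE)
    if (side == "3" && grow$strand == "-" && pos < ex$end[nrow(ex) - exon + 1])
      return(FALSE)
  }
  TRUE
}

.gene_distance <- function(g1, g2) {
  if (g1$chrom != g2$chrom) return(Inf)
  max(0, max(g1$start, g2$start) - min(g1$end, g2$end))
}

#' Match a fusion transcript to an underlying genomic rearrangement
#'
#' `genomic-direct` when some rearrangement has one breakend in the 5'
#' partner's gene body oriented to retain its upstream part and the other
#' breakend in the 3' partner's body oriented to retain its downstream
#' part (a collinear 5'->3' chimera); `genomic-read-through` when the
#' breakend instead falls in a neighboring gene (within
#' `read_through_bp`, same strand) of a partner; otherwise
#' `unsupported`. Partner genes absent from the models give
#' `unsupported` with a warning.
#'
#' @param fusion one-row fusion data.frame.
#' @param rearrangements rearrangement data.frame.
#' @param models a [gene_models()] object.
#' @param read_through_bp neighbor search window (default 1 Mb).
#' @return `ConcordanceResult` list: `id`, `status`, `matched`,
#'   `rationale`.
#' @export
match_fusion_to_genome <- function(fusion, rearrangements, models,
                                   read_through_bp = 1e6) {
  g5 <- models$genes[models$genes$gene_id == fusion$gene5, ]
  g3 <- models$genes[models$genes$gene_id == fusion$gene3, ]
  if (nrow(g5) == 0 || nrow(g3) == 0) {
    warning("fusion partner absent from gene models: ",
            if (nrow(g5) == 0) fusion$gene5 else fusion$gene3)
    return(list(id = fusion$id, status = "unsupported", matched = NA,
                rationale = "partner gene not in models"))
  }
  e5 <- if ("exon5" %in% names(fusion)) fusion$exon5 else NA
  e3 <- if ("exon3" %in% names(fusion)) fusion$exon3 else NA
  supports <- function(r, grow, side, exon) {
    .breakend_supports(r$chrom_a, r$pos_a, r$orient_a, grow, side, models,
                       exon) ||
    .breakend_supports(r$chrom_b, r$pos_b, r$orient_b, grow, side, models,
                       exon)
  }
  for (i in seq_len(nrow(rearrangements))) {
    r <- rearrangements[i, ]
    hit5 <- .breakend_supports(r$chrom_a, r$pos_a, r$orient_a, g5, "5",
                               models, e5)
    hit3 <- .breakend_supports(r$chrom_b, r$pos_b, r$orient_b, g3, "3",
                               models, e3)
    hit5r <- .breakend_supports(r$chrom_b, r$pos_b, r$orient_b, g5, "5",
                                models, e5)
    hit3r <- .breakend_supports(r$chrom_a, r$pos_a, r$orient_a, g3, "3",
                                models, e3)
    if ((hit5 && hit3) || (hit5r && hit3r))
      return(list(id = fusion$id, status = "genomic-direct",
                  matched = r$id,
                  rationale = "breakends in both partner bodies, collinear"))
  }
  # read-through: one partner matched directly, the other via a same-strand
  # neighbor gene within the window
  neighbors_of <- function(grow) {
    cand <- models$genes[models$genes$chrom == grow$chrom &
                         models$genes$strand == grow$strand &
                         models$genes$gene_id != grow$gene_id, , drop = FALSE]
    if (nrow(cand) == 0) return(cand)
    d <- vapply(seq_len(nrow(cand)), function(k)
      .gene_distance(grow, cand[k, ]), numeric(1))
    cand[d <= read_through_bp, , drop = FALSE]
  }
  nb3 <- neighbors_of(g3); nb5 <- neighbors_of(g5)
  for (i in seq_len(nrow(rearrangements))) {
    r <- rearrangements[i, ]
    if (supports(r, g5, "5", NA)) {
      for (k in seq_len(nrow(nb3)))
        if (supports(r, nb3[k, ], "3", NA))
          return(list(id = fusion$id, status = "genomic-read-through",
                      matched = r$id,
                      rationale = paste0("3' breakend in neighbor gene ",
                                         nb3$gene_id[k])))
    }
    if (supports(r, g3, "3", NA)) {
      for (k in seq_len(nrow(nb5)))
        if (supports(r, nb5[k, ], "5", NA))
          return(list(id = fusion$id, status = "genomic-read-through",
                      matched = r$id,
                      rationale = paste0("5' breakend in neighbor gene ",
                                         nb5$gene_id[k])))
    }
  }
  list(id = fusion$id, status = "unsupported", matched = NA,
       rationale = "no candidate rearrangement")
}

#' RNA-DNA concordance summary per sample
#'
#' Matches every fusion to the rearrangement set and tabulates per sample
#' how many are genomically supported (direct or read-through).
#'
#' @param fusions fusion data.frame.
#' @param rearrangements rearrangement data.frame.
#' @param models a [gene_models()] object.
#' @param read_through_bp neighbor search window.
#' @return list with `results` (per-fusion `ConcordanceResult`
#'   data.frame) and `summary` (per-sample `total`, `direct`,
#'   `read_through`, `supported`, `unsupported`).
#' @export
concordance_summary <- function(fusions, rearrangements, models,
                                read_through_bp = 1e6) {
  res <- lapply(seq_len(nrow(fusions)), function(i)
    match_fusion_to_genome(fusions[i, ], rearrangements, models,
                           read_through_bp))
  rdf <- data.frame(id = vapply(res, `[[`, "", "id"),
                    sample = fusions$sample,
                    status = vapply(res, `[[`, "", "status"),
                    matched = vapply(res, function(x)
                      as.character(x$matched %||% NA), ""),
                    rationale = vapply(res, `[[`, "", "rationale"))
  summ <- do.call(rbind, lapply(split(rdf, rdf$sample), function(sx)
    data.frame(sample = sx$sample[1], total = nrow(sx),
               direct = sum(sx$status == "genomic-direct"),
               read_through = sum(sx$status == "genomic-read-through"),
               supported = sum(sx$status != "unsupported"),
               unsupported = sum(sx$status == "unsupported"))))
  rownames(summ) <- NULL
  list(results = rdf, summary = summ)
}

#' Expression enrichment of fusion partner genes
#'
#' Two-sided Wilcoxon rank-sum test comparing the abundance of the
#' distinct fusion-partner genes against all other genes in the
#' expression table.
#'
#' @param fusions fusion data.frame (one sample).
#' @param expression expression data.frame (`gene_id` + sample columns).
#' @param sample expression column to use (default: first).
#' @return list `p_value`, `n_partners`, `median_partner`,
#'   `median_other`; p is `NA` with a flag when fewer than 3 partner
#'   genes are present.
#' @export
partner_expression_enrichment <- function(fusions, expression,
                                          sample = NULL) {
  col <- sample %||% setdiff(names(expression), "gene_id")[1]
  partners <- unique(c(fusions$gene5, fusions$gene3))
  partners <- intersect(partners, expression$gene_id)
  if (length(partners) < 3)
    return(list(p_value = NA_real_, n_partners = length(partners),
                median_partner = NA_real_, median_other = NA_real_,
                degenerate = TRUE))
  x <- expression[[col]][match(partners, expression$gene_id)]
  y <- expression[[col]][!(expression$gene_id %in% partners)]
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
  list(p_value = wt$p.value, n_partners = length(partners),
       median_partner = stats::median(x), median_other = stats::median(y),
       degenerate = FALSE)
}
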