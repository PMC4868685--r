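#' Read-support and allele-fraction thresholds for SV calls
#'
#' Defaults are the standard stringency for short-read SV calling in this
#' kind of analysis: at least 8 spanning and 3 split (breakpoint-covering)
#' reads, allele fraction >= 10% measured from concordant reads in a
#' 500-bp window around the breakpoint.
#'
#' @param min_spanning,min_split minimum read support.
#' @param min_allele_fraction minimum allele fraction (inclusive).
#' @param af_window_bp window used when counting concordant reads.
#' @return a named list of thresholds.
#' @export
filter_thresholds <- function(min_spanning = 8L, min_split = 3L,
                              min_allele_fraction = 0.10,
                              af_window_bp = 500L) {
  stopifnot(min_spanning >= 0, min_split >= 0,
            min_allele_fraction >= 0, min_allele_fraction <= 1,
            af_window_bp > 0)
  list(min_spanning = min_spanning, min_split = min_split,
       min_allele_fraction = min_allele_fraction,
       af_window_bp = af_window_bp)
}

#' Filter SV calls on read support
#'
#' Keeps calls with `spanning >= min_spanning` AND `split >= min_split`;
#' order is preserved and the operation is idempotent.
#'
#' @param calls rearrangement data.frame.
#' @param thresholds a [filter_thresholds()] list.
#' @return subset of `calls`.
#' @export
filter_sv_calls <- function(calls, thresholds = filter_thresholds()) {
  if (nrow(calls) == 0) return(calls)
  keep <- calls$spanning >= thresholds$min_spanning &
    calls$split >= thresholds$min_split
  keep[is.na(keep)] <- FALSE
  calls[keep, , drop = FALSE]
}

#' Allele fraction of a rearrangement from read counts
#'
#' AF = S / (S + C-bar), with S the supporting reads (spanning + split)
#' and C-bar the mean of the two per-breakend concordant counts. The
#' formula is symmetric in the breakends and reduces to the read fraction
#' at a single junction. Scale-invariant: multiplying all counts by k
#' leaves the AF unchanged.
#'
#' @param calls rearrangement data.frame (vectorized).
#' @param concordant_stat `"mean"` (default) or `"sum"` across breakends.
#' @return numeric vector in `[0, 1]`; `NA` (flagged, not 0) where
#'   S + C-bar = 0.
#' @export
allele_frequency <- function(calls, concordant_stat = c("mean", "sum")) {
  concordant_stat <- match.arg(concordant_stat)
  s <- calls$spanning + calls$split
  cbar <- if (concordant_stat == "mean")
    (calls$concordant_a + calls$concordant_b) / 2
  else calls$concordant_a + calls$concordant_b
  af <- ifelse(s + cbar > 0, s / (s + cbar), NA_real_)
  af
}

#' Filter SV calls on allele fraction
#'
#' Keeps calls with AF >= `min_af` (inclusive). Calls with undefined AF
#' are dropped unless `min_af == 0`.
#'
#' @param calls rearrangement data.frame.
#' @param min_af minimum allele fraction.
#' @inheritParams allele_frequency
#' @return subset of `calls`.
#' @export
af_filter <- function(calls, min_af = 0.10,
                      concordant_stat = c("mean", "sum")) {
  if (nrow(calls) == 0) return(calls)
  if (min_af == 0) return(calls)
  af <- allele_frequency(calls, concordant_stat)
  keep <- !is.na(af) & af >= min_af
  calls[keep, , drop = FALSE]
}

#' Classify breakpoints relative to genes and their expression
#'
#' Each breakend overlaps a gene when its position lies in the gene body
#' `[start, end)` (half-open containment, so a breakend exactly at a
#' gene's start coordinate is intragenic). Per rearrangement the category
#' is intergenic-both / intragenic-one / intragenic-both; rearrangements
#' with at least one intragenic side additionally get an expression
#' category (none / one / both sides in an expressed gene).
#'
#' @param calls rearrangement data.frame.
#' @param models a [gene_models()] object.
#' @param expression expression data.frame (`gene_id` + one column per
#'   sample) or `NULL`; genes missing from the table are treated as not
#'   expressed.
#' @param sample column of `expression` to use; defaults to the calls'
#'   sample.
#' @param expressed_threshold abundance above which a gene counts as
#'   expressed (default 1 FPKM-equivalent).
#' @param fusions optional fusion data.frame used to set the
#'   `yields_fusion` flag (gene pair matched in either orientation).
#' @return list with `classes` (per-call data.frame: `gene_a`, `gene_b`,
#'   `category`, `expression_category`, `yields_fusion`) and `fractions`
#'   (named fractions over both partitions; each partition sums to 1).
#' @export
classify_breakpoints <- function(calls, models, expression = NULL,
                                 sample = NULL, expressed_threshold = 1,
                                 fusions = NULL) {
  n <- nrow(calls)
  expr_of <- function(gene) {
    if (is.null(expression) || length(gene) == 0) return(FALSE)
    i <- match(gene, expression$gene_id)
    if (is.na(i)) return(FALSE)
    col <- sample %||% setdiff(names(expression), "gene_id")[1]
    isTRUE(expression[[col]][i] > expressed_threshold)
  }
  gene_a <- character(n); gene_b <- character(n)
  category <- character(n); expr_cat <- rep(NA_character_, n)
  yields <- logical(n)
  for (i in seq_len(n)) {
    ga <- .genes_at(models, calls$chrom_a[i], calls$pos_a[i])
    gb <- .genes_at(models, calls$chrom_b[i], calls$pos_b[i])
    gene_a[i] <- if (length(ga)) ga[1] else NA_character_
    gene_b[i] <- if (length(gb)) gb[1] else NA_character_
    n_in <- (length(ga) > 0) + (length(gb) > 0)
    category[i] <- c("intergenic-both", "intragenic-one",
                     "intragenic-both")[n_in + 1L]
    if (n_in > 0) {
      n_expr <- 0L
      if (length(ga) && expr_of(ga[1])) n_expr <- n_expr + 1L
      if (length(gb) && expr_of(gb[1])) n_expr <- n_expr + 1L
      expr_cat[i] <- c("none-expressed", "one-expressed",
                       "both-expressed")[n_expr + 1L]
    }
    if (!is.null(fusions) && n_in == 2) {
      hit <- (fusions$gene5 == ga[1] & fusions$gene3 == gb[1]) |
             (fusions$gene5 == gb[1] & fusions$gene3 == ga[1])
      yields[i] <- any(hit)
    }
  }
  classes <- data.frame(id = calls$id, gene_a = gene_a, gene_b = gene_b,
                        category = category,
                        expression_category = expr_cat,
                        yields_fusion = yields)
  gene_part <- prop.table(table(factor(category,
    levels = c("intergenic-both", "intragenic-one", "intragenic-both"))))
  has_expr <- !is.na(expr_cat)
  expr_part <- if (any(has_expr))
    prop.table(table(factor(expr_cat[has_expr],
      levels = c("none-expressed", "one-expressed", "both-expressed"))))
  else NULL
  list(classes = classes,
       fractions = list(gene = gene_part, expression = expr_part,
                        intragenic_any = mean(category != "intergenic-both")))
}

#' Fraction of the genome covered by gene bodies
#'
#' Union length of all gene bodies (overlaps counted once, via a
#' GenomicRanges reduce) divided by the total genome length.
#'
#' @param models a [gene_models()] object.
#' @param genome_lengths named vector of chromosome lengths.
#' @return fraction in `[0, 1]`.
#' @export
intragenic_genome_fraction <- function(models, genome_lengths) {
  if (nrow(models$genes) == 0) return(0)
  gr <- GenomicRanges::reduce(.genes_granges(models))
  sum(as.numeric(IRanges::width(GenomicRanges::ranges(gr)))) /
    sum(as.numeric(genome_lengths))
}
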