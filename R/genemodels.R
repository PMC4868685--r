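#' Gene model container
#'
#' Holds gene bodies and their exon structure in 0-based half-open
#' coordinates. Introns are derived as the gaps between consecutive exons.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end`.
#' @param exons data.frame with columns `gene_id`, `exon_number`
#'   (1-based, in genomic order), `start`, `end`.
#' @param domains optional data.frame of protein domains per gene:
#'   `gene_id`, `domain`, `start_aa`, `end_aa`, plus per-gene
#'   `protein_length` in `genes` when supplied.
#' @return object of class `gene_models`.
#' @export
gene_models <- function(genes, exons, domains = NULL) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)),
            all(c("gene_id", "exon_number", "start", "end") %in% names(exons)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  # exons must be sorted and non-overlapping within a gene
  by_gene <- split(exons, exons$gene_id)
  for (gx in by_gene) {
    if (nrow(gx) > 1 && any(gx$start[-1] < gx$end[-nrow(gx)]))
      stop("overlapping exons in gene ", gx$gene_id[1])
  }
  structure(list(genes = genes, exons = exons, domains = domains),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Derive intron intervals from a gene model set
#'
#' @param models a [gene_models()] object.
#' @return data.frame `gene_id`, `intron_number`, `start`, `end`
#'   (0-based half-open gaps between consecutive exons, numbered in
#'   transcription order, i.e. reversed for minus-strand genes).
#' @export
gene_introns <- function(models) {
  out <- lapply(split(models$exons, models$exons$gene_id), function(gx) {
    if (nrow(gx) < 2) return(NULL)
    gx <- gx[order(gx$start), ]
    data.frame(gene_id = gx$gene_id[1],
               intron_number = seq_len(nrow(gx) - 1L),
               start = gx$end[-nrow(gx)],
               end = gx$start[-1])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(gene_id = character(), intron_number = integer(),
                      start = integer(), end = integer()))
  strand <- models$genes$strand[match(out$gene_id, models$genes$gene_id)]
  # number introns in transcription order
  neg <- strand == "-"
  if (any(neg)) {
    for (g in unique(out$gene_id[neg])) {
      i <- which(out$gene_id == g)
      out$intron_number[i] <- rev(out$intron_number[i])
    }
  }
  rownames(out) <- NULL
  out
}

# GRanges view of gene bodies (1-based, as GenomicRanges expects).
.genes_granges <- function(models) {
  GenomicRanges::GRanges(
    seqnames = models$genes$chrom,
    ranges = IRanges::IRanges(start = models$genes$start + 1L,
                              end = models$genes$end),
    strand = models$genes$strand,
    gene_id = models$genes$gene_id)
}

# Gene(s) overlapping a 0-based position; returns gene ids (may be empty).
.genes_at <- function(models, chrom, pos) {
  hit <- models$genes$chrom == chrom &
    models$genes$start <= pos & pos < models$genes$end
  models$genes$gene_id[hit]
}
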