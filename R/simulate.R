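#' Simulate a toy reference genome and gene models
#'
#' Chromosome sequences are i.i.d. random bases at the configured GC
#' content. Genes of fixed length are tiled evenly so that gene bodies
#' cover `gene_fraction` of each chromosome (up to granularity of one
#' gene), which makes the intragenic-fraction statistic controllable.
#'
#' @param config a [sim_config()] object.
#' @return list with `reference` (named character vector of chromosome
#'   sequences) and `models` (a [gene_models()] object).
#' @export
simulate_genome <- function(config) {
  config <- validate_sim_config(config)
  set.seed(.sub_seed(config$seed, "genome"))
  L <- config$chrom_length_bp
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  reference <- vapply(chroms, function(ch) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))

  glen <- config$gene_length_bp
  n_genes <- floor(L * config$gene_fraction / glen)
  genes <- list(); exons <- list()
  for (ci in seq_along(chroms)) {
    if (n_genes == 0) next
    gap <- (L - n_genes * glen) / (n_genes + 1)
    starts <- round(gap + (seq_len(n_genes) - 1L) * (glen + gap))
    ids <- sprintf("g%s_%03d", sub("chr", "", chroms[ci]), seq_len(n_genes))
    genes[[ci]] <- data.frame(gene_id = ids, chrom = chroms[ci],
                              strand = rep(c("+", "-"), length.out = n_genes),
                              start = as.integer(starts),
                              end = as.integer(starts + glen))
    ne <- config$exons_per_gene
    piece <- glen %/% (2L * ne - 1L)
    exons[[ci]] <- do.call(rbind, lapply(seq_len(n_genes), function(gi) {
      es <- starts[gi] + (seq_len(ne) - 1L) * 2L * piece
      ee <- es + piece
      ee[ne] <- starts[gi] + glen   # last exon absorbs the remainder
      data.frame(gene_id = ids[gi], exon_number = seq_len(ne),
                 start = as.integer(es), end = as.integer(ee))
    }))
  }
  models <- gene_models(do.call(rbind, genes), do.call(rbind, exons))
  list(reference = reference, models = models)
}

.DIFF_BASE <- c(A = "C", C = "G", G = "T", T = "A", N = "A")

#' Plant a rearrangement junction with an exact microhomology length
#'
#' Copies `mh_len` flank bases across the junction so that the measured
#' junction ambiguity is exactly `mh_len`, then forces mismatches at both
#' extension points so the homology cannot accidentally extend (the
#' round-trip guarantee). Orientations follow the SV type's standard join
#' semantics; inversion-type joins plant homology through the
#' reverse-complement path.
#'
#' @param reference named character vector (or split list) of chromosome
#'   sequences; the modified reference is returned.
#' @param sv_type one of `"DEL"`, `"DUP"`, `"INV"`, `"TRA"`.
#' @param chrom_a,pos_a,chrom_b,pos_b 0-based breakend positions. For
#'   intrachromosomal types `pos_a < pos_b` is required.
#' @param mh_len microhomology length to plant, 0-25 bp.
#' @param id,sample identifiers carried into the returned call record.
#' @param inv_side which inversion join to emit (`"tail"` = tail-tail,
#'   `"head"` = head-head).
#' @param orientations optional length-2 override of the breakend
#'   orientations (only meaningful for TRA, whose four join classes are
#'   all legal).
#' @return list with `reference`, `call` (one-row rearrangement
#'   data.frame, evidence counts NA) and `truth` (one-row truth record).
#' @export
plant_rearrangement <- function(reference, sv_type, chrom_a, pos_a,
                                chrom_b, pos_b, mh_len, id = "sv1",
                                sample = "SIM1", inv_side = "tail",
                                orientations = NULL) {
  if (mh_len < 0 || mh_len > 25)
    stop("mh_len outside the 0-25 bp category system")
  sv_type <- match.arg(sv_type, c("DEL", "DUP", "INV", "TRA"))
  if (sv_type == "TRA" && chrom_a == chrom_b)
    stop("TRA requires different chromosomes")
  if (sv_type != "TRA") {
    if (chrom_a != chrom_b) stop(sv_type, " requires one chromosome")
    if (pos_a >= pos_b) stop("pos_a < pos_b required for ", sv_type)
    if (pos_b - pos_a < 2L * (mh_len + 2L))
      stop("breakends too close to plant ", mh_len, " bp of homology")
  }
  for (bx in list(c(chrom_a, pos_a), c(chrom_b, pos_b))) {
    len <- .seq_nchar(reference, bx[1])
    p <- as.numeric(bx[2])
    if (p < max(2 * mh_len, 30) || p > len - max(2 * mh_len, 30))
      stop("breakend too close to a chromosome end")
  }
  or <- orientations %||% sv_type_orientations(sv_type, inv_side)
  if (sv_type != "TRA" &&
      !identical(unname(or), sv_type_orientations(sv_type, "tail")) &&
      !identical(unname(or), sv_type_orientations(sv_type, "head")))
    stop("orientations inconsistent with sv_type ", sv_type)
  k <- as.integer(mh_len)
  s <- k + 1L
  out_a_w <- .junction_window(pos_a, or[1], "left", "outside", s)
  in_b_w  <- .junction_window(pos_b, or[2], "right", "inside", s)
  o <- .extract_jf(reference, chrom_a, out_a_w)$seq
  if (k > 0) {
    for (i in seq_len(k))
      reference <- .write_jf(reference, chrom_b, in_b_w, i,
                             substr(o, i, i))
  }
  reference <- .write_jf(reference, chrom_b, in_b_w, s,
                         unname(.DIFF_BASE[substr(o, s, s)]))
  # force left-shift ambiguity to zero
  ia <- .extract_jf(reference, chrom_a,
                    .junction_window(pos_a, or[1], "left", "inside", 1L))$seq
  ob_w <- .junction_window(pos_b, or[2], "right", "outside", 1L)
  reference <- .write_jf(reference, chrom_b, ob_w, 1L,
                         unname(.DIFF_BASE[ia]))
  call <- data.frame(id = id, sample = sample, sv_type = sv_type,
                     chrom_a = chrom_a, pos_a = as.integer(pos_a),
                     orient_a = or[1],
                     chrom_b = chrom_b, pos_b = as.integer(pos_b),
                     orient_b = or[2],
                     spanning = NA_integer_, split = NA_integer_,
                     concordant_a = NA_integer_, concordant_b = NA_integer_,
                     mh_len = k)
  truth <- data.frame(id = id, mh_len = k,
                      allele_fraction = NA_real_,
                      cluster = NA_character_,
                      genomically_supported = TRUE)
  list(reference = reference, call = call, truth = truth)
}

#' Simulate junction read evidence for given depth and allele fraction
#'
#' Per-breakend window totals are Poisson with the given mean depth; reads
#' at the junction split binomially between the rearranged and the
#' reference allele, so the allele-frequency estimator
#' S / (S + mean(concordant)) is unbiased up to ratio-estimator terms.
#'
#' @param depth mean read pairs per 500-bp breakend window.
#' @param allele_fraction vector of planted allele fractions in `[0, 1]`.
#' @param span_share fraction of supporting reads counted as spanning
#'   (the rest are split reads).
#' @return data.frame with columns `spanning`, `split`, `concordant_a`,
#'   `concordant_b` (one row per element of `allele_fraction`).
#' @export
simulate_read_evidence <- function(depth, allele_fraction,
                                   span_share = 0.7) {
  stopifnot(depth > 0, all(allele_fraction >= 0 & allele_fraction <= 1))
  n <- length(allele_fraction)
  n_a <- stats::rpois(n, depth)
  n_b <- stats::rpois(n, depth)
  total <- round((n_a + n_b) / 2)
  s <- stats::rbinom(n, total, allele_fraction)
  spanning <- stats::rbinom(n, s, span_share)
  data.frame(spanning = spanning, split = s - spanning,
             concordant_a = stats::rbinom(n, n_a, 1 - allele_fraction),
             concordant_b = stats::rbinom(n, n_b, 1 - allele_fraction))
}

# Sample breakpoint positions on one chromosome, a fraction of them inside
# the chromosome's single cluster window, all pairwise separated by at
# least min_sep (so planted junctions cannot interfere).
.sample_positions <- function(existing, n, chrom_len, clustered,
                              cluster_window, min_sep = 80L,
                              margin = 60L) {
  pos <- integer(0)
  all_pos <- existing
  tries <- 0L
  while (length(pos) < n) {
    cl <- clustered[length(pos) + 1L]
    cand <- if (isTRUE(cl)) {
      round(stats::runif(1, cluster_window[1], cluster_window[2]))
    } else {
      round(stats::runif(1, margin, chrom_len - margin))
    }
    if (length(all_pos) == 0L || min(abs(all_pos - cand)) >= min_sep) {
      pos <- c(pos, cand)
      all_pos <- c(all_pos, cand)
    }
    tries <- tries + 1L
    if (tries > 200L * max(n, 1L))
      stop("could not place breakpoints with the required separation")
  }
  pos
}

#' Simulate a rearrangement truth set on a toy genome
#'
#' Plants `sv_counts` junctions with microhomology lengths drawn from the
#' per-stratum category mixtures, places a `clustered_fraction` of
#' breakpoints inside one cluster window per chromosome (the
#' chromothripsis-like alternative; the rest are uniform genome-wide),
#' draws planted allele fractions uniformly from `allele_fraction_range`
#' and attaches simulated read evidence.
#'
#' @param genome output of [simulate_genome()] (or any list with a
#'   `reference` element).
#' @param config a [sim_config()] object.
#' @param sample sample identifier for the emitted calls.
#' @return list with `reference` (modified), `calls` (rearrangement
#'   data.frame) and `truth` (planted microhomology, allele fraction and
#'   cluster assignment per call).
#' @export
simulate_rearrangements <- function(genome, config, sample = "SIM1") {
  config <- validate_sim_config(config)
  set.seed(.sub_seed(config$seed, "sv"))
  ref <- .ref_split(genome$reference)
  chroms <- names(ref)
  lens <- vapply(chroms, function(ch) length(ref[[ch]]), integer(1))
  windows <- lapply(chroms, function(ch) {
    w <- min(config$cluster_width_bp, lens[[ch]] - 500L)
    center <- round(stats::runif(1, w / 2 + 100, lens[[ch]] - w / 2 - 100))
    c(center - w / 2, center + w / 2)
  })
  names(windows) <- chroms

  draw_mh <- function(stratum) {
    p <- config$microhomology_mixture[[stratum]]
    cat3 <- sample(c("none", "short", "long"), 1, prob = p)
    switch(cat3, none = 0L, short = sample(1:5, 1), long = sample(6:25, 1))
  }
  placed <- stats::setNames(lapply(chroms, function(x) integer(0)), chroms)
  calls <- list(); truths <- list()
  idn <- 0L
  types <- rep(names(config$sv_counts), times = config$sv_counts)
  for (tp in types) {
    idn <- idn + 1L
    id <- sprintf("sv%04d", idn)
    if (tp == "TRA") {
      cab <- sample(chroms, 2)
      cl <- stats::runif(2) < config$clustered_fraction
      pa <- .sample_positions(placed[[cab[1]]], 1, lens[[cab[1]]],
                              cl[1], windows[[cab[1]]])
      pb <- .sample_positions(placed[[cab[2]]], 1, lens[[cab[2]]],
                              cl[2], windows[[cab[2]]])
      placed[[cab[1]]] <- c(placed[[cab[1]]], pa)
      placed[[cab[2]]] <- c(placed[[cab[2]]], pb)
      mh <- draw_mh("other")
      pl <- plant_rearrangement(ref, "TRA", cab[1], pa, cab[2], pb, mh,
                                id = id, sample = sample,
                                orientations = sample(c("tail", "head"), 2,
                                                      replace = TRUE))
      clust <- if (any(cl)) paste0("cluster_", cab[which(cl)[1]]) else NA
    } else {
      ch <- sample(chroms, 1)
      size <- round(10^stats::runif(1, log10(200), log10(40000)))
      cl <- stats::runif(1) < config$clustered_fraction
      repeat {
        pa <- .sample_positions(placed[[ch]], 1, lens[[ch]] - size - 100,
                                cl, windows[[ch]])
        if (pa + size <= lens[[ch]] - 100) break
      }
      pb <- pa + size
      if (length(placed[[ch]]) && min(abs(placed[[ch]] - pb)) < 80) next
      placed[[ch]] <- c(placed[[ch]], pa, pb)
      stratum <- if (tp != "DEL") "other"
        else if (size < 5000) "del_lt5kb"
        else if (size < 10000) "del_5to10kb" else "del_ge10kb"
      mh <- draw_mh(stratum)
      pl <- plant_rearrangement(ref, tp, ch, pa, ch, pb, mh,
                                id = id, sample = sample,
                                inv_side = sample(c("tail", "head"), 1))
      clust <- if (cl) paste0("cluster_", ch) else NA
    }
    ref <- pl$reference
    af <- stats::runif(1, config$allele_fraction_range[1],
                       config$allele_fraction_range[2])
    ev <- simulate_read_evidence(config$depth, af)
    pl$call[c("spanning", "split", "concordant_a", "concordant_b")] <-
      ev[1, ]
    pl$truth$allele_fraction <- af
    pl$truth$cluster <- clust
    calls[[length(calls) + 1L]] <- pl$call
    truths[[length(truths) + 1L]] <- pl$truth
  }
  list(reference = .ref_join(ref),
       calls = do.call(rbind, calls),
       truth = do.call(rbind, truths))
}

#' Simulate a windowed coverage track with optional amplified regions
#'
#' Window counts are Poisson with mean `depth`, or `fold * depth` for
#' windows whose midpoint falls inside an amplified region, emulating the
#' MMBIR-like local copy-number gain.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param amplified_regions data.frame `chrom`, `start`, `end` (0-based
#'   half-open); may have zero rows.
#' @param fold fold change planted in amplified regions (>= 1).
#' @param depth mean reads per window elsewhere.
#' @param window_bp coverage window size.
#' @param seed integer seed.
#' @return data.frame `chrom`, `start`, `end`, `depth`.
#' @export
simulate_coverage <- function(chrom_lengths, amplified_regions = NULL,
                              fold = 1, depth = 30, window_bp = 50000L,
                              seed = 1L) {
  stopifnot(fold >= 1, depth > 0)
  set.seed(.sub_seed(seed, "coverage"))
  out <- lapply(names(chrom_lengths), function(ch) {
    starts <- seq(0L, chrom_lengths[[ch]] - 1L, by = window_bp)
    ends <- pmin(starts + window_bp, chrom_lengths[[ch]])
    mid <- (starts + ends) / 2
    mu <- rep(depth, length(starts))
    if (!is.null(amplified_regions) && nrow(amplified_regions) > 0) {
      amp <- amplified_regions[amplified_regions$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(amp)))
        mu[mid >= amp$start[i] & mid < amp$end[i]] <- fold * depth
    }
    data.frame(chrom = ch, start = starts, end = ends,
               depth = stats::rpois(length(mu), mu))
  })
  do.call(rbind, out)
}

#' Simulate per-gene expression abundances
#'
#' A fixed fraction of genes is "expressed" (log-normal abundances around
#' 20); the rest get sub-threshold values, so expression-based breakpoint
#' classification has known truth.
#'
#' @param models a [gene_models()] object.
#' @param samples character vector of sample names.
#' @param expressed_fraction fraction of genes expressed per sample.
#' @param seed integer seed.
#' @return data.frame with `gene_id` plus one abundance column per sample;
#'   attribute `"expressed"` holds the per-sample truth (list of gene id
#'   vectors).
#' @export
simulate_expression <- function(models, samples = "SIM1",
                                expressed_fraction = 0.6, seed = 1L) {
  set.seed(.sub_seed(seed, "evidence"))
  ids <- models$genes$gene_id
  out <- data.frame(gene_id = ids)
  truth <- list()
  for (s in samples) {
    expr <- stats::runif(length(ids), 0, 0.5)
    on <- sample(length(ids), round(expressed_fraction * length(ids)))
    expr[on] <- stats::rlnorm(length(on), log(20), 1)
    out[[s]] <- expr
    truth[[s]] <- ids[on]
  }
  attr(out, "expressed") <- truth
  out
}

# 200-bp junction context for a planted fusion: 100 retained bases from the
# 5' side followed by 100 from the 3' side, in junction frame.
.fusion_context <- function(reference, chrom5, pos5, or5, chrom3, pos3, or3,
                            window = 200L) {
  half <- window %/% 2L
  a <- .extract_jf(reference, chrom5,
                   .junction_window(pos5, or5, "left", "inside", half))$seq
  b <- .extract_jf(reference, chrom3,
                   .junction_window(pos3, or3, "right", "inside", half))$seq
  paste0(a, b)
}

#' Simulate fusion-transcript calls of known provenance
#'
#' Emits a mixture of genomically supported fusions (with a matching
#' planted rearrangement), read-through fusions (the rearrangement
#' breakend lies in the neighbor gene of the reported 3' partner),
#' trans-splice-only chimeras (no rearrangement at all) and normal-panel
#' artifacts, in the proportions given by the configuration.
#'
#' @param genome output of [simulate_genome()].
#' @param config a [sim_config()] object.
#' @param n_fusions total number of fusion calls to emit.
#' @param sample sample identifier.
#' @param normal_panel optional character vector of order-sensitive
#'   `"GENE5>GENE3"` keys; generated when `NULL`.
#' @return list `fusions`, `rearrangements`, `truth`, `panel`,
#'   `reference`.
#' @export
simulate_fusion_calls <- function(genome, config, n_fusions = 40L,
                                  sample = "SIM1", normal_panel = NULL) {
  config <- validate_sim_config(config)
  if (config$trans_splice_fraction + config$normal_panel_fraction > 1)
    stop("trans_splice_fraction + normal_panel_fraction > 1")
  set.seed(.sub_seed(config$seed, "fusion"))
  models <- genome$models
  if (nrow(models$genes) == 0) stop("gene models are empty")
  ref <- genome$reference
  n_ts <- round(n_fusions * config$trans_splice_fraction)
  n_np <- round(n_fusions * config$normal_panel_fraction)
  n_rt <- round(n_fusions * config$read_through_fraction)
  n_gen <- n_fusions - n_ts - n_np - n_rt
  if (n_gen < 0) stop("fusion provenance fractions exceed 1")

  genes <- models$genes
  introns <- gene_introns(models)
  ne <- max(models$exons$exon_number)
  # an intron position inside gene g, in genomic order slot k (1..ne-1)
  intron_pos <- function(g, k) {
    gx <- models$exons[models$exons$gene_id == g, ]
    gx <- gx[order(gx$start), ]
    round((gx$end[k] + gx$start[k + 1L]) / 2)
  }
  or5 <- function(strand) if (strand == "+") "tail" else "head"
  or3 <- function(strand) if (strand == "+") "head" else "tail"
  # genomic intron slot of the transcript-order intron after exon k
  slot5 <- function(strand, e5) if (strand == "+") e5 else ne - e5
  slot3 <- function(strand, e3) if (strand == "+") e3 - 1L else ne - e3 + 1L

  fus <- list(); rearr <- list(); truth <- list()
  rid <- 0L
  emit_genomic <- function(fid, g5row, g3row, breakend_gene3) {
    # breakend_gene3: the gene that physically carries the 3' breakend
    rid <<- rid + 1L
    e5 <- sample(seq_len(ne - 1L), 1)
    e3 <- sample(2:ne, 1)
    p5 <- intron_pos(g5row$gene_id, slot5(g5row$strand, e5))
    p3 <- intron_pos(breakend_gene3$gene_id,
                     slot3(breakend_gene3$strand, e3))
    o5 <- or5(g5row$strand); o3 <- or3(breakend_gene3$strand)
    ev <- simulate_read_evidence(config$depth, 0.4)
    r <- data.frame(id = sprintf("fsv%03d", rid), sample = sample,
                    sv_type = "TRA",
                    chrom_a = g5row$chrom, pos_a = p5, orient_a = o5,
                    chrom_b = breakend_gene3$chrom, pos_b = p3, orient_b = o3,
                    spanning = ev$spanning + 8L, split = ev$split + 3L,
                    concordant_a = ev$concordant_a,
                    concordant_b = ev$concordant_b, mh_len = NA_integer_)
    f <- data.frame(id = fid, sample = sample,
                    gene5 = g5row$gene_id, gene3 = g3row$gene_id,
                    exon5 = e5, exon3 = e3,
                    chrom5 = g5row$chrom, pos5 = p5,
                    chrom3 = g3row$chrom, pos3 = p3,
                    spanning = 8L + stats::rpois(1, 20),
                    split = 3L + stats::rpois(1, 10),
                    context = .fusion_context(ref, g5row$chrom, p5, o5,
                                              breakend_gene3$chrom, p3, o3))
    list(f = f, r = r)
  }

  fi <- 0L
  used <- character(0)   # genes are never reused across emitted fusions,
                         # so planted provenance classes cannot collide
  pick2 <- function() {
    for (tries in 1:2000) {
      i <- sample(nrow(genes), 2)
      if (genes$chrom[i[1]] != genes$chrom[i[2]] &&
          !any(genes$gene_id[i] %in% used)) return(i)
    }
    stop("not enough unused genes to emit further fusions")
  }
  for (j in seq_len(n_gen)) {
    fi <- fi + 1L
    i <- pick2()
    out <- emit_genomic(sprintf("fus%03d", fi), genes[i[1], ], genes[i[2], ],
                        genes[i[2], ])
    used <- c(used, genes$gene_id[i])
    fus[[fi]] <- out$f; rearr[[length(rearr) + 1L]] <- out$r
    truth[[fi]] <- data.frame(id = out$f$id, class = "genomic",
                              rearrangement = out$r$id,
                              genomically_supported = TRUE)
  }
  # read-through: breakend in gene A, fusion reported to A's neighbor on
  # the same chromosome and strand
  for (j in seq_len(n_rt)) {
    nb <- NULL
    repeat {
      i <- pick2()
      a <- genes[i[2], ]
      cand <- genes[genes$chrom == a$chrom & genes$strand == a$strand &
                    !(genes$gene_id %in% c(used, a$gene_id)), ]
      if (nrow(cand) == 0) next
      d <- pmax(cand$start - a$end, a$start - cand$end, 0)
      cand <- cand[d <= 1e6, ]
      if (nrow(cand) > 0) { nb <- cand[which.min(abs(cand$start - a$start)), ]; break }
    }
    fi <- fi + 1L
    out <- emit_genomic(sprintf("fus%03d", fi), genes[i[1], ], nb, a)
    used <- c(used, genes$gene_id[i], nb$gene_id)
    fus[[fi]] <- out$f; rearr[[length(rearr) + 1L]] <- out$r
    truth[[fi]] <- data.frame(id = out$f$id, class = "read-through",
                              rearrangement = out$r$id,
                              genomically_supported = TRUE)
  }
  # normal-panel artifacts
  if (is.null(normal_panel) && n_np > 0) {
    normal_panel <- vapply(seq_len(max(n_np, 5)), function(j) {
      i <- pick2()
      used <<- c(used, genes$gene_id[i])
      paste0(genes$gene_id[i[1]], ">", genes$gene_id[i[2]])
    }, character(1))
    normal_panel <- unique(normal_panel)
  }
  emit_unsupported <- function(fid, g5row, g3row, cls) {
    e5 <- sample(seq_len(ne - 1L), 1); e3 <- sample(2:ne, 1)
    p5 <- intron_pos(g5row$gene_id, slot5(g5row$strand, e5))
    p3 <- intron_pos(g3row$gene_id, slot3(g3row$strand, e3))
    data.frame(id = fid, sample = sample,
               gene5 = g5row$gene_id, gene3 = g3row$gene_id,
               exon5 = e5, exon3 = e3,
               chrom5 = g5row$chrom, pos5 = p5,
               chrom3 = g3row$chrom, pos3 = p3,
               spanning = 8L + stats::rpois(1, 10),
               split = 3L + stats::rpois(1, 5),
               context = .fusion_context(ref, g5row$chrom, p5,
                                         or5(g5row$strand),
                                         g3row$chrom, p3,
                                         or3(g3row$strand)))
  }
  for (j in seq_len(n_np)) {
    fi <- fi + 1L
    key <- sample(normal_panel, 1)
    gg <- strsplit(key, ">", fixed = TRUE)[[1]]
    f <- emit_unsupported(sprintf("fus%03d", fi),
                          genes[genes$gene_id == gg[1], ],
                          genes[genes$gene_id == gg[2], ], "normal-panel")
    fus[[fi]] <- f
    truth[[fi]] <- data.frame(id = f$id, class = "normal-panel",
                              rearrangement = NA_character_,
                              genomically_supported = FALSE)
  }
  for (j in seq_len(n_ts)) {
    fi <- fi + 1L
    i <- pick2()
    used <- c(used, genes$gene_id[i])
    f <- emit_unsupported(sprintf("fus%03d", fi), genes[i[1], ],
                          genes[i[2], ], "trans-splice")
    fus[[fi]] <- f
    truth[[fi]] <- data.frame(id = f$id, class = "trans-splice",
                              rearrangement = NA_character_,
                              genomically_supported = FALSE)
  }
  list(fusions = do.call(rbind, fus),
       rearrangements = if (length(rearr)) do.call(rbind, rearr) else NULL,
       truth = do.call(rbind, truth),
       panel = normal_panel %||% character(0),
       reference = ref)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a radiation-damage qPCR assay (Ct table)
#'
#' Targets CDKN1A and BAX against a TBP-like endogenous reference, at 0 h
#' and 8 h after irradiation, with technical replicates and Gaussian Ct
#' noise. p53-functional samples get a planted induction (target Ct drops
#' by log2(fold) at 8 h); deficient samples get fold 1.
#'
#' @param p53_status `"functional"` or `"deficient"` (vectorized; one
#'   simulated sample per element, named by `samples`).
#' @param samples sample names (default S1, S2, ...).
#' @param planted_fold induction fold planted for functional samples.
#' @param ct_noise_sd Gaussian noise SD in cycles.
#' @param replicates technical replicates per condition.
#' @param seed integer seed.
#' @return data.frame `sample`, `target`, `timepoint` (`"0h"`/`"8h"`),
#'   `replicate`, `ct`; the reference gene rows have `target == "TBP"`.
#' @export
simulate_damage_assay <- function(p53_status, samples = NULL,
                                  planted_fold = 4, ct_noise_sd = 0.15,
                                  replicates = 3L, seed = 1L) {
  stopifnot(all(p53_status %in% c("functional", "deficient")))
  set.seed(.sub_seed(seed, "damage"))
  if (is.null(samples)) samples <- sprintf("S%d", seq_along(p53_status))
  rows <- list()
  for (i in seq_along(p53_status)) {
    fold <- if (p53_status[i] == "functional") planted_fold else 1
    base <- c(CDKN1A = 28, BAX = 28.5, TBP = 25)
    for (target in names(base)) {
      for (tp in c("0h", "8h")) {
        mu <- base[[target]]
        if (target != "TBP" && tp == "8h") mu <- mu - log2(fold)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples[i], target = target, timepoint = tp,
          replicate = seq_len(replicates),
          ct = mu + stats::rnorm(replicates, 0, ct_noise_sd))
      }
    }
  }
  do.call(rbind, rows)
}
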