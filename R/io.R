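# Readers and writers for the external formats the pipeline touches.
# Internal coordinates are uniformly 0-based half-open; every +-1
# conversion happens here and only here. Text outputs are UTF-8,
# tab-separated, with a header line starting "#".

.ORIENT_TO_STRAND <- c(tail = "+", head = "-")
.STRAND_TO_ORIENT <- c(`+` = "tail", `-` = "head")
.SV_TYPES <- c("DEL", "DUP", "INV", "TRA")

.read_tsv_hash <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#") & nzchar(lines)
  hdr_idx <- which(startsWith(lines, "#"))
  first_body <- if (any(keep)) which(keep)[1] else length(lines) + 1L
  hdr_idx <- hdr_idx[hdr_idx < first_body]
  # the header is the last comment line before the data (earlier comment
  # lines are free-text documentation)
  header <- sub("^#", "", lines[hdr_idx[length(hdr_idx)]])
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  body <- lines[keep]
  list(cols = cols, body = body, line_no = which(keep),
       comments = lines[hdr_idx])
}

#' Read / write structural-variant calls in BEDPE
#'
#' The dialect is standard 10-column BEDPE (0-based half-open, strand `+`
#' = retain-left/tail, `-` = retain-right/head) with extension columns
#' `sv_type`, `sample`, `spanning`, `split`, `concordant_a`,
#' `concordant_b`, `mh_len`. `write_sv_bedpe` and `read_sv_bedpe` are
#' exact inverses on valid files.
#'
#' @param path file path.
#' @return `read_sv_bedpe`: a rearrangement data.frame (see
#'   [plant_rearrangement()] for the columns).
#' @export
read_sv_bedpe <- function(path) {
  tv <- .read_tsv_hash(path)
  empty <- data.frame(id = character(), sample = character(),
                      sv_type = character(),
                      chrom_a = character(), pos_a = integer(),
                      orient_a = character(),
                      chrom_b = character(), pos_b = integer(),
                      orient_b = character(),
                      spanning = integer(), split = integer(),
                      concordant_a = integer(), concordant_b = integer(),
                      mh_len = integer())
  if (length(tv$body) == 0) return(empty)
  rows <- lapply(seq_along(tv$body), function(i) {
    f <- strsplit(tv$body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 17)
      stop("malformed BEDPE line ", tv$line_no[i], ": expected 17 fields, got ",
           length(f))
    if (!(f[11] %in% .SV_TYPES))
      stop("unknown sv_type '", f[11], "' at line ", tv$line_no[i])
    data.frame(id = f[7], sample = f[12], sv_type = f[11],
               chrom_a = f[1], pos_a = as.integer(f[2]),
               orient_a = unname(.STRAND_TO_ORIENT[f[9]]),
               chrom_b = f[4], pos_b = as.integer(f[5]),
               orient_b = unname(.STRAND_TO_ORIENT[f[10]]),
               spanning = as.integer(f[13]), split = as.integer(f[14]),
               concordant_a = as.integer(f[15]),
               concordant_b = as.integer(f[16]),
               mh_len = suppressWarnings(as.integer(f[17])))
  })
  out <- do.call(rbind, rows)
  bad <- is.na(out$pos_a) | is.na(out$pos_b) | is.na(out$orient_a) |
    is.na(out$orient_b)
  if (any(bad))
    stop("malformed BEDPE line ", tv$line_no[which(bad)[1]])
  out
}

#' @rdname read_sv_bedpe
#' @param calls rearrangement data.frame.
#' @export
write_sv_bedpe <- function(calls, path) {
  header <- paste0("#", paste(c("chrom1", "start1", "end1", "chrom2",
                                "start2", "end2", "name", "score",
                                "strand1", "strand2", "sv_type", "sample",
                                "spanning", "split", "concordant_a",
                                "concordant_b", "mh_len"), collapse = "\t"))
  lines <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    lines[i] <- paste(c(r$chrom_a, r$pos_a, r$pos_a + 1L,
                        r$chrom_b, r$pos_b, r$pos_b + 1L,
                        r$id, ".",
                        .ORIENT_TO_STRAND[r$orient_a],
                        .ORIENT_TO_STRAND[r$orient_b],
                        r$sv_type, r$sample,
                        r$spanning, r$split, r$concordant_a, r$concordant_b,
                        if (is.na(r$mh_len)) "NA" else r$mh_len),
                      collapse = "\t")
  }
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

.info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

#' Read structural variants from a minimal VCF 4.x dialect
#'
#' Supports symbolic `SVTYPE=DEL/DUP/INV` records with `END=` (converted
#' from 1-based to the internal 0-based half-open interval) and paired
#' `SVTYPE=BND` records with bracket-notation ALT alleles, which are
#' mapped to translocations with retain-left/retain-right orientations
#' following the four bracket cases of the VCF specification. `PE`/`SR`
#' INFO keys are taken as spanning/split read counts when present.
#' Insertion records and unpaired breakends are skipped with a warning.
#'
#' @param path VCF file path (plain text).
#' @return rearrangement data.frame.
#' @export
read_sv_vcf_bnd <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  recs <- list(); bnds <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed VCF record: ", ln)
    chrom <- f[1]; pos <- as.integer(f[2]); id <- f[3]; alt <- f[5]
    info <- f[8]
    svtype <- .info_field(info, "SVTYPE")
    if (is.na(svtype)) next
    if (svtype == "INS") {
      warning("skipping SVTYPE=INS record ", id,
              " (outside the DEL/DUP/INV/TRA class system)")
      next
    }
    pe <- suppressWarnings(as.integer(.info_field(info, "PE")))
    sr <- suppressWarnings(as.integer(.info_field(info, "SR")))
    smp <- .info_field(info, "SAMPLE"); if (is.na(smp)) smp <- "VCF"
    if (svtype %in% c("DEL", "DUP", "INV")) {
      end <- as.integer(.info_field(info, "END"))
      or <- sv_type_orientations(svtype)
      ct <- .info_field(info, "CT")   # DELLY-style 3to3 / 5to5 for INV
      if (svtype == "INV" && !is.na(ct) && ct == "5to5") or <- c("head", "head")
      recs[[length(recs) + 1L]] <- data.frame(
        id = id, sample = smp, sv_type = svtype,
        chrom_a = chrom, pos_a = pos - 1L, orient_a = or[1],
        chrom_b = chrom, pos_b = end, orient_b = or[2],
        spanning = pe, split = sr,
        concordant_a = NA_integer_, concordant_b = NA_integer_,
        mh_len = NA_integer_)
    } else if (svtype == "BND") {
      m <- regmatches(alt, regexec(
        "^([ACGTNacgtn]*)(\\[|\\])([^:]+):([0-9]+)(\\[|\\])([ACGTNacgtn]*)$",
        alt))[[1]]
      if (length(m) == 0) {
        warning("unparseable BND ALT '", alt, "' for ", id, "; skipped")
        next
      }
      t_before <- nzchar(m[2]); bracket <- m[3]
      mate_chrom <- m[4]; mate_pos <- as.integer(m[5])
      # four VCF bracket cases:
      #  t[p[ : this tail, mate head;   t]p] : this tail, mate tail
      #  ]p]t : this head, mate tail;   [p[t : this head, mate head
      this_or <- if (t_before) "tail" else "head"
      mate_or <- if (bracket == "[") "head" else "tail"
      this_pos0 <- if (this_or == "tail") pos else pos - 1L
      mate_pos0 <- if (mate_or == "tail") mate_pos else mate_pos - 1L
      bnds[[length(bnds) + 1L]] <- data.frame(
        id = id, mate = .info_field(info, "MATEID"), sample = smp,
        chrom = chrom, pos = this_pos0, orient = this_or,
        mate_chrom = mate_chrom, mate_pos = mate_pos0, mate_orient = mate_or,
        spanning = pe, split = sr)
    }
  }
  if (length(bnds) > 0) {
    b <- do.call(rbind, bnds)
    used <- rep(FALSE, nrow(b))
    for (i in seq_len(nrow(b))) {
      if (used[i]) next
      j <- which(!used & b$chrom == b$mate_chrom[i] &
                 b$pos == b$mate_pos[i] & b$mate_chrom == b$chrom[i] &
                 b$mate_pos == b$pos[i])
      j <- setdiff(j, i)
      if (!is.na(b$mate[i])) j <- intersect(j, which(b$id == b$mate[i]))
      if (length(j) == 0) {
        warning("unpaired BND record ", b$id[i], "; skipped")
        used[i] <- TRUE
        next
      }
      j <- j[1]
      used[c(i, j)] <- TRUE
      recs[[length(recs) + 1L]] <- data.frame(
        id = b$id[i], sample = b$sample[i],
        sv_type = if (b$chrom[i] == b$mate_chrom[i]) "INV" else "TRA",
        chrom_a = b$chrom[i], pos_a = b$pos[i], orient_a = b$orient[i],
        chrom_b = b$mate_chrom[i], pos_b = b$mate_pos[i],
        orient_b = b$mate_orient[i],
        spanning = b$spanning[i], split = b$split[i],
        concordant_a = NA_integer_, concordant_b = NA_integer_,
        mh_len = NA_integer_)
    }
  }
  if (length(recs) == 0)
    return(read_sv_bedpe(textConnection("#empty")))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Read / write gene models (GTF-lite or BED12)
#'
#' The GTF-lite dialect carries one `exon` feature line per exon with
#' `gene_id` and `exon_number` attributes (1-based closed coordinates,
#' converted to internal 0-based half-open). BED12 files are accepted on
#' read; `blockCount` mismatches are an error.
#'
#' @param path file path; format chosen by extension (`.bed` = BED12,
#'   anything else GTF-lite).
#' @return a [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE))
    return(.read_bed12(path))
  lines <- readLines(path, encoding = "UTF-8")
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) stop("malformed GTF line ", i)
    if (f[3] != "exon") return(NULL)
    gid <- sub('.*gene_id "([^"]+)".*', "\\1", f[9])
    en <- suppressWarnings(as.integer(sub('.*exon_number "?([0-9]+)"?.*',
                                          "\\1", f[9])))
    data.frame(gene_id = gid, chrom = f[1], strand = f[7],
               start = as.integer(f[4]) - 1L, end = as.integer(f[5]),
               exon_number = en)
  })
  ex <- do.call(rbind, rows)
  if (is.null(ex)) stop("no exon records in ", path)
  genes <- do.call(rbind, lapply(split(ex, ex$gene_id), function(gx)
    data.frame(gene_id = gx$gene_id[1], chrom = gx$chrom[1],
               strand = gx$strand[1], start = min(gx$start),
               end = max(gx$end))))
  rownames(genes) <- NULL
  gene_models(genes,
              ex[, c("gene_id", "exon_number", "start", "end")])
}

.read_bed12 <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  genes <- list(); exons <- list()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) stop("BED12 line ", i, ": expected 12 fields")
    n <- as.integer(f[10])
    sizes <- as.integer(strsplit(sub(",$", "", f[11]), ",")[[1]])
    starts <- as.integer(strsplit(sub(",$", "", f[12]), ",")[[1]])
    if (length(sizes) != n || length(starts) != n)
      stop("BED12 line ", i, ": blockCount mismatch")
    gstart <- as.integer(f[2])
    genes[[i]] <- data.frame(gene_id = f[4], chrom = f[1], strand = f[6],
                             start = gstart, end = as.integer(f[3]))
    exons[[i]] <- data.frame(gene_id = f[4], exon_number = seq_len(n),
                             start = gstart + starts,
                             end = gstart + starts + sizes)
  }
  gene_models(do.call(rbind, genes), do.call(rbind, exons))
}

#' @rdname read_gene_models
#' @param models a [gene_models()] object.
#' @export
write_gene_models <- function(models, path) {
  header <- "#GTF-lite: exon features with gene_id/exon_number attributes"
  ex <- models$exons
  strand <- models$genes$strand[match(ex$gene_id, models$genes$gene_id)]
  chrom <- models$genes$chrom[match(ex$gene_id, models$genes$gene_id)]
  lines <- sprintf(
    '%s\tsvforensics\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; exon_number "%d";',
    chrom, ex$start + 1L, ex$end, strand, ex$gene_id, ex$exon_number)
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a gene-by-sample expression table
#'
#' Tab-separated, header line `#gene_id<TAB>sample...`, one FPKM-like
#' unit-free abundance per gene and sample.
#'
#' @param path file path.
#' @return data.frame with `gene_id` plus one numeric column per sample.
#' @export
read_expression_table <- function(path) {
  tv <- .read_tsv_hash(path)
  if (length(tv$cols) < 2) stop("expression table needs >= 1 sample column")
  rows <- strsplit(tv$body, "\t", fixed = TRUE)
  out <- data.frame(gene_id = vapply(rows, `[`, "", 1))
  for (j in 2:length(tv$cols))
    out[[tv$cols[j]]] <- as.numeric(vapply(rows, `[`, "", j))
  if (anyDuplicated(out$gene_id))
    stop("duplicate gene ids in ", path)
  out
}

#' @rdname read_expression_table
#' @param expr expression data.frame (first column `gene_id`).
#' @export
write_expression_table <- function(expr, path) {
  header <- paste0("#", paste(names(expr), collapse = "\t"))
  lines <- do.call(paste, c(lapply(expr, as.character), sep = "\t"))
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write fusion-transcript call tables
#'
#' Columns: `id, sample, gene5, gene3, exon5, exon3, chrom5, pos5, chrom3,
#' pos3, spanning, split, context` (0-based positions, 200-bp junction
#' context sequence).
#'
#' @param path file path.
#' @return fusion data.frame.
#' @export
read_fusion_table <- function(path) {
  tv <- .read_tsv_hash(path)
  int_cols <- c("exon5", "exon3", "pos5", "pos3", "spanning", "split")
  if (length(tv$body) == 0) {
    out <- data.frame(id = character(), sample = character(),
                      gene5 = character(), gene3 = character(),
                      exon5 = integer(), exon3 = integer(),
                      chrom5 = character(), pos5 = integer(),
                      chrom3 = character(), pos3 = integer(),
                      spanning = integer(), split = integer(),
                      context = character())
    return(out)
  }
  rows <- strsplit(tv$body, "\t", fixed = TRUE)
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- tv$cols
  for (cc in intersect(int_cols, names(out)))
    out[[cc]] <- as.integer(out[[cc]])
  out
}

#' @rdname read_fusion_table
#' @param fusions fusion data.frame.
#' @export
write_fusion_table <- function(fusions, path) {
  header <- paste0("#", paste(names(fusions), collapse = "\t"))
  lines <- do.call(paste, c(lapply(fusions, as.character), sep = "\t"))
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a bedGraph-like coverage track
#'
#' Tab-separated `chrom, start, end, depth` (0-based half-open windows)
#' with a `#` header line.
#'
#' @param path file path.
#' @return coverage data.frame.
#' @export
read_coverage <- function(path) {
  tv <- .read_tsv_hash(path)
  rows <- strsplit(tv$body, "\t", fixed = TRUE)
  data.frame(chrom = vapply(rows, `[`, "", 1),
             start = as.integer(vapply(rows, `[`, "", 2)),
             end = as.integer(vapply(rows, `[`, "", 3)),
             depth = as.numeric(vapply(rows, `[`, "", 4)))
}

#' @rdname read_coverage
#' @param track coverage data.frame.
#' @export
write_coverage <- function(track, path) {
  header <- "#chrom\tstart\tend\tdepth"
  lines <- paste(track$chrom, track$start, track$end, track$depth,
                 sep = "\t")
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write reference sequences as FASTA
#'
#' Thin wrappers over Biostrings, returning / accepting the package's
#' named-character-vector reference representation.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param reference named character vector of sequences.
#' @export
write_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
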