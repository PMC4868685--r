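# Junction-frame sequence arithmetic.
#
# Internally every coordinate is 0-based half-open. A breakend is
# (chrom, pos, orient) where orient "tail" retains [0, pos) of the
# chromosome and orient "head" retains [pos, L). A rearrangement junction
# glues the retained flank of breakend A (left partner) to the retained
# flank of breakend B (right partner); flanks retained on the "wrong"
# side for their role are reverse-complemented, which is what makes
# inversion-type joins work.

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                 a = "t", c = "g", g = "c", t = "a", n = "n")

revcomp_chr <- function(x) {
  x <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(x, function(s) {
    if (!nzchar(s)) return(s)
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Genomic window backing one junction-frame flank string.
# role: "left" (segment ends at the junction) or "right" (segment starts
# at it). kind: "inside" = retained bases adjacent to the junction,
# "outside" = the reference continuation past the junction.
# Returns 0-based half-open [start, end) plus rev flag: the junction-frame
# string is revcomp(reference[start, end)) when rev, else the plain
# forward extract. "inside"/"outside" strings of a left partner end at the
# junction (suffix semantics); those of a right partner start at it
# (prefix semantics).
.junction_window <- function(pos, orient, role, kind, s) {
  fwd <- (role == "left" && orient == "tail") ||
         (role == "right" && orient == "head")
  if (kind == "inside") {
    if (fwd && role == "left")   w <- c(pos - s, pos)
    if (fwd && role == "right")  w <- c(pos, pos + s)
    if (!fwd && role == "left")  w <- c(pos, pos + s)
    if (!fwd && role == "right") w <- c(pos - s, pos)
  } else {
    if (fwd && role == "left")   w <- c(pos, pos + s)
    if (fwd && role == "right")  w <- c(pos - s, pos)
    if (!fwd && role == "left")  w <- c(pos - s, pos)
    if (!fwd && role == "right") w <- c(pos, pos + s)
  }
  list(start = w[1], end = w[2], rev = !fwd)
}

# Extract the junction-frame string for a window; truncates at contig ends.
.extract_jf <- function(seqs, chrom, w) {
  len <- .seq_nchar(seqs, chrom)
  start <- max(w$start, 0L)
  end <- min(w$end, len)
  truncated <- (start > w$start) || (end < w$end)
  s <- if (end > start) .seq_get(seqs, chrom, start, end) else ""
  if (w$rev) s <- revcomp_chr(s)
  # orientation of truncation: a rev window truncated at its genomic start
  # loses junction-frame characters at its far (outward) end, which is the
  # same end a fwd window loses when truncated at its genomic end; both
  # cases shorten the string away from the junction, so no padding needed.
  list(seq = s, truncated = truncated)
}

# Write a single junction-frame character at 1-based index i of a window.
.write_jf <- function(seqs, chrom, w, i, base) {
  if (w$rev) {
    gpos <- w$end - i            # 0-based
    base <- unname(.COMPLEMENT[base])
  } else {
    gpos <- w$start + i - 1L
  }
  .seq_set1(seqs, chrom, gpos, base)
}

.lcp <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  if (n == 0L) return(0L)
  xb <- charToRaw(substr(x, 1L, n))
  yb <- charToRaw(substr(y, 1L, n))
  d <- which(xb != yb)
  if (length(d) == 0L) n else d[1L] - 1L
}

.rev_str <- function(x) if (nzchar(x)) intToUtf8(rev(utf8ToInt(x))) else x

.lcs_suffix <- function(x, y) .lcp(.rev_str(x), .rev_str(y))

#' Measure junction microhomology at a rearrangement breakpoint
#'
#' Computes the junction-ambiguity overlap: the number of bases over which
#' the breakpoint placement is ambiguous because the retained flank of one
#' breakend exactly continues the reference past the other breakend. The
#' total is the sum of the leftward and rightward shift ambiguities, capped
#' at `max_scan`. Flanks retained on the far side for their role in the
#' junction are reverse-complemented, so inversion-type joins are handled.
#'
#' @param reference named character vector of chromosome sequences.
#' @param chrom_a,pos_a,orient_a first breakend (0-based `pos`; orient
#'   `"tail"` retains the left flank, `"head"` the right flank).
#' @param chrom_b,pos_b,orient_b second breakend.
#' @param max_scan scan cap in bp (default 25; longer homologies are
#'   reported as `max_scan` with `capped = TRUE`).
#' @return list with `length` (bp), `seq` (the homologous bases),
#'   `left`/`right` shift components, `truncated` (flank shorter than
#'   `max_scan` near a contig end) and `capped`.
#' @export
junction_microhomology <- function(reference, chrom_a, pos_a, orient_a,
                                   chrom_b, pos_b, orient_b,
                                   max_scan = 25L) {
  stopifnot(max_scan >= 0)
  s <- as.integer(max_scan)
  in_a  <- .extract_jf(reference, chrom_a,
                       .junction_window(pos_a, orient_a, "left", "inside", s))
  out_a <- .extract_jf(reference, chrom_a,
                       .junction_window(pos_a, orient_a, "left", "outside", s))
  in_b  <- .extract_jf(reference, chrom_b,
                       .junction_window(pos_b, orient_b, "right", "inside", s))
  out_b <- .extract_jf(reference, chrom_b,
                       .junction_window(pos_b, orient_b, "right", "outside", s))
  right <- .lcp(in_b$seq, out_a$seq)        # junction slides right
  left  <- .lcs_suffix(in_a$seq, out_b$seq) # junction slides left
  capped <- (left + right) > s
  len <- min(left + right, s)
  hom <- paste0(
    if (left > 0) substr(in_a$seq, nchar(in_a$seq) - left + 1L, nchar(in_a$seq)) else "",
    if (right > 0) substr(in_b$seq, 1L, right) else "")
  if (nchar(hom) > len) hom <- substr(hom, 1L, len)
  list(length = as.integer(len), seq = hom,
       left = as.integer(left), right = as.integer(right),
       truncated = in_a$truncated || out_a$truncated ||
                   in_b$truncated || out_b$truncated,
       capped = capped)
}

# Default breakend orientations implied by an SV type (standard join
# semantics: DEL tail-head, DUP head-tail, INV tail-tail or head-head).
sv_type_orientations <- function(sv_type, inv_side = c("tail", "head")) {
  inv_side <- match.arg(inv_side)
  switch(sv_type,
         DEL = c("tail", "head"),
         DUP = c("head", "tail"),
         INV = c(inv_side, inv_side),
         TRA = c("tail", "head"),
         stop("unknown sv_type: ", sv_type))
}
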