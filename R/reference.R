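# Two interchangeable in-memory representations of a reference genome:
# a named character vector of chromosome strings (the user-facing one,
# cheap to read with substr) and a list of per-chromosome character
# vectors (cheap to mutate base-by-base while planting junctions).

.ref_is_split <- function(reference) is.list(reference)

.ref_split <- function(reference) {
  if (.ref_is_split(reference)) return(reference)
  lapply(as.list(reference), function(s) strsplit(s, "", fixed = TRUE)[[1]])
}

.ref_join <- function(reference) {
  if (!.ref_is_split(reference)) return(reference)
  vapply(reference, paste, character(1), collapse = "")
}

.seq_nchar <- function(reference, chrom) {
  if (.ref_is_split(reference)) length(reference[[chrom]])
  else nchar(reference[[chrom]])
}

# 0-based half-open extraction (assumes bounds already clamped)
.seq_get <- function(reference, chrom, start0, end0) {
  if (end0 <= start0) return("")
  if (.ref_is_split(reference))
    paste(reference[[chrom]][(start0 + 1L):end0], collapse = "")
  else substr(reference[[chrom]], start0 + 1L, end0)
}

.seq_set1 <- function(reference, chrom, pos0, base) {
  if (.ref_is_split(reference)) {
    reference[[chrom]][pos0 + 1L] <- base
  } else {
    substr(reference[[chrom]], pos0 + 1L, pos0 + 1L) <- base
  }
  reference
}
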