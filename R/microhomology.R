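#' Microhomology category of a junction
#'
#' Three categories: `"none"` (0 bp), `"1-5"` and `"6-25"` bp. Lengths
#' above 25 bp are outside the category system and return `NA` with a
#' warning (the measurement caps at 25, so this only occurs for
#' externally supplied lengths).
#'
#' @param mh_len integer vector of microhomology lengths in bp.
#' @return factor with levels `none`, `1-5`, `6-25`.
#' @export
categorize_microhomology <- function(mh_len) {
  out <- ifelse(is.na(mh_len), NA_character_,
         ifelse(mh_len == 0, "none",
         ifelse(mh_len <= 5, "1-5",
         ifelse(mh_len <= 25, "6-25", NA_character_))))
  if (any(!is.na(mh_len) & mh_len > 25)) {
    warning("microhomology length > 25 bp outside the category system; NA")
  }
  factor(out, levels = c("none", "1-5", "6-25"))
}

.MH_GROUPS <- c("TRA", "INV", "DUP", "DEL_lt5kb", "DEL_ge5kb", "DEL_ge10kb")

.mh_group <- function(sv_type, size) {
  ifelse(sv_type != "DEL", sv_type,
    ifelse(size < 5000, "DEL_lt5kb",
    ifelse(size < 10000, "DEL_ge5kb", "DEL_ge10kb")))
}

#' Measure microhomology for a table of rearrangement calls
#'
#' @param calls rearrangement data.frame.
#' @param reference named character vector of chromosome sequences.
#' @param max_scan scan cap in bp.
#' @return `calls` with an updated `mh_len` column (measured, not the
#'   caller-supplied value).
#' @export
measure_microhomology <- function(calls, reference, max_scan = 25L) {
  calls$mh_len <- vapply(seq_len(nrow(calls)), function(i)
    junction_microhomology(reference,
                           calls$chrom_a[i], calls$pos_a[i], calls$orient_a[i],
                           calls$chrom_b[i], calls$pos_b[i], calls$orient_b[i],
                           max_scan = max_scan)$length,
    integer(1))
  calls
}

#' Microhomology category profile by SV type and deletion-length stratum
#'
#' Groups calls into TRA, INV, DUP and deletion-length strata
#' (`DEL_lt5kb`, `DEL_ge5kb`, `DEL_ge10kb`; deletions >= 10 kb appear in
#' both `ge` strata, mirroring the nested "longer than 5 kb" / "longer
#' than 10 kb" presentation) and tabulates the three microhomology
#' categories per group.
#'
#' @param calls rearrangement data.frame; `mh_len` must be present
#'   (see [measure_microhomology()]) unless `reference` is supplied.
#' @param reference optional reference; when given, microhomology is
#'   (re)measured from sequence.
#' @param max_scan scan cap in bp.
#' @return data.frame of class `mh_profile`: `group`, `category`,
#'   `count`, `fraction`, `n` (per-group fractions sum to 1 when n > 0).
#' @export
build_mh_profile <- function(calls, reference = NULL, max_scan = 25L) {
  if (!is.null(reference)) calls <- measure_microhomology(calls, reference,
                                                          max_scan)
  if (any(is.na(calls$mh_len)))
    stop("mh_len missing; supply a reference to measure it")
  size <- ifelse(calls$sv_type == "DEL", calls$pos_b - calls$pos_a, NA)
  cat3 <- categorize_microhomology(calls$mh_len)
  rows <- list()
  for (grp in .MH_GROUPS) {
    sel <- switch(grp,
      TRA = calls$sv_type == "TRA",
      INV = calls$sv_type == "INV",
      DUP = calls$sv_type == "DUP",
      DEL_lt5kb = calls$sv_type == "DEL" & size < 5000,
      DEL_ge5kb = calls$sv_type == "DEL" & size >= 5000,
      DEL_ge10kb = calls$sv_type == "DEL" & size >= 10000)
    tab <- table(cat3[sel])
    n <- sum(tab)
    rows[[grp]] <- data.frame(group = grp, category = names(tab),
                              count = as.integer(tab),
                              fraction = if (n > 0) as.numeric(tab) / n
                                         else rep(NA_real_, 3),
                              n = n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mh_profile", class(out))
  out
}

#' Random-junction microhomology background profile
#'
#' Measures microhomology for `n` synthetic junctions formed by uniformly
#' random breakend pairs on the reference, processed identically to real
#' calls. This is the "average genome" null the observed profiles are
#' tested against.
#'
#' @param reference named character vector of chromosome sequences.
#' @param n number of random junctions (default 500).
#' @param seed integer seed.
#' @param max_scan scan cap in bp.
#' @return one-group `mh_profile` data.frame (`group == "background"`).
#' @export
random_background_profile <- function(reference, n = 500L, seed = 1L,
                                      max_scan = 25L) {
  if (n <= 0) stop("n must be positive")
  set.seed(.sub_seed(seed, "background"))
  chroms <- names(reference)
  lens <- vapply(chroms, function(ch) nchar(reference[[ch]]), integer(1))
  margin <- max_scan + 2L
  mh <- integer(n)
  for (i in seq_len(n)) {
    ca <- sample(chroms, 1); cb <- sample(chroms, 1)
    pa <- sample((margin):(lens[[ca]] - margin), 1)
    pb <- sample((margin):(lens[[cb]] - margin), 1)
    ors <- sample(c("tail", "head"), 2, replace = TRUE)
    mh[i] <- junction_microhomology(reference, ca, pa, ors[1],
                                    cb, pb, ors[2], max_scan)$length
  }
  tab <- table(categorize_microhomology(mh))
  out <- data.frame(group = "background", category = names(tab),
                    count = as.integer(tab),
                    fraction = as.numeric(tab) / n, n = n)
  attr(out, "lengths") <- mh
  class(out) <- c("mh_profile", class(out))
  out
}

#' Monte-Carlo Fisher test of a profile group against the background
#'
#' Builds the 2x3 contingency table (observed vs background counts over
#' the three microhomology categories) and computes Fisher's exact test
#' for count data with simulated p-values, conditioning on the margins.
#'
#' @param profile_group `mh_profile` rows of one group (3 category counts).
#' @param background background `mh_profile` (3 category counts).
#' @param replicates Monte-Carlo replicates (default 1e5).
#' @param seed integer seed for the resampling.
#' @return list `p_value`, `table`; degenerate margins give p = 1 with a
#'   warning.
#' @export
compare_to_background <- function(profile_group, background,
                                  replicates = 100000L, seed = 1L) {
  lv <- c("none", "1-5", "6-25")
  obs <- profile_group$count[match(lv, profile_group$category)]
  bg <- background$count[match(lv, background$category)]
  obs[is.na(obs)] <- 0L; bg[is.na(bg)] <- 0L
  tab <- rbind(observed = obs, background = bg)
  colnames(tab) <- lv
  if (any(rowSums(tab) == 0)) {
    warning("degenerate margin (empty row); p = 1")
    return(list(p_value = 1, table = tab))
  }
  keep <- colSums(tab) > 0
  set.seed(.sub_seed(seed, "background"))
  p <- stats::fisher.test(tab[, keep, drop = FALSE],
                          simulate.p.value = TRUE,
                          B = replicates)$p.value
  list(p_value = p, table = tab)
}

#' Deletion length vs microhomology length association
#'
#' Spearman rank correlation between deletion length and junction
#' microhomology length; negative when longer deletions carry shorter
#' homology (the MMEJ signature is concentrated in short deletions).
#'
#' @param deletions data.frame with `length` and `mh_len` columns (or a
#'   rearrangement data.frame of DEL calls with measured `mh_len`, from
#'   which lengths are derived).
#' @return list `rho`, `p_value`, `n`; `rho = NA` with a flag when either
#'   variable is constant.
#' @export
length_homology_association <- function(deletions) {
  if (!"length" %in% names(deletions)) {
    deletions <- deletions[deletions$sv_type == "DEL", , drop = FALSE]
    deletions$length <- deletions$pos_b - deletions$pos_a
  }
  x <- deletions$length; y <- deletions$mh_len
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       degenerate = FALSE)
}
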