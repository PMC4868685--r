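#' Relative expression fold change by the 2^-ddCt method
#'
#' Technical replicate Ct values are averaged per condition first; then
#' dCt(t) = mean Ct(target, t) - mean Ct(reference, t), ddCt =
#' dCt(8h) - dCt(0h) and fold = 2^-ddCt. A missing condition is an error
#' naming the sample, target and timepoint.
#'
#' @param ct_table data.frame `sample`, `target`, `timepoint`
#'   (`"0h"`/`"8h"`), `replicate`, `ct` (see [simulate_damage_assay()]).
#' @param reference reference (housekeeping) gene name (default `"TBP"`).
#' @param timepoints baseline and treated timepoint labels.
#' @return data.frame `sample`, `target`, `ddct`, `fold` (one row per
#'   sample x non-reference target).
#' @export
delta_delta_ct <- function(ct_table, reference = "TBP",
                           timepoints = c("0h", "8h")) {
  stopifnot(all(ct_table$ct > 0))
  mean_ct <- function(s, g, tp) {
    v <- ct_table$ct[ct_table$sample == s & ct_table$target == g &
                     ct_table$timepoint == tp]
    if (length(v) == 0)
      stop("missing Ct for sample ", s, ", target ", g, ", timepoint ", tp)
    mean(v)
  }
  out <- list()
  for (s in unique(ct_table$sample)) {
    targets <- setdiff(unique(ct_table$target[ct_table$sample == s]),
                       reference)
    for (g in targets) {
      d0 <- mean_ct(s, g, timepoints[1]) - mean_ct(s, reference, timepoints[1])
      d8 <- mean_ct(s, g, timepoints[2]) - mean_ct(s, reference, timepoints[2])
      ddct <- d8 - d0
      out[[length(out) + 1L]] <- data.frame(sample = s, target = g,
                                            ddct = ddct,
                                            fold = 2^(-ddct))
    }
  }
  do.call(rbind, out)
}

#' p53 functional call from induction fold changes
#'
#' A sample is called `functional` when both damage-response targets
#' (CDKN1A and BAX) are induced at least `induction_threshold`-fold
#' (inclusive), else `deficient`. With `partial = TRUE` samples inducing
#' exactly one target are called `partial` instead of `deficient`.
#'
#' @param folds output of [delta_delta_ct()] (columns `sample`, `target`,
#'   `fold`).
#' @param induction_threshold fold-change cutoff (default 2).
#' @param targets the two targets required.
#' @param partial report a partial-response category.
#' @return data.frame `sample`, `call`.
#' @export
p53_functional_call <- function(folds, induction_threshold = 2,
                                targets = c("CDKN1A", "BAX"),
                                partial = FALSE) {
  out <- lapply(unique(folds$sample), function(s) {
    fx <- folds[folds$sample == s & folds$target %in% targets, ]
    n_ind <- sum(fx$fold >= induction_threshold)
    call <- if (n_ind == length(targets)) "functional"
            else if (partial && n_ind > 0) "partial"
            else "deficient"
    data.frame(sample = s, call = call)
  })
  do.call(rbind, out)
}
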