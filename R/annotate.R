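# Annotation of curated variants: substitution-pair categories on the four
# chemistry axes, predictor-ensemble ddG averages, magnitude-based stability
# classes, and the destabilizing fraction. Two distinct notions of
# "destabilizing" are exposed deliberately: any ddG < 0 (used for the
# destabilizing-fraction statistic) and |ddG| beyond a magnitude cutoff
# (used for stabilizing/destabilizing counts at 1, 1.1 or 2 kcal/mol).

#' Add substitution-category columns to a variant table
#'
#' Appends `cat_hydropathy`, `cat_size`, `cat_aromatic`, `cat_charge`
#' (NA where an axis does not apply to both residues). The functional class
#' is carried as a given column, never inferred.
#'
#' @param variants Data frame with `wt_aa` and `mut_aa` columns.
#' @return The input with four category columns appended.
#' @export
annotate_variants <- function(variants) {
  need <- c("wt_aa", "mut_aa")
  miss <- setdiff(need, names(variants))
  if (length(miss)) {
    stop(sprintf("variant table lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  .check_canonical(variants$wt_aa, "wt_aa")
  .check_canonical(variants$mut_aa, "mut_aa")
  if (any(variants$wt_aa == variants$mut_aa)) {
    stop("wt_aa must differ from mut_aa in every row", call. = FALSE)
  }
  variants$cat_hydropathy <- .pair_label(variants$wt_aa, variants$mut_aa, "hydropathy")
  variants$cat_size <- .pair_label(variants$wt_aa, variants$mut_aa, "size")
  variants$cat_aromatic <- .pair_label(variants$wt_aa, variants$mut_aa, "ring")
  variants$cat_charge <- .pair_label(variants$wt_aa, variants$mut_aa, "charge")
  variants
}

#' Ensemble (average) ddG over selected predictors
#'
#' @param variants Data frame carrying the predictor columns.
#' @param which Character vector of predictor column names, e.g.
#'   `c("ddg_p1", "ddg_p3")`.
#' @return Numeric vector: the row-wise arithmetic mean (kcal/mol).
#' @export
ensemble_ddg <- function(variants, which) {
  if (length(which) == 0) stop("'which' must name at least one predictor", call. = FALSE)
  miss <- setdiff(which, names(variants))
  if (length(miss)) {
    stop(sprintf("unknown predictor column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  unname(rowMeans(as.data.frame(variants)[, which, drop = FALSE]))
}

#' Stability class at a magnitude cutoff
#'
#' With the convention negative = destabilizing: `destabilizing` when
#' `ddg <= -cutoff`, `stabilizing` when `ddg >= +cutoff`, `neither` between.
#'
#' @param ddg Numeric vector (kcal/mol).
#' @param cutoff Positive magnitude (kcal/mol), e.g. 1, 1.1 or 2.
#' @return Character vector over stabilizing/destabilizing/neither.
#' @export
stability_class <- function(ddg, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    stop("cutoff must be a single positive magnitude in kcal/mol", call. = FALSE)
  }
  ifelse(ddg <= -cutoff, "destabilizing",
         ifelse(ddg >= cutoff, "stabilizing", "neither"))
}

#' Fraction of destabilizing variants
#'
#' The fraction of variants with ddG strictly below zero (any destabilization,
#' no magnitude cutoff).
#'
#' @param ddg Numeric vector of ddG values (kcal/mol), non-empty.
#' @return Fraction in \[0,1\].
#' @export
fraction_destabilizing <- function(ddg) {
  if (length(ddg) == 0) stop("empty ddG vector", call. = FALSE)
  mean(ddg < 0)
}
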