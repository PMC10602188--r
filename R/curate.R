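# Curation of raw ClinVar-style variant tables into two analysis datasets:
# a strict one holding only definitive benign/pathogenic calls and an
# extended superset that also admits likely_benign/likely_pathogenic.
# Filters are applied in a fixed, auditable order:
#   1. drop records with conflicting interpretations;
#   2. allele-frequency plausibility filter at 0.01;
#   3. per-gene 10% rule deciding dataset membership.
# The 10% denominator is the gene's total variant count reaching stage 3
# (all significance classes). Boundaries are literal: the gene rule is a
# strict ">", the frequency filter removes strictly below/above 0.01 so a
# frequency of exactly 0.01 is always retained, and records with a missing
# frequency are retained by default.

DEFINITIVE_CLASSES <- c("benign", "pathogenic")
EXTENDED_CLASSES <- c("benign", "likely_benign", "pathogenic", "likely_pathogenic")

.check_variant_table <- function(records) {
  need <- c("gene", "clin_sig")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop(sprintf("variant table lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  bad <- !(records$clin_sig %in% SIGNIFICANCE_CLASSES)
  if (any(bad)) {
    stop(sprintf("unrecognized clinical significance at row(s) %s",
                 paste(utils::head(which(bad), 5), collapse = ", ")), call. = FALSE)
  }
  invisible(records)
}

#' Remove variants with conflicting interpretations
#'
#' @param records Variant data frame with a `clin_sig` column.
#' @return The records with `clin_sig == "conflicting"` removed, order preserved.
#' @export
drop_conflicting <- function(records) {
  .check_variant_table(records)
  records[records$clin_sig != "conflicting", , drop = FALSE]
}

#' Allele-frequency plausibility filter
#'
#' Benign-side variants (benign, likely_benign) with population frequency
#' strictly below `cutoff` are removed, pathogenic-side variants strictly
#' above `cutoff` are removed; a frequency equal to the cutoff is retained
#' either way. VUS and conflicting records pass through untouched.
#'
#' @param records Variant data frame with `clin_sig` and `allele_freq`.
#' @param cutoff Frequency boundary, default 0.01.
#' @param retain_missing Keep records whose frequency is NA (default TRUE).
#' @return Filtered data frame, order preserved.
#' @export
apply_frequency_filter <- function(records, cutoff = 0.01, retain_missing = TRUE) {
  .check_variant_table(records)
  af <- records$allele_freq
  keep <- rep(TRUE, nrow(records))
  b <- .is_benign_class(records$clin_sig)
  p <- .is_pathogenic_class(records$clin_sig)
  keep[b] <- af[b] >= cutoff
  keep[p] <- af[p] <= cutoff
  keep[is.na(af) & (b | p)] <- retain_missing
  records[keep, , drop = FALSE]
}

#' Dataset membership of one gene under the 10% rule
#'
#' A gene enters the strict dataset (dataset 1) when its definitive fraction
#' (benign + pathogenic) / (all variants) is strictly greater than
#' `min_fraction`, and the extended dataset (dataset 2) when the fraction
#' with likely calls included in the numerator exceeds `min_fraction`.
#' Dataset-1 membership implies dataset-2 membership.
#'
#' @param records Variant data frame for a single gene.
#' @param min_fraction Strict threshold on the fraction, default 0.10.
#' @return One of `"dataset1"`, `"dataset2"`, `"excluded"`.
#' @export
assign_dataset <- function(records, min_fraction = 0.10) {
  .check_variant_table(records)
  if (nrow(records) == 0) stop("no records for gene", call. = FALSE)
  if (length(unique(records$gene)) != 1) {
    stop("assign_dataset() expects records of a single gene", call. = FALSE)
  }
  def_frac <- mean(records$clin_sig %in% DEFINITIVE_CLASSES)
  ext_frac <- mean(records$clin_sig %in% EXTENDED_CLASSES)
  if (def_frac > min_fraction) "dataset1"
  else if (ext_frac > min_fraction) "dataset2"
  else "excluded"
}

#' Build the strict and extended curated datasets
#'
#' Applies, in order: conflict exclusion, the allele-frequency filter, and
#' the per-gene 10% rule. Dataset 1 contains benign/pathogenic variants of
#' dataset-1 genes with `label` 0/1; dataset 2 is its superset over all
#' qualifying genes, additionally mapping likely_benign to 0 and
#' likely_pathogenic to 1. VUS records never reach the outputs.
#'
#' @param raw Raw variant data frame (see [generate_raw_variants()] for the
#'   schema; only gene, clin_sig and allele_freq are required).
#' @param min_fraction Per-gene strict threshold, default 0.10.
#' @param af_cutoff Frequency boundary, default 0.01.
#' @param retain_missing_af Keep NA frequencies (default TRUE).
#' @return Object of class `curation_result`: list with `dataset1`,
#'   `dataset2` (data frames with a `label` column) and `report`
#'   (a `curation_report` with per-stage removal counts, per-gene fractions
#'   and final class splits).
#' @examples
#' cfg <- generator_config(seed = 3, n_genes = 12)
#' cur <- build_datasets(generate_raw_variants(cfg))
#' cur
#' @export
build_datasets <- function(raw, min_fraction = 0.10, af_cutoff = 0.01,
                           retain_missing_af = TRUE) {
  .check_variant_table(raw)
  n_input <- nrow(raw)
  after_conflict <- drop_conflicting(raw)
  n_conflict <- n_input - nrow(after_conflict)
  after_freq <- apply_frequency_filter(after_conflict, cutoff = af_cutoff,
                                       retain_missing = retain_missing_af)
  n_freq <- nrow(after_conflict) - nrow(after_freq)

  genes <- unique(after_freq$gene)
  per_gene <- data.frame(gene = genes,
                         n = rep(NA_integer_, length(genes)),
                         definitive_fraction = rep(NA_real_, length(genes)),
                         extended_fraction = rep(NA_real_, length(genes)),
                         membership = rep(NA_character_, length(genes)),
                         stringsAsFactors = FALSE)
  membership <- setNames(character(length(genes)), genes)
  for (i in seq_along(genes)) {
    g <- after_freq[after_freq$gene == genes[i], , drop = FALSE]
    per_gene$n[i] <- nrow(g)
    per_gene$definitive_fraction[i] <- mean(g$clin_sig %in% DEFINITIVE_CLASSES)
    per_gene$extended_fraction[i] <- mean(g$clin_sig %in% EXTENDED_CLASSES)
    membership[i] <- assign_dataset(g, min_fraction)
    per_gene$membership[i] <- membership[i]
  }

  d1_genes <- genes[membership == "dataset1"]
  d2_genes <- genes[membership %in% c("dataset1", "dataset2")]
  dataset1 <- after_freq[after_freq$gene %in% d1_genes &
                           after_freq$clin_sig %in% DEFINITIVE_CLASSES, , drop = FALSE]
  dataset2 <- after_freq[after_freq$gene %in% d2_genes &
                           after_freq$clin_sig %in% EXTENDED_CLASSES, , drop = FALSE]
  dataset1$label <- as.integer(dataset1$clin_sig == "pathogenic")
  dataset2$label <- as.integer(.is_pathogenic_class(dataset2$clin_sig))
  rownames(dataset1) <- NULL
  rownames(dataset2) <- NULL

  report <- structure(list(
    n_input = n_input,
    removed_conflicting = n_conflict,
    removed_frequency = n_freq,
    n_after_filters = nrow(after_freq),
    per_gene = per_gene,
    dataset1_n = nrow(dataset1),
    dataset1_benign = sum(dataset1$label == 0),
    dataset1_pathogenic = sum(dataset1$label == 1),
    dataset2_n = nrow(dataset2),
    dataset2_benign = sum(dataset2$label == 0),
    dataset2_pathogenic = sum(dataset2$label == 1),
    min_fraction = min_fraction,
    af_cutoff = af_cutoff,
    retain_missing_af = retain_missing_af), class = "curation_report")

  structure(list(dataset1 = dataset1, dataset2 = dataset2, report = report),
            class = "curation_result")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Variant curation report\n")
  cat(sprintf("  input records:          %d\n", x$n_input))
  cat(sprintf("  removed (conflicting):  %d\n", x$removed_conflicting))
  cat(sprintf("  removed (frequency):    %d\n", x$removed_frequency))
  cat(sprintf("  reaching gene rule:     %d in %d genes\n", x$n_after_filters,
              nrow(x$per_gene)))
  cat(sprintf("  dataset 1: %d variants (%d benign / %d pathogenic)\n",
              x$dataset1_n, x$dataset1_benign, x$dataset1_pathogenic))
  cat(sprintf("  dataset 2: %d variants (%d benign / %d pathogenic)\n",
              x$dataset2_n, x$dataset2_benign, x$dataset2_pathogenic))
  invisible(x)
}

#' @export
print.curation_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
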