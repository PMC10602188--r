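# Evaluation mathematics: confusion counts under a threshold rule, MCC,
# ROC/AUC by two independent routes (threshold sweep with trapezoidal area,
# and the Mann-Whitney pairwise-concordance estimator -- the two must agree
# exactly), MCC-optimal threshold search, balanced resampling assessment,
# and stratified AUC tables.
#
# Score direction: pathogenicity increases as ddG decreases (more
# destabilizing) and as RSA decreases (more buried), so both are evaluated
# with the pathogenic_if_le rule and negative ddG cutoffs. A score equal to
# the threshold predicts pathogenic (closed boundary).

.orient <- function(scores, higher_is_pathogenic) {
  if (higher_is_pathogenic) -scores else scores
}

.check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have the same length", call. = FALSE)
  }
  if (length(scores) == 0) stop("empty input", call. = FALSE)
  if (any(!labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  invisible(NULL)
}

.check_two_classes <- function(labels) {
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
}

#' Confusion counts under a threshold rule
#'
#' @param scores Numeric scores (ddG, RSA, probabilities, ...).
#' @param labels 0 (benign) / 1 (pathogenic) of the same length.
#' @param threshold Decision threshold.
#' @param rule `"pathogenic_if_le"` (predict pathogenic iff score <=
#'   threshold; the default, matching ddG and RSA) or `"pathogenic_if_ge"`.
#' @return Object of class `confusion_counts`: list with tp, tn, fp, fn.
#' @export
confusion_counts <- function(scores, labels, threshold,
                             rule = c("pathogenic_if_le", "pathogenic_if_ge")) {
  rule <- match.arg(rule)
  .check_scores_labels(scores, labels)
  pred <- if (rule == "pathogenic_if_le") scores <= threshold else scores >= threshold
  structure(list(tp = sum(pred & labels == 1),
                 tn = sum(!pred & labels == 0),
                 fp = sum(pred & labels == 0),
                 fn = sum(!pred & labels == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: tp=%d tn=%d fp=%d fn=%d (mcc=%.3f)\n",
              x$tp, x$tn, x$fp, x$fn, mcc(x)))
  invisible(x)
}

#' Rates derived from confusion counts
#'
#' @param counts A `confusion_counts` object.
#' @return Named vector: tpr, fpr, fnr, accuracy (tpr + fnr = 1 exactly).
#' @export
confusion_rates <- function(counts) {
  with(counts, c(tpr = tp / (tp + fn),
                 fpr = fp / (fp + tn),
                 fnr = fn / (tp + fn),
                 accuracy = (tp + tn) / (tp + tn + fp + fn)))
}

#' Matthews correlation coefficient
#'
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' convention that a zero denominator factor yields 0.
#'
#' @param counts A `confusion_counts` object, or tp when the four counts are
#'   given positionally/by name.
#' @param tn,fp,fn Counts when not passing a `confusion_counts` object.
#' @return Value in \[-1, 1\].
#' @export
mcc <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (inherits(counts, "confusion_counts") || (is.list(counts))) {
    tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  } else {
    tp <- counts
  }
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (d == 0) return(0)
  (tp * tn - fp * fn) / sqrt(d)
}

#' AUC by pairwise concordance (Mann-Whitney estimator)
#'
#' The mean over all (pathogenic, benign) pairs of 1 if the pathogenic
#' variant is scored more pathogenic, 0.5 if tied. Equals the trapezoidal
#' area under [roc_curve()] exactly.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @param higher_is_pathogenic FALSE (default) when low scores indicate
#'   pathogenicity (ddG, RSA); TRUE for e.g. predicted probabilities.
#' @return AUC in \[0, 1\].
#' @export
auc_concordance <- function(scores, labels, higher_is_pathogenic = FALSE) {
  .check_scores_labels(scores, labels)
  .check_two_classes(labels)
  x <- .orient(scores, !higher_is_pathogenic)  # internally: higher = pathogenic
  r <- rank(x, ties.method = "average")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over every unique score plus -Inf/+Inf
#' sentinels under the pathogenic_if_le rule (scores are negated first when
#' `higher_is_pathogenic`), and integrates the area by the trapezoidal rule.
#'
#' @inheritParams auc_concordance
#' @return Object of class `roc_sweep`: list with `points` (data frame of
#'   threshold, tpr, fpr, sorted by threshold, endpoints (0,0) and (1,1)
#'   included) and `auc`.
#' @export
roc_curve <- function(scores, labels, higher_is_pathogenic = FALSE) {
  .check_scores_labels(scores, labels)
  .check_two_classes(labels)
  x <- .orient(scores, higher_is_pathogenic)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  o <- order(x)
  xs <- x[o]; ys <- labels[o]
  u <- unique(xs)
  idx <- match(xs, u)
  n_at <- tabulate(idx, length(u))
  pos_at <- tabulate(idx[ys == 1], length(u))
  tpr <- c(0, cumsum(pos_at) / n1, 1)
  fpr <- c(0, cumsum(n_at - pos_at) / n0, 1)
  thr <- c(-Inf, u, Inf)
  pts <- data.frame(threshold = thr, tpr = tpr, fpr = fpr)
  if (higher_is_pathogenic) {
    # report thresholds on the input scale, keep the frame threshold-sorted
    pts$threshold <- -pts$threshold
    pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
    rownames(pts) <- NULL
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = pts,
                 auc = auc, higher_is_pathogenic = higher_is_pathogenic),
            class = "roc_sweep")
}

#' @export
print.roc_sweep <- function(x, ...) {
  cat(sprintf("ROC sweep: %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_sweep <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' MCC-optimal decision threshold
#'
#' Exhaustive scan over candidate thresholds: the midpoints between
#' consecutive sorted unique scores plus a below-minimum and an above-maximum
#' sentinel. Ties in MCC are broken by the smallest `|threshold|`, then by
#' the smaller threshold.
#'
#' @inheritParams confusion_counts
#' @return List with `threshold` and `mcc`.
#' @export
optimal_threshold <- function(scores, labels,
                              rule = c("pathogenic_if_le", "pathogenic_if_ge")) {
  rule <- match.arg(rule)
  .check_scores_labels(scores, labels)
  .check_two_classes(labels)
  x <- if (rule == "pathogenic_if_le") scores else -scores
  u <- sort(unique(x))
  cands <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  mccs <- vapply(cands, function(t) {
    mcc(confusion_counts(x, labels, t, "pathogenic_if_le"))
  }, numeric(1))
  if (rule == "pathogenic_if_ge") cands <- -cands
  best <- which(mccs == max(mccs))
  best <- best[order(abs(cands[best]), cands[best])][1]
  list(threshold = cands[best], mcc = mccs[best])
}

#' Balanced resampling assessment of a fixed classifier
#'
#' Repeatedly draws N benign and N pathogenic variants uniformly without
#' replacement, with `N = floor(0.5 * min(n_benign, n_pathogenic))`, and
#' summarizes TPR, FPR, FNR and accuracy over the repeats. The classifier is
#' given as its predicted labels on the full population (a fixed threshold
#' rule or a fitted model applied once), so a repeat only selects rows.
#'
#' @param predicted 0/1 predicted labels for every variant.
#' @param labels 0/1 true labels.
#' @param n_repeats Number of resampling repeats, default 100.
#' @param seed RNG seed for the draws.
#' @return Object of class `resampling_summary`: data frame with mean and sd
#'   of tpr, fpr, fnr and accuracy, plus `n_repeats` and `n_per_class`
#'   attributes.
#' @export
balanced_resample_evaluate <- function(predicted, labels, n_repeats = 100, seed = 1) {
  .check_scores_labels(predicted, labels)
  .check_two_classes(labels)
  if (any(!predicted %in% c(0, 1))) stop("predicted must be 0/1", call. = FALSE)
  idx1 <- which(labels == 1)
  idx0 <- which(labels == 0)
  n_draw <- floor(0.5 * min(length(idx0), length(idx1)))
  if (n_draw == 0) stop("insufficient data: balanced sample size is 0", call. = FALSE)
  with_seed(seed, {
    mets <- matrix(NA_real_, n_repeats, 4,
                   dimnames = list(NULL, c("tpr", "fpr", "fnr", "accuracy")))
    for (r in seq_len(n_repeats)) {
      take <- c(sample(idx1, n_draw), sample(idx0, n_draw))
      cc <- structure(list(
        tp = sum(predicted[take] == 1 & labels[take] == 1),
        tn = sum(predicted[take] == 0 & labels[take] == 0),
        fp = sum(predicted[take] == 1 & labels[take] == 0),
        fn = sum(predicted[take] == 0 & labels[take] == 1)),
        class = "confusion_counts")
      mets[r, ] <- confusion_rates(cc)
    }
    out <- data.frame(metric = colnames(mets),
                      mean = colMeans(mets),
                      sd = apply(mets, 2, sd),
                      row.names = NULL)
    structure(out, class = c("resampling_summary", "data.frame"),
              n_repeats = n_repeats, n_per_class = n_draw)
  })
}

#' @export
print.resampling_summary <- function(x, ...) {
  cat(sprintf("Balanced resampling: %d repeats, N = %d per class\n",
              attr(x, "n_repeats"), attr(x, "n_per_class")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Stratified AUC table
#'
#' AUC of one score within each level of a grouping column, keeping only
#' groups whose size strictly exceeds `min_count` and that contain both
#' classes.
#'
#' @param variants Data frame with the score, label and grouping columns.
#' @param group_col Name of the grouping column (a substitution-category
#'   axis or the functional class).
#' @param score_col Name of the score column.
#' @param higher_is_pathogenic Passed to [auc_concordance()].
#' @param min_count Strict group-size threshold, default 100.
#' @param label_col Name of the 0/1 label column, default "label".
#' @return Data frame with columns group, n, auc (possibly zero rows).
#' @export
stratified_auc <- function(variants, group_col, score_col,
                           higher_is_pathogenic = FALSE, min_count = 100,
                           label_col = "label") {
  for (col in c(group_col, score_col, label_col)) {
    if (!col %in% names(variants)) {
      stop(sprintf("column '%s' not found", col), call. = FALSE)
    }
  }
  keep <- !is.na(variants[[group_col]])
  variants <- variants[keep, , drop = FALSE]
  out <- list()
  for (g in sort(unique(variants[[group_col]]))) {
    sub <- variants[variants[[group_col]] == g, , drop = FALSE]
    labs <- sub[[label_col]]
    if (nrow(sub) <= min_count || length(unique(labs)) < 2) next
    out[[g]] <- data.frame(group = g, n = nrow(sub),
                           auc = auc_concordance(sub[[score_col]], labs,
                                                 higher_is_pathogenic),
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(group = character(0), n = integer(0), auc = numeric(0)))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
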