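test_that("confusion counts implement the closed-boundary threshold rule", {
  cc <- confusion_counts(c(-2.0, -0.5), c(1, 0), -1.1, "pathogenic_if_le")
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  cc2 <- confusion_counts(rep(-3, 5), rep(1, 5), -1, "pathogenic_if_le")
  expect_equal(cc2$tp, 5); expect_equal(cc2$fn, 0)
  cc3 <- confusion_counts(rep(-3, 4), rep(0, 4), -1, "pathogenic_if_le")
  expect_equal(cc3$fp, 4)
  # score equal to threshold predicts pathogenic
  expect_equal(confusion_counts(0.5, 1, 0.5, "pathogenic_if_le")$tp, 1)
  expect_error(confusion_counts(1:3, c(0, 1), 0), "same length")
})

test_that("rates satisfy their identities for arbitrary counts", {
  set.seed(1)
  for (i in 1:20) {
    n <- 50
    cc <- confusion_counts(runif(n), rbinom(n, 1, 0.5), runif(1))
    r <- confusion_rates(cc)
    expect_equal(unname(r["tpr"] + r["fnr"]), 1)
    expect_equal(unname(r["accuracy"]),
                 (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn))
  }
})

test_that("MCC matches hand-evaluated values and its symmetries", {
  expect_equal(mcc(50, 50, 0, 0), 1.0)
  expect_equal(mcc(25, 25, 25, 25), 0.0)
  expect_equal(mcc(40, 30, 20, 10), 1000 / sqrt(60 * 50 * 50 * 40))
  expect_equal(mcc(0, 0, 0, 10), 0)  # degenerate denominator convention
  set.seed(2)
  for (i in 1:20) {
    v <- rpois(4, 20)
    expect_equal(mcc(v[1], v[2], v[3], v[4]), mcc(v[2], v[1], v[4], v[3]))
    expect_true(abs(mcc(v[1], v[2], v[3], v[4])) <= 1)
  }
})

test_that("concordance AUC matches pair enumeration and handles ties", {
  expect_equal(auc_concordance(c(-3, -2, 0, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_concordance(rep(0.3, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # pairs: (-3,-2) ok, (-3,0) ok, (-1,-2) wrong, (-1,0) ok -> 3/4
  expect_equal(auc_concordance(c(-3, -1, -2, 0), c(1, 1, 0, 0)), 0.75)
  expect_error(auc_concordance(1:3, c(1, 1, 1)), "both classes")
})

test_that("concordance AUC agrees with an established ROC implementation", {
  set.seed(3)
  for (i in 1:10) {
    n <- 80
    scores <- round(rnorm(n), 1)  # force ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ours <- auc_concordance(scores, labels, higher_is_pathogenic = TRUE)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("the ROC sweep has proper endpoints and reverses with the direction flag", {
  r <- roc_curve(c(-3, -2, 0, 1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  expect_true(any(r$points$fpr == 0 & r$points$tpr == 1))
  expect_equal(r$points[1, c("tpr", "fpr")], data.frame(tpr = 0, fpr = 0),
               ignore_attr = TRUE)
  expect_equal(r$points[nrow(r$points), c("tpr", "fpr")],
               data.frame(tpr = 1, fpr = 1), ignore_attr = TRUE)
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_true(all(diff(r$points$fpr) >= 0))
  set.seed(4)
  scores <- rnorm(60)  # tie-free
  labels <- rbinom(60, 1, 0.5)
  a1 <- roc_curve(scores, labels, higher_is_pathogenic = FALSE)$auc
  a2 <- roc_curve(scores, labels, higher_is_pathogenic = TRUE)$auc
  expect_equal(a1 + a2, 1)
})

test_that("the optimal threshold is found exhaustively with documented tie-breaks", {
  ot <- optimal_threshold(c(-3, -2, 0, 1), c(1, 1, 0, 0))
  expect_equal(ot$threshold, -1.0)  # midpoint of -2 and 0
  expect_equal(ot$mcc, 1.0)
  # translation equivariance
  set.seed(5)
  scores <- rnorm(100); labels <- rbinom(100, 1, 0.5)
  base <- optimal_threshold(scores, labels)
  shifted <- optimal_threshold(scores + 2.5, labels)
  expect_equal(shifted$threshold, base$threshold + 2.5)
  expect_equal(shifted$mcc, base$mcc)
  expect_error(optimal_threshold(1:4, rep(1, 4)), "both classes")
})

test_that("label permutation keeps the optimal MCC near chance on average", {
  set.seed(6)
  scores <- rnorm(200)
  labels <- rep(c(0, 1), each = 100)
  best <- replicate(100, optimal_threshold(scores, sample(labels))$mcc)
  expect_lt(mean(best), 0.25)
})

test_that("balanced resampling uses N = floor(half the minority class)", {
  labels <- rep(c(0, 1), c(10, 40))
  res <- balanced_resample_evaluate(rep(1, 50), labels, n_repeats = 5)
  expect_equal(attr(res, "n_per_class"), 5)
  expect_error(balanced_resample_evaluate(c(1, 0), c(1, 0), 5),
               "insufficient")
})

test_that("resampling means match the fixed-rule population expectation", {
  set.seed(7)
  labels <- rep(c(0, 1), each = 300)
  predicted <- as.integer(runif(600) < ifelse(labels == 1, 0.8, 0.3))
  pop_tpr <- mean(predicted[labels == 1])
  pop_fpr <- mean(predicted[labels == 0])
  res <- balanced_resample_evaluate(predicted, labels, n_repeats = 100, seed = 8)
  for (m in c("tpr", "fpr")) {
    pop <- if (m == "tpr") pop_tpr else pop_fpr
    row <- res[res$metric == m, ]
    expect_lt(abs(row$mean - pop), 3 * row$sd / sqrt(100) + 1e-12)
  }
})

test_that("stratified AUC applies the strict group-size rule", {
  d <- generate_annotated_variants(generator_config(seed = 10), 150, 150)
  d$grp <- rep(c("a", "b"), c(100, 200))  # group a has exactly min_count
  out <- stratified_auc(d, "grp", "ddg_p1", min_count = 100)
  expect_equal(out$group, "b")
  d$one <- "all"
  out2 <- stratified_auc(d, "one", "ddg_p1", min_count = 100)
  expect_equal(out2$auc, auc_concordance(d$ddg_p1, d$label))
  expect_equal(nrow(stratified_auc(d, "one", "ddg_p1", min_count = 1000)), 0)
})
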