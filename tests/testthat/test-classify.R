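test_that("the ridge-logistic solver reaches the separable and shrinkage limits", {
  x <- matrix(c(-3, -2.5, -2, 1, 1.5, 2), ncol = 1)
  y <- c(1, 1, 1, 0, 0, 0)
  fit <- fit_logistic(x, y, c = 1e6)
  acc <- mean((predict(fit, x) >= 0.5) == y)
  expect_equal(acc, 1.0)
  # c -> 0+: weights shrink, predictions approach the class balance
  small <- fit_logistic(x, y, c = 1e-8)
  expect_lt(abs(coef(small)[2]), 1e-4)
  expect_true(all(abs(predict(small, x) - mean(y)) < 0.01))
  expect_error(fit_logistic(x, rep(1, 6), 1), "both classes")
  expect_error(fit_logistic(matrix(c(1, NA), 2), c(0, 1), 1), "non-finite")
  expect_error(fit_logistic(x, y, -1), "c must be")
})

test_that("the unpenalized limit reproduces glm and glmnet agrees at finite c", {
  set.seed(11)
  n <- 300
  x <- cbind(rnorm(n), rnorm(n))
  y <- rbinom(n, 1, plogis(0.5 + x[, 1] - 0.7 * x[, 2]))
  ours <- coef(fit_logistic(x, y, c = 1e8))
  ref <- coef(glm(y ~ x, family = binomial))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-5)
  # independent penalized fit: glmnet ridge with lambda = 1/(n*c)
  c_val <- 2
  g <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                      lambda = 1 / (n * c_val), standardize = FALSE,
                      thresh = 1e-14)
  ours_pen <- coef(fit_logistic(x, y, c = c_val))
  expect_equal(unname(ours_pen), as.numeric(coef(g)), tolerance = 1e-3)
})

test_that("duplicating the data while doubling the penalty leaves the fit unchanged", {
  set.seed(12)
  x <- matrix(rnorm(80), ncol = 2)
  y <- rbinom(40, 1, 0.5); y[1:2] <- 0:1
  # doubling every observation doubles the log-likelihood, so the ridge
  # penalty must double too (c -> c/2) for the optimum to be unchanged
  a <- coef(fit_logistic(x, y, c = 1))
  b <- coef(fit_logistic(rbind(x, x), c(y, y), c = 0.5))
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("c selection is deterministic and honours a one-point grid", {
  d <- generate_annotated_variants(generator_config(seed = 13), 150, 150)
  x <- scale(cbind(d$ddg_p1, d$rsa))
  one <- split_protocol(repeats = 1, c_grid = 0.5, seed = 1)
  expect_equal(select_c(x, d$label, one)$c, 0.5)
  p <- quick_protocol(seed = 4)
  expect_equal(select_c(x, d$label, p)$c, select_c(x, d$label, p)$c)
})

test_that("a pure-noise feature does not degrade the selected model", {
  cfg <- generator_config(seed = 14)
  d <- generate_annotated_variants(cfg, 1200, 1200)
  d$rsa <- runif(nrow(d))  # RSA carries no signal here
  fit <- fit_pathogenicity(d, ddg = "ddg_p1", rsa = TRUE,
                           protocol = quick_protocol(seed = 2))
  ddg_auc <- auc_concordance(fit$test$x[, "ddg"], fit$test$y)
  model_auc <- fit$metrics$auc[fit$metrics$portion == "test"]
  expect_lt(abs(model_auc - ddg_auc), 0.03)
})

test_that("predicted probabilities are proper and monotone in the weight direction", {
  d <- generate_annotated_variants(generator_config(seed = 15), 400, 400)
  fit <- fit_pathogenicity(d, ddg = "ddg_p1", protocol = quick_protocol(seed = 3))
  p <- predict(fit, d)
  expect_true(all(p > 0 & p < 1))
  w <- coef(fit)
  grid <- data.frame(ddg_p1 = seq(-4, 2, length.out = 20), rsa = 0.4)
  pg <- predict(fit, grid)
  expect_true(all(diff(pg) * sign(w[["ddg"]]) >= 0))
  expect_equal(predict(fit, d, type = "class"), as.integer(p >= 0.5))
})

test_that("training metrics dominate held-out metrics on average over seeds", {
  diffs <- vapply(1:8, function(s) {
    d <- generate_annotated_variants(generator_config(seed = 100 + s), 200, 200)
    fit <- fit_pathogenicity(d, ddg = "ddg_p1",
                             protocol = split_protocol(repeats = 1,
                                                       c_grid = c(0.1, 10),
                                                       seed = s))
    m <- fit$metrics
    m$auc[m$portion == "train"] - m$auc[m$portion == "test"]
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("held-out accuracy recovers the generator's Bayes-level separation", {
  cfg <- generator_config(seed = 16)
  d <- generate_annotated_variants(cfg, 2000, 2000)
  fit <- fit_pathogenicity(d, ddg = "ddg_p1", rsa = FALSE,
                           protocol = quick_protocol(seed = 5))
  # single-feature model cannot beat, and should approach, the analytic AUC
  test_auc <- fit$metrics$auc[fit$metrics$portion == "test"]
  expect_lt(abs(test_auc - analytic_auc(cfg, "ddg_p1")), 0.03)
})
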