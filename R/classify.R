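# Two-feature (ddG, RSA) L2-regularized logistic classifier.
#
# The fit minimizes the negative binomial log-likelihood plus a ridge
# penalty 1/(2c) * ||w||^2 on the feature weights (the intercept is not
# penalized); c is the usual inverse regularization strength. The solver is
# damped Newton/IRLS with a documented convergence tolerance (max absolute
# coefficient update < 1e-10), which is deterministic given the data and c.
#
# The training protocol mirrors the study design: balance the classes by a
# seeded subsample of the majority class, split 80/20 stratified by label,
# select c on the training portion by repeated stratified 5-fold
# cross-validation maximizing mean validation AUC (ties -> smaller c,
# i.e. stronger regularization), refit on the full training portion, and
# report AUC (pairwise concordance of predicted probabilities) and MCC at
# probability threshold 0.5 on both portions. Features are standardized
# with training-portion statistics only.

#' Cross-validation and split protocol
#'
#' @param train_fraction Training share of the balanced data, default 0.8.
#' @param folds Cross-validation folds, default 5 (must be >= 2).
#' @param repeats Repetitions of the CV with reshuffled folds, default 100.
#' @param c_grid Candidate inverse regularization strengths; default 13
#'   points log-spaced over \[1e-3, 1e3\].
#' @param seed Seed controlling balancing, the split and fold shuffles.
#' @return Object of class `split_protocol`.
#' @export
split_protocol <- function(train_fraction = 0.8, folds = 5, repeats = 100,
                           c_grid = 10^seq(-3, 3, length.out = 13), seed = 1) {
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (length(c_grid) < 1) stop("c_grid must be non-empty", call. = FALSE)
  if (any(c_grid <= 0)) stop("c values must be > 0", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(train_fraction = train_fraction, folds = as.integer(folds),
                 repeats = as.integer(repeats), c_grid = sort(c_grid),
                 seed = as.integer(seed)),
            class = "split_protocol")
}

#' L2-regularized logistic regression at a fixed c
#'
#' Fits by damped Newton/IRLS the model minimizing
#' `-loglik + 1/(2c) * ||w||^2` (intercept unpenalized).
#'
#' @param x Numeric feature matrix (rows = variants).
#' @param y 0/1 labels, both classes present.
#' @param c Inverse regularization strength, > 0.
#' @param tol Convergence tolerance on the max absolute coefficient update.
#' @param max_iter Newton iteration cap.
#' @return Object of class `ridge_logit` with elements `coefficients`
#'   (intercept first), `c`, `converged`, `iterations`.
#' @export
fit_logistic <- function(x, y, c, tol = 1e-10, max_iter = 100) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (length(y) != nrow(x)) stop("x and y sizes differ", call. = FALSE)
  .check_two_classes(y)
  if (!is.numeric(c) || length(c) != 1 || c <= 0) stop("c must be > 0", call. = FALSE)
  X <- cbind(`(intercept)` = 1, x)
  p <- ncol(X)
  pen <- c(0, rep(1 / c, p - 1))  # intercept unpenalized
  beta <- numeric(p)
  obj <- function(b) {
    eta <- drop(X %*% b)
    # numerically safe -loglik: log(1+exp(eta)) - y*eta
    sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta) +
      sum(pen * b^2) / 2
  }
  f <- obj(beta)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    mu <- plogis(drop(X %*% beta))
    g <- drop(crossprod(X, mu - y)) + pen * beta
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + diag(pen, p)
    step <- solve(H, g)
    # damped update: halve until the objective does not increase
    lam <- 1
    repeat {
      cand <- beta - lam * step
      fc <- obj(cand)
      if (fc <= f + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    moved <- max(abs(beta - cand))
    beta <- cand
    f <- fc
    if (moved < tol) { converged <- TRUE; break }
  }
  structure(list(coefficients = setNames(beta, colnames(X)), c = c,
                 converged = converged, iterations = it),
            class = "ridge_logit")
}

#' @export
coef.ridge_logit <- function(object, ...) object$coefficients

#' @export
predict.ridge_logit <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- cbind(1, as.matrix(newdata))
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else plogis(eta)
}

.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lab in unique(y)) {
    idx <- sample(which(y == lab))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Select the regularization strength by repeated cross-validation
#'
#' For each candidate c, runs `protocol$repeats` repetitions of stratified
#' `protocol$folds`-fold cross-validation (fold assignments reshuffled each
#' repetition) and averages the validation AUC of the predicted
#' probabilities. Returns the c with the best mean AUC; ties go to the
#' smaller c.
#'
#' @param x Feature matrix (already standardized by the caller).
#' @param y 0/1 labels.
#' @param protocol A [split_protocol()].
#' @return List with `c` (selected value) and `cv_auc` (named mean
#'   validation AUC per candidate).
#' @export
select_c <- function(x, y, protocol = split_protocol()) {
  x <- as.matrix(x)
  .check_two_classes(y)
  with_seed(protocol$seed + 11L, {
    grid <- protocol$c_grid
    mean_auc <- setNames(numeric(length(grid)), format(grid))
    aucs <- matrix(NA_real_, protocol$repeats * protocol$folds, length(grid))
    row <- 0
    for (r in seq_len(protocol$repeats)) {
      fold <- .stratified_folds(y, protocol$folds)
      for (k in seq_len(protocol$folds)) {
        row <- row + 1
        tr <- fold != k
        for (j in seq_along(grid)) {
          fit <- fit_logistic(x[tr, , drop = FALSE], y[tr], grid[j])
          prob <- predict(fit, x[!tr, , drop = FALSE])
          aucs[row, j] <- auc_concordance(prob, y[!tr], higher_is_pathogenic = TRUE)
        }
      }
    }
    mean_auc[] <- colMeans(aucs)
    best <- which(mean_auc == max(mean_auc))[1]  # grid sorted: ties -> smaller c
    list(c = grid[best], cv_auc = mean_auc)
  })
}

#' Fit the two-feature pathogenicity classifier
#'
#' The package's central fitting function. Builds the feature matrix
#' (ensemble-averaged \eqn{\Delta\Delta G} and, optionally, RSA), balances
#' the classes by a seeded subsample of the majority class, splits 80/20
#' stratified by label, selects the regularization strength with
#' [select_c()], refits on the training portion, and reports AUC and MCC
#' (probability threshold 0.5) for both portions.
#'
#' @param data Data frame of annotated variants with the predictor columns,
#'   `rsa` and a 0/1 label column.
#' @param ddg Character vector of ddG predictor columns to average, e.g.
#'   `"ddg_p1"` or `c("ddg_p1", "ddg_p3")`.
#' @param rsa Include RSA as a second feature (default TRUE).
#' @param label_col Name of the label column, default "label".
#' @param protocol A [split_protocol()].
#' @return Object of class `pathogenicity_fit` with the fitted
#'   `ridge_logit`, the selected c, standardization constants, train/test
#'   metrics, and the held-out split for inspection. Methods: `print`,
#'   `summary`, `coef`, `predict`.
#' @examples
#' cfg <- generator_config(seed = 5)
#' d <- generate_annotated_variants(cfg, 300, 300)
#' fit <- fit_pathogenicity(d, ddg = "ddg_p1",
#'                          protocol = split_protocol(repeats = 2,
#'                                                    c_grid = c(0.1, 1, 10)))
#' fit
#' @export
fit_pathogenicity <- function(data, ddg = "ddg_p1", rsa = TRUE,
                              label_col = "label", protocol = split_protocol()) {
  if (!label_col %in% names(data)) {
    stop(sprintf("column '%s' not found", label_col), call. = FALSE)
  }
  y_all <- data[[label_col]]
  if (any(is.na(y_all))) stop("labels must be 0/1 without NA", call. = FALSE)
  .check_two_classes(y_all)
  feat <- data.frame(ddg = ensemble_ddg(data, ddg))
  if (isTRUE(rsa)) {
    if (!"rsa" %in% names(data)) stop("column 'rsa' not found", call. = FALSE)
    feat$rsa <- data$rsa
  }
  if (any(!is.finite(as.matrix(feat)))) stop("non-finite feature values", call. = FALSE)

  with_seed(protocol$seed + 7L, {
    # balance: seeded subsample of the majority class, without replacement
    idx1 <- which(y_all == 1); idx0 <- which(y_all == 0)
    n_bal <- min(length(idx0), length(idx1))
    if (n_bal < 2 * protocol$folds) {
      stop("insufficient data after class balancing", call. = FALSE)
    }
    keep <- c(sample(idx1, n_bal), sample(idx0, n_bal))
    x_bal <- as.matrix(feat)[keep, , drop = FALSE]
    y_bal <- y_all[keep]

    # stratified 80/20 split
    test <- logical(length(y_bal))
    for (lab in 0:1) {
      idx <- sample(which(y_bal == lab))
      n_te <- round((1 - protocol$train_fraction) * length(idx))
      test[idx[seq_len(n_te)]] <- TRUE
    }
    x_tr <- x_bal[!test, , drop = FALSE]; y_tr <- y_bal[!test]
    x_te <- x_bal[test, , drop = FALSE]; y_te <- y_bal[test]

    # standardize with training-portion statistics only
    center <- colMeans(x_tr)
    scale_ <- apply(x_tr, 2, sd)
    scale_[scale_ == 0] <- 1
    std <- function(m) sweep(sweep(m, 2, center), 2, scale_, "/")
    z_tr <- std(x_tr); z_te <- std(x_te)

    sel <- select_c(z_tr, y_tr, protocol)
    model <- fit_logistic(z_tr, y_tr, sel$c)

    metrics_of <- function(z, y) {
      prob <- predict(model, z)
      cc <- confusion_counts(prob, y, 0.5, "pathogenic_if_ge")
      c(auc = auc_concordance(prob, y, higher_is_pathogenic = TRUE),
        mcc = mcc(cc))
    }
    tr_m <- metrics_of(z_tr, y_tr)
    te_m <- metrics_of(z_te, y_te)

    structure(list(model = model, c = sel$c, cv_auc = sel$cv_auc,
                   center = center, scale = scale_,
                   features = list(ddg = ddg, rsa = isTRUE(rsa)),
                   metrics = data.frame(
                     portion = c("train", "test"),
                     n = c(length(y_tr), length(y_te)),
                     auc = c(tr_m["auc"], te_m["auc"]),
                     mcc = c(tr_m["mcc"], te_m["mcc"]),
                     row.names = NULL),
                   train = list(x = x_tr, y = y_tr),
                   test = list(x = x_te, y = y_te),
                   protocol = protocol,
                   call = match.call()),
              class = "pathogenicity_fit")
  })
}

.pathfit_features <- function(object, newdata) {
  if (is.matrix(newdata)) return(newdata)
  feat <- data.frame(ddg = ensemble_ddg(newdata, object$features$ddg))
  if (object$features$rsa) feat$rsa <- newdata$rsa
  as.matrix(feat)
}

#' Predict pathogenicity probabilities
#'
#' @param object A `pathogenicity_fit`.
#' @param newdata Data frame with the predictor columns used at fit time
#'   (or a raw feature matrix in ddg\[, rsa\] order).
#' @param type `"response"` (probability of pathogenic), `"link"`, or
#'   `"class"` (0/1 at probability 0.5).
#' @param ... Unused.
#' @export
predict.pathogenicity_fit <- function(object, newdata,
                                      type = c("response", "link", "class"), ...) {
  type <- match.arg(type)
  x <- .pathfit_features(object, newdata)
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  if (type == "class") {
    as.integer(predict(object$model, z) >= 0.5)
  } else {
    predict(object$model, z, type = if (type == "link") "link" else "response")
  }
}

#' @export
coef.pathogenicity_fit <- function(object, ...) coef(object$model)

#' @export
print.pathogenicity_fit <- function(x, ...) {
  cat("Two-feature pathogenicity classifier (L2 logistic regression)\n")
  cat(sprintf("  ddG feature: mean of %s%s\n", paste(x$features$ddg, collapse = ", "),
              if (x$features$rsa) "; RSA included" else ""))
  cat(sprintf("  selected c = %g (%d-fold CV x %d)\n", x$c, x$protocol$folds,
              x$protocol$repeats))
  print.data.frame(x$metrics, digits = 3)
  invisible(x)
}

#' @export
summary.pathogenicity_fit <- function(object, ...) {
  print(object)
  cat("\nCoefficients (standardized features):\n")
  print(coef(object))
  cat("\nMean validation AUC over the c grid:\n")
  print(round(object$cv_auc, 4))
  invisible(object)
}
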