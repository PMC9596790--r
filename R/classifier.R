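#' Assemble the conduction-classification feature table
#'
#' One row per (profile, fibrosis, drug) simulation: the nine profile
#' modifiers, the three drug-induced conductance factors `G_i / G_0` (1.0
#' when no drug), the fibrosis percentage, and the binary label
#' (`conduct` = 1, `block` = 0) taken from the biomarker table's conducted
#' flag.
#'
#' @param biomarker_table `data.frame` with `profile_id`, `fibrosis`
#'   (percent), `drug` (name or "none") and `conducted`.
#' @param profiles `data.frame` with `profile_id` and the nine parameter
#'   columns.
#' @return `data.frame` of features with a `label` factor
#'   (`block`/`conduct`).
#' @export
assemble_features <- function(biomarker_table, profiles) {
  need <- c("profile_id", "fibrosis", "drug", "conducted")
  miss <- setdiff(need, names(biomarker_table))
  if (length(miss) > 0)
    stop("biomarker table missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(biomarker_table$conducted)))
    stop("missing conduction label for run(s): ",
         paste(which(is.na(biomarker_table$conducted)), collapse = ", "))
  idx <- match(biomarker_table$profile_id, profiles$profile_id)
  if (any(is.na(idx))) stop("unknown profile_id in biomarker table")
  pf <- profiles[idx, profile_parameter_names(), drop = FALSE]
  fac <- t(vapply(biomarker_table$drug,
                  function(d) drug_factors(drug_spec(d)), numeric(3)))
  out <- cbind(pf,
               f_IKr = fac[, "IKr"], f_ICaL = fac[, "ICaL"],
               f_INa = fac[, "INa"],
               fibrosis = biomarker_table$fibrosis)
  out$label <- factor(ifelse(biomarker_table$conducted, "conduct", "block"),
                      levels = c("block", "conduct"))
  rownames(out) <- NULL
  out
}

feature_columns <- function() {
  c(profile_parameter_names(), "f_IKr", "f_ICaL", "f_INa", "fibrosis")
}

## Stratified 80:20 split: per-class test counts sum to floor(0.2 n)
## (remainder to train), preserving the class ratio within one row.
stratified_split <- function(label, test_frac = 0.2, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- length(label)
  n_test <- floor(test_frac * n)
  cls <- levels(label)
  raw <- test_frac * table(label)[cls]
  base <- floor(raw)
  extra <- n_test - sum(base)
  if (extra > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  test_idx <- unlist(lapply(cls, function(cl) {
    ids <- which(label == cl)
    sample(ids, base[[cl]])
  }), use.names = FALSE)
  list(train = setdiff(seq_len(n), test_idx), test = sort(test_idx))
}

#' Wilson score confidence interval for a proportion
#'
#' @param k successes, `n` trials, `conf` confidence level.
#' @param n number of trials.
#' @param conf confidence level.
#' @return `c(lower, upper)` proportions.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity, specificity, positive/negative predictive value and accuracy
#' (percent) with Wilson confidence intervals. Ratios with a zero
#' denominator are reported as `NA` (not applicable), never as 0.
#'
#' @param tp,fp,tn,fn confusion-matrix counts (conduction = positive class).
#' @param conf confidence level for the intervals.
#' @return `data.frame` with metric, value (%), lower, upper.
#' @export
classification_metrics <- function(tp, fp, tn, fn, conf = 0.95) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  vals <- c(sensitivity = ratio(tp, tp + fn),
            specificity = ratio(tn, tn + fp),
            ppv = ratio(tp, tp + fp),
            npv = ratio(tn, tn + fn),
            accuracy = (tp + tn) / (tp + fp + tn + fn))
  dens <- c(tp + fn, tn + fp, tp + fp, tn + fn, tp + fp + tn + fn)
  ci <- t(mapply(function(v, d) {
    if (is.na(v)) c(NA_real_, NA_real_) else wilson_ci(round(v * d), d, conf)
  }, vals, dens))
  data.frame(metric = names(vals), value = 100 * unname(vals),
             lower = 100 * ci[, 1], upper = 100 * ci[, 2])
}

## Orientation-safe AUC: `scores` must be increasing with P(conduct).
auc_from_scores <- function(truth, scores) {
  r <- pROC::roc(response = truth, predictor = scores,
                 levels = c("block", "conduct"), direction = "<",
                 quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)),
       roc_points = data.frame(fpr = 1 - r$specificities,
                               tpr = r$sensitivities))
}

## seeded k-fold assignment, stratified by class
cv_folds_assign <- function(label, k, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(label))
  for (cl in levels(label)) {
    ids <- sample(which(label == cl))
    fold[ids] <- rep_len(seq_len(k), length(ids))
  }
  fold
}

fit_predict_model <- function(model, train, test, hyper) {
  xcols <- feature_columns()
  fx <- stats::as.formula(paste("label ~", paste(xcols, collapse = " + ")))
  if (model %in% c("qsvm", "csvm")) {
    degree <- if (model == "qsvm") 2 else 3
    fit <- e1071::svm(fx, data = train, kernel = "polynomial",
                      degree = degree, coef0 = 1, cost = hyper,
                      scale = TRUE)
    pred <- predict(fit, newdata = test, decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    # orient the decision value towards the "conduct" class
    cn <- colnames(attr(pred, "decision.values"))[1]
    if (!startsWith(cn, "conduct")) dv <- -dv
    list(fit = fit, pred = pred, score = dv)
  } else if (model == "dt") {
    fit <- rpart::rpart(fx, data = train, method = "class",
                        control = rpart::rpart.control(cp = hyper, xval = 0))
    prob <- predict(fit, newdata = test, type = "prob")[, "conduct"]
    pred <- factor(ifelse(prob >= 0.5, "conduct", "block"),
                   levels = c("block", "conduct"))
    list(fit = fit, pred = pred, score = prob)
  } else if (model == "knn") {
    xs_tr <- scale(train[, xcols])
    ctr <- attr(xs_tr, "scaled:center"); sc <- attr(xs_tr, "scaled:scale")
    sc[sc == 0] <- 1
    xs_te <- scale(test[, xcols], center = ctr, scale = sc)
    pred <- class::knn(xs_tr, xs_te, cl = train$label, k = hyper,
                       prob = TRUE)
    pwin <- attr(pred, "prob")
    prob <- ifelse(pred == "conduct", pwin, 1 - pwin)
    list(fit = list(k = hyper, center = ctr, scale = sc), pred = pred,
         score = prob)
  } else stop("unknown model: ", model)
}

model_hyper_grid <- function(model) {
  switch(model,
         qsvm = c(0.1, 1, 10),
         csvm = c(0.1, 1, 10),
         dt = c(0.001, 0.01, 0.05),
         knn = c(3L, 5L, 7L, 9L, 11L))
}

#' Train and evaluate the four conduction classifiers
#'
#' Quadratic and cubic polynomial-kernel SVMs, a decision tree and
#' k-nearest neighbours. Protocol: stratified 80:20 train/test split;
#' hyperparameters (SVM cost, tree complexity, k) selected by stratified
#' 10-fold cross-validation on the training portion; reported metrics come
#' from the held-out 20%. Fully seeded and reproducible.
#'
#' @param dataset feature table from [assemble_features()] or
#'   [surrogate_ml_dataset()]; must contain both classes.
#' @param split_seed integer seed controlling the split, fold assignment and
#'   tie-breaks.
#' @param models subset of `c("qsvm", "csvm", "dt", "knn")`.
#' @param cv_folds number of cross-validation folds.
#' @return Named list of `classifier_report` objects: confusion matrix,
#'   metric table with Wilson confidence intervals, AUC with ROC points,
#'   selected hyperparameter, split sizes and seeds; the fitted model is
#'   attached for feature ranking.
#' @export
train_conduction_models <- function(dataset,
                                    models = c("qsvm", "csvm", "dt", "knn"),
                                    split_seed = 1L, cv_folds = 10L) {
  stopifnot(is.factor(dataset$label))
  if (nlevels(droplevels(dataset$label)) < 2)
    stop("dataset contains a single class; cannot train")
  if (!all(complete.cases(dataset[, c(feature_columns(), "label")])))
    stop("missing values in feature table")
  sp <- stratified_split(dataset$label, 0.2, seed = split_seed)
  train <- dataset[sp$train, , drop = FALSE]
  test <- dataset[sp$test, , drop = FALSE]
  fold <- cv_folds_assign(train$label, cv_folds, seed = split_seed + 1L)

  reports <- lapply(models, function(mod) {
    grid <- model_hyper_grid(mod)
    cv_acc <- vapply(grid, function(h) {
      accs <- vapply(seq_len(cv_folds), function(f) {
        tr <- train[fold != f, , drop = FALSE]
        va <- train[fold == f, , drop = FALSE]
        if (nrow(va) == 0 || nlevels(droplevels(tr$label)) < 2) return(NA_real_)
        r <- fit_predict_model(mod, tr, va, h)
        mean(r$pred == va$label)
      }, numeric(1))
      mean(accs, na.rm = TRUE)
    }, numeric(1))
    best <- grid[which.max(cv_acc)]
    final <- fit_predict_model(mod, train, test, best)
    tp <- sum(final$pred == "conduct" & test$label == "conduct")
    fp <- sum(final$pred == "conduct" & test$label == "block")
    tn <- sum(final$pred == "block" & test$label == "block")
    fn <- sum(final$pred == "block" & test$label == "conduct")
    roc <- auc_from_scores(test$label, final$score)
    structure(list(
      model = mod, hyperparameter = best,
      cv_accuracy = stats::setNames(cv_acc, as.character(grid)),
      confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                         dimnames = list(predicted = c("conduct", "block"),
                                         truth = c("conduct", "block"))),
      metrics = classification_metrics(tp, fp, tn, fn),
      auc = roc$auc, roc_points = roc$roc_points,
      n_train = nrow(train), n_test = nrow(test),
      split_seed = split_seed, fit = final$fit,
      test_scores = final$score, test_labels = test$label),
      class = "classifier_report")
  })
  names(reports) <- models
  attr(reports, "split") <- sp
  reports
}

#' @export
print.classifier_report <- function(x, ...) {
  acc <- x$metrics$value[x$metrics$metric == "accuracy"]
  cat(sprintf("<classifier_report: %s, accuracy %.1f%%, AUC %.3f, test n = %d>\n",
              toupper(x$model), acc, x$auc, x$n_test))
  invisible(x)
}

#' Rank features by importance for a trained SVM
#'
#' Two rankings are reported: (a) an SVM-internal score that aggregates, per
#' feature, the dual-coefficient-weighted contribution of the support
#' vectors to the decision function -- concretely the mean magnitude of the
#' polynomial-kernel decision-function gradient component over the support
#' vectors, in the model's scaled feature space; and (b) seeded permutation
#' importance (mean held-out accuracy drop) on supplied evaluation data.
#' Disagreement in the top feature is flagged in the result.
#'
#' @param report a `classifier_report` for an SVM model.
#' @param eval_data feature table with labels for the permutation method
#'   (typically the held-out split).
#' @param n_perm permutation repetitions.
#' @param seed RNG seed for permutations.
#' @return `data.frame` with per-feature `svm_score` and
#'   `perm_importance` plus both rankings; attribute `"agree"` says whether
#'   the two top features coincide.
#' @export
rank_features <- function(report, eval_data, n_perm = 10L, seed = 1L) {
  if (!inherits(report$fit, "svm"))
    stop("rank_features requires a trained SVM report")
  fit <- report$fit
  sv <- as.matrix(fit$SV)
  co <- as.numeric(fit$coefs)
  gam <- fit$gamma; c0 <- fit$coef0; dg <- fit$degree
  # d/dx_j sum_i co_i (gam <x_i, x> + c0)^dg, evaluated at each support vector
  gram <- (gam * tcrossprod(sv) + c0)^(dg - 1)      # nSV x nSV
  grad <- (gram %*% (co * sv)) * (dg * gam)          # rows: eval points
  svm_score <- colMeans(abs(grad))
  names(svm_score) <- colnames(sv)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  xcols <- feature_columns()
  base_acc <- mean(predict(fit, newdata = eval_data) == eval_data$label)
  perm <- vapply(xcols, function(col) {
    drops <- vapply(seq_len(n_perm), function(r) {
      shuf <- eval_data
      shuf[[col]] <- sample(shuf[[col]])
      base_acc - mean(predict(fit, newdata = shuf) == shuf$label)
    }, numeric(1))
    mean(drops)
  }, numeric(1))

  ord_names <- names(sort(svm_score, decreasing = TRUE))
  out <- data.frame(feature = xcols,
                    svm_score = unname(svm_score[xcols]),
                    svm_rank = match(xcols, ord_names),
                    perm_importance = unname(perm[xcols]),
                    perm_rank = match(xcols, names(sort(perm, decreasing = TRUE))))
  attr(out, "agree") <- ord_names[1] == names(sort(perm, decreasing = TRUE))[1]
  out
}
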