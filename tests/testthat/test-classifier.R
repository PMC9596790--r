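test_that("feature assembly counts rows and carries drug factors", {
  profs <- lhs_profiles(2, seed = 1)
  tab <- expand.grid(profile_id = 1:2, fibrosis = c(0, 5, 10),
                     drug = c("none", "amiodarone", "dofetilide", "sotalol"),
                     stringsAsFactors = FALSE)
  tab$conducted <- rep(c(TRUE, FALSE), length.out = nrow(tab))
  ft <- assemble_features(tab, profs)
  expect_equal(nrow(ft), 24)
  expect_true(all(ft$f_IKr[tab$drug == "none"] == 1))
  expect_true(all(ft$f_ICaL[tab$drug == "none"] == 1))
  expect_equal(unique(ft$f_IKr[tab$drug == "dofetilide"]), 0.2857,
               tolerance = 1e-4)
  expect_equal(levels(ft$label), c("block", "conduct"))
  expect_identical(as.integer(ft$label) - 1L, as.integer(tab$conducted))
  tab2 <- tab; tab2$conducted[3] <- NA
  expect_error(assemble_features(tab2, profs), "missing conduction label")
})

test_that("surrogate data matches the study feature schema", {
  d <- surrogate_ml_dataset(50, seed = 2)
  profs <- lhs_profiles(1, seed = 1)
  tab <- data.frame(profile_id = 1, fibrosis = 0, drug = "none",
                    conducted = TRUE)
  ft <- assemble_features(tab, profs)
  expect_identical(names(d), names(ft))
  expect_true(all(d$fibrosis %in% c(0, 5, 10)))
  expect_true(all(d[atriasim:::profile_parameter_names()] >= -50 &
                  d[atriasim:::profile_parameter_names()] <= 100))
  # generators are pure functions of spec + seed
  expect_identical(d, surrogate_ml_dataset(50, seed = 2))
})

test_that("ratio metrics and Wilson intervals are exact on hand confusion matrices", {
  m <- classification_metrics(tp = 9, fn = 1, tn = 8, fp = 2)
  v <- setNames(m$value, m$metric)
  expect_equal(unname(v["sensitivity"]), 90)
  expect_equal(unname(v["specificity"]), 80)
  expect_equal(unname(v["ppv"]), 100 * 9 / 11, tolerance = 1e-9)
  expect_equal(unname(v["npv"]), 100 * 8 / 9, tolerance = 1e-9)
  expect_equal(unname(v["accuracy"]), 85)
  # intervals contain the point estimate and are within [0, 100]
  expect_true(all(m$lower <= m$value & m$value <= m$upper))
  expect_true(all(m$lower >= 0 & m$upper <= 100))
  # zero denominator reported as NA, not 0
  m2 <- classification_metrics(tp = 0, fn = 0, tn = 5, fp = 5)
  expect_true(is.na(m2$value[m2$metric == "sensitivity"]))
  expect_false(is.na(m2$value[m2$metric == "specificity"]))
  # Wilson interval closed form at k = n/2
  ci <- wilson_ci(50, 100)
  expect_equal(mean(ci), 0.5, tolerance = 1e-9)
})

test_that("AUC is 1 for perfect scores, ~0.5 for random, monotone-invariant", {
  truth <- factor(rep(c("block", "conduct"), each = 100),
                  levels = c("block", "conduct"))
  perfect <- c(rnorm(100, 0), rnorm(100, 10))
  expect_equal(atriasim:::auc_from_scores(truth, perfect)$auc, 1)
  # monotone transform leaves AUC unchanged
  set.seed(8)
  sc <- c(rnorm(100, 0, 2), rnorm(100, 1.2, 2))
  a1 <- atriasim:::auc_from_scores(truth, sc)$auc
  a2 <- atriasim:::auc_from_scores(truth, exp(sc / 3))$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  set.seed(9)
  big <- factor(sample(rep(c("block", "conduct"), 1000)),
                levels = c("block", "conduct"))
  a3 <- atriasim:::auc_from_scores(big, rnorm(2000))$auc
  expect_lt(abs(a3 - 0.5), 0.03)
})

test_that("stratified 80:20 split matches the documented rounding rule", {
  lab <- factor(c(rep("conduct", 562), rep("block", 470)),
                levels = c("block", "conduct"))
  sp <- atriasim:::stratified_split(lab, 0.2, seed = 1)
  expect_equal(length(sp$test), 206)       # floor(0.2 * 1032)
  expect_equal(length(sp$train), 826)
  # class ratio preserved within one row
  r_all <- mean(lab == "conduct")
  r_test <- mean(lab[sp$test] == "conduct")
  expect_lt(abs(r_test * 206 - r_all * 206), 1 + 1e-9)
})

test_that("all four models separate a wide-margin surrogate perfectly", {
  d <- surrogate_ml_dataset(500, noise_rate = 0, seed = 7)
  rep <- train_conduction_models(d, split_seed = 3)
  for (m in c("qsvm", "csvm", "dt", "knn")) {
    acc <- rep[[m]]$metrics$value[rep[[m]]$metrics$metric == "accuracy"]
    expect_equal(acc, 100, info = m)
    expect_equal(sum(rep[[m]]$confusion), rep[[m]]$n_test)
  }
  expect_equal(rep$csvm$auc, 1)
  # metrics recomputable exactly from the stored confusion matrix
  cm <- rep$qsvm$confusion
  re <- classification_metrics(cm["conduct", "conduct"], cm["conduct", "block"],
                               cm["block", "block"], cm["block", "conduct"])
  expect_equal(re$value, rep$qsvm$metrics$value)
})

test_that("training is deterministic and rejects degenerate input", {
  d <- surrogate_ml_dataset(200, noise_rate = 0.05, seed = 4)
  r1 <- train_conduction_models(d, models = "qsvm", split_seed = 11)
  r2 <- train_conduction_models(d, models = "qsvm", split_seed = 11)
  expect_identical(r1$qsvm$confusion, r2$qsvm$confusion)
  expect_identical(r1$qsvm$metrics, r2$qsvm$metrics)
  single <- d[d$label == "conduct", ]
  expect_error(train_conduction_models(single), "single class")
})

test_that("known label noise caps test accuracy at the Bayes ceiling", {
  d <- surrogate_ml_dataset(1000, noise_rate = 0.1, seed = 8)
  rep <- train_conduction_models(d, models = "csvm", split_seed = 3)
  acc <- rep$csvm$metrics$value[rep$csvm$metrics$metric == "accuracy"]
  expect_lt(abs(acc - 90), 3 * 100 / sqrt(200))  # ceiling +/- sampling noise
  expect_lt(acc, 100)
})

test_that("a planted single-feature signal is ranked first by both methods", {
  d <- surrogate_ml_dataset(600, seed = 11, rule = "gna")
  rep <- train_conduction_models(d, models = "csvm", split_seed = 3)
  test_rows <- d[attr(rep, "split")$test, ]
  rk <- rank_features(rep$csvm, test_rows, seed = 5)
  expect_equal(rk$feature[rk$svm_rank == 1], "gNa")
  expect_equal(rk$feature[rk$perm_rank == 1], "gNa")
  expect_true(is.logical(attr(rk, "agree")))
})

test_that("label-shuffled data gives near-uniform permutation importances", {
  d <- surrogate_ml_dataset(400, seed = 13)
  set.seed(99)
  d$label <- sample(d$label)
  rep <- train_conduction_models(d, models = "csvm", split_seed = 7)
  rk <- rank_features(rep$csvm, d[attr(rep, "split")$test, ], n_perm = 20,
                      seed = 3)
  spread <- max(rk$perm_importance) - min(rk$perm_importance)
  expect_lt(spread, 3 * max(sd(rk$perm_importance), 1e-6) + 0.05)
})
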