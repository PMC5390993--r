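toy_xy <- function(n = 200, p = 5, signal = TRUE, seed = 61,
                   frac_pos = 0.5) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n,
                            dimnames = list(NULL, paste0("f", 1:p))))
  y <- if (signal) factor(ifelse(x$f1 > 0, "pos", "neg"),
                          levels = c("neg", "pos"))
       else factor(sample(c("neg", "pos"), n, TRUE,
                          prob = c(1 - frac_pos, frac_pos)),
                   levels = c("neg", "pos"))
  list(x = x, y = y)
}

test_that("learner specifications validate algorithm/mode pairs", {
  expect_error(learner_spec("rusboost", mode = "regress"),
               "classification")
  expect_error(learner_spec("naive_bayes", mode = "regress"),
               "classification")
  expect_s3_class(learner_spec("adaboost", mode = "regress"),
                  "learner_spec")
})

test_that("every RUSBoost round trains on a balanced resample", {
  set.seed(62)
  n <- 220
  x <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
  y <- factor(rep(c("neg", "pos"), c(200, 20)), c("neg", "pos"))
  x$f1[y == "pos"] <- x$f1[y == "pos"] + 2
  m <- boost_fit(x, y, "rus", n_rounds = 25)
  expect_true(all(m$resample_counts[, "neg"] == 20))
  expect_true(all(m$resample_counts[, "pos"] == 20))
})

test_that("one-round AdaBoost equals a single stump", {
  d <- toy_xy(n = 120, seed = 63)
  m <- boost_fit(d$x, d$y, "ada", n_rounds = 1, depth = 1)
  stump <- rpart::rpart(y ~ ., data = cbind(d$x, y = d$y),
                        method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 1, cp = 0, minsplit = 10,
                          minbucket = 5, xval = 0))
  expect_equal(predict(m, d$x) > 0.5,
               predict(stump, d$x, type = "class") == "pos")
})

test_that("learners separate linearly separable toy data perfectly", {
  d <- toy_xy(n = 150, seed = 64)
  for (alg in c("rusboost", "adaboost", "random_forest",
                "decision_tree")) {
    set.seed(1)
    m <- train_learner(learner_spec(alg), d$x, d$y)
    ev <- evaluate_classification(predict_scores(m, d$x), d$y)
    expect_equal(ev$auc, 1.0, label = alg)
  }
})

test_that("AUC matches hand-ranked values including ties", {
  lab <- factor(c("pos", "pos", "neg", "neg"), c("neg", "pos"))
  expect_equal(evaluate_classification(c(0.9, 0.8, 0.1, 0.2),
                                       lab)$auc, 1.0)
  # pairs: (.6 > .5) x2 win, (.4 < .5) x2 loss -> 0.5
  expect_equal(evaluate_classification(c(0.6, 0.4, 0.5, 0.5),
                                       lab)$auc, 0.5)
  # agreement with the independent rank-statistic oracle
  set.seed(65)
  sc <- round(runif(60), 2)  # rounded: forces ties
  y <- runif(60) < 0.4
  lab2 <- factor(ifelse(y, "pos", "neg"), c("neg", "pos"))
  expect_equal(evaluate_classification(sc, lab2)$auc,
               auc_by_rank(sc, y), tolerance = 1e-12)
})

test_that("confusion rows are percentages of each actual class", {
  lab <- factor(c("pos", "pos", "neg", "neg"), c("neg", "pos"))
  ev <- evaluate_classification(c(0.9, 0.8, 0.7, 0.6), lab)
  expect_equal(as.numeric(rowSums(ev$confusion)), c(100, 100))
  expect_equal(as.numeric(ev$confusion["pos", "pos"]), 100)
  expect_equal(as.numeric(ev$confusion["neg", "neg"]), 0)
})

test_that("nRMSE follows its closed form", {
  expect_equal(evaluate_regression(1:5, 1:5), 0)
  # constant shift c over range R -> 100 c / R
  expect_equal(evaluate_regression(1:5 + 2, 1:5), 100 * 2 / 4)
  expect_equal(evaluate_regression(c(0, 1, 2, 5), c(0, 1, 2, 3)),
               100 * 1 / 3, tolerance = 1e-12)
  expect_error(evaluate_regression(c(1, 2), c(3, 3)), "range")
})

test_that("repeated holdout is calibrated on null and planted labels", {
  null <- toy_xy(n = 500, signal = FALSE, seed = 66)
  cv0 <- repeated_holdout(null$x, null$y,
                          learner_spec("random_forest", n_trees = 150),
                          n_repeats = 20, seed = 5)
  expect_gte(cv0$mean, 0.45)
  expect_lte(cv0$mean, 0.55)

  sig <- toy_xy(n = 200, signal = TRUE, seed = 67)
  cv1 <- repeated_holdout(sig$x, sig$y,
                          learner_spec("random_forest", n_trees = 150),
                          n_repeats = 20, seed = 5)
  expect_gt(cv1$mean, 0.95)

  cv1b <- repeated_holdout(sig$x, sig$y,
                           learner_spec("random_forest", n_trees = 150),
                           n_repeats = 20, seed = 5)
  expect_identical(cv1$per_repeat, cv1b$per_repeat)
})

test_that("holdout tolerates missing cells via train-fold imputation", {
  d <- toy_xy(n = 150, seed = 68)
  d$x$f2[sample(150, 40)] <- NA
  cv <- repeated_holdout(d$x, d$y, learner_spec("decision_tree"),
                         n_repeats = 5, seed = 3)
  expect_equal(length(cv$per_repeat), 5)
  expect_true(all(is.finite(cv$per_repeat)))
})

test_that("permutation importance finds planted signal, not noise", {
  d <- toy_xy(n = 300, seed = 69)
  set.seed(2)
  m <- train_learner(learner_spec("random_forest", n_trees = 200),
                     d$x[1:200, ], d$y[1:200])
  imp <- variable_importance(m, d$x[201:300, ], d$y[201:300],
                             n_perm = 5, seed = 4)
  expect_equal(imp$feature[1], "f1")
  noise_imp <- imp$importance[imp$feature != "f1"]
  expect_true(all(abs(noise_imp) < 0.1))
})

test_that("reduced model search stops at the planted feature set", {
  set.seed(70)
  n <- 220; p <- 30
  x <- as.data.frame(matrix(rnorm(n * p), n,
                            dimnames = list(NULL, paste0("v", 1:p))))
  score <- x$v1 + x$v2 + x$v3 + x$v4
  y <- factor(ifelse(score > 0, "pos", "neg"), c("neg", "pos"))
  spec <- learner_spec("random_forest", n_trees = 120)
  cv <- repeated_holdout(x, y, spec, n_repeats = 8, seed = 6,
                         importance = TRUE, importance_repeats = 4)
  red <- reduced_model_search(x, y, spec, cv$importance$feature,
                              n_repeats = 8, seed = 6, full = cv)
  expect_true(red$satisfied)
  expect_lte(red$n_features, 6)
  expect_gte(length(intersect(red$features,
                              c("v1", "v2", "v3", "v4"))), 3)

  # degenerate tolerance: the first feature alone is always enough
  red1 <- reduced_model_search(x, y, spec, cv$importance$feature,
                               tol = 1, n_repeats = 4, seed = 6,
                               full = cv)
  expect_equal(red1$n_features, 1)
})

test_that("feature tables follow each experiment's variable rules", {
  fits <- data.frame(
    subject_id = rep(c("s1", "s2"), each = 4),
    variable = rep(c("alsfrs_total", "alsfrs_q1", "weight", "pulse"),
                   2),
    family = "exponential",
    A = runif(8, 30, 80), k = runif(8, 0, 0.01), b = NA,
    n = 8, sse = 1, rmse = 0.3, aicc = 5, converged = TRUE,
    stringsAsFactors = FALSE)
  statics <- data.frame(subject_id = c("s1", "s2"), age = c(50, 60),
                        onset_site = c("limb", "bulbar"),
                        stringsAsFactors = FALSE)
  tr <- build_feature_table(fits, statics, "decline_traj")
  expect_setequal(names(tr), c("subject_id", "weight_A", "weight_k",
                               "pulse_A", "pulse_k", "age",
                               "onset_site"))
  expect_s3_class(tr$onset_site, "factor")
  bl <- build_feature_table(fits, statics, "decline_baseline")
  expect_false(any(grepl("_k$", names(bl))))
  expect_true("alsfrs_total_A" %in% names(bl))
  sb <- build_feature_table(fits, statics, "survival_baseline")
  expect_true("alsfrs_q1_A" %in% names(sb))
  st <- build_feature_table(fits, statics, "survival_traj")
  expect_true(all(c("alsfrs_total_k", "weight_k") %in% names(st)))
  expect_false("alsfrs_q1_A" %in% names(st))

  # a missing fitted k leaves an NA cell, the row is retained
  fits2 <- fits
  fits2$k[fits2$subject_id == "s2" & fits2$variable == "weight"] <- NA
  tr2 <- build_feature_table(fits2, statics, "decline_traj")
  expect_equal(nrow(tr2), 2)
  expect_true(is.na(tr2$weight_k[tr2$subject_id == "s2"]))
})
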