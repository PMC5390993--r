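# The five prediction experiments: decline class from trajectory
# features, decline class from baseline features, continuous ALSFRS-R
# decline rate from baseline features, and survival class from
# trajectory+baseline or baseline-only features. Learners run under
# repeated stratified 60/40 holdout with within-fold imputation,
# permutation importance on held-out folds, and importance-ranked reduced
# model search.

.EXPERIMENTS <- c("decline_traj", "decline_baseline", "k_baseline",
                  "survival_traj", "survival_baseline")

#' Learner specification
#'
#' @param algorithm One of `"rusboost"`, `"adaboost"`,
#'   `"random_forest"`, `"naive_bayes"`, `"decision_tree"`.
#' @param mode `"classify"` or `"regress"` (`rusboost` and
#'   `naive_bayes` are classification-only; `adaboost` in regression
#'   mode is least-squares boosting on regression trees).
#' @param n_rounds Boosting rounds.
#' @param depth Base-tree depth (boosting) or rpart depth.
#' @param learning_rate Boosting shrinkage.
#' @param n_trees Random-forest tree count.
#' @return A list of class `learner_spec`.
#' @export
learner_spec <- function(algorithm = c("rusboost", "adaboost",
                                       "random_forest", "naive_bayes",
                                       "decision_tree"),
                         mode = c("classify", "regress"),
                         n_rounds = 100, depth = 3, learning_rate = 0.5,
                         n_trees = 500) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  if (mode == "regress" && algorithm %in% c("rusboost", "naive_bayes"))
    stop(algorithm, " supports classification only", call. = FALSE)
  structure(list(algorithm = algorithm, mode = mode,
                 n_rounds = n_rounds, depth = depth,
                 learning_rate = learning_rate, n_trees = n_trees),
            class = "learner_spec")
}

#' Build the feature table for a prediction experiment
#'
#' Pivots per-subject exponential fits into `<variable>_A` /
#' `<variable>_k` columns, joins the static covariates, and applies each
#' experiment's feature rules:
#'
#' * `decline_traj`: `A` and `k`; all ALSFRS-R variables (total and
#'   items) and FVC/SVC excluded.
#' * `decline_baseline`: `A` only; ALSFRS-R items and FVC/SVC excluded.
#' * `k_baseline`: `A` only; ALSFRS-R items and FVC/SVC excluded
#'   (continuous-rate target).
#' * `survival_traj`: `A` and `k`; ALSFRS-R items excluded.
#' * `survival_baseline`: `A` only; item scores allowed.
#'
#' Missing cells (e.g. no fitted `k` for a short series) are retained as
#' `NA`; imputation happens inside the training folds.
#'
#' @param fits Exponential fit table from [fit_trajectories()].
#' @param statics Per-subject static covariates (`subject_id` + columns).
#' @param experiment One of the five experiment names.
#' @param alsfrs_variable,alsfrs_items Names of the ALSFRS-R total and
#'   item variables.
#' @return Data frame, one row per subject, first column `subject_id`.
#' @export
build_feature_table <- function(fits, statics = NULL,
                                experiment = .EXPERIMENTS,
                                alsfrs_variable = "alsfrs_total",
                                alsfrs_items = paste0("alsfrs_q", 1:12)) {
  experiment <- match.arg(experiment)
  fits <- fits[fits$family == "exponential", , drop = FALSE]
  excl <- switch(experiment,
    decline_traj = c(alsfrs_variable, alsfrs_items, "fvc", "svc",
                     "fvc_percent", "svc_percent"),
    decline_baseline = ,
    k_baseline = c(alsfrs_items, "fvc", "svc", "fvc_percent",
                   "svc_percent"),
    survival_traj = alsfrs_items,
    survival_baseline = character(0))
  use_k <- experiment %in% c("decline_traj", "survival_traj")
  fits <- fits[!(fits$variable %in% excl), , drop = FALSE]
  if (!nrow(fits)) stop("no usable features for experiment ", experiment,
                        call. = FALSE)

  ids <- sort(unique(fits$subject_id))
  tab <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (v in sort(unique(fits$variable))) {
    fv <- fits[fits$variable == v, , drop = FALSE]
    i <- match(ids, fv$subject_id)
    tab[[paste0(v, "_A")]] <- fv$A[i]
    if (use_k) tab[[paste0(v, "_k")]] <- fv$k[i]
  }
  if (!is.null(statics)) {
    st <- statics
    for (cn in setdiff(names(st), "subject_id"))
      if (is.character(st[[cn]])) st[[cn]] <- factor(st[[cn]])
    tab <- merge(tab, st, by = "subject_id", all.x = TRUE)
  }
  tab
}

# train-fold imputation: numeric -> median, factor -> mode
.impute_fit <- function(x) {
  lapply(x, function(col) {
    if (is.numeric(col)) median(col, na.rm = TRUE)
    else names(which.max(table(col)))
  })
}

.impute_apply <- function(x, fills) {
  for (cn in names(fills)) {
    miss <- is.na(x[[cn]])
    if (any(miss)) x[[cn]][miss] <- fills[[cn]]
  }
  x
}

#' Train one learner
#'
#' @param spec A [learner_spec()].
#' @param x Feature data frame (no `subject_id`, no missing values).
#' @param y Labels: factor with the positive class as second level
#'   (classification) or numeric (regression).
#' @return A fitted model with a score method understood by
#'   [predict_scores()].
#' @export
train_learner <- function(spec, x, y) {
  stopifnot(inherits(spec, "learner_spec"))
  if (spec$mode == "classify") {
    y <- droplevels(as.factor(y))
    if (nlevels(y) < 2)
      stop("training fold contains a single class", call. = FALSE)
  }
  switch(spec$algorithm,
    rusboost = boost_fit(x, y, "rus", spec$n_rounds, spec$depth,
                         spec$learning_rate),
    adaboost = if (spec$mode == "classify")
        boost_fit(x, y, "ada", spec$n_rounds, spec$depth,
                  spec$learning_rate)
      else
        boost_fit(x, y, "ls", spec$n_rounds, spec$depth,
                  spec$learning_rate),
    random_forest = randomForest::randomForest(x, y,
                                               ntree = spec$n_trees),
    naive_bayes = structure(list(fit = e1071::naiveBayes(x, y),
                                 classes = levels(y)),
                            class = "nb_model"),
    decision_tree = {
      dat <- cbind(x, .y = y)
      structure(list(fit = rpart::rpart(
        .y ~ ., data = dat,
        method = if (spec$mode == "classify") "class" else "anova",
        control = .rpart_ctrl(pmax(spec$depth, 5))),
        classes = if (spec$mode == "classify") levels(y) else NULL),
        class = "tree_model")
    })
}

#' Score new data with a trained learner
#'
#' @param model Output of [train_learner()].
#' @param x Feature data frame.
#' @return Classification: score in \[0, 1\] for the positive (second)
#'   class; regression: predicted response.
#' @export
predict_scores <- function(model, x) {
  x <- as.data.frame(x)
  if (inherits(model, "boost_model")) return(predict(model, x))
  if (inherits(model, "nb_model"))
    return(predict(model$fit, x, type = "raw")[, model$classes[2L]])
  if (inherits(model, "tree_model")) {
    if (is.null(model$classes))
      return(as.numeric(predict(model$fit, newdata = x)))
    return(predict(model$fit, newdata = x,
                   type = "prob")[, model$classes[2L]])
  }
  if (inherits(model, "randomForest")) {
    if (model$type == "regression")
      return(as.numeric(predict(model, x)))
    return(predict(model, x, type = "prob")[, levels(model$y)[2L]])
  }
  stop("unknown model type", call. = FALSE)
}

#' Rank-statistic AUC and row-normalised confusion matrix
#'
#' AUC is the Mann-Whitney probability that a random positive scores
#' above a random negative (ties counted half), computed via pROC. The
#' confusion matrix applies the 0.5 score threshold and reports row
#' percentages (each actual class sums to 100).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Factor with the positive class as second level.
#' @return List with `auc` and `confusion` (2x2 matrix of row
#'   percentages, actual classes in rows).
#' @export
evaluate_classification <- function(scores, labels) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2)
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = levels(labels), direction = "<", quiet = TRUE)))
  pred <- factor(ifelse(scores >= 0.5, levels(labels)[2L],
                        levels(labels)[1L]), levels = levels(labels))
  counts <- table(actual = labels, predicted = pred)
  list(auc = auc, confusion = 100 * counts / rowSums(counts))
}

#' Range-normalised RMSE
#'
#' `100 * RMSE / (max(actuals) - min(actuals))`, in percent.
#'
#' @param predictions,actuals Numeric vectors.
#' @return nRMSE in percent.
#' @export
evaluate_regression <- function(predictions, actuals) {
  stopifnot(length(actuals) >= 2)
  rng <- max(actuals) - min(actuals)
  if (rng <= 0) stop("degenerate actuals: zero range", call. = FALSE)
  100 * sqrt(mean((predictions - actuals)^2)) / rng
}

#' Repeated stratified holdout validation
#'
#' Repeats a stratified random 60/40 train/test split `n_repeats` times.
#' Within each repeat, imputation statistics are fitted on the training
#' fold only, the learner is trained and scored on the held-out fold,
#' and AUC plus the 0.5-threshold confusion matrix (or nRMSE for
#' regression) are recorded. Optionally accumulates permutation
#' importance of each feature on the held-out folds of the first
#' `importance_repeats` repeats.
#'
#' @param features Feature table (may include `subject_id`, dropped).
#' @param labels Factor (positive class second level) or numeric vector
#'   aligned with `features` rows.
#' @param spec A [learner_spec()].
#' @param n_repeats Number of repeats (100 in the full protocol).
#' @param train_frac Training fraction of each class.
#' @param seed Master seed; all resampling derives from it.
#' @param importance Compute held-out permutation importance.
#' @param importance_repeats Repeats used for importance.
#' @return Object of class `cv_result`: per-repeat metrics, aggregate
#'   mean/SD, mean confusion percentages, and (if requested) the
#'   importance ranking.
#' @export
repeated_holdout <- function(features, labels, spec, n_repeats = 100,
                             train_frac = 0.6, seed = 1L,
                             importance = FALSE,
                             importance_repeats = 5L) {
  x <- features
  x$subject_id <- NULL
  classify <- spec$mode == "classify"
  if (classify) {
    labels <- droplevels(as.factor(labels))
    stopifnot(nlevels(labels) == 2)
    if (min(table(labels)) < 10)
      stop("need at least 10 subjects per class", call. = FALSE)
  }
  n <- nrow(x)
  set.seed(seed)
  metrics <- numeric(n_repeats)
  conf_sum <- NULL
  imp_sum <- setNames(numeric(ncol(x)), names(x))
  imp_n <- 0L
  redraws <- 0L
  for (r in seq_len(n_repeats)) {
    for (attempt in 1:10) {
      train_idx <- if (classify) {
        unlist(lapply(levels(labels), function(l) {
          ii <- which(labels == l)
          sample(ii, max(1L, round(train_frac * length(ii))))
        }))
      } else sample(n, round(train_frac * n))
      test_idx <- setdiff(seq_len(n), train_idx)
      ok <- !classify ||
        (length(unique(labels[test_idx])) == 2 &&
           length(unique(labels[train_idx])) == 2)
      if (ok) break
      redraws <- redraws + 1L
    }
    fills <- .impute_fit(x[train_idx, , drop = FALSE])
    xtr <- .impute_apply(x[train_idx, , drop = FALSE], fills)
    xte <- .impute_apply(x[test_idx, , drop = FALSE], fills)
    model <- train_learner(spec, xtr, labels[train_idx])
    scores <- predict_scores(model, xte)
    if (classify) {
      ev <- evaluate_classification(scores, labels[test_idx])
      metrics[r] <- ev$auc
      cm <- unclass(ev$confusion)
      conf_sum <- if (is.null(conf_sum)) cm else conf_sum + cm
    } else {
      metrics[r] <- evaluate_regression(scores, labels[test_idx])
    }
    if (importance && r <= importance_repeats) {
      base <- metrics[r]
      for (cn in names(x)) {
        xp <- xte
        xp[[cn]] <- xp[[cn]][sample(nrow(xp))]
        sp <- predict_scores(model, xp)
        perm <- if (classify)
          evaluate_classification(sp, labels[test_idx])$auc
        else evaluate_regression(sp, labels[test_idx])
        # importance = performance lost when the feature is destroyed
        imp_sum[cn] <- imp_sum[cn] +
          if (classify) base - perm else perm - base
      }
      imp_n <- imp_n + 1L
    }
  }
  imp <- NULL
  if (importance && imp_n > 0) {
    sc <- imp_sum / imp_n
    imp <- data.frame(feature = names(sc), importance = unname(sc),
                      stringsAsFactors = FALSE)
    imp <- imp[order(-imp$importance, imp$feature), , drop = FALSE]
    rownames(imp) <- NULL
  }
  structure(list(
    metric = if (classify) "auc" else "nrmse",
    per_repeat = metrics, mean = mean(metrics), sd = sd(metrics),
    confusion = if (classify) conf_sum / n_repeats else NULL,
    importance = imp, spec = spec, n = n, n_repeats = n_repeats,
    redraws = redraws, seed = seed), class = "cv_result")
}

#' @export
print.cv_result <- function(x, digits = 3, ...) {
  cat(sprintf("Repeated holdout (%d repeats, n = %d, %s/%s)\n",
              x$n_repeats, x$n, x$spec$algorithm, x$spec$mode))
  cat(sprintf("  mean %s = %s (SD %s)\n", toupper(x$metric),
              format(x$mean, digits = digits),
              format(x$sd, digits = digits)))
  if (!is.null(x$confusion)) {
    cat("  mean confusion (row %):\n")
    print(round(x$confusion, 1))
  }
  if (!is.null(x$importance)) {
    cat("  top features:",
        paste(head(x$importance$feature, 5), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Held-out permutation importance of a single trained model
#'
#' @param model Output of [train_learner()].
#' @param x_test,y_test Held-out features and labels.
#' @param n_perm Permutations per feature (averaged).
#' @param seed Seed for the permutations.
#' @return Data frame `feature`, `importance`, sorted descending with
#'   deterministic name tie-break.
#' @export
variable_importance <- function(model, x_test, y_test, n_perm = 3,
                                seed = 1L) {
  set.seed(seed)
  classify <- !is.numeric(y_test)
  base_scores <- predict_scores(model, x_test)
  base <- if (classify)
    evaluate_classification(base_scores, y_test)$auc
  else evaluate_regression(base_scores, y_test)
  sc <- vapply(names(x_test), function(cn) {
    mean(vapply(seq_len(n_perm), function(j) {
      xp <- x_test
      xp[[cn]] <- xp[[cn]][sample(nrow(xp))]
      p <- predict_scores(model, xp)
      if (classify) base - evaluate_classification(p, y_test)$auc
      else evaluate_regression(p, y_test) - base
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(feature = names(sc), importance = unname(sc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Importance-ranked reduced model search
#'
#' Scans N = 1, 2, ... over the importance ranking and returns the
#' smallest feature set whose retrained cross-validated performance is
#' within `tol` of the full model (mean AUC >= full - tol, or mean nRMSE
#' <= full + tol). If no N satisfies the tolerance the full set is
#' returned with `satisfied = FALSE`.
#'
#' @param features,labels,spec,n_repeats,train_frac,seed As in
#'   [repeated_holdout()].
#' @param ranking Character vector of feature names, most important
#'   first (e.g. from a `cv_result` importance table).
#' @param tol Tolerance: AUC units for classification (default 0.01),
#'   nRMSE percentage points for regression (default 1).
#' @param full Optional precomputed full-model `cv_result`.
#' @return List: selected `features`, `n_features`, their `cv`
#'   result, the `full` result and `satisfied`.
#' @export
reduced_model_search <- function(features, labels, spec, ranking,
                                 tol = NULL, n_repeats = 20,
                                 train_frac = 0.6, seed = 1L,
                                 full = NULL) {
  stopifnot(length(ranking) > 0)
  classify <- spec$mode == "classify"
  if (is.null(tol)) tol <- if (classify) 0.01 else 1
  keep_id <- intersect("subject_id", names(features))
  if (is.null(full))
    full <- repeated_holdout(features, labels, spec, n_repeats,
                             train_frac, seed)
  for (N in seq_along(ranking)) {
    sub <- features[, c(keep_id, ranking[seq_len(N)]), drop = FALSE]
    cv <- repeated_holdout(sub, labels, spec, n_repeats, train_frac,
                           seed)
    hit <- if (classify) cv$mean >= full$mean - tol
           else cv$mean <= full$mean + tol
    if (hit)
      return(list(features = ranking[seq_len(N)], n_features = N,
                  cv = cv, full = full, satisfied = TRUE))
  }
  list(features = ranking, n_features = length(ranking), cv = full,
       full = full, satisfied = FALSE)
}
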