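# Boosting learners used by the prediction experiments. AdaBoost.M1 with
# depth-limited CART base trees; RUSBoost, which additionally
# random-undersamples the majority class to the minority count at every
# boosting round (the weight update is still computed on the full
# training set); and least-squares gradient boosting for the continuous
# decline-rate target. CART trees come from rpart.

.rpart_ctrl <- function(depth) {
  rpart::rpart.control(maxdepth = depth, cp = 0, minsplit = 10,
                       minbucket = 5, xval = 0)
}

#' Fit a boosted tree ensemble
#'
#' @param x Data frame of features (numeric or factor).
#' @param y Class labels (factor, 2 levels) or numeric response for
#'   `type = "ls"`.
#' @param type `"ada"` (AdaBoost.M1), `"rus"` (RUSBoost) or `"ls"`
#'   (least-squares gradient boosting, numeric `y`).
#' @param n_rounds Boosting rounds.
#' @param depth Maximum depth of the base trees.
#' @param learning_rate Shrinkage applied to the round weights
#'   (classification) or tree contributions (regression).
#' @return Object of class `boost_model`. For RUSBoost the per-round
#'   class counts of the undersampled training sets are kept in
#'   `$resample_counts`.
#' @export
boost_fit <- function(x, y, type = c("ada", "rus", "ls"),
                      n_rounds = 100, depth = 3, learning_rate = 0.5) {
  type <- match.arg(type)
  x <- as.data.frame(x)
  if (type == "ls") return(.lsboost_fit(x, y, n_rounds, depth,
                                        learning_rate))
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2)
    stop("boosting requires exactly two classes in the training fold",
         call. = FALSE)
  n <- nrow(x)
  w <- rep(1 / n, n)
  trees <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  resample_counts <- matrix(NA_integer_, n_rounds, 2,
                            dimnames = list(NULL, levels(y)))
  dat <- cbind(x, .y = y)
  m_used <- 0L
  for (m in seq_len(n_rounds)) {
    rc <- c(NA_integer_, NA_integer_)
    if (type == "rus") {
      minority <- names(which.min(table(y)))
      majority <- setdiff(levels(y), minority)
      idx_min <- which(y == minority)
      idx_maj <- sample(which(y == majority), length(idx_min))
      idx <- c(idx_min, idx_maj)
      rc <- as.integer(table(y[idx])[levels(y)])
    } else {
      idx <- seq_len(n)
    }
    # scale weights to sum to the fold size: rpart's minsplit/minbucket
    # operate on weighted counts
    fit <- rpart::rpart(.y ~ ., data = dat[idx, , drop = FALSE],
                        weights = w[idx] * length(idx) / sum(w[idx]),
                        method = "class", control = .rpart_ctrl(depth))
    pred <- predict(fit, newdata = x, type = "class")
    miss <- pred != y
    err <- sum(w * miss) / sum(w)
    if (err >= 0.5) {  # no better than chance on current weights: reset
      w <- rep(1 / n, n)
      next
    }
    err <- max(err, 1e-10)
    alpha <- learning_rate * log((1 - err) / err)
    m_used <- m_used + 1L
    trees[[m_used]] <- fit
    alphas[m_used] <- alpha
    resample_counts[m_used, ] <- rc
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    if (err <= 1e-9) break  # perfect classifier; voting is decided
  }
  if (m_used == 0L)
    stop("boosting failed: no round improved on chance", call. = FALSE)
  structure(list(type = type, trees = trees[seq_len(m_used)],
                 alphas = alphas[seq_len(m_used)], classes = levels(y),
                 depth = depth,
                 resample_counts = resample_counts[seq_len(m_used), ,
                                                   drop = FALSE]),
            class = "boost_model")
}

.lsboost_fit <- function(x, y, n_rounds, depth, learning_rate) {
  stopifnot(is.numeric(y))
  f0 <- mean(y)
  fhat <- rep(f0, length(y))
  trees <- vector("list", n_rounds)
  dat <- cbind(x, .r = 0)
  for (m in seq_len(n_rounds)) {
    dat$.r <- y - fhat
    fit <- rpart::rpart(.r ~ ., data = dat, method = "anova",
                        control = .rpart_ctrl(depth))
    trees[[m]] <- fit
    fhat <- fhat + learning_rate * predict(fit, newdata = x)
  }
  structure(list(type = "ls", trees = trees, init = f0,
                 learning_rate = learning_rate, depth = depth),
            class = "boost_model")
}

#' Predict from a boosted ensemble
#'
#' @param object A `boost_model`.
#' @param newdata Feature data frame.
#' @param ... Unused.
#' @return For classification, the weighted-vote score for the second
#'   class in `object$classes` (in \[0, 1\], 0.5 decision threshold);
#'   for regression, the predicted response.
#' @export
predict.boost_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (object$type == "ls") {
    p <- rep(object$init, nrow(newdata))
    for (tr in object$trees)
      p <- p + object$learning_rate * predict(tr, newdata = newdata)
    return(p)
  }
  pos <- object$classes[2L]
  votes <- numeric(nrow(newdata))
  for (i in seq_along(object$trees)) {
    pred <- predict(object$trees[[i]], newdata = newdata, type = "class")
    votes <- votes + object$alphas[i] * (pred == pos)
  }
  votes / sum(object$alphas)
}

#' @export
print.boost_model <- function(x, ...) {
  cat("Boosted ensemble:", switch(x$type, ada = "AdaBoost.M1",
                                  rus = "RUSBoost", ls = "LS-Boost"),
      "with", length(x$trees), "trees of depth", x$depth, "\n")
  invisible(x)
}
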