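# Unsupervised derivation of the two binary patient classes: fast/slow
# progression from the fitted ALSFRS-R decline rate k, and high/low death
# risk from days to death (last follow-up as a proxy when the death day is
# unrecorded). Both k-means and PAM are run; cluster counts are chosen by
# average silhouette width.

.km <- function(x, k, nstart = 25) kmeans(x, centers = k, nstart = nstart)

#' Choose the cluster count by average silhouette width
#'
#' Runs k-means for k = 2..kmax and returns the k maximising the average
#' silhouette width.
#'
#' @param values Numeric vector to cluster (1-D).
#' @param kmax Largest cluster count considered.
#' @param seed Seed for the k-means restarts.
#' @return Integer: the silhouette-optimal cluster count.
#' @export
optimal_cluster_count <- function(values, kmax = 6, seed = 1L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < kmax + 1)
    stop("need more than kmax distinct values", call. = FALSE)
  set.seed(seed)
  d <- stats::dist(matrix(values, ncol = 1))
  widths <- vapply(2:kmax, function(k) {
    cl <- .km(values, k)$cluster
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  as.integer((2:kmax)[which.max(widths)])
}

#' Derive fast/slow progression classes from fitted decline rates
#'
#' Clusters the subjects' fitted ALSFRS-R decline rates `k` with both
#' k-means and PAM at the silhouette-chosen cluster count (binary in
#' practice), keeps the method with the larger between-cluster difference
#' in median `|k|`, and labels the cluster with the larger median `|k|`
#' "fast".
#'
#' @param k_values Named numeric vector of fitted rates (names =
#'   subject ids).
#' @param n_clusters Cluster count, or `NULL` to choose by silhouette.
#' @param seed Seed for k-means restarts.
#' @return Object of class `decline_classes`: data frame `classes`
#'   (`subject_id`, `class`), chosen `method`, cluster `centers`, the
#'   per-method median-rate difference, and assignments from both
#'   methods.
#' @export
derive_decline_classes <- function(k_values, n_clusters = NULL,
                                   seed = 1L) {
  if (is.null(names(k_values)))
    names(k_values) <- as.character(seq_along(k_values))
  k_values <- k_values[is.finite(k_values)]
  if (length(k_values) < 4) stop("need at least 4 subjects", call. = FALSE)
  if (length(unique(k_values)) < 2)
    stop("degenerate rates: all values identical", call. = FALSE)
  if (is.null(n_clusters))
    n_clusters <- optimal_cluster_count(k_values,
                                        kmax = min(6, length(unique(k_values)) - 1),
                                        seed = seed)
  set.seed(seed)
  km <- .km(k_values, n_clusters)
  pm <- cluster::pam(matrix(k_values, ncol = 1), k = n_clusters)

  med_gap <- function(assign) {
    meds <- tapply(abs(k_values), assign, median)
    max(meds) - min(meds)
  }
  gaps <- c(kmeans = med_gap(km$cluster), pam = med_gap(pm$clustering))
  method <- names(gaps)[which.max(gaps)]
  assign <- if (method == "kmeans") km$cluster else pm$clustering
  centers <- tapply(k_values, assign, mean)
  fast_cluster <- as.integer(names(which.max(tapply(abs(k_values),
                                                    assign, median))))
  cls <- ifelse(assign == fast_cluster, "fast", "slow")
  structure(list(
    classes = data.frame(subject_id = names(k_values), class = cls,
                         k = unname(k_values), stringsAsFactors = FALSE,
                         row.names = NULL),
    method = method, n_clusters = n_clusters,
    centers = sort(unname(centers)), median_gap = gaps,
    kmeans_assign = km$cluster, pam_assign = pm$clustering),
    class = "decline_classes")
}

#' @export
print.decline_classes <- function(x, ...) {
  tab <- table(x$classes$class)
  cat("Decline classes (", x$method, ", ", x$n_clusters,
      " clusters):\n", sep = "")
  cat(sprintf("  fast: %d (%.0f%%), slow: %d (%.0f%%)\n",
              tab[["fast"]], 100 * tab[["fast"]] / sum(tab),
              tab[["slow"]], 100 * tab[["slow"]] / sum(tab)))
  cat("  cluster centers (k/day):",
      paste(signif(x$centers, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Survival time with the last-follow-up proxy
#'
#' Days from trial start to death when a death day is recorded, otherwise
#' to the last follow-up contact (a proxy known to underestimate the true
#' survival time).
#'
#' @param outcomes Data frame with `subject_id`, `death_day` (`NA` when
#'   unrecorded) and `last_followup_day`.
#' @return Data frame `subject_id`, `days`, `event_observed`; subjects
#'   with neither day are dropped.
#' @export
derive_survival_outcome <- function(outcomes) {
  stopifnot(all(c("subject_id", "death_day", "last_followup_day") %in%
                  names(outcomes)))
  has_death <- !is.na(outcomes$death_day)
  has_fu <- !is.na(outcomes$last_followup_day)
  keep <- has_death | has_fu
  data.frame(
    subject_id = outcomes$subject_id[keep],
    days = ifelse(has_death[keep], outcomes$death_day[keep],
                  outcomes$last_followup_day[keep]),
    event_observed = has_death[keep],
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Derive high/low death-risk classes from survival times
#'
#' Binary k-means on days to death (or last follow-up as proxy). The
#' cluster with the smaller center is labelled high death risk; the class
#' threshold is reported as the midpoint between the two cluster centers.
#'
#' @param outcomes Output of [derive_survival_outcome()].
#' @param seed Seed for the k-means restarts.
#' @return Object of class `survival_classes`: `outcomes` with a
#'   `risk_class` column, cluster `centers` and the `threshold` (days).
#' @export
derive_survival_classes <- function(outcomes, seed = 1L) {
  if (nrow(outcomes) < 4) stop("need at least 4 outcomes", call. = FALSE)
  days <- outcomes$days
  if (length(unique(days)) < 2)
    stop("degenerate survival times: all values identical", call. = FALSE)
  set.seed(seed)
  km <- .km(days, 2)
  centers <- sort(as.numeric(km$centers))
  high_cluster <- which.min(km$centers)
  outcomes$risk_class <- ifelse(km$cluster == high_cluster, "high", "low")
  structure(list(outcomes = outcomes, centers = centers,
                 threshold = mean(centers)),
            class = "survival_classes")
}

#' @export
print.survival_classes <- function(x, ...) {
  tab <- table(x$outcomes$risk_class)
  cat("Survival classes (k-means, 2 clusters):\n")
  cat(sprintf("  high death risk: %d (%.0f%%), low: %d (%.0f%%)\n",
              tab[["high"]], 100 * tab[["high"]] / sum(tab),
              tab[["low"]], 100 * tab[["low"]] / sum(tab)))
  cat(sprintf("  centers %.0f / %.0f days; threshold %.0f days\n",
              x$centers[1L], x$centers[2L], x$threshold))
  invisible(x)
}

#' Cross-tabulate decline and survival classes
#'
#' 2x2 counts and percentages over the subjects carrying both
#' classifications, plus row-wise high-risk rates per decline class.
#'
#' @param decline A `decline_classes` object (or its `classes` data
#'   frame).
#' @param survival A `survival_classes` object (or its `outcomes` data
#'   frame with `risk_class`).
#' @return List with `counts` and `percent` (2x2 tables, decline class in
#'   rows), `n` subjects in the intersection and `row_high_risk_rate`.
#' @export
cross_tabulate <- function(decline, survival) {
  d <- if (inherits(decline, "decline_classes")) decline$classes
       else decline
  s <- if (inherits(survival, "survival_classes")) survival$outcomes
       else survival
  m <- merge(d[, c("subject_id", "class")],
             s[, c("subject_id", "risk_class")], by = "subject_id")
  if (!nrow(m)) stop("no subjects carry both classifications",
                     call. = FALSE)
  counts <- table(factor(m$class, c("fast", "slow")),
                  factor(m$risk_class, c("high", "low")))
  names(dimnames(counts)) <- c("decline", "risk")
  list(counts = counts,
       percent = 100 * counts / sum(counts),
       n = sum(counts),
       row_high_risk_rate = counts[, "high"] / rowSums(counts))
}
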