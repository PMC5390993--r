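# Ranking of candidate families per subject by small-sample-corrected AIC
# and by RMSE, with the equivalence rules |dAICc| < 2 and dRMSE < 10% of
# the top model. The census over subjects is reporting only: downstream
# feature construction always uses the exponential fit.

#' Small-sample-corrected Akaike information criterion
#'
#' Gaussian profile form: `n log(SSE/n) + 2p + 2p(p+1)/(n - p - 1)`, where
#' `p` counts curve parameters only (2 or 3), kept consistent across
#' families so differences are comparable.
#'
#' @param sse Residual sum of squares.
#' @param n Number of observations.
#' @param p Number of curve parameters.
#' @return AICc (scalar); `-Inf` for a perfect fit.
#' @examples
#' aicc(10, 10, 2)  # 4 + 12/7
#' @export
aicc <- function(sse, n, p) {
  if (n <= p + 1)
    stop("AICc undefined for n <= p + 1 (n = ", n, ", p = ", p, ")",
         call. = FALSE)
  if (sse <= 0) return(-Inf)
  n * log(sse / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
}

.family_rank_order <- function(families) {
  # deterministic tie-break: fewer parameters first, then fixed family order
  arity <- vapply(families, family_arity, integer(1))
  order_in <- match(families, .FAMILIES)
  list(arity = arity, fixed = order_in)
}

#' Rank candidate family fits for one series
#'
#' Orders the available fits ascending by AICc and by RMSE and applies the
#' equivalence rules: the 2nd model is "as good as" the top model when the
#' absolute AICc difference is below 2, or when the RMSE difference is
#' below 10% of the top model's RMSE. Ties in the orderings are broken by
#' fewer parameters, then a fixed family order.
#'
#' @param fits A `traj_fitlist` from [fit_all_families()], or a data frame
#'   with columns `family`, `aicc`, `rmse` (and optionally `converged`).
#' @return An object of class `model_comparison`: rankings by each
#'   criterion, tie flags, and the chosen (top-AICc) family.
#' @export
rank_models <- function(fits) {
  if (inherits(fits, "traj_fitlist")) {
    fits <- do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      data.frame(family = f$family, aicc = f$aicc, rmse = f$rmse,
                 converged = fitted_ok(f), stringsAsFactors = FALSE)
    }))
  }
  stopifnot(is.data.frame(fits),
            all(c("family", "aicc", "rmse") %in% names(fits)))
  if (!"converged" %in% names(fits)) fits$converged <- TRUE
  valid <- fits[fits$converged & is.finite(fits$rmse) &
                  !is.na(fits$aicc), , drop = FALSE]

  rank_by <- function(score) {
    tb <- .family_rank_order(valid$family)
    valid$family[order(score, tb$arity, tb$fixed)]
  }
  if (nrow(valid) < 2) {
    return(structure(list(
      aicc_ranking = valid$family, rmse_ranking = valid$family,
      aicc_tie = FALSE, rmse_tie = FALSE,
      chosen = if (nrow(valid)) valid$family[1L] else NA_character_,
      table = valid), class = "model_comparison"))
  }
  aicc_rank <- rank_by(valid$aicc)
  rmse_rank <- rank_by(valid$rmse)
  a <- valid$aicc[match(aicc_rank, valid$family)]
  r <- valid$rmse[match(rmse_rank, valid$family)]
  structure(list(
    aicc_ranking = aicc_rank,
    rmse_ranking = rmse_rank,
    aicc_tie = abs(a[1L] - a[2L]) < 2,
    rmse_tie = (r[2L] - r[1L]) / r[1L] < 0.10,
    chosen = aicc_rank[1L],
    table = valid), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison\n")
  cat("  AICc order:", paste(x$aicc_ranking, collapse = " < "),
      if (x$aicc_tie) " [top two equivalent, dAICc < 2]" else "", "\n")
  cat("  RMSE order:", paste(x$rmse_ranking, collapse = " < "),
      if (x$rmse_tie) " [top two equivalent, dRMSE < 10%]" else "", "\n")
  invisible(x)
}

#' Rank families for every series in a cohort fit table
#'
#' @param fits_df Output of [fit_trajectories()] run with several
#'   families.
#' @return Data frame with one row per (subject, variable): best family
#'   and tie flag under each criterion.
#' @export
compare_trajectories <- function(fits_df) {
  key <- interaction(fits_df$subject_id, fits_df$variable, drop = TRUE)
  rows <- lapply(split(fits_df, key), function(g) {
    mc <- rank_models(g)
    data.frame(subject_id = g$subject_id[1L], variable = g$variable[1L],
               best_aicc = if (length(mc$aicc_ranking)) mc$aicc_ranking[1L]
                           else NA_character_,
               best_rmse = if (length(mc$rmse_ranking)) mc$rmse_ranking[1L]
                           else NA_character_,
               aicc_tie = mc$aicc_tie, rmse_tie = mc$rmse_tie,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best-fit census across subjects
#'
#' Fraction of series best fitted by each family, separately under the
#' AICc and RMSE orderings. Equivalence ties are credited to the
#' top-ranked model.
#'
#' @param comparisons Output of [compare_trajectories()].
#' @return Data frame with columns `family`, `criterion`, `fraction`;
#'   fractions sum to 1 within each criterion.
#' @export
best_fit_census <- function(comparisons) {
  stopifnot(nrow(comparisons) > 0)
  one <- function(col, criterion) {
    x <- comparisons[[col]]
    x <- x[!is.na(x)]
    tab <- table(x) / length(x)
    data.frame(family = names(tab), criterion = criterion,
               fraction = as.numeric(tab), stringsAsFactors = FALSE)
  }
  out <- rbind(one("best_aicc", "aicc"), one("best_rmse", "rmse"))
  rownames(out) <- NULL
  out
}
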