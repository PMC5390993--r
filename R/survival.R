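# Association between progression class and survival: univariate Cox
# regression (fast vs slow, Efron ties) and Kaplan-Meier curves, both
# delegated to the survival package.

#' Univariate Cox regression of survival on decline class
#'
#' Fits a proportional-hazards model with the binary progression class as
#' the only covariate (reference level: slow progression) and the
#' recorded-death flag as the event indicator. Ties are handled by the
#' Efron approximation.
#'
#' @param outcomes Data frame with `subject_id`, `days`,
#'   `event_observed` (see [derive_survival_outcome()]).
#' @param classes Data frame with `subject_id` and `class`
#'   (`fast`/`slow`), e.g. `decline_classes$classes`. Subjects without a
#'   class are excluded.
#' @return Object of class `cox_decline`: hazard ratio (fast vs slow),
#'   95% confidence interval, p-value, per-group sizes, and the
#'   underlying `coxph` fit. A monotone-likelihood (separation) warning
#'   from `coxph` is surfaced as `flagged = TRUE`.
#' @export
cox_univariate <- function(outcomes, classes) {
  if (inherits(classes, "decline_classes")) classes <- classes$classes
  m <- merge(outcomes, classes[, c("subject_id", "class")],
             by = "subject_id")
  m$class <- factor(m$class, levels = c("slow", "fast"))
  if (nlevels(droplevels(m$class)) < 2)
    stop("both decline classes must be present", call. = FALSE)
  if (!any(m$event_observed)) stop("no observed events", call. = FALSE)
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(days, event_observed) ~ class,
                    data = m, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  structure(list(
    hr = unname(s$conf.int[1L, "exp(coef)"]),
    ci = unname(s$conf.int[1L, c("lower .95", "upper .95")]),
    p_value = unname(s$coefficients[1L, "Pr(>|z|)"]),
    n = table(m$class), n_events = sum(m$event_observed),
    flagged = flagged, fit = fit), class = "cox_decline")
}

#' @export
print.cox_decline <- function(x, ...) {
  cat(sprintf(
    "Univariate Cox: fast vs slow progression\n  HR = %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
    x$hr, x$ci[1L], x$ci[2L], x$p_value))
  cat(sprintf("  n = %d slow / %d fast, %d events%s\n",
              x$n[["slow"]], x$n[["fast"]], x$n_events,
              if (x$flagged) " [flagged: monotone likelihood]" else ""))
  invisible(x)
}

#' Kaplan-Meier survival curves by class
#'
#' Product-limit estimates per class with right censoring at
#' `event_observed = FALSE`.
#'
#' @inheritParams cox_univariate
#' @return Data frame with `class`, `time`, `survival`, `at_risk`.
#' @export
km_curves <- function(outcomes, classes) {
  if (inherits(classes, "decline_classes")) classes <- classes$classes
  m <- merge(outcomes, classes[, c("subject_id", "class")],
             by = "subject_id")
  fit <- survival::survfit(
    survival::Surv(days, event_observed) ~ class, data = m)
  strata <- if (is.null(fit$strata)) {
    rep(unique(m$class), length(fit$time))
  } else {
    rep(sub("^class=", "", names(fit$strata)), fit$strata)
  }
  data.frame(class = strata, time = fit$time, survival = fit$surv,
             at_risk = fit$n.risk, stringsAsFactors = FALSE)
}
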