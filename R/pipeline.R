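# End-to-end orchestration: trajectory fitting, family census, class
# derivation, survival analysis, and the five prediction experiments.

#' Run the disease-course analysis on a cohort
#'
#' Fits all four families to the ALSFRS-R total score (for the best-fit
#' census) and the exponential model to every variable (for features),
#' derives fast/slow progression classes from the fitted ALSFRS-R rates,
#' derives high/low death-risk classes from days to death (last
#' follow-up as proxy), cross-tabulates the two classifications and fits
#' the univariate Cox model of survival on progression class.
#'
#' @param cohort An `als_cohort` (or a list with `visits`, `statics`,
#'   `outcomes` of the same shape).
#' @param control [anneal_control()] for the trajectory fits.
#' @param seed Seed for fitting and clustering.
#' @param alsfrs_variable Name of the ALSFRS-R total-score variable.
#' @return Object of class `als_analysis` with elements `fits`,
#'   `census`, `decline`, `survival` (classified outcomes), `crosstab`
#'   and `cox`.
#' @export
als_pipeline <- function(cohort, control = anneal_control(), seed = 1L,
                         alsfrs_variable = "alsfrs_total") {
  visits <- cohort$visits

  census_fits <- fit_trajectories(
    visits, families = trajectory_families(),
    variables = alsfrs_variable, alsfrs_variable = alsfrs_variable,
    control = control, seed = seed)
  census <- best_fit_census(compare_trajectories(census_fits))

  fits <- fit_trajectories(visits, families = "exponential",
                           alsfrs_variable = alsfrs_variable,
                           control = control, seed = seed + 1L)

  af <- fits[fits$variable == alsfrs_variable & fits$converged, ]
  k_values <- setNames(af$k, af$subject_id)
  decline <- derive_decline_classes(k_values, n_clusters = 2,
                                    seed = seed)

  outcome <- derive_survival_outcome(cohort$outcomes)
  surv_cls <- derive_survival_classes(outcome, seed = seed)

  crosstab <- cross_tabulate(decline, surv_cls)
  cox <- cox_univariate(outcome, decline)

  structure(list(fits = fits, census_fits = census_fits,
                 census = census, decline = decline,
                 survival = surv_cls, crosstab = crosstab, cox = cox,
                 alsfrs_variable = alsfrs_variable),
            class = "als_analysis")
}

#' @export
print.als_analysis <- function(x, ...) {
  cat("ALS disease-course analysis\n\n")
  cat("Best-fit census (fraction of subjects):\n")
  print(transform(x$census, fraction = round(fraction, 3)))
  cat("\n")
  print(x$decline)
  print(x$survival)
  cat("\n")
  print(x$cox)
  invisible(x)
}

#' Write an analysis run report as JSON
#'
#' Exports the headline quantities of an [als_pipeline()] run — family
#' census, class counts, survival cluster centers and threshold, and the
#' Cox hazard ratio with its confidence interval — to a JSON file.
#'
#' @param analysis An `als_analysis`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_analysis_json <- function(analysis, path) {
  stopifnot(inherits(analysis, "als_analysis"))
  cls <- analysis$decline$classes$class
  risk <- analysis$survival$outcomes$risk_class
  report <- list(
    census = analysis$census,
    decline = list(method = analysis$decline$method,
                   centers = analysis$decline$centers,
                   n_fast = sum(cls == "fast"),
                   n_slow = sum(cls == "slow")),
    survival = list(centers = analysis$survival$centers,
                    threshold_days = analysis$survival$threshold,
                    n_high = sum(risk == "high"),
                    n_low = sum(risk == "low")),
    cox = list(hr_fast_vs_slow = analysis$cox$hr,
               ci95 = analysis$cox$ci, p_value = analysis$cox$p_value,
               n_events = analysis$cox$n_events))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.default_learner <- function(experiment) {
  switch(experiment,
    decline_traj = ,
    decline_baseline = learner_spec("rusboost"),
    survival_traj = ,
    survival_baseline = learner_spec("adaboost"),
    k_baseline = learner_spec("random_forest", mode = "regress"))
}

#' Run one prediction experiment
#'
#' Assembles the experiment's feature table and labels from a fitted
#' [als_pipeline()] analysis and runs [repeated_holdout()]. The default
#' learner follows the experiment's best-performing algorithm: RUSBoost
#' for the imbalanced decline classes, AdaBoost for the survival
#' classes, random forest regression for the continuous decline rate.
#'
#' @param analysis An `als_analysis`.
#' @param cohort The cohort the analysis was run on (for statics).
#' @param experiment One of `"decline_traj"`, `"decline_baseline"`,
#'   `"k_baseline"`, `"survival_traj"`, `"survival_baseline"`.
#' @param spec Optional [learner_spec()] overriding the default.
#' @param n_repeats,seed,importance Passed to [repeated_holdout()].
#' @return A `cv_result`.
#' @export
run_experiment <- function(analysis, cohort, experiment,
                           spec = NULL, n_repeats = 100, seed = 1L,
                           importance = FALSE) {
  experiment <- match.arg(experiment, .EXPERIMENTS)
  if (is.null(spec)) spec <- .default_learner(experiment)
  feats <- build_feature_table(analysis$fits, cohort$statics, experiment,
                               alsfrs_variable = analysis$alsfrs_variable)
  if (grepl("^decline|^k_", experiment)) {
    cls <- analysis$decline$classes
    m <- merge(feats, cls, by = "subject_id")
    labels <- if (experiment == "k_baseline") m$k
              else factor(m$class, levels = c("slow", "fast"))
    m$class <- NULL; m$k <- NULL
  } else {
    oc <- analysis$survival$outcomes
    m <- merge(feats, oc[, c("subject_id", "risk_class")],
               by = "subject_id")
    labels <- factor(m$risk_class, levels = c("low", "high"))
    m$risk_class <- NULL
  }
  repeated_holdout(m, labels, spec, n_repeats = n_repeats, seed = seed,
                   importance = importance)
}
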