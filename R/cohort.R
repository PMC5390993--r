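# Synthetic cohort generator emulating the structure of pooled ALS trial
# databases: irregular visit days over ~300-day studies, latent fast/slow
# progression classes with distinct decline rates, correlated death times
# with about half of the subjects lacking a recorded death day, and
# cell-level missingness. Ground truth (latent classes, planted curve
# parameters, true death days) is returned alongside so downstream stages
# can be validated against it.

#' Specification of one simulated clinical variable
#'
#' @param family Trajectory family the variable follows.
#' @param A_mean Baseline mean; a single number, or a named vector over
#'   the linked classes (`fast`/`slow` or `high`/`low`).
#' @param A_sd Between-subject SD of the baseline.
#' @param k_mean Decline-rate mean per day; single number or named vector
#'   over the linked classes.
#' @param k_sd Between-subject SD of the rate.
#' @param noise_sd Within-subject Gaussian measurement noise SD.
#' @param link Which latent class (if any) shifts this variable's
#'   parameters: `"none"`, `"decline"` (fast/slow progression) or
#'   `"survival"` (high/low death risk).
#' @param b Weibull shape (ignored unless `family = "weibull"`).
#' @param A_range Optional hard clip for simulated baselines.
#' @return A list of class `variable_spec`.
#' @export
variable_spec <- function(family = "exponential", A_mean, A_sd, k_mean,
                          k_sd, noise_sd, link = c("none", "decline",
                          "survival"), b = 1, A_range = NULL) {
  link <- match.arg(link)
  if (any(noise_sd < 0)) stop("variable_spec: noise_sd must be >= 0",
                              call. = FALSE)
  if (any(k_sd < 0)) stop("variable_spec: k_sd must be >= 0",
                          call. = FALSE)
  structure(list(family = match.arg(family, .FAMILIES), A_mean = A_mean,
                 A_sd = A_sd, k_mean = k_mean, k_sd = k_sd,
                 noise_sd = noise_sd, link = link, b = b,
                 A_range = A_range), class = "variable_spec")
}

.cls_names <- function(link) {
  if (link == "decline") c("fast", "slow") else c("high", "low")
}

.param_for <- function(mean, link, class) {
  if (length(mean) == 1L) return(unname(mean))
  unname(mean[[class]])
}

#' Default simulated variable set
#'
#' ALSFRS-R total and 12 item scores, plus the laboratory and vital-sign
#' variables that carry planted class signatures (albumin, weight,
#' alkaline phosphatase and creatine kinase trajectories for the
#' progression classes; bicarbonate, total bilirubin,
#' gamma-glutamyltransferase, chloride and pulse trajectories for the
#' death-risk classes; urine specific gravity and the climbing-stairs
#' item at baseline for death risk), and inert filler variables to
#' stress variable selection. Units are conventional clinical units;
#' rates are per day.
#'
#' @param n_filler Number of additional inert variables.
#' @return Named list of [variable_spec()] objects.
#' @export
default_variable_specs <- function(n_filler = 5) {
  sp <- list(
    alsfrs_total = variable_spec(
      "exponential", A_mean = 39.4, A_sd = 5.28,
      k_mean = c(fast = 0.004, slow = 5e-4),
      k_sd = c(fast = 1e-3, slow = 1.5e-4),
      noise_sd = 1.5, link = "decline", A_range = c(10, 48)),
    weight = variable_spec(
      "exponential", A_mean = 75.6, A_sd = 18.31,
      k_mean = c(fast = 5e-4, slow = 1.5e-4), k_sd = 8e-5,
      noise_sd = 1.0, link = "decline", A_range = c(35, 140)),
    albumin = variable_spec(
      "exponential", A_mean = 43, A_sd = 3,
      k_mean = c(fast = 6e-4, slow = -3e-4), k_sd = 1.5e-4,
      noise_sd = 1.5, link = "decline", A_range = c(28, 55)),
    alkaline_phosphatase = variable_spec(
      "exponential", A_mean = 80, A_sd = 20,
      k_mean = c(fast = -8e-4, slow = -3e-4), k_sd = 2e-4,
      noise_sd = 6, link = "decline", A_range = c(30, 160)),
    creatine_kinase = variable_spec(
      "exponential", A_mean = c(fast = 150, slow = 190), A_sd = 65,
      k_mean = c(fast = 1.2e-3, slow = 4e-4), k_sd = 3e-4,
      noise_sd = 15, link = "decline", A_range = c(30, 600)),
    bicarbonate = variable_spec(
      "exponential", A_mean = 26, A_sd = 2,
      k_mean = c(high = -8e-4, low = -1e-4), k_sd = 1.2e-4,
      noise_sd = 0.8, link = "survival", A_range = c(18, 34)),
    bilirubin_total = variable_spec(
      "exponential", A_mean = c(high = 7.5, low = 9), A_sd = 2.5,
      k_mean = c(high = -1.5e-3, low = -2e-4), k_sd = 2.5e-4,
      noise_sd = 1.2, link = "survival", A_range = c(2, 25)),
    gamma_glutamyltransferase = variable_spec(
      "exponential", A_mean = 40, A_sd = 18,
      k_mean = c(high = -1.8e-3, low = -3e-4), k_sd = 3e-4,
      noise_sd = 5, link = "survival", A_range = c(8, 150)),
    chloride = variable_spec(
      "exponential", A_mean = 102, A_sd = 2.5,
      k_mean = c(high = 3e-4, low = 5e-5), k_sd = 6e-5,
      noise_sd = 1.0, link = "survival", A_range = c(90, 115)),
    pulse = variable_spec(
      "exponential", A_mean = 75, A_sd = 9,
      k_mean = c(high = -7e-4, low = -1e-4), k_sd = 1.2e-4,
      noise_sd = 3, link = "survival", A_range = c(45, 120)),
    urine_specific_gravity = variable_spec(
      "exponential", A_mean = c(high = 1.022, low = 1.018), A_sd = 0.004,
      k_mean = 0, k_sd = 1e-6, noise_sd = 0.003, link = "survival",
      A_range = c(1.001, 1.035)),
    bp_systolic = variable_spec(
      "exponential", A_mean = 130, A_sd = 14, k_mean = 1e-4, k_sd = 1e-4,
      noise_sd = 6, A_range = c(90, 190)),
    bp_diastolic = variable_spec(
      "exponential", A_mean = 80, A_sd = 9, k_mean = 1e-4, k_sd = 8e-5,
      noise_sd = 5, A_range = c(50, 120))
  )
  # ALSFRS-R items: decline like the total; climbing stairs additionally
  # separates the death-risk classes at baseline
  items <- paste0("alsfrs_q", 1:12)
  for (it in items) {
    sp[[it]] <- variable_spec(
      "exponential", A_mean = 3.3, A_sd = 0.5,
      k_mean = c(fast = 0.004, slow = 5e-4),
      k_sd = 4e-4, noise_sd = 0.3, link = "decline",
      A_range = c(0.5, 4))
  }
  sp$alsfrs_q10 <- variable_spec(  # climbing stairs
    "exponential", A_mean = c(high = 3.4, low = 2.8), A_sd = 0.5,
    k_mean = c(high = 0.003, low = 0.001), k_sd = 4e-4, noise_sd = 0.3,
    link = "survival", A_range = c(0.5, 4))
  filler <- list(
    sodium = c(140, 2.5, 0, 5e-5, 1.0, 125, 150),
    potassium = c(4.2, 0.35, 0, 8e-5, 0.2, 3, 6),
    glucose = c(5.6, 1.0, 0, 1e-4, 0.6, 3, 12),
    hematocrit = c(42, 4, 0, 8e-5, 1.5, 28, 55),
    creatinine_serum = c(75, 15, 2e-4, 1e-4, 6, 30, 140))
  for (nm in head(names(filler), n_filler)) {
    f <- filler[[nm]]
    sp[[nm]] <- variable_spec("exponential", A_mean = f[1], A_sd = f[2],
                              k_mean = f[3], k_sd = f[4], noise_sd = f[5],
                              A_range = c(f[6], f[7]))
  }
  sp
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the published cohort characteristics of pooled ALS
#' trials: age 56.2 (SD 11.78), 40.1% female, 64.1% limb onset, 65.3%
#' riluzole, baseline ALSFRS-R 39.4 (SD 5.28), time in study 314.9 days
#' (SD 109.6), 21% fast progressors, about 47% of subjects with a
#' recorded death day, and class-conditional log-normal death times with
#' medians near 150 (high risk) and 433 (low risk) days. Death-risk class
#' membership is correlated with progression class (63% of fast and 57%
#' of slow progressors are high risk).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param fraction_fast Proportion of fast progressors in \[0, 1\].
#' @param visit_days Nominal visit schedule in days from trial start.
#' @param visit_jitter_sd SD (days) of Gaussian jitter on visit days.
#' @param study_length Nominal trial length in days.
#' @param time_in_study_mean,time_in_study_sd Per-subject follow-up
#'   duration distribution (normal, truncated to \[60, 600\] days).
#' @param variable_specs Named list of [variable_spec()]s.
#' @param missing_rate Proportion of visit cells dropped at random.
#' @param death_median Named vector: median days to death for the
#'   `high` and `low` death-risk classes (log-normal).
#' @param death_sdlog Log-scale SD of the death-time distribution.
#' @param death_decline_offset Named vector (`fast`, `slow`): log-scale
#'   accelerated-failure shift of death times by progression class
#'   within each risk class. Fast progressors die earlier at every level
#'   of the coarse risk class; the default shift of about -0.65/+0.19
#'   yields a fast-vs-slow hazard ratio near 4 at `death_sdlog = 0.4`
#'   while leaving the risk-class median times approximately unchanged.
#' @param p_high_risk Named vector: probability of high death risk given
#'   `fast` / `slow` progression class.
#' @param followup_censor_rate Proportion of subjects whose death day is
#'   withheld (last follow-up day used downstream as a proxy).
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 600, fraction_fast = 0.21,
                          visit_days = seq(0, 300, by = 30),
                          visit_jitter_sd = 3, study_length = 309,
                          time_in_study_mean = 314.9,
                          time_in_study_sd = 109.6,
                          variable_specs = default_variable_specs(),
                          missing_rate = 0.15,
                          death_median = c(high = 150, low = 433),
                          death_sdlog = 0.4,
                          death_decline_offset = c(fast = -0.65,
                                                   slow = 0.19),
                          p_high_risk = c(fast = 0.633, slow = 0.566),
                          followup_censor_rate = 0.53, seed = 1L) {
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1))
      stop("cohort_config: ", nm, " must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("cohort_config: n_subjects must be >= 2", call. = FALSE)
  chk01(fraction_fast, "fraction_fast")
  chk01(missing_rate, "missing_rate")
  chk01(followup_censor_rate, "followup_censor_rate")
  chk01(p_high_risk, "p_high_risk")
  if (visit_jitter_sd < 0)
    stop("cohort_config: visit_jitter_sd must be >= 0", call. = FALSE)
  if (any(visit_days < 0) || is.unsorted(visit_days))
    stop("cohort_config: visit_days must be nonnegative and sorted",
         call. = FALSE)
  if (!all(c("high", "low") %in% names(death_median)))
    stop("cohort_config: death_median needs names high, low",
         call. = FALSE)
  if (!all(c("fast", "slow") %in% names(death_decline_offset)))
    stop("cohort_config: death_decline_offset needs names fast, slow",
         call. = FALSE)
  for (nm in names(variable_specs))
    if (!inherits(variable_specs[[nm]], "variable_spec"))
      stop("cohort_config: variable_specs[['", nm,
           "']] is not a variable_spec", call. = FALSE)
  af <- variable_specs[["alsfrs_total"]]
  if (!is.null(af) && af$link == "decline") {
    km <- af$k_mean
    if (length(km) == 2 && !(abs(km[["fast"]]) > abs(km[["slow"]])))
      stop("cohort_config: alsfrs_total fast |k| must exceed slow |k|",
           call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), fraction_fast = fraction_fast,
    visit_days = visit_days, visit_jitter_sd = visit_jitter_sd,
    study_length = study_length, time_in_study_mean = time_in_study_mean,
    time_in_study_sd = time_in_study_sd, variable_specs = variable_specs,
    missing_rate = missing_rate, death_median = death_median,
    death_sdlog = death_sdlog,
    death_decline_offset = death_decline_offset,
    p_high_risk = p_high_risk,
    followup_censor_rate = followup_censor_rate,
    seed = as.integer(seed)), class = "cohort_config")
}

#' Simulate a synthetic ALS trial cohort
#'
#' Draws latent progression and death-risk classes, death and follow-up
#' times, per-subject curve parameters for every configured variable, and
#' noisy measurements at jittered visit days (truncated at death or end
#' of follow-up). Byte-identical output for identical configurations.
#'
#' @param config A [cohort_config()].
#' @return A list of class `als_cohort` with elements `visits` (long
#'   format: `subject_id`, `variable`, `day`, `value`), `statics` (one
#'   row per subject), `outcomes` (`subject_id`, `death_day` — `NA` when
#'   withheld — and `last_followup_day`) and `truth` (latent classes,
#'   true death days and planted parameters).
#' @examples
#' co <- simulate_cohort(cohort_config(n_subjects = 10, seed = 3))
#' head(co$visits)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  id <- sprintf("S%04d", seq_len(n))

  decline <- ifelse(runif(n) < config$fraction_fast, "fast", "slow")
  risk <- ifelse(runif(n) < config$p_high_risk[decline], "high", "low")
  death <- pmax(10, round(rlnorm(
    n, log(config$death_median[risk]) +
      config$death_decline_offset[decline], config$death_sdlog)))
  tis <- pmin(pmax(rnorm(n, config$time_in_study_mean,
                         config$time_in_study_sd), 60), 600)
  last_fu <- pmin(death, round(tis))
  withheld <- runif(n) < config$followup_censor_rate
  death_rec <- ifelse(withheld, NA_real_, death)

  statics <- data.frame(
    subject_id = id,
    age = round(pmin(pmax(rnorm(n, 56.2, 11.78), 18), 90), 1),
    sex_female = as.integer(runif(n) < 0.401),
    onset_site = sample(c("limb", "bulbar", "other"), n, replace = TRUE,
                        prob = c(0.641, 0.191, 0.168)),
    riluzole = as.integer(runif(n) < 0.653),
    height = round(rnorm(n, 169, 9.94), 1),
    stringsAsFactors = FALSE)

  specs <- config$variable_specs
  vars <- names(specs)
  horizon <- pmin(death, round(tis))

  visit_list <- vector("list", n)
  par_list <- vector("list", n)
  for (i in seq_len(n)) {
    days <- round(config$visit_days +
                    if (config$visit_jitter_sd > 0)
                      rnorm(length(config$visit_days), 0,
                            config$visit_jitter_sd) else 0)
    days <- pmax(days, 0)
    days <- sort(unique(days[days <= max(horizon[i], min(days))]))
    if (!length(days)) days <- 0
    nv <- length(vars)
    Avec <- kvec <- numeric(nv)
    vis <- vector("list", nv)
    for (j in seq_len(nv)) {
      sp <- specs[[j]]
      cls <- switch(sp$link, none = NA_character_, decline = decline[i],
                    survival = risk[i])
      A_mu <- .param_for(sp$A_mean, sp$link, cls)
      k_mu <- .param_for(sp$k_mean, sp$link, cls)
      k_sd <- .param_for(sp$k_sd, sp$link, cls)
      A_i <- rnorm(1, A_mu, sp$A_sd)
      if (!is.null(sp$A_range))
        A_i <- min(max(A_i, sp$A_range[1L]), sp$A_range[2L])
      k_i <- rnorm(1, k_mu, k_sd)
      if (sp$family == "weibull") k_i <- max(k_i, 0)
      vals <- plant_trajectory(sp$family, A_i, k_i, sp$b, days,
                               sp$noise_sd)
      Avec[j] <- A_i; kvec[j] <- k_i
      vis[[j]] <- data.frame(subject_id = id[i], variable = vars[j],
                             day = days, value = vals,
                             stringsAsFactors = FALSE)
    }
    visit_list[[i]] <- do.call(rbind, vis)
    par_list[[i]] <- data.frame(subject_id = id[i], variable = vars,
                                A = Avec, k = kvec,
                                stringsAsFactors = FALSE)
  }
  visits <- do.call(rbind, visit_list)
  rownames(visits) <- NULL

  if (config$missing_rate > 0) {
    drop <- runif(nrow(visits)) < config$missing_rate
    # keep each subject's first ALSFRS-R record so every subject retains
    # a visit at the first scheduled day
    first_of_group <- !duplicated(paste(visits$subject_id,
                                        visits$variable))
    drop[first_of_group & visits$variable == "alsfrs_total"] <- FALSE
    visits <- visits[!drop, , drop = FALSE]
  }

  truth_params <- do.call(rbind, par_list)
  rownames(truth_params) <- NULL
  truth_subjects <- data.frame(
    subject_id = id, decline_class = decline, risk_class = risk,
    true_death_day = death, death_withheld = withheld,
    stringsAsFactors = FALSE)
  outcomes <- data.frame(subject_id = id, death_day = death_rec,
                         last_followup_day = last_fu,
                         stringsAsFactors = FALSE)
  structure(list(visits = visits, statics = statics, outcomes = outcomes,
                 truth = list(subjects = truth_subjects,
                              params = truth_params),
                 config = config), class = "als_cohort")
}

#' @export
print.als_cohort <- function(x, ...) {
  tr <- x$truth$subjects
  cat("Synthetic ALS cohort:", nrow(tr), "subjects,",
      length(unique(x$visits$variable)), "variables,",
      nrow(x$visits), "visit records\n")
  cat(sprintf("  fast progressors: %d (%.0f%%); recorded death day: %d (%.0f%%)\n",
              sum(tr$decline_class == "fast"),
              100 * mean(tr$decline_class == "fast"),
              sum(!tr$death_withheld),
              100 * mean(!tr$death_withheld)))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `visits.csv` (long format), `statics.csv` (long format:
#' `subject_id`, `feature`, `value`), `outcomes.csv`,
#' `truth_subjects.csv` and `truth_params.csv` into `dir`.
#'
#' @param cohort An `als_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "als_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, f) write.csv(df, file.path(dir, f), row.names = FALSE)
  w(cohort$visits, "visits.csv")
  st <- cohort$statics
  long <- do.call(rbind, lapply(setdiff(names(st), "subject_id"),
    function(f) data.frame(subject_id = st$subject_id, feature = f,
                           value = as.character(st[[f]]),
                           stringsAsFactors = FALSE)))
  w(long, "statics.csv")
  w(cohort$outcomes, "outcomes.csv")
  w(cohort$truth$subjects, "truth_subjects.csv")
  w(cohort$truth$params, "truth_params.csv")
  invisible(dir)
}

#' Read a cohort configuration from YAML
#'
#' Scalar fields map directly onto [cohort_config()] arguments;
#' `variable_specs` may be given as a map of per-variable maps with the
#' [variable_spec()] fields (class-conditional means as named maps).
#'
#' @param path YAML file path.
#' @return A [cohort_config()].
#' @export
cohort_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$variable_specs)) {
    y$variable_specs <- lapply(y$variable_specs, function(v) {
      v <- lapply(v, function(x) if (is.list(x)) unlist(x) else x)
      do.call(variable_spec, v)
    })
  }
  for (nm in c("death_median", "p_high_risk"))
    if (!is.null(y[[nm]])) y[[nm]] <- unlist(y[[nm]])
  do.call(cohort_config, y)
}
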