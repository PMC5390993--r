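# Shared fixtures. Everything is generated in code; the heavier
# end-to-end cohort run is memoised so several tests can share it.

# a small variable set for fast cohort tests
small_specs <- function() {
  list(
    alsfrs_total = variable_spec(
      "exponential", A_mean = 39.4, A_sd = 5,
      k_mean = c(fast = 0.004, slow = 5e-4),
      k_sd = c(fast = 1e-3, slow = 1.5e-4),
      noise_sd = 1.5, link = "decline", A_range = c(10, 48)),
    weight = variable_spec(
      "exponential", A_mean = 75, A_sd = 15,
      k_mean = c(fast = 5e-4, slow = 1.5e-4), k_sd = 8e-5,
      noise_sd = 1.0, link = "decline"),
    pulse = variable_spec(
      "exponential", A_mean = 75, A_sd = 9,
      k_mean = c(high = -7e-4, low = -1e-4), k_sd = 1.2e-4,
      noise_sd = 3, link = "survival"))
}

small_cohort <- function(n = 20, seed = 7, ...) {
  simulate_cohort(cohort_config(
    n_subjects = n, variable_specs = small_specs(), seed = seed, ...))
}

# annealing control used for cohort-scale fitting in tests: two restarts
# are enough once the Nelder-Mead polish is applied
fast_control <- function() anneal_control(restarts = 2)

# independent rank-statistic AUC oracle (Mann-Whitney with ties at 1/2)
auc_by_rank <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# memoised end-to-end run shared by the acceptance tests
.e2e_cache <- new.env(parent = emptyenv())
e2e_run <- function() {
  if (!is.null(.e2e_cache$res)) return(.e2e_cache$res)
  co <- simulate_cohort(cohort_config(n_subjects = 600, seed = 101))
  an <- als_pipeline(co, control = fast_control(), seed = 1)
  decl <- run_experiment(an, co, "decline_traj", n_repeats = 20,
                         seed = 21)
  surv <- run_experiment(an, co, "survival_traj", n_repeats = 20,
                         seed = 22)
  base <- run_experiment(an, co, "decline_baseline", n_repeats = 20,
                         seed = 23)
  .e2e_cache$res <- list(cohort = co, analysis = an, decline_traj = decl,
                         survival_traj = surv, decline_baseline = base)
  .e2e_cache$res
}
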