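days <- seq(0, 300, by = 30)

test_that("noise-free planted parameters are recovered within 1%", {
  cases <- list(
    list(family = "linear", A = 40, k = 0.05),
    list(family = "exponential", A = 40, k = 0.004),
    list(family = "harmonic", A = 40, k = 0.004),
    list(family = "weibull", A = 40, k = 0.004, b = 1.6))
  for (cs in cases) {
    y <- model_value(cs$family, cs$A, cs$k,
                     if (is.null(cs$b)) 1 else cs$b, days)
    set.seed(42)
    fit <- traj_fit(days, y, family = cs$family)
    expect_equal(coef(fit)[["A"]], cs$A, tolerance = 0.01,
                 label = paste(cs$family, "A"))
    expect_equal(coef(fit)[["k"]], cs$k, tolerance = 0.01,
                 label = paste(cs$family, "k"))
  }
})

test_that("a flat series yields k near zero for every family", {
  y <- rep(40, length(days))
  for (fam in trajectory_families()) {
    set.seed(5)
    fit <- traj_fit(days, y, family = fam)
    expect_equal(coef(fit)[["A"]], 40, tolerance = 0.01, label = fam)
    expect_lt(abs(coef(fit)[["k"]]), 1e-4)
    expect_lt(fit$sse, 1e-6)
  }
})

test_that("fitted parameters always respect their bounds", {
  set.seed(9)
  for (i in 1:12) {
    fam <- sample(trajectory_families(), 1)
    y <- pmax(rnorm(8, 30, 12), 0.5)
    fit <- traj_fit(sort(sample(0:300, 8)), y, family = fam,
                    A_upper = 53)
    cf <- coef(fit)
    expect_gte(cf[["A"]], 0)
    expect_lte(cf[["A"]], 53)
    expect_gte(cf[["k"]], if (fam == "weibull") 0 else -5)
    expect_lte(cf[["k"]], 5)
    if (fam == "weibull") {
      expect_gte(cf[["b"]], 1e-4)
      expect_lte(cf[["b"]], 5)
    }
  }
})

test_that("short series return a baseline-only marker, not a fit", {
  fit <- traj_fit(c(0, 30), c(40, 38), family = "exponential")
  expect_false(fitted_ok(fit))
  expect_equal(coef(fit)[["A"]], 40)  # earliest observed value
  expect_true(is.na(coef(fit)[["k"]]))
  # weibull needs 4 distinct days
  expect_false(fitted_ok(traj_fit(c(0, 30, 60), c(40, 38, 36),
                                  family = "weibull")))
  expect_true(fitted_ok(traj_fit(c(0, 30, 60), c(40, 38, 36),
                                 family = "exponential")))
})

test_that("fitting is deterministic given the RNG seed", {
  set.seed(3)
  y <- plant_trajectory("exponential", 40, 0.004, times = days,
                        noise_sd = 1.5)
  set.seed(11); f1 <- traj_fit(days, y, family = "weibull")
  set.seed(11); f2 <- traj_fit(days, y, family = "weibull")
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$sse, f2$sse)
})

test_that("negative log-likelihood is monotone in SSE and guarded", {
  set.seed(2)
  y <- plant_trajectory("exponential", 40, 0.004, times = days,
                        noise_sd = 1)
  good <- neg_log_likelihood(days, y, "exponential",
                             c(A = 40, k = 0.004))
  bad <- neg_log_likelihood(days, y, "exponential",
                            c(A = 40, k = 0.02))
  expect_lt(good, bad)
  # residual-free series: guard returns a large negative bound
  y0 <- model_value("exponential", 40, 0.004, t = days)
  expect_equal(neg_log_likelihood(days, y0, "exponential",
                                  c(A = 40, k = 0.004)), -1e300)
  expect_error(neg_log_likelihood(c(5, 5, 5), c(1, 2, 3), "exponential",
                                  c(A = 1, k = 0)), "degenerate")
})

test_that("the likelihood minimum sits at the truth on exact data", {
  # 3-point exact exponential; coarse grid oracle over (A, k)
  t3 <- c(0, 100, 200)
  y3 <- model_value("exponential", 40, 0.004, t = t3)
  As <- seq(30, 50, by = 0.5)
  ks <- seq(0, 0.01, by = 2.5e-4)
  nll <- outer(As, ks, Vectorize(function(A, k)
    neg_log_likelihood(t3, y3, "exponential", c(A = A, k = k),
                       sigma = 1)))
  idx <- which(nll == min(nll), arr.ind = TRUE)
  expect_equal(As[idx[1]], 40)
  expect_equal(ks[idx[2]], 0.004)
})

test_that("boundary and unit Weibull shapes collapse to the exponential", {
  set.seed(6)
  y <- plant_trajectory("exponential", 40, 0.004, times = days,
                        noise_sd = 0.5)
  wf <- traj_fit(days, y, family = "weibull")
  cf <- collapse_weibull(wf)
  expect_equal(cf$family, "exponential")
  expect_true(cf$collapsed)
  expect_false("b" %in% names(coef(cf)))
  set.seed(6)
  ef <- traj_fit(days, y, family = "exponential")
  expect_lt(abs(cf$sse - ef$sse), 1e-6 * (1 + ef$sse))

  # a clearly non-exponential shape is left alone
  y2 <- model_value("weibull", 40, 0.004, b = 2.5, t = days)
  set.seed(8)
  wf2 <- traj_fit(days, y2, family = "weibull")
  expect_gt(abs(coef(wf2)[["b"]] - 1), 0.15)
  expect_identical(collapse_weibull(wf2), wf2)
})

test_that("fit_all_families returns one fit per family with collapse", {
  set.seed(10)
  y <- plant_trajectory("exponential", 40, 0.004, times = days,
                        noise_sd = 1)
  fits <- fit_all_families(days, y, A_upper = 53)
  expect_named(fits, trajectory_families())
  expect_true(all(vapply(fits, fitted_ok, logical(1))))
  expect_equal(fits$weibull$family, "exponential")  # collapsed here
})

test_that("traj_fit methods are mutually consistent", {
  d <- data.frame(day = days)
  set.seed(12)
  d$score <- plant_trajectory("exponential", 40, 0.004, times = days,
                              noise_sd = 1)
  fit <- traj_fit(score ~ day, d, family = "exponential")
  expect_equal(unname(predict(fit, data.frame(day = 0))),
               coef(fit)[["A"]])
  expect_equal(fitted(fit) + residuals(fit), d$score)
  expect_equal(fit$rmse, sqrt(fit$sse / fit$n))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(length(days), 3))
  expect_output(print(summary(fit)), "Residual SD")
})

test_that("cohort-level fitting returns one row per series and family", {
  co <- small_cohort(n = 8, seed = 21)
  fits <- fit_trajectories(co$visits, families = c("linear",
                                                   "exponential"),
                           control = fast_control(), seed = 2)
  expect_setequal(unique(fits$family), c("linear", "exponential"))
  expect_equal(nrow(fits),
               2 * nrow(unique(co$visits[, c("subject_id",
                                             "variable")])))
  expect_true(all(fits$A[fits$variable == "alsfrs_total"] <= 53))
  # deterministic
  fits2 <- fit_trajectories(co$visits, families = c("linear",
                                                    "exponential"),
                            control = fast_control(), seed = 2)
  expect_identical(fits, fits2)
})
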