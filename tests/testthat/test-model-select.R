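test_that("AICc matches the closed form and its identities", {
  # n ln(sse/n) + 2p + 2p(p+1)/(n-p-1) = 0 + 4 + 12/7
  expect_equal(aicc(10, 10, 2), 4 + 12 / 7, tolerance = 1e-12)
  # extra parameter penalised at equal SSE
  expect_gt(aicc(5, 10, 3), aicc(5, 10, 2))
  # halving SSE lowers AICc by n ln 2
  expect_equal(aicc(10, 10, 2) - aicc(5, 10, 2), 10 * log(2),
               tolerance = 1e-12)
  expect_error(aicc(10, 3, 2), "AICc undefined")
  expect_equal(aicc(0, 10, 2), -Inf)
})

fits_df <- function(aiccs, rmses = NULL) {
  fams <- names(aiccs)
  data.frame(family = fams, aicc = as.numeric(aiccs),
             rmse = if (is.null(rmses)) seq_along(fams)
                    else as.numeric(rmses[fams]),
             converged = TRUE, stringsAsFactors = FALSE)
}

test_that("equivalence rules fire exactly at the printed thresholds", {
  # |dAICc| = 1.5 < 2 -> tie
  mc <- rank_models(fits_df(c(exponential = 10.0, linear = 11.5)))
  expect_equal(mc$aicc_ranking[1], "exponential")
  expect_true(mc$aicc_tie)
  # |dAICc| = 3 -> no tie
  expect_false(rank_models(fits_df(c(exponential = 10.0,
                                     linear = 13.0)))$aicc_tie)
  # boundary: exactly 2 is NOT smaller than two
  expect_false(rank_models(fits_df(c(exponential = 10.0,
                                     linear = 12.0)))$aicc_tie)
  # RMSE 9% apart -> tie; exactly 10% -> no tie
  m2 <- rank_models(fits_df(c(exponential = 1, weibull = 2),
                            rmses = c(exponential = 1.00,
                                      weibull = 1.09)))
  expect_true(m2$rmse_tie)
  m3 <- rank_models(fits_df(c(exponential = 1, weibull = 2),
                            rmses = c(exponential = 1.00,
                                      weibull = 1.10)))
  expect_false(m3$rmse_tie)
})

test_that("rankings are shift-invariant and deterministically tie-broken", {
  a <- c(linear = 12, exponential = 10, harmonic = 15, weibull = 11)
  r1 <- rank_models(fits_df(a))
  r2 <- rank_models(fits_df(a + 100))
  expect_identical(r1$aicc_ranking, r2$aicc_ranking)
  # exact AICc tie: fewer parameters first, then fixed family order
  tie <- rank_models(fits_df(c(weibull = 10, harmonic = 10,
                               exponential = 10)))
  expect_identical(tie$aicc_ranking, c("exponential", "harmonic",
                                       "weibull"))
  # fewer than two valid fits: single entry, no ties
  single <- rank_models(fits_df(c(exponential = 10)))
  expect_equal(single$chosen, "exponential")
  expect_false(single$aicc_tie)
})

test_that("census fractions partition the subjects", {
  cmp <- data.frame(
    subject_id = sprintf("s%d", 1:4), variable = "alsfrs_total",
    best_aicc = c("exponential", "exponential", "linear", "linear"),
    best_rmse = c("exponential", "exponential", "exponential",
                  "weibull"),
    aicc_tie = FALSE, rmse_tie = FALSE, stringsAsFactors = FALSE)
  cen <- best_fit_census(cmp)
  by_crit <- tapply(cen$fraction, cen$criterion, sum)
  expect_equal(as.numeric(by_crit), c(1, 1), tolerance = 1e-12)
  expect_equal(cen$fraction[cen$criterion == "aicc" &
                              cen$family == "exponential"], 0.5)
  expect_equal(cen$fraction[cen$criterion == "rmse" &
                              cen$family == "exponential"], 0.75)
  one <- best_fit_census(cmp[1:2, ])
  expect_equal(one$fraction, c(1, 1))
})

test_that("exponential wins the census on strongly exponential cohorts", {
  set.seed(31)
  d <- seq(0, 300, 30)
  rows <- lapply(1:40, function(i) {
    y <- plant_trajectory("exponential", rnorm(1, 39, 3),
                          rnorm(1, 0.004, 8e-4), times = d,
                          noise_sd = 0.8)
    data.frame(subject_id = sprintf("s%02d", i),
               variable = "alsfrs_total", day = d, value = y)
  })
  fits <- fit_trajectories(do.call(rbind, rows),
                           families = trajectory_families(),
                           control = fast_control(), seed = 4)
  cen <- best_fit_census(compare_trajectories(fits))
  frac <- function(crit) {
    f <- cen$fraction[cen$criterion == crit &
                        cen$family == "exponential"]
    if (length(f)) f else 0
  }
  expect_gt(frac("aicc"), 0.5)
  expect_gt(frac("rmse"), 0.5)
})
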