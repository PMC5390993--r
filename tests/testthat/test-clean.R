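rec <- function(...) {
  m <- rbind(...)
  data.frame(subject_id = m[, 1], variable = m[, 2],
             day = suppressWarnings(as.numeric(m[, 3])), value = m[, 4],
             stringsAsFactors = FALSE)
}

test_that("records with missing days or non-numeric values are dropped", {
  r <- rec(c("s1", "weight", "0", "75.6"),
           c("s1", "weight", NA, "74"))
  out <- drop_invalid_records(r)
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$value, 75.6)
  expect_equal(out$log$n[out$log$reason == "missing_time"], 1)

  out2 <- drop_invalid_records(rec(c("s1", "weight", "7", "abc")))
  expect_equal(nrow(out2$records), 0)
  expect_equal(out2$log$n[out2$log$reason == "non_numeric"], 1)

  r3 <- rec(c("s1", "w", "0", "70"), c("s1", "w", "7", "71"),
            c("s1", "w", "14", "72"), c("s2", "w", "0", "69"),
            c("s2", "w", "7", "68"), c("s2", "w", NA, "67"),
            c("s2", "w", "21", "oops"))
  out3 <- drop_invalid_records(r3)
  expect_equal(nrow(out3$records), 5)
  expect_equal(sum(out3$log$n), 2)
})

test_that("configured physical ranges flag ambiguous values", {
  r <- rec(c("s1", "pulse", "0", "72"), c("s1", "pulse", "7", "720"))
  out <- drop_invalid_records(r, valid_ranges = list(pulse = c(20, 250)))
  expect_equal(out$records$value, 72)
  expect_equal(out$log$n[out$log$reason == "out_of_range"], 1)
})

test_that("duplicated time points collapse to their arithmetic mean", {
  r <- rec(c("s1", "w", "0", "70"), c("s1", "w", "0", "72"))
  r$value <- as.numeric(r$value)
  out <- collapse_duplicates(r)
  expect_equal(nrow(out), 1)
  expect_equal(out$value, 71)

  r2 <- rec(c("s1", "w", "0", "70"), c("s1", "w", "7", "71"))
  r2$value <- as.numeric(r2$value)
  expect_equal(collapse_duplicates(r2)$value, c(70, 71))

  r3 <- rec(c("s1", "w", "5", "1"), c("s1", "w", "5", "2"),
            c("s1", "w", "5", "6"))
  r3$value <- as.numeric(r3$value)
  expect_equal(collapse_duplicates(r3)$value, 3)
})

test_that("synonymous headings merge onto the canonical name", {
  r <- rec(c("s1", "ALT (SGPT)", "0", "30"), c("s2", "ALT", "0", "28"))
  r$value <- as.numeric(r$value)
  out <- merge_synonyms(r, list(ALT = c("ALT (SGPT)", "ALT")))
  expect_equal(unique(out$variable), "ALT")
  expect_equal(nrow(out), 2)

  # overlap at the same day is averaged with a warning
  r2 <- rec(c("s1", "X", "0", "10"), c("s1", "Y", "0", "12"))
  r2$value <- as.numeric(r2$value)
  expect_warning(out2 <- merge_synonyms(r2, list(Z = c("X", "Y"))),
                 "averag")
  expect_equal(out2$value, 11)

  expect_error(merge_synonyms(r, list(A = "ALT", B = "ALT")),
               "conflict")
})

test_that("derivable instrument scores are back-calculated, others not", {
  items <- paste0("alsfrs_q", 1:12)
  full <- data.frame(subject_id = "s1", variable = items, day = 0,
                     value = 4, stringsAsFactors = FALSE)
  out <- backcalculate_score(full)
  expect_equal(out$value[out$variable == "alsfrs_total"], 48)

  # total present, one item missing -> item = total - sum(others)
  part <- rbind(full[1:11, ],
                data.frame(subject_id = "s1", variable = "alsfrs_total",
                           day = 0, value = 40))
  part$value[1:11] <- c(4, 4, 4, 4, 4, 4, 4, 4, 3, 1, 1)  # sums to 37
  out2 <- backcalculate_score(part)
  expect_equal(out2$value[out2$variable == "alsfrs_q12"], 3)

  # two items missing -> unchanged
  out3 <- backcalculate_score(part[-1, ])
  expect_equal(nrow(out3), nrow(part) - 1)

  # impossible back-calculated item -> warning, unchanged
  bad <- part
  bad$value[bad$variable == "alsfrs_total"] <- 48  # implies item = 11
  expect_warning(out4 <- backcalculate_score(bad), "alsfrs_q12")
  expect_false("alsfrs_q12" %in% out4$variable)
})

test_that("vital-capacity percent-of-normal derives from the raw value", {
  r <- rec(c("s1", "fvc", "0", "3.2"), c("s2", "fvc_percent", "0", "80"))
  r$value <- as.numeric(r$value)
  out <- backcalculate_capacity(r, "fvc", "fvc_percent",
                                normal = c(s1 = 4.0, s2 = 4.0))
  expect_equal(out$value[out$subject_id == "s1" &
                           out$variable == "fvc_percent"], 80)
  expect_equal(out$value[out$subject_id == "s2" &
                           out$variable == "fvc"], 3.2)
})

test_that("the cleaning chain is idempotent and never grows the data", {
  set.seed(4)
  n <- 80
  raw <- data.frame(
    subject_id = sample(c("s1", "s2", "s3"), n, TRUE),
    variable = sample(c("weight", "pulse", "ALT", "ALT (SGPT)"), n, TRUE),
    day = sample(c(0, 7, 7, 14, NA), n, TRUE),
    value = as.character(round(runif(n, 20, 90), 1)),
    stringsAsFactors = FALSE)
  raw$value[sample(n, 5)] <- "bad"
  map <- list(ALT = c("ALT", "ALT (SGPT)"))
  once <- clean_records(raw, synonym_map = map)
  twice <- clean_records(once$records, synonym_map = map)
  expect_equal(twice$records, once$records)
  expect_equal(sum(twice$log$n), 0)
  expect_lte(nrow(once$records), n)

  # each pre-backcalculation stage is non-increasing
  s1 <- drop_invalid_records(raw)$records
  expect_lte(nrow(s1), nrow(raw))
  s2 <- suppressWarnings(merge_synonyms(s1, map))
  expect_lte(nrow(s2), nrow(s1))
  expect_lte(nrow(collapse_duplicates(s2)), nrow(s2))
})
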