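test_that("cohort CSV round-trips field-for-field and keeps missing scores", {
  co <- make_cohort(age = c(19, 25, 67), gender = c("Female", "Male", "Female"),
                    ethnicity = c("White", "Mixed", "BlackOrBlackBritish"),
                    initial = c(4, 2, 0), followup = c(2, 2, 1),
                    uptake = list(CBTp = c("TakenUp", "Refused", "Waiting")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_identical(as.data.frame(back), as.data.frame(co))

  # an empty follow-up cell is missing data, not an excluded record
  df <- as.data.frame(co)
  df$honos6_followup[2] <- NA
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort_table(df), f2)
  back2 <- read_cohort(f2)
  expect_equal(nrow(back2), 3)
  expect_true(is.na(back2$honos6_followup[2]))
})

test_that("reader rejects malformed input with informative errors", {
  co <- make_cohort(age = c(20, 30))
  f <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(co)
  write.csv(df[, setdiff(names(df), "gender")], f, row.names = FALSE)
  expect_error(read_cohort(f), "gender")

  f2 <- withr::local_tempfile(fileext = ".csv")
  df2 <- as.data.frame(co)
  df2$age <- c("20", "thirty")
  write.csv(df2, f2, row.names = FALSE)
  expect_error(read_cohort(f2), "row.*2|2")

  # unknown labels fall back to the field's unknown category, with a warning
  f3 <- withr::local_tempfile(fileext = ".csv")
  df3 <- as.data.frame(co)
  df3$ethnicity <- c("Martian", "White")
  df3$uptake_CBTp <- c("??", "TakenUp")
  write.csv(df3, f3, row.names = FALSE)
  w <- capture_warnings(back <- read_cohort(f3))
  expect_match(w, "ethnicity", all = FALSE)
  expect_match(w, "CBTp", all = FALSE)
  expect_equal(back$ethnicity[1], "UnknownUndocumented")
  expect_equal(back$uptake_CBTp[1], "Unknown")
})

test_that("schema config remaps columns and labels", {
  schema <- cohort_schema()
  schema$columns[["gender"]] <- "sex"
  schema$labels$gender <- c(F = "Female", M = "Male")
  f <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(make_cohort(age = c(20, 30)))
  names(df)[names(df) == "gender"] <- "sex"
  df$sex <- c("F", "M")
  write.csv(df, f, row.names = FALSE)
  back <- read_cohort(f, schema)
  expect_equal(back$gender, c("Female", "Male"))
})

test_that("age groups use the audit bins with an open-ended top bin", {
  expect_equal(as.character(encode_age_group(c(18, 24, 25, 34, 35, 44, 45, 54, 55, 67, 80))),
               c("18-24", "18-24", "25-34", "25-34", "35-44", "35-44",
                 "45-54", "45-54", "55-69", "55-69", "55-69"))
  expect_error(encode_age_group(17), "18")
})

test_that("uptake binarisation dichotomises taken-up against all else", {
  expect_equal(binarise_uptake(c("TakenUp", "NotEligible", "Waiting",
                                 "Refused", "NotOffered", "Unknown")),
               c(1L, 0L, 0L, 0L, 0L, 0L))
  # the 0 class is configurable: excluding Waiting leaves it unclassified
  expect_true(is.na(binarise_uptake("Waiting",
                                    not_taken_up = c("Refused", "NotOffered",
                                                     "NotEligible"))))
})

test_that("exclusion pipeline applies the two staged filters in order", {
  co <- make_cohort(age = c(17, 20, 30, 40, 50),
                    followup = c(1L, NA, 1L, 1L, 1L))
  ex <- apply_exclusions(co)
  log <- exclusion_log(ex)
  expect_equal(log$n_before, c(5, 4))
  expect_equal(log$n_excluded, c(1, 1))
  expect_equal(log$n_after, c(4, 3))
  expect_equal(log$n_after, log$n_before - log$n_excluded)
  expect_equal(nrow(ex), 3)
  # input order preserved
  expect_equal(ex$patient_id, c("T003", "T004", "T005"))

  # a record failing both rules is counted once, at the age stage
  co2 <- make_cohort(age = c(17, 20), followup = c(NA, 1L))
  log2 <- exclusion_log(apply_exclusions(co2))
  expect_equal(log2$n_excluded, c(1, 0))

  # idempotent: a second application excludes nothing
  log3 <- exclusion_log(apply_exclusions(ex))
  expect_equal(nrow(log3), 4)
  expect_equal(log3$n_excluded[3:4], c(0, 0))
  expect_identical(as.data.frame(apply_exclusions(ex)), as.data.frame(ex))
})

test_that("chi-squared balance check matches the hand-computed Pearson statistic", {
  before <- make_cohort(age = rep(30, 100), gender = rep(c("Female", "Male"), each = 50))
  after <- make_cohort(age = rep(30, 50), gender = rep(c("Female", "Male"), c(30, 20)))
  bc <- balance_check(before, after, "gender")
  # direct evaluation of sum((O - E)^2 / E) on the 2x2 table
  O <- matrix(c(50, 50, 30, 20), 2, dimnames = list(c("F", "M"), NULL))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(bc$statistic, sum((O - E)^2 / E))
  expect_equal(bc$df, 1)
  expect_equal(bc$p_value, pchisq(bc$statistic, 1, lower.tail = FALSE))

  # identical cohorts give exactly zero and p = 1
  bc0 <- balance_check(before, before, "gender")
  expect_equal(bc0$statistic, 0)
  expect_equal(bc0$p_value, 1)

  # symmetric in its two cohorts
  expect_equal(balance_check(after, before, "gender")$statistic, bc$statistic)

  # categories absent from both cohorts are dropped from the table (df = k - 1)
  expect_equal(bc$df, 1)  # NonBinaryOther absent in both
  expect_error(balance_check(make_cohort(age = 20), make_cohort(age = 30)),
               "degenerate")
})
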