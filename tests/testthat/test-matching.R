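test_that("nearest-neighbour matching equals the exhaustive all-pairs scan", {
  set.seed(17)
  for (r in 1:30) {
    nt <- sample(1:20, 1)
    np <- sample(1:50, 1)
    p <- sample(2:12, 1)
    Xt <- matrix(rbinom(nt * p, 1, 0.5), nt)
    Xp <- matrix(rbinom(np * p, 1, 0.5), np)
    # one quarter-scaled score coordinate in half the instances
    if (r %% 2 == 0) {
      Xt[, 1] <- sample(0:4, nt, TRUE) / 4
      Xp[, 1] <- sample(0:4, np, TRUE) / 4
    }
    for (dist in c("hamming", "euclidean")) {
      mr <- match_nearest(Xt, Xp, distance = dist)
      want <- brute_match(Xt, Xp, distance = dist)
      expect_equal(mr$pairs$pool, want[, 1])
      expect_equal(mr$pairs$distance, want[, 2])
    }
  }
})

test_that("exact duplicates match at distance zero and ties break to the lowest index", {
  Xp <- rbind(c(1, 0, 1), c(0, 1, 1), c(1, 0, 1))
  mr <- match_nearest(matrix(c(1, 0, 1), 1), Xp)
  expect_equal(mr$pairs$pool, 1)   # row 3 is equidistant; lowest index wins
  expect_equal(mr$pairs$distance, 0)

  # two pool units at equal non-zero distance
  mr2 <- match_nearest(matrix(c(0, 0, 0), 1), rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(mr2$pairs$pool, 1)
  expect_equal(mr2$pairs$distance, 1)
})

test_that("a target never matches a pool unit carrying its own record id", {
  Xt <- matrix(c(1, 1, 0), 1)
  Xp <- rbind(c(1, 1, 0), c(1, 0, 0))  # row 1 is the target's own duplicate
  mr <- match_nearest(Xt, Xp, target_ids = 7L, pool_ids = c(7L, 8L))
  expect_equal(mr$pairs$pool, 2)
  # duplicates of other records remain eligible
  mr2 <- match_nearest(Xt, Xp, target_ids = 7L, pool_ids = c(9L, 8L))
  expect_equal(mr2$pairs$pool, 1)
  expect_error(match_nearest(Xt, Xp[1, , drop = FALSE],
                             target_ids = 7L, pool_ids = 7L), "excluded")
})

test_that("matching validates its inputs", {
  expect_error(match_nearest(matrix(1, 1), matrix(numeric(), 0, 1)), "empty")
  expect_error(match_nearest(matrix(1, 1, 2), matrix(1, 1, 3)), "covariates")
  expect_error(match_nearest(matrix(0.3, 1), matrix(1, 1)), "quarter")
  expect_error(match_nearest(matrix(1, 1), matrix(1, 1), target_ids = 1L),
               "both")
})

test_that("tie-averaged matched outcomes equal the brute-force tie-set mean", {
  set.seed(23)
  for (r in 1:10) {
    nt <- sample(5:15, 1)
    np <- sample(10:40, 1)
    Xt <- cbind(sample(0:4, nt, TRUE) / 4,
                matrix(rbinom(nt * 6, 1, 0.4), nt))
    Xp <- cbind(sample(0:4, np, TRUE) / 4,
                matrix(rbinom(np * 6, 1, 0.4), np))
    dp <- rnorm(np)
    got <- equityaudit:::nn_match_avg_cpp(
      equityaudit:::quarter_grid_int(Xt, "t"),
      equityaudit:::quarter_grid_int(Xp, "p"), dp, 0L, 4L)$matched_mean
    expect_equal(got, brute_tie_mean(Xt, Xp, dp, score_weight = 4))
  }
})

test_that("initial-score-only moderation equals exact subclassification on the score", {
  co <- apply_exclusions(generate_cohort(analysed_config(2000, seed = 51)))
  memb <- co$ethnicity == "BlackOrBlackBritish"
  delta <- co$honos6_followup - co$honos6_initial
  s0 <- co$honos6_initial
  w <- table(factor(s0[memb], 0:4)) / sum(memb)
  tbar <- tapply(delta[memb], factor(s0[memb], 0:4), mean)
  pbar <- tapply(delta[!memb], factor(s0[!memb], 0:4), mean)
  want <- sum(w * (tbar - pbar), na.rm = TRUE)
  got <- moderation_effect(co, "ethnicity", "BlackOrBlackBritish",
                           mode = "initial_score", n_boot = 1, seed = 1)
  expect_equal(got$effect, want)
})

test_that("moderation effects are reproducible and respect the sign convention", {
  cfg <- analysed_config(6813, seed = 61,
                         outcome = list(demographic = c(BlackOrBlackBritish = 0.37)))
  co <- apply_exclusions(generate_cohort(cfg))
  a <- moderation_effect(co, "ethnicity", "BlackOrBlackBritish", mode = "full",
                         n_boot = 100, seed = 9)
  b <- moderation_effect(co, "ethnicity", "BlackOrBlackBritish", mode = "full",
                         n_boot = 100, seed = 9)
  expect_identical(a, b)
  # harmful direct effect (less improvement) estimates positive
  expect_gt(a$effect, 0.15)
  expect_gt(a$ci_low, 0)
})

test_that("alternative estimator configurations run and stay near the default", {
  cfg <- analysed_config(1500, seed = 71,
                         outcome = list(demographic = c(Male = 0.3)))
  co <- apply_exclusions(generate_cohort(cfg))
  d <- suppressWarnings(moderation_effect(co, "gender", "Male", n_boot = 50, seed = 1))
  for (args in list(list(ci_method = "pairs"),
                    list(distance = "euclidean"),
                    list(score_weight = 1L),
                    list(estimand = "ate"))) {
    alt <- suppressWarnings(do.call(
      moderation_effect,
      c(list(co, "gender", "Male", n_boot = 50, seed = 1), args)))
    expect_true(is.finite(alt$effect))
    expect_lt(abs(alt$effect - d$effect), 0.25)
    expect_lt(alt$ci_low, alt$ci_high + 1e-12)
  }
})

test_that("moderation table covers observed levels and masks small cells", {
  co <- make_cohort(age = rep(c(20, 30), c(40, 40)),
                    gender = c(rep("Female", 45), rep("Male", 30),
                               rep("NonBinaryOther", 5)),
                    initial = rep(c(2L, 3L), 40),
                    followup = rep(c(1L, 3L, 2L, 0L), 20))
  expect_message(
    mt <- suppressWarnings(moderation_table(co, n_boot = 30, seed = 3)),
    "suppressed"
  )
  expect_true(all(mt$level[mt$variable == "ethnicity"] == "White"))
  nbo <- mt[mt$level == "NonBinaryOther", ]
  expect_true(all(nbo$suppressed))
  expect_true(all(is.na(nbo$effect)))
  expect_true(all(c("initial_score", "full") %in% mt$mode))
  # deterministic given the seed
  mt2 <- suppressWarnings(suppressMessages(moderation_table(co, n_boot = 30, seed = 3)))
  expect_identical(mt, mt2)
})

test_that("degenerate groups warn rather than fail", {
  co <- make_cohort(age = rep(30, 20), gender = rep(c("Female", "Male"), 10))
  expect_warning(
    out <- moderation_effect(co, "ethnicity", "Mixed", n_boot = 10, seed = 1),
    "no members")
  expect_true(is.na(out$effect))
  expect_warning(
    moderation_effect(co, "gender", "Female", n_boot = 10, seed = 1),
    "pool smaller")
})

test_that("full adjustment removes uptake-mediated confounding better than score-only", {
  ok <- vapply(1:10, function(s) {
    cfg <- analysed_config(3000, seed = 300 + s,
                           uptake_shifts = list(CBTp = c("18-24" = -1.5)),
                           outcome = list(treatment = c(CBTp = -0.8)))
    co <- apply_exclusions(generate_cohort(cfg))
    suppressWarnings({
      f <- moderation_effect(co, "age_group", "18-24", mode = "full",
                             n_boot = 1, seed = 1)$effect
      i <- moderation_effect(co, "age_group", "18-24", mode = "initial_score",
                             n_boot = 1, seed = 1)$effect
    })
    abs(f) < abs(i)  # true direct effect is zero
  }, logical(1))
  expect_gte(sum(ok), 8)
})
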