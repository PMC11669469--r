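test_that("design matrix encodes the cohort exactly as specified", {
  co <- make_cohort(age = c(20, 38, 60, 25),
                    gender = c("Female", "Male", "Male", "Male"),
                    ethnicity = c("White", "Mixed", "Mixed", "White"),
                    initial = c(2L, 4L, 0L, 3L), followup = c(1L, 3L, 0L, 2L),
                    uptake = list(CBTp = c("TakenUp", "NotOffered", "TakenUp", "TakenUp"),
                                  Clozapine = c("TakenUp", "TakenUp", "NotOffered", "Refused")))
  X <- suppressWarnings(build_design(co))
  expect_equal(unname(X[, "initial_score"]), c(2, 4, 0, 3))
  expect_equal(unname(X[, "uptake_CBTp"]), c(1, 0, 1, 1))
  expect_equal(unname(X[, "uptake_Clozapine"]), c(1, 1, 0, 0))
  expect_equal(unname(X[, "gender_Male"]), c(0, 1, 1, 1))
  expect_equal(unname(X[, "ethnicity_Mixed"]), c(0, 1, 1, 0))
  expect_equal(unname(X[, "age_group_18-24"]), c(1, 0, 0, 0))
  expect_equal(unname(X[, "age_group_55-69"]), c(0, 0, 1, 0))
  # levels with no members are dropped, with a warning
  expect_warning(build_design(co), "dropped")
  expect_false("ethnicity_Other" %in% colnames(X))

  # interactions are exact products of their parents; whitelists restrict them
  Xi <- suppressWarnings(build_design(co, include_interactions = TRUE,
                                      interaction_whitelist =
                                        c("gender_Male:uptake_CBTp",
                                          "gender_Male:uptake_Clozapine")))
  expect_equal(unname(Xi[, "gender_Male:uptake_CBTp"]),
               unname(Xi[, "gender_Male"] * Xi[, "uptake_CBTp"]))
  expect_equal(sum(grepl(":", colnames(Xi))), 2)
  # a patient with no uptake anywhere has all-zero interaction entries
  expect_equal(unname(Xi[2, "gender_Male:uptake_Clozapine"]), 1)
  expect_equal(unname(Xi[1, grepl(":", colnames(Xi))]), c(0, 0))
})

test_that("the negative log-likelihood matches independent evaluations", {
  # even split over two categories at beta = 0: -log(0.5) per observation
  X <- matrix(0, 2, 1)
  expect_equal(ordinal_probit_nll(0, 0, X, c(1, 2)), -2 * log(0.5))

  # independent plain-loop implementation on random instances
  set.seed(31)
  for (r in 1:5) {
    n <- 40
    Xr <- cbind(rbinom(n, 1, .5), runif(n, 0, 4))
    y <- sample(1:4, n, TRUE)
    beta <- rnorm(2)
    cuts <- sort(rnorm(3))
    expect_equal(ordinal_probit_nll(beta, cuts, Xr, y),
                 loop_nll(beta, cuts, Xr, y, 4))
  }

  # established-package oracle: the likelihood at the polr optimum agrees
  set.seed(32)
  n <- 400
  Xp <- cbind(x1 = rbinom(n, 1, .4), x2 = round(runif(n, 0, 4)))
  y <- findInterval(0.4 * Xp[, 1] - 0.2 * Xp[, 2] + rnorm(n), c(-1, 0.5)) + 1
  pf <- MASS::polr(factor(y, ordered = TRUE) ~ x1 + x2,
                   data = data.frame(Xp, y), method = "probit")
  expect_equal(ordinal_probit_nll(coef(pf), pf$zeta, Xp, y),
               -as.numeric(logLik(pf)), tolerance = 1e-8)
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(41)
  n <- 60
  X <- cbind(rbinom(n, 1, .5), runif(n, 0, 1))
  y <- sample(1:4, n, TRUE)
  beta <- rnorm(2) / 2
  cuts <- c(-0.8, 0.1, 1.1)
  g <- ordinal_probit_grad(beta, cuts, X, y)
  par <- c(beta, cuts)
  h <- 1e-5
  fd <- vapply(seq_along(par), function(k) {
    up <- par; up[k] <- up[k] + h
    dn <- par; dn[k] <- dn[k] - h
    (ordinal_probit_nll(up[1:2], up[3:5], X, y) -
       ordinal_probit_nll(dn[1:2], dn[3:5], X, y)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - fd)), 1e-6)
})

test_that("an intercept-only fit reproduces the closed-form cutpoints", {
  co <- apply_exclusions(generate_cohort(analysed_config(3000, seed = 55)))
  delta <- co$honos6_followup - co$honos6_initial
  fit <- fit_ordinal_probit(matrix(numeric(0), length(delta), 0), delta)
  expect_true(fit$converged)
  cats <- sort(unique(delta))
  want <- qnorm(cumsum(as.vector(table(factor(delta, cats)))) / length(delta))
  expect_equal(unname(fit$cutpoints), want[-length(want)], tolerance = 1e-4)
})

test_that("parameter estimates agree with an established ordinal-probit fitter", {
  set.seed(61)
  worst <- 0
  for (r in 1:20) {
    n <- 300
    X <- cbind(x1 = rbinom(n, 1, .5), x2 = rbinom(n, 1, .3),
               x3 = round(runif(n, 0, 4)))
    y <- findInterval(drop(X %*% c(0.5, -0.4, 0.15)) + rnorm(n),
                      c(-0.6, 0.4, 1.4)) + 1
    if (length(unique(y)) < 3) next
    fit <- fit_ordinal_probit(X, y)
    pf <- MASS::polr(factor(y, ordered = TRUE) ~ x1 + x2 + x3,
                     data = data.frame(X), method = "probit",
                     control = list(reltol = 1e-12))
    worst <- max(worst, abs(c(coef(fit) - coef(pf), fit$cutpoints - pf$zeta)))
  }
  expect_lt(worst, 1e-4)
})

test_that("duplicating every row leaves estimates unchanged and shrinks SEs by sqrt(2)", {
  set.seed(71)
  n <- 500
  X <- cbind(x1 = rbinom(n, 1, .5), x2 = round(runif(n, 0, 4)))
  y <- findInterval(0.5 * X[, 1] - 0.2 * X[, 2] + rnorm(n), c(-1, 0.6)) + 1
  f1 <- fit_ordinal_probit(X, y)
  f2 <- fit_ordinal_probit(rbind(X, X), c(y, y))
  expect_equal(coef(f2), coef(f1), tolerance = 1e-5)
  expect_equal(unname(f1$se[1:2] / f2$se[1:2]), rep(sqrt(2), 2),
               tolerance = 1e-3)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
})

test_that("predicted probabilities are coherent and the likelihood is maximal at the MLE", {
  set.seed(81)
  X <- cbind(rbinom(200, 1, .5), round(runif(200, 0, 4)))
  beta <- c(0.4, -0.2)
  cuts <- c(-1, 0, 1)
  pr <- ordinal_probit_probs(beta, cuts, X)
  expect_equal(rowSums(pr), rep(1, 200), tolerance = 1e-8)
  expect_true(all(pr >= 0))
  # larger linear predictor shifts cumulative mass to higher categories
  lo <- ordinal_probit_probs(beta, cuts, matrix(c(0, 0), 1))
  hi <- ordinal_probit_probs(beta, cuts, matrix(c(1, 0), 1))
  expect_true(all(cumsum(hi[1, ])[1:3] <= cumsum(lo[1, ])[1:3] + 1e-12))

  y <- findInterval(drop(X %*% beta) + rnorm(200), cuts) + 1
  expect_equal(sort(unique(y)), 1:4)  # all categories observed at this seed
  fit <- fit_ordinal_probit(X, y)
  expect_gte(fit$loglik + 1e-6, -ordinal_probit_nll(beta, cuts, X, y))
})

test_that("Wald tests and the interaction report follow the stated conventions", {
  fit <- structure(list(
    coefficients = c(a = 0, "gender_Male:uptake_CBTp" = -1.96, b = 0.5),
    se = c(a = 1, "gender_Male:uptake_CBTp" = 1, b = 0.1,
           cut_1 = 0.1),
    cutpoints = c(cut_1 = 0),
    converged = TRUE, diagnostic = "ok"), class = "ordinal_probit_fit")
  wt <- wald_tests(fit)
  expect_equal(wt$z[wt$term == "a"], 0)
  expect_equal(wt$p_value[wt$term == "a"], 1)
  expect_equal(wt$p_value[wt$term == "gender_Male:uptake_CBTp"], 0.05,
               tolerance = 1e-3)
  expect_equal(nrow(wt), 3)  # cutpoints excluded

  si <- significant_interactions(wt, alpha = 0.06)
  expect_equal(si$term, "gender_Male:uptake_CBTp")
  expect_equal(si$direction, "improvement")
  # no interaction columns -> empty report
  expect_equal(nrow(significant_interactions(wt[wt$term == "b", ])), 0)
  # Benjamini-Hochberg adjustment is applied across interaction terms only
  wt2 <- rbind(wt, data.frame(term = "gender_Male:uptake_Smoking",
                              estimate = 0.2, std_error = 1, z = 0.2,
                              p_value = 0.9, significant = FALSE))
  si2 <- significant_interactions(wt2, alpha = 0.2, mtc = "benjamini_hochberg")
  expect_equal(si2$term, "gender_Male:uptake_CBTp")
  expect_equal(si2$p_adjusted, p.adjust(c(wt$p_value[2], 0.9), "BH")[1])

  fitbad <- structure(list(converged = FALSE, diagnostic = "separation"),
                      class = "ordinal_probit_fit")
  expect_error(wald_tests(fitbad), "converge")
})

test_that("degenerate regression inputs are rejected or flagged", {
  expect_error(fit_ordinal_probit(matrix(0, 5, 1), rep(1, 5)), "2 observed")
  expect_error(fit_ordinal_probit(matrix(rnorm(20), 5, 4), c(1, 1, 2, 2, 1)),
               "parameters")
})
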