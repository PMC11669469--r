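# Builders for small hand-made cohorts and independent oracles shared across
# test files. Everything is generated in code; no fixture files.

# A cohort_table from minimal per-patient vectors; uptake defaults to
# NotOffered for every treatment, overridable per treatment.
make_cohort <- function(age, gender = "Female", ethnicity = "White",
                        initial = 2L, followup = 1L, uptake = list()) {
  n <- length(age)
  rec <- data.frame(patient_id = sprintf("T%03d", seq_len(n)),
                    age = as.integer(age),
                    gender = rep_len(gender, n),
                    ethnicity = rep_len(ethnicity, n),
                    stringsAsFactors = FALSE)
  for (tr in treatment_names()) {
    rec[[paste0("uptake_", tr)]] <-
      rep_len(if (!is.null(uptake[[tr]])) uptake[[tr]] else "NotOffered", n)
  }
  rec$honos6_initial <- as.integer(rep_len(initial, n))
  rec$honos6_followup <- as.integer(rep_len(followup, n))
  cohort_table(rec)
}

# Generator config for an analysed cohort of exactly n adults with complete
# assessments (the estimator-study conditions).
analysed_config <- function(n, seed, ...) {
  generator_config(n = n, seed = seed, followup_missing = 0,
                   under18_fraction = 0, ...)
}

# Brute-force all-pairs 1-NN scan: the independent oracle for match_nearest.
# First minimum = lowest pool index, matching the stated tie-break.
brute_match <- function(Xt, Xp, distance = "hamming") {
  t(vapply(seq_len(nrow(Xt)), function(i) {
    d <- vapply(seq_len(nrow(Xp)), function(j) {
      dv <- Xt[i, ] - Xp[j, ]
      if (distance == "hamming") sum(abs(dv)) else sqrt(sum(dv^2))
    }, numeric(1))
    c(which.min(d), min(d))
  }, numeric(2)))
}

# Brute-force tie-averaged matched outcome with a weighted score coordinate:
# binary columns cost 1 per disagreement, non-binary columns cost
# score_weight per unit of absolute difference (L1).
brute_tie_mean <- function(Xt, Xp, delta_pool, score_weight = 4) {
  isbin <- apply(rbind(Xt, Xp), 2, function(v) all(v %in% c(0, 1)))
  vapply(seq_len(nrow(Xt)), function(i) {
    d <- vapply(seq_len(nrow(Xp)), function(j) {
      dv <- abs(Xt[i, ] - Xp[j, ])
      sum(dv[isbin]) + score_weight * sum(dv[!isbin])
    }, numeric(1))
    mean(delta_pool[abs(d - min(d)) < 1e-12])
  }, numeric(1))
}

# Closed-form expected outcome change under the generator's latent-index
# mechanism for a given latent shift and initial score (integration over the
# standard-normal noise via the cutpoint probabilities, then clipping).
expected_change <- function(shift, s0, intercept = -0.8, score = -0.35,
                            cutpoints = seq(-3.5, 3.5, 1)) {
  mu <- intercept + score * s0 + shift
  cum <- pnorm(cutpoints - mu)
  pk <- diff(c(0, cum, 1))
  k <- seq(-4, 4)
  sum(pmin(pmax(k, -s0), 4 - s0) * pk)
}

# Independent plain-loop evaluation of the cumulative-probit negative
# log-likelihood (oracle for ordinal_probit_nll).
loop_nll <- function(beta, cutpoints, X, y_idx, J) {
  a <- c(-Inf, cutpoints, Inf)
  s <- 0
  for (i in seq_len(nrow(X))) {
    eta <- sum(X[i, ] * beta)
    s <- s - log(pnorm(a[y_idx[i] + 1] - eta) - pnorm(a[y_idx[i]] - eta))
  }
  s
}
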