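#' Configuration for the synthetic cohort generator
#'
#' Defines a fully seeded generative model for audit-like cohorts: independent
#' demographic draws from configurable marginals, demographic-dependent
#' treatment uptake through a logistic model, and an ordinal outcome change
#' produced by a latent-index probit mechanism. Every estimand the package's
#' estimators target has a known ground truth under this model
#' ([compute_truth()]).
#'
#' The data-generating process for one patient is:
#' * gender, broad ethnicity category and age group drawn independently from
#'   `gender_marginal`, `ethnicity_marginal`, `age_group_marginal`; exact age
#'   uniform within the bin (top bin 55--67). A fraction `under18_fraction`
#'   of records instead receives an age of 14--17 to exercise the exclusion
#'   pipeline.
#' * initial score \eqn{s_0} drawn from `initial_score_dist` over 0..4.
#' * each treatment \eqn{t} taken up with probability
#'   \eqn{\mathrm{logit}^{-1}(a_t + \sum_d b_{t,d} x_d)} where \eqn{a_t} is
#'   the logit of `uptake_rates[t]` and \eqn{b_{t,d}} are the log-odds shifts
#'   in `uptake_shifts` for the patient's demographic levels \eqn{x_d}.
#'   Non-taken-up records receive a fine status drawn from
#'   `non_uptake_status_probs`.
#' * latent index
#'   \eqn{y^* = \gamma_0 + \gamma_s s_0 + \sum_t \gamma_t T_t +
#'   \sum_d \gamma_d x_d + \sum_{d,t} \gamma_{d,t} x_d T_t + \epsilon},
#'   \eqn{\epsilon \sim N(0,1)} (sd fixed at 1 for probit identification),
#'   cut at `cutpoints` into a candidate change \eqn{\Delta \in \{-4..4\}},
#'   then clipped so the follow-up score \eqn{s_0 + \Delta} stays in 0..4.
#' * the follow-up score is set missing with probability `followup_missing`.
#'
#' Positive demographic coefficients push \eqn{\Delta} up, i.e. make the
#' group improve less (the harmful direction); negative treatment
#' coefficients make a treatment beneficial.
#'
#' Default marginals follow the published post-exclusion cohort composition
#' (38.87% female; 13.15% Asian or Asian British, 13.31% Black or Black
#' British, 3.85% Mixed, 64.17% White, 3.08% other ethnicity, the remainder
#' split between the refused/unknown administrative categories). The default
#' cohort size (10557) and missingness/under-18 rates emulate the audit's
#' exclusion flow, leaving roughly 6813 analysable adults with complete
#' assessments. Remaining defaults (age-group mix centred near a mean age of
#' 30, uptake rates, initial-score distribution skewed towards 2--4) are
#' plausible audit-scale values documented in the methods vignette. All
#' effect coefficients default to zero, so the default configuration is a
#' null model.
#'
#' @param n Cohort size.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param gender_marginal,ethnicity_marginal,age_group_marginal Named
#'   probability vectors over the corresponding levels (must sum to 1).
#' @param initial_score_dist Probability vector over initial scores 0..4.
#' @param uptake_rates Named baseline take-up probabilities per treatment.
#' @param uptake_shifts Named list: treatment -> named numeric vector of
#'   log-odds shifts per demographic level (e.g.
#'   `list(CBTp = c("18-24" = -1))`).
#' @param non_uptake_status_probs Named probabilities over the fine
#'   non-taken-up statuses.
#' @param outcome List of latent-index coefficients: `intercept`
#'   (\eqn{\gamma_0}), `score` (\eqn{\gamma_s}), `treatment` (named,
#'   \eqn{\gamma_t}), `demographic` (named by level, \eqn{\gamma_d}),
#'   `interaction` (named `"level:treatment"`, \eqn{\gamma_{d,t}}).
#' @param cutpoints Increasing vector of 8 latent thresholds mapping
#'   \eqn{y^*} to \eqn{\Delta \in \{-4..4\}}.
#' @param noise `"normal"` (probit; the default and the analysis model) or
#'   `"logistic"` for misspecification scenarios.
#' @param followup_missing Probability that the follow-up score is missing.
#' @param under18_fraction Fraction of records given an under-18 age.
#' @param reference Reference level per demographic variable, used when
#'   toggling category membership off in [compute_truth()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 10557,
                             seed = 1L,
                             gender_marginal = c(Female = 0.3887, Male = 0.6063,
                                                 NonBinaryOther = 0.0050),
                             ethnicity_marginal = c(AsianOrAsianBritish = 0.1315,
                                                    BlackOrBlackBritish = 0.1331,
                                                    Mixed = 0.0385,
                                                    Other = 0.0308,
                                                    White = 0.6417,
                                                    Refused = 0.0122,
                                                    UnknownUndocumented = 0.0122),
                             age_group_marginal = c("18-24" = 0.40, "25-34" = 0.32,
                                                    "35-44" = 0.16, "45-54" = 0.08,
                                                    "55-69" = 0.04),
                             initial_score_dist = c(0.05, 0.10, 0.25, 0.35, 0.25),
                             uptake_rates = c(CBTp = 0.40, FamilyIntervention = 0.25,
                                              Antipsychotic = 0.90, Clozapine = 0.05,
                                              SupportedEmployment = 0.25,
                                              CarerIntervention = 0.20,
                                              Smoking = 0.30, Alcohol = 0.15,
                                              SubstanceMisuse = 0.20,
                                              WeightGain = 0.30, Hypertension = 0.10,
                                              Diabetes = 0.08, Dyslipidaemia = 0.08),
                             uptake_shifts = list(),
                             non_uptake_status_probs = c(NotOffered = 0.50,
                                                         Refused = 0.25,
                                                         NotEligible = 0.15,
                                                         Waiting = 0.10),
                             outcome = list(),
                             cutpoints = seq(-3.5, 3.5, by = 1),
                             noise = c("normal", "logistic"),
                             followup_missing = 0.34,
                             under18_fraction = 0.02,
                             reference = list(gender = "Female",
                                              ethnicity = "White",
                                              age_group = "35-44")) {
  noise <- match.arg(noise)
  outcome <- utils::modifyList(
    list(intercept = -0.8, score = -0.35,
         treatment = numeric(), demographic = numeric(),
         interaction = numeric()),
    outcome)
  cfg <- list(n = n, seed = seed,
              gender_marginal = gender_marginal,
              ethnicity_marginal = ethnicity_marginal,
              age_group_marginal = age_group_marginal,
              initial_score_dist = initial_score_dist,
              uptake_rates = uptake_rates,
              uptake_shifts = uptake_shifts,
              non_uptake_status_probs = non_uptake_status_probs,
              outcome = outcome,
              cutpoints = cutpoints,
              noise = noise,
              followup_missing = followup_missing,
              under18_fraction = under18_fraction,
              reference = reference)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n > 0)
  check_marg <- function(p, levels, what) {
    if (is.null(names(p)) || !all(names(p) %in% levels)) {
      stop(what, " must be named with levels in {",
           paste(levels, collapse = ", "), "}", call. = FALSE)
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be a probability vector summing to 1", call. = FALSE)
    }
    if (all(p == 0)) stop(what, " is degenerate", call. = FALSE)
  }
  check_marg(cfg$gender_marginal, gender_levels(), "gender_marginal")
  check_marg(cfg$ethnicity_marginal, ethnicity_levels(), "ethnicity_marginal")
  check_marg(cfg$age_group_marginal, age_group_levels(), "age_group_marginal")
  if (length(cfg$initial_score_dist) != 5 ||
      abs(sum(cfg$initial_score_dist) - 1) > 1e-9) {
    stop("initial_score_dist must be 5 probabilities over scores 0..4 summing to 1",
         call. = FALSE)
  }
  if (!setequal(names(cfg$uptake_rates), treatment_names())) {
    stop("uptake_rates must name every configured treatment", call. = FALSE)
  }
  if (length(cfg$cutpoints) != 8 || any(diff(cfg$cutpoints) <= 0)) {
    stop("cutpoints must be 8 strictly increasing thresholds", call. = FALSE)
  }
  if (abs(sum(cfg$non_uptake_status_probs) - 1) > 1e-9 ||
      !all(names(cfg$non_uptake_status_probs) %in% setdiff(uptake_levels(), "TakenUp"))) {
    stop("non_uptake_status_probs must be probabilities over non-taken-up statuses",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> n =", x$n, ", seed =", x$seed, "\n")
  eff <- x$outcome
  nz <- c(length(eff$treatment), length(eff$demographic), length(eff$interaction))
  cat("latent effects: ", nz[1], " treatment, ", nz[2], " demographic, ",
      nz[3], " interaction coefficient(s)\n", sep = "")
  invisible(x)
}

# All primitive random draws for n patients, in a fixed order so cohorts are
# byte-identical given the seed. Kept separate from assembly so that
# compute_truth() can reuse the same draws for counterfactuals
# (common random numbers).
draw_raw <- function(cfg, n = cfg$n, seed = cfg$seed) {
  with_seed(seed, {
    demo <- data.frame(
      gender = sample(names(cfg$gender_marginal), n, TRUE, cfg$gender_marginal),
      ethnicity = sample(names(cfg$ethnicity_marginal), n, TRUE, cfg$ethnicity_marginal),
      age_group = sample(names(cfg$age_group_marginal), n, TRUE, cfg$age_group_marginal),
      stringsAsFactors = FALSE)
    age_lo <- c("18-24" = 18L, "25-34" = 25L, "35-44" = 35L,
                "45-54" = 45L, "55-69" = 55L)
    age_hi <- c("18-24" = 24L, "25-34" = 34L, "35-44" = 44L,
                "45-54" = 54L, "55-69" = 67L)
    lo <- age_lo[demo$age_group]; hi <- age_hi[demo$age_group]
    age <- lo + as.integer(floor(runif(n) * (hi - lo + 1L)))
    under18 <- runif(n) < cfg$under18_fraction
    age[under18] <- 14L + as.integer(floor(runif(sum(under18)) * 4))
    s0 <- sample(0:4, n, TRUE, cfg$initial_score_dist)
    u_uptake <- matrix(runif(n * length(treatment_names())), n,
                       dimnames = list(NULL, treatment_names()))
    u_status <- matrix(runif(n * length(treatment_names())), n,
                       dimnames = list(NULL, treatment_names()))
    eps <- if (cfg$noise == "normal") rnorm(n) else stats::rlogis(n)
    u_missing <- runif(n)
    list(demo = demo, age = age, s0 = s0, u_uptake = u_uptake,
         u_status = u_status, eps = eps, u_missing = u_missing)
  })
}

# Per-patient take-up probability for every treatment given demographics.
uptake_probs <- function(cfg, demo) {
  trs <- treatment_names()
  p <- matrix(0, nrow(demo), length(trs), dimnames = list(NULL, trs))
  for (tr in trs) {
    eta <- stats::qlogis(cfg$uptake_rates[[tr]])
    shifts <- cfg$uptake_shifts[[tr]]
    if (!is.null(shifts)) {
      for (lev in names(shifts)) {
        member <- demo$gender == lev | demo$ethnicity == lev | demo$age_group == lev
        eta <- eta + shifts[[lev]] * member
      }
    }
    p[, tr] <- stats::plogis(eta)
  }
  p
}

# Latent index -> candidate ordinal change -> clipped change.
latent_to_delta <- function(cfg, demo, Tmat, s0, eps) {
  out <- cfg$outcome
  ystar <- out$intercept + out$score * s0 + eps
  for (tr in names(out$treatment)) {
    ystar <- ystar + out$treatment[[tr]] * Tmat[, tr]
  }
  member_of <- function(lev) {
    demo$gender == lev | demo$ethnicity == lev | demo$age_group == lev
  }
  for (lev in names(out$demographic)) {
    ystar <- ystar + out$demographic[[lev]] * member_of(lev)
  }
  for (key in names(out$interaction)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    ystar <- ystar + out$interaction[[key]] * member_of(parts[1]) * Tmat[, parts[2]]
  }
  cand <- findInterval(ystar, cfg$cutpoints) - 4L
  pmin(pmax(cand, -s0), 4L - s0)
}

#' Generate a synthetic audit cohort
#'
#' Draws a cohort from the generative model described in
#' [generator_config()]. Deterministic given the configuration: the same
#' config (including its seed) always produces an identical cohort.
#'
#' @param config A [generator_config()].
#' @return A [cohort_table()] (pre-exclusion: it may contain under-18
#'   records and missing follow-up scores, which [apply_exclusions()]
#'   removes).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  raw <- draw_raw(config)
  n <- config$n
  p <- uptake_probs(config, raw$demo)
  Tmat <- (raw$u_uptake < p) * 1L

  delta <- latent_to_delta(config, raw$demo, Tmat, raw$s0, raw$eps)
  followup <- raw$s0 + delta
  followup[raw$u_missing < config$followup_missing] <- NA_integer_

  rec <- data.frame(patient_id = sprintf("P%06d", seq_len(n)),
                    age = raw$age,
                    gender = raw$demo$gender,
                    ethnicity = raw$demo$ethnicity,
                    stringsAsFactors = FALSE)
  probs <- config$non_uptake_status_probs
  statuses <- names(probs)
  cum <- cumsum(probs)
  for (tr in treatment_names()) {
    fine <- statuses[findInterval(raw$u_status[, tr], c(0, head(cum, -1)))]
    rec[[uptake_col(tr)]] <- ifelse(Tmat[, tr] == 1L, "TakenUp", fine)
  }
  rec$honos6_initial <- raw$s0
  rec$honos6_followup <- as.integer(followup)
  cohort_table(rec)
}

#' Monte-Carlo ground truth for a generator configuration
#'
#' Estimates every estimand the package's estimators target by brute-force
#' simulation with common random numbers: a large latent population is drawn
#' (complete follow-up, adults only), and counterfactual outcomes are
#' recomputed holding every primitive draw fixed.
#'
#' For each demographic level \eqn{g} the average effect of membership among
#' members (the ATT) is reported in two versions: `att_direct` toggles
#' members to the variable's reference level while holding their realised
#' treatment uptake fixed (the direct, unmediated effect that full-adjustment
#' matching targets), and `att_total` also re-draws uptake under the
#' counterfactual demographic profile using the same uniforms (so inequality
#' in take-up propagates; the total effect that unadjusted contrasts absorb).
#' For each treatment the average effect of take-up
#' \eqn{E[\Delta(T=1) - \Delta(T=0)]} is reported, and interaction rows echo
#' the configured latent moderation coefficients.
#'
#' @param config A [generator_config()].
#' @param oracle_n Simulation size (1e5 or more recommended; Monte-Carlo
#'   standard errors shrink as \eqn{1/\sqrt{n}}).
#' @param oracle_seed Seed for the oracle draw, independent of the cohort
#'   seed.
#' @return A list of class `truth_table`: `demographics` (variable, level,
#'   n_members, att_direct, att_total), `treatments` (treatment, ate),
#'   `interactions` (term, coefficient).
#' @export
compute_truth <- function(config, oracle_n = 1e5, oracle_seed = 20260101L) {
  validate_generator_config(config)
  cfg <- config
  cfg$under18_fraction <- 0     # truth is defined on the analysed population:
  cfg$followup_missing <- 0     # adults with complete assessments
  raw <- draw_raw(cfg, n = oracle_n, seed = oracle_seed)
  p <- uptake_probs(cfg, raw$demo)
  Tmat <- (raw$u_uptake < p) * 1L
  delta <- latent_to_delta(cfg, raw$demo, Tmat, raw$s0, raw$eps)

  vars <- c(gender = "gender", ethnicity = "ethnicity", age_group = "age_group")
  demo_rows <- list()
  for (v in vars) {
    lv <- switch(v, gender = gender_levels(), ethnicity = ethnicity_levels(),
                 age_group = age_group_levels())
    for (lev in lv) {
      members <- raw$demo[[v]] == lev
      if (!any(members)) next
      cf_demo <- raw$demo
      cf_demo[[v]][members] <- cfg$reference[[v]]
      d_direct <- latent_to_delta(cfg, cf_demo, Tmat, raw$s0, raw$eps)
      p_cf <- uptake_probs(cfg, cf_demo)
      T_cf <- (raw$u_uptake < p_cf) * 1L
      d_total <- latent_to_delta(cfg, cf_demo, T_cf, raw$s0, raw$eps)
      demo_rows[[paste(v, lev)]] <- data.frame(
        variable = v, level = lev, n_members = sum(members),
        att_direct = mean(delta[members] - d_direct[members]),
        att_total = mean(delta[members] - d_total[members]),
        stringsAsFactors = FALSE)
    }
  }

  tr_rows <- lapply(treatment_names(), function(tr) {
    T1 <- Tmat; T1[, tr] <- 1L
    T0 <- Tmat; T0[, tr] <- 0L
    d1 <- latent_to_delta(cfg, raw$demo, T1, raw$s0, raw$eps)
    d0 <- latent_to_delta(cfg, raw$demo, T0, raw$s0, raw$eps)
    data.frame(treatment = tr, ate = mean(d1 - d0), stringsAsFactors = FALSE)
  })

  inter <- cfg$outcome$interaction
  interactions <- if (length(inter) == 0) {
    data.frame(term = character(), coefficient = numeric(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(term = names(inter), coefficient = as.numeric(unlist(inter)),
               stringsAsFactors = FALSE)
  }

  structure(list(demographics = do.call(rbind, demo_rows),
                 treatments = do.call(rbind, tr_rows),
                 interactions = interactions,
                 oracle_n = oracle_n, oracle_seed = oracle_seed),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("<truth_table> oracle_n =", format(x$oracle_n, big.mark = ","), "\n")
  nz <- x$demographics[abs(x$demographics$att_direct) > 1e-3 |
                         abs(x$demographics$att_total) > 1e-3, ]
  if (nrow(nz) > 0) {
    cat("non-null demographic ATTs:\n")
    print.data.frame(nz, row.names = FALSE, digits = 3)
  } else cat("all demographic ATTs ~ 0\n")
  invisible(x)
}

#' Export a truth table as CSV
#'
#' @param truth A [compute_truth()] result.
#' @param path Output CSV path; the three blocks are stacked with a
#'   `block` column.
#' @export
write_truth_table <- function(truth, path) {
  blk <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    cbind(block = name, df)
  }
  rows <- list(blk(truth$demographics, "demographic_att"),
               blk(truth$treatments, "treatment_ate"),
               blk(truth$interactions, "interaction_coefficient"))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, lapply(rows, function(df) {
    all_cols <- c("block", "variable", "level", "treatment", "term",
                  "n_members", "att_direct", "att_total", "ate", "coefficient")
    for (cl in setdiff(all_cols, names(df))) df[[cl]] <- NA
    df[all_cols]
  }))
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
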