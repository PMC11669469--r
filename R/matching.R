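#' Single nearest-neighbour matching with replacement
#'
#' Pairs every target unit with the pool unit minimising the covariate
#' distance. Matching is with replacement (pool units may be reused), and
#' equidistant pool units break ties to the lowest pool index, so the result
#' is deterministic. Covariates are expected on the scale the moderation
#' estimator uses: binary indicators and/or the initial score rescaled to
#' \[0,1\] (i.e. values on the quarter grid 0, 0.25, ..., 1).
#'
#' Distances: `"hamming"` is the L1 distance, which on binary coordinates
#' counts disagreements and on the rescaled score contributes the absolute
#' difference; `"euclidean"` squares the coordinate differences instead.
#'
#' When `target_ids`/`pool_ids` are supplied, a target is never matched to a
#' pool unit carrying its own id — the self-match guard needed when bootstrap
#' resampling duplicates records (duplicates of *other* records remain
#' eligible).
#'
#' @param targets,pool Numeric matrices (rows = units, columns = covariates
#'   on the quarter grid).
#' @param distance `"hamming"` (default) or `"euclidean"`.
#' @param target_ids,pool_ids Optional integer record ids for self-match
#'   exclusion.
#' @return A list of class `match_result`: `pairs` (data.frame `target`,
#'   `pool`, `distance`) and `multiplicity` (reuse count per matched pool
#'   unit).
#' @export
match_nearest <- function(targets, pool, distance = c("hamming", "euclidean"),
                          target_ids = NULL, pool_ids = NULL) {
  distance <- match.arg(distance)
  targets <- as.matrix(targets); pool <- as.matrix(pool)
  if (nrow(pool) == 0) stop("pool is empty", call. = FALSE)
  if (ncol(targets) != ncol(pool)) {
    stop("targets and pool must have the same covariates", call. = FALSE)
  }
  if (xor(is.null(target_ids), is.null(pool_ids))) {
    stop("supply both target_ids and pool_ids, or neither", call. = FALSE)
  }
  Xt <- quarter_grid_int(targets, "targets")
  Xp <- quarter_grid_int(pool, "pool")
  metric <- if (distance == "hamming") 0L else 1L
  res <- nn_match_cpp(Xt, Xp, metric,
                      if (is.null(target_ids)) NULL else as.integer(target_ids),
                      if (is.null(pool_ids)) NULL else as.integer(pool_ids))
  d <- if (distance == "hamming") res$dist_scaled / 4 else sqrt(res$dist_scaled / 16)
  pairs <- data.frame(target = seq_len(nrow(targets)), pool = res$match,
                      distance = d)
  structure(list(pairs = pairs, multiplicity = table(res$match),
                 distance = distance),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$pairs), " targets matched (",
      x$distance, " distance); ", sum(x$multiplicity > 1),
      " pool unit(s) reused\n", sep = "")
  print.data.frame(head(x$pairs, 6), row.names = FALSE)
  invisible(x)
}

# Covariates live on {0, .25, .5, .75, 1}; scale x4 to exact integers for
# the compiled kernel.
quarter_grid_int <- function(x, what) {
  x4 <- x * 4
  if (any(!is.finite(x4)) || max(abs(x4 - round(x4))) > 1e-9 ||
      any(x4 < 0) || any(x4 > 4)) {
    stop(what, " covariates must be binary or quarter-scaled to [0,1]",
         call. = FALSE)
  }
  matrix(as.integer(round(x4)), nrow(x), ncol(x), dimnames = dimnames(x))
}

#' Matching covariates for a moderation analysis
#'
#' Builds the covariate matrix the moderation estimator matches on.
#' `"initial_score"` mode uses the initial symptom score alone (rescaled to
#' \[0,1\]); `"full"` mode adds every binarised treatment-uptake indicator
#' and a one-hot encoding of every demographic variable *except* the one
#' being inspected (the whole variable is left out, not just the inspected
#' level, so group membership cannot leak into the match).
#'
#' @param cohort A post-exclusion [cohort_table()].
#' @param mode `"full"` or `"initial_score"`.
#' @param exclude_variable Demographic variable under inspection
#'   (`"gender"`, `"ethnicity"`, `"age_group"`); ignored in
#'   `"initial_score"` mode.
#' @return Numeric matrix with one row per patient.
#' @export
matching_covariates <- function(cohort, mode = c("full", "initial_score"),
                                exclude_variable = NULL) {
  mode <- match.arg(mode)
  df <- as.data.frame(cohort)
  score <- df$honos6_initial / 4
  if (mode == "initial_score") {
    return(matrix(score, ncol = 1, dimnames = list(NULL, "initial_score")))
  }
  cols <- list(initial_score = score)
  for (tr in cohort_treatments(cohort)) {
    cols[[uptake_col(tr)]] <- as.numeric(binarise_uptake(df[[uptake_col(tr)]]))
  }
  demo <- list(gender = df$gender, ethnicity = df$ethnicity,
               age_group = as.character(encode_age_group(df$age)))
  lv <- list(gender = gender_levels(), ethnicity = ethnicity_levels(),
             age_group = age_group_levels())
  for (v in setdiff(names(demo), exclude_variable)) {
    for (l in lv[[v]]) cols[[paste(v, l, sep = "_")]] <- as.numeric(demo[[v]] == l)
  }
  do.call(cbind, cols)
}

#' Moderation effect of demographic category membership on outcome change
#'
#' Estimates how membership of one demographic category moderates symptom
#' outcome change: every category member (target) is matched, with
#' replacement, to its nearest non-members, and the effect is the mean
#' outcome change of members minus the mean matched outcome change — the
#' average effect of membership among members (ATT). Positive values mean
#' the group improved *less* than comparable non-members.
#'
#' When several pool units are equidistant-nearest, the matched outcome for
#' that target is the *mean* outcome change over the whole tie set (the
#' expected value under random tie-breaking). This keeps the estimator
#' deterministic while avoiding the degenerate comparison sets a fixed
#' tie-break would produce on coarse covariates (in `"initial_score"` mode
#' there are only five covariate profiles, so the estimator is effectively
#' exact subclassification on the initial score).
#'
#' Two adjustment modes mirror the two audit analyses: `"initial_score"`
#' matches on the initial score alone, while `"full"` matches on initial
#' score, all binarised treatment-uptake indicators and the remaining
#' demographic variables (the inspected variable itself is excluded from the
#' covariates). A group effect present under `"initial_score"` but absent
#' under `"full"` indicates mediation through treatment uptake rather than a
#' direct disparity.
#'
#' The 95% confidence interval is a percentile bootstrap: by default the
#' whole cohort is resampled with replacement and the matching is *re-run
#' inside every resample* (`ci_method = "rematch"`), so the interval reflects
#' matching variability; `ci_method = "pairs"` instead resamples the matched
#' pair differences from the single original match.
#'
#' @param cohort A post-exclusion [cohort_table()].
#' @param variable Demographic variable (`"gender"`, `"ethnicity"`,
#'   `"age_group"`).
#' @param level Category level under inspection.
#' @param mode Adjustment mode, `"full"` or `"initial_score"`.
#' @param distance Matching distance, `"hamming"` or `"euclidean"`.
#' @param n_boot Bootstrap replicates (audit default 1000).
#' @param seed Integer seed for the bootstrap resampling.
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method `"rematch"` (default) or `"pairs"`.
#' @param score_weight Distance cost of one initial-score point relative to
#'   one binary disagreement: 4 (default; one score point = one covariate
#'   disagreement) or 1 (the score rescaled to \[0,1\] as a single
#'   coordinate). The default avoids the mismatch-resolution bias of the
#'   cheap-score metric: when no exact match exists, a cheap score
#'   coordinate makes the nearest neighbour preferentially mismatch on
#'   initial score — the one covariate that strongly drives outcome change —
#'   pulling matched scores toward the pool mode.
#' @param estimand `"att"` (default) or `"ate"`; `"ate"` additionally
#'   matches non-members to members and weights the two directions by group
#'   share.
#' @return One-row `data.frame`: `variable`, `level`, `mode`, `n_group`,
#'   `effect`, `ci_low`, `ci_high`.
#' @export
moderation_effect <- function(cohort, variable, level,
                              mode = c("full", "initial_score"),
                              distance = c("hamming", "euclidean"),
                              n_boot = 1000, seed = NULL, conf_level = 0.95,
                              ci_method = c("rematch", "pairs"),
                              score_weight = 4L,
                              estimand = c("att", "ate")) {
  mode <- match.arg(mode)
  distance <- match.arg(distance)
  ci_method <- match.arg(ci_method)
  estimand <- match.arg(estimand)
  stopifnot(n_boot >= 1, conf_level > 0, conf_level < 1,
            score_weight %in% c(1L, 4L))

  df <- as.data.frame(cohort)
  memb <- switch(variable,
                 gender = df$gender == level,
                 ethnicity = df$ethnicity == level,
                 age_group = as.character(encode_age_group(df$age)) == level,
                 stop("unknown demographic variable: ", variable, call. = FALSE))
  n <- nrow(df)
  n_group <- sum(memb)
  if (n_group == 0) {
    warning("no members of ", variable, " = ", level, "; effect suppressed",
            call. = FALSE)
    return(data.frame(variable = variable, level = level, mode = mode,
                      n_group = 0L, effect = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_))
  }
  if (n - n_group == 0) {
    warning("pool of non-members for ", variable, " = ", level,
            " is empty; effect suppressed", call. = FALSE)
    return(data.frame(variable = variable, level = level, mode = mode,
                      n_group = n_group, effect = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_))
  }
  if ((n - n_group) < 5 * n_group) {
    warning("pool smaller than 5x group for ", variable, " = ", level,
            "; matches will be heavily reused", call. = FALSE)
  }

  X <- quarter_grid_int(matching_covariates(cohort, mode, exclude_variable = variable), "cohort")
  delta <- df$honos6_followup - df$honos6_initial
  metric <- if (distance == "hamming") 0L else 1L
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)

  if (ci_method == "pairs") {
    mm <- nn_match_avg_cpp(X[memb, , drop = FALSE], X[!memb, , drop = FALSE],
                           delta[!memb], metric, as.integer(score_weight))
    pd <- delta[memb] - mm$matched_mean
    effect <- mean(pd)
    boots <- with_seed(seed, {
      idx <- matrix(sample.int(length(pd), length(pd) * n_boot, replace = TRUE),
                    ncol = n_boot)
      colMeans(matrix(pd[idx], ncol = n_boot))
    })
    ci <- unname(quantile(boots, probs))
    return(data.frame(variable = variable, level = level, mode = mode,
                      n_group = n_group, effect = effect,
                      ci_low = ci[1], ci_high = ci[2]))
  }

  resamples <- with_seed(seed, matrix(sample.int(n, n * n_boot, replace = TRUE),
                                      nrow = n, ncol = n_boot))
  eff_att <- moderation_boot_cpp(X, memb, delta, resamples, metric,
                                 as.integer(score_weight))
  if (estimand == "ate") {
    eff_rev <- moderation_boot_cpp(X, !memb, delta, resamples, metric,
                                   as.integer(score_weight))
    w <- c(n_group, colSums(matrix(memb[resamples], nrow = n))) / n
    eff <- w * eff_att - (1 - w) * eff_rev
  } else {
    eff <- eff_att
  }
  if (anyNA(eff[-1])) {
    warning(sum(is.na(eff[-1])), " bootstrap resample(s) had an empty group ",
            "or pool and were dropped", call. = FALSE)
  }
  ci <- unname(quantile(eff[-1], probs, na.rm = TRUE))
  data.frame(variable = variable, level = level, mode = mode,
             n_group = n_group, effect = eff[1],
             ci_low = ci[1], ci_high = ci[2])
}

#' Moderation-effect table across all demographic categories
#'
#' Runs [moderation_effect()] for every observed level of gender, age group
#' and broad ethnicity category, under one or both adjustment modes — the
#' tabular analogue of the audit's moderation analysis. Categories with
#' fewer than `suppress_n` members are reported with `suppressed = TRUE` and
#' masked estimates (statistical-disclosure floor; low-count administrative
#' ethnicity categories fall out of reporting this way while remaining in
#' the data-set and in every matching pool).
#'
#' @inheritParams moderation_effect
#' @param modes Adjustment modes to run (default both).
#' @param suppress_n Minimum group size for reporting (default 10).
#' @return `data.frame` with columns `variable`, `level`, `mode`, `n_group`,
#'   `effect`, `ci_low`, `ci_high`, `suppressed`.
#' @export
moderation_table <- function(cohort, n_boot = 1000, seed = NULL,
                             modes = c("initial_score", "full"),
                             distance = c("hamming", "euclidean"),
                             ci_method = c("rematch", "pairs"),
                             score_weight = 4L,
                             suppress_n = 10, conf_level = 0.95) {
  distance <- match.arg(distance)
  ci_method <- match.arg(ci_method)
  df <- as.data.frame(cohort)
  demo <- list(gender = df$gender, ethnicity = df$ethnicity,
               age_group = as.character(encode_age_group(df$age)))
  lv <- list(gender = gender_levels(), ethnicity = ethnicity_levels(),
             age_group = age_group_levels())
  specs <- list()
  for (v in names(demo)) {
    for (l in lv[[v]][lv[[v]] %in% unique(demo[[v]])]) {
      for (m in modes) specs[[length(specs) + 1]] <- list(v = v, l = l, m = m)
    }
  }
  seeds <- split_seed(seed, length(specs))
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    row <- moderation_effect(cohort, s$v, s$l, mode = s$m, distance = distance,
                             n_boot = n_boot, seed = seeds[[i]],
                             conf_level = conf_level, ci_method = ci_method,
                             score_weight = score_weight)
    row$suppressed <- row$n_group < suppress_n
    if (row$suppressed) {
      message("suppressed moderation cell ", s$v, " = ", s$l, " (mode ", s$m,
              "): n = ", row$n_group, " < ", suppress_n)
      row$effect <- row$ci_low <- row$ci_high <- NA_real_
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
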