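#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples `values` with replacement (`n_boot` resamples of the full
#' sample size), takes the mean of each resample, and returns the
#' percentile interval of that bootstrap distribution. Seeded and
#' reproducible; a constant (or singleton) input yields a zero-width
#' interval.
#'
#' @param values Non-empty numeric vector.
#' @param n_boot Number of bootstrap resamples (audit default 1000).
#' @param level Confidence level in (0, 1), default 0.95.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000, level = 0.95, seed = NULL) {
  if (length(values) == 0) stop("values must be non-empty", call. = FALSE)
  stopifnot(n_boot >= 1, level > 0, level < 1)
  m <- length(values)
  means <- with_seed(seed, {
    idx <- sample.int(m, m * n_boot, replace = TRUE)
    colMeans(matrix(values[idx], nrow = m, ncol = n_boot))
  })
  unname(quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Mean outcome change by demographic category or treatment uptake
#'
#' Groups a post-exclusion cohort by one demographic category type (gender,
#' age group, broad ethnicity) or by the *fine* uptake status of one
#' treatment (taken up / refused / waiting / not offered / not eligible /
#' unknown — deliberately not the binary encoding), and reports each group's
#' size, mean initial and follow-up scores, mean outcome change (follow-up
#' minus initial; negative = improvement) and a percentile-bootstrap
#' confidence interval for the mean change. Group means are resampled
#' within group, independently across groups. Groups below `suppress_n`
#' members are reported with masked statistics (`suppressed = TRUE`).
#'
#' @param cohort A post-exclusion [cohort_table()].
#' @param by `"gender"`, `"age_group"`, `"ethnicity"` or `"treatment"`.
#' @param treatment Treatment name, required when `by = "treatment"`.
#' @param n_boot,level,seed Bootstrap settings as in [bootstrap_ci()].
#' @param suppress_n Minimum group size for reporting (default 10).
#' @return `data.frame`: `group`, `n`, `mean_initial`, `mean_followup`,
#'   `mean_change`, `ci_low`, `ci_high`, `suppressed`.
#' @export
group_outcomes <- function(cohort, by = c("gender", "age_group", "ethnicity",
                                          "treatment"),
                           treatment = NULL, n_boot = 1000, level = 0.95,
                           seed = NULL, suppress_n = 10) {
  by <- match.arg(by)
  df <- as.data.frame(cohort)
  g <- switch(by,
              gender = factor(df$gender, levels = gender_levels()),
              ethnicity = factor(df$ethnicity, levels = ethnicity_levels()),
              age_group = encode_age_group(df$age),
              treatment = {
                if (is.null(treatment) ||
                    !(treatment %in% cohort_treatments(cohort))) {
                  stop("by = \"treatment\" requires a configured treatment name",
                       call. = FALSE)
                }
                factor(df[[uptake_col(treatment)]], levels = uptake_levels())
              })
  delta <- df$honos6_followup - df$honos6_initial
  groups <- levels(g)[levels(g) %in% g]
  seeds <- split_seed(seed, length(groups))
  rows <- lapply(seq_along(groups), function(i) {
    sel <- !is.na(g) & g == groups[i]
    n <- sum(sel)
    if (n < suppress_n) {
      return(data.frame(group = groups[i], n = n, mean_initial = NA_real_,
                        mean_followup = NA_real_, mean_change = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        suppressed = TRUE, stringsAsFactors = FALSE))
    }
    ci <- bootstrap_ci(delta[sel], n_boot = n_boot, level = level,
                       seed = seeds[[i]])
    data.frame(group = groups[i], n = n,
               mean_initial = mean(df$honos6_initial[sel]),
               mean_followup = mean(df$honos6_followup[sel]),
               mean_change = mean(delta[sel]),
               ci_low = ci[1], ci_high = ci[2], suppressed = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "by") <- by
  attr(out, "treatment") <- treatment
  out
}
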