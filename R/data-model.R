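#' Category levels used by the cohort data model
#'
#' The data model uses closed enumerations for gender, broad (ONS) ethnicity
#' category, age group, treatment/intervention names and uptake status.
#' Ethnicity uses the five broad ONS groups plus the audit's "Refused" and
#' "Unknown/undocumented" administrative categories, which stay in the
#' analysis data-set but are masked from reported summaries when counts are
#' low. Age groups are 18-24, 25-34, 35-44, 45-54 and 55-69, the last bin
#' absorbing all ages 55 and over.
#'
#' @return A character vector of level names.
#' @name cohort-levels
NULL

#' @rdname cohort-levels
#' @export
gender_levels <- function() c("Female", "Male", "NonBinaryOther")

#' @rdname cohort-levels
#' @export
ethnicity_levels <- function() {
  c("AsianOrAsianBritish", "BlackOrBlackBritish", "Mixed", "Other", "White",
    "Refused", "UnknownUndocumented")
}

#' @rdname cohort-levels
#' @export
age_group_levels <- function() c("18-24", "25-34", "35-44", "45-54", "55-69")

#' @rdname cohort-levels
#' @export
uptake_levels <- function() {
  c("TakenUp", "Refused", "Waiting", "NotOffered", "NotEligible", "Unknown")
}

#' @rdname cohort-levels
#' @export
treatment_names <- function() {
  c("CBTp", "FamilyIntervention", "Antipsychotic", "Clozapine",
    "SupportedEmployment", "CarerIntervention", "Smoking", "Alcohol",
    "SubstanceMisuse", "WeightGain", "Hypertension", "Diabetes",
    "Dyslipidaemia")
}

uptake_col <- function(treatment) paste0("uptake_", treatment)

#' Construct a cohort table
#'
#' A cohort table is a `data.frame` (class `cohort_table`) with one row per
#' audited patient: `patient_id`, `age` (integer years), `gender`,
#' `ethnicity`, one `uptake_<Treatment>` column per configured treatment
#' (an [uptake_levels()] status), and two ordinal symptom scores
#' `honos6_initial` and `honos6_followup` (integers 0--4, `NA` when not
#' recorded). An `exclusion_log` attribute records each filtering stage as
#' `(stage, n_before, n_excluded, n_after)`.
#'
#' @param records A `data.frame` with the columns described above.
#' @param treatments Character vector of treatment names; defaults to
#'   [treatment_names()].
#' @param exclusion_log A `data.frame` of applied exclusion stages, or `NULL`
#'   for a cohort with no filtering applied yet.
#' @return A `cohort_table`.
#' @export
cohort_table <- function(records, treatments = treatment_names(),
                         exclusion_log = NULL) {
  stopifnot(is.data.frame(records))
  needed <- c("patient_id", "age", "gender", "ethnicity",
              "honos6_initial", "honos6_followup", uptake_col(treatments))
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  validate_scores(records$honos6_initial, "honos6_initial")
  validate_scores(records$honos6_followup, "honos6_followup")
  if (any(!is.na(records$age) & records$age < 0)) {
    stop("age must be non-negative", call. = FALSE)
  }
  if (is.null(exclusion_log)) {
    exclusion_log <- data.frame(stage = character(), n_before = integer(),
                                n_excluded = integer(), n_after = integer(),
                                stringsAsFactors = FALSE)
  }
  structure(records,
            class = c("cohort_table", "data.frame"),
            treatments = treatments,
            exclusion_log = exclusion_log)
}

validate_scores <- function(x, name) {
  bad <- !is.na(x) & (!is.finite(x) | x != as.integer(x) | x < 0 | x > 4)
  if (any(bad)) {
    stop(name, " must be an integer in 0..4 or missing (rows ",
         paste(head(which(bad), 5), collapse = ", "), ")", call. = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.cohort_table <- function(x, ...) {
  attr(x, "treatments") <- NULL
  attr(x, "exclusion_log") <- NULL
  class(x) <- "data.frame"
  x
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x), " patients, ",
      length(attr(x, "treatments")), " treatments\n", sep = "")
  log <- exclusion_log(x)
  if (nrow(log) > 0) {
    cat("exclusions applied:\n")
    print.data.frame(log, row.names = FALSE)
  }
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

#' Exclusion log of a cohort
#'
#' @param cohort A [cohort_table()].
#' @return A `data.frame` with columns `stage`, `n_before`, `n_excluded`,
#'   `n_after`, one row per applied filtering stage (the flow-chart analogue).
#' @export
exclusion_log <- function(cohort) {
  attr(cohort, "exclusion_log")
}

#' Treatments configured for a cohort
#' @param cohort A [cohort_table()].
#' @return Character vector of treatment names.
#' @export
cohort_treatments <- function(cohort) attr(cohort, "treatments")

#' Default schema for reading cohort CSV files
#'
#' Maps file columns to cohort fields and raw labels to enumeration levels.
#' The default is the identity mapping (file columns named exactly as the
#' cohort fields, labels equal to the level names). Pass a modified copy, or
#' a YAML/JSON file path via [read_schema()], to ingest differently-labelled
#' extracts.
#'
#' @param treatments Character vector of treatment names.
#' @return A list with elements `columns` (named character: field -> file
#'   column) and `labels` (named list of named character vectors: raw label ->
#'   level, per categorical field).
#' @export
cohort_schema <- function(treatments = treatment_names()) {
  fields <- c("patient_id", "age", "gender", "ethnicity",
              uptake_col(treatments), "honos6_initial", "honos6_followup")
  list(columns = setNames(fields, fields),
       labels = list(),
       treatments = treatments)
}

#' Read a schema config from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose top level has
#'   the structure of [cohort_schema()]; omitted entries keep their defaults.
#' @return A schema list as from [cohort_schema()].
#' @export
read_schema <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML schema files")
    }
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the 'jsonlite' package is required to read JSON schema files")
    }
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  schema <- cohort_schema(cfg$treatments %||% treatment_names())
  if (!is.null(cfg$columns)) schema$columns[names(cfg$columns)] <- unlist(cfg$columns)
  if (!is.null(cfg$labels)) {
    schema$labels[names(cfg$labels)] <- lapply(cfg$labels, unlist)
  }
  schema
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a patient-level cohort from CSV
#'
#' Reads an RFC 4180 comma-separated cohort table (header row required).
#' Unrecognised category labels are mapped to the field's unknown category
#' (`UnknownUndocumented` for ethnicity, `Unknown` for uptake, `NA` for
#' gender, which has no unknown level) with a warning. Missing scores are
#' retained as `NA`; filtering is a separate, logged step
#' ([apply_exclusions()]).
#'
#' @param path Path to a CSV file (or a connection).
#' @param schema A schema config from [cohort_schema()] / [read_schema()].
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character", na.strings = c("", "NA"))
  cols <- schema$columns
  missing_cols <- cols[!cols %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("input is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(cols)) out[[field]] <- raw[[cols[[field]]]]

  out$age <- parse_int_column(out$age, "age")
  out$honos6_initial <- parse_int_column(out$honos6_initial, "honos6_initial")
  out$honos6_followup <- parse_int_column(out$honos6_followup, "honos6_followup")

  out$gender <- decode_labels(out$gender, gender_levels(),
                              schema$labels$gender, "gender", unknown = NA_character_)
  out$ethnicity <- decode_labels(out$ethnicity, ethnicity_levels(),
                                 schema$labels$ethnicity, "ethnicity",
                                 unknown = "UnknownUndocumented")
  for (tr in schema$treatments) {
    cl <- uptake_col(tr)
    out[[cl]] <- decode_labels(out[[cl]], uptake_levels(),
                               schema$labels$uptake, cl, unknown = "Unknown")
  }
  cohort_table(out, treatments = schema$treatments)
}

parse_int_column <- function(x, name) {
  ok <- is.na(x) | grepl("^\\s*-?[0-9]+\\s*$", x)
  if (!all(ok)) {
    stop("non-integer value in column '", name, "' at row(s) ",
         paste(head(which(!ok), 5), collapse = ", "), call. = FALSE)
  }
  as.integer(x)
}

decode_labels <- function(x, levels, mapping, field, unknown) {
  if (!is.null(mapping)) {
    hit <- x %in% names(mapping)
    x[hit] <- unname(mapping[x[hit]])
  }
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    warning(sum(bad), " unparseable label(s) in '", field, "' mapped to ",
            if (is.na(unknown)) "NA" else unknown, call. = FALSE)
    x[bad] <- unknown
  }
  x
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()] under the default schema: a written cohort
#' round-trips field-for-field.
#'
#' @param cohort A [cohort_table()].
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export the exclusion log as CSV
#'
#' @param cohort A [cohort_table()] after [apply_exclusions()].
#' @param path Output CSV path.
#' @export
write_exclusion_log <- function(cohort, path) {
  write.csv(exclusion_log(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Assign an adult age to its audit age group
#'
#' Bins are 18-24, 25-34, 35-44, 45-54 and 55-69 (inclusive edges). Any age
#' of 55 or over, including ages beyond 69, falls in the top bin, which keeps
#' sparse older ages pooled.
#'
#' @param age Integer vector of ages in years; all must be >= 18.
#' @return Factor with levels [age_group_levels()].
#' @export
encode_age_group <- function(age) {
  if (any(!is.na(age) & age < 18)) {
    stop("age groups are defined for ages >= 18 only; apply exclusions first",
         call. = FALSE)
  }
  cut(age, breaks = c(18, 25, 35, 45, 55, Inf), right = FALSE,
      labels = age_group_levels())
}

#' Binarise an uptake status
#'
#' Dichotomises fine uptake statuses into taken-up (1) versus everything else
#' (refused, waiting, not offered, not eligible, unknown; 0). `not_taken_up`
#' lets the 0 class be restricted (e.g. to exclude `Waiting`), in which case
#' statuses outside both classes become `NA`.
#'
#' @param status Character vector of [uptake_levels()] statuses.
#' @param not_taken_up Statuses mapped to 0; default all non-taken-up levels.
#' @return Integer vector of 0/1 (NA for statuses in neither class).
#' @export
binarise_uptake <- function(status, not_taken_up = setdiff(uptake_levels(), "TakenUp")) {
  out <- ifelse(status == "TakenUp", 1L,
                ifelse(status %in% not_taken_up, 0L, NA_integer_))
  out[is.na(status)] <- NA_integer_
  out
}

#' Apply the study exclusion pipeline
#'
#' Two sequential logged stages mirror the audit inclusion criteria:
#' (1) drop patients younger than 18 (or with unrecorded age); (2) drop
#' patients missing either the initial or the follow-up symptom score. Row
#' order is preserved and each stage is appended to the exclusion log, so the
#' log reads as the study flow chart. Applying the pipeline twice is a no-op
#' beyond two zero-count log rows.
#'
#' @param cohort A [cohort_table()].
#' @return The filtered [cohort_table()] with an updated exclusion log.
#' @export
apply_exclusions <- function(cohort) {
  log <- exclusion_log(cohort)
  n0 <- nrow(cohort)

  keep1 <- !is.na(cohort$age) & cohort$age >= 18
  stage1 <- as.data.frame(cohort)[keep1, , drop = FALSE]
  log <- rbind(log, data.frame(stage = "age_18_plus", n_before = n0,
                               n_excluded = n0 - nrow(stage1),
                               n_after = nrow(stage1)))

  keep2 <- !is.na(stage1$honos6_initial) & !is.na(stage1$honos6_followup)
  stage2 <- stage1[keep2, , drop = FALSE]
  log <- rbind(log, data.frame(stage = "both_honos6_scores",
                               n_before = nrow(stage1),
                               n_excluded = nrow(stage1) - nrow(stage2),
                               n_after = nrow(stage2)))
  if (nrow(stage2) == 0) {
    warning("all records excluded; cohort is empty", call. = FALSE)
  }
  rownames(stage2) <- NULL
  cohort_table(stage2, treatments = cohort_treatments(cohort),
               exclusion_log = log)
}

#' Chi-squared demographic balance check
#'
#' Compares the distribution of one demographic variable before and after
#' exclusions with a plain Pearson chi-squared test (no continuity
#' correction) on the categories-by-cohort contingency table, the check used
#' to confirm that filtering introduced no new demographic bias. Categories
#' with zero count in both cohorts are dropped; the degrees of freedom are
#' k - 1 for k retained categories.
#'
#' @param before,after Two [cohort_table()]s (typically pre/post exclusion).
#' @param variable One of `"gender"`, `"ethnicity"`, `"age_group"`.
#' @return A list of class `chisq_balance`: `statistic`, `df`, `p_value`,
#'   and the contingency `table`.
#' @export
balance_check <- function(before, after, variable = c("gender", "ethnicity", "age_group")) {
  variable <- match.arg(variable)
  if (nrow(before) == 0 || nrow(after) == 0) {
    stop("both cohorts must be non-empty", call. = FALSE)
  }
  pull <- function(cohort) {
    if (variable == "age_group") as.character(encode_age_group(cohort$age))
    else as.data.frame(cohort)[[variable]]
  }
  lv <- switch(variable, gender = gender_levels(),
               ethnicity = ethnicity_levels(), age_group = age_group_levels())
  tab <- cbind(before = table(factor(pull(before), levels = lv)),
               after = table(factor(pull(after), levels = lv)))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2) {
    stop("fewer than 2 categories with non-zero counts; balance check is degenerate",
         call. = FALSE)
  }
  # Pearson X^2 computed directly so that identical distributions give an
  # exact 0 (chisq.test's expected-count warnings are irrelevant here).
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- nrow(tab) - 1L
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 table = tab, variable = variable),
            class = "chisq_balance")
}

#' @export
print.chisq_balance <- function(x, ...) {
  cat("Pearson chi-squared balance check on ", x$variable, ": X^2 = ",
      format(x$statistic, digits = 4), ", df = ", x$df, ", p = ",
      format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}
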