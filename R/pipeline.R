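#' Configuration for an end-to-end audit run
#'
#' Bundles every knob of the full pipeline (ingest, exclusions, balance
#' checks, observational tables, moderation table, regression, interaction
#' report) into one serialisable object that is embedded verbatim in the
#' output bundle, so a run is reproducible from its own report.
#'
#' Exactly one of `input` (a cohort CSV path) or `generator` (a
#' [generator_config()]) must be supplied.
#'
#' @param input Path to a cohort CSV, or `NULL`.
#' @param generator A [generator_config()], or `NULL`.
#' @param seed Global seed; per-stage seeds are fanned out deterministically
#'   so stages can be re-run in isolation.
#' @param n_boot Bootstrap replicates for every interval (audit default
#'   1000).
#' @param alpha Two-sided significance level (default 0.05).
#' @param modes Moderation adjustment modes to run.
#' @param include_interactions,interaction_whitelist Regression interaction
#'   settings (see [build_design()]).
#' @param mtc Multiple-testing correction for the interaction report.
#' @param suppress_n Reporting suppression floor (default 10).
#' @param schema Schema for [read_cohort()] when `input` is used.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, generator = NULL, seed = 1L,
                       n_boot = 1000, alpha = 0.05,
                       modes = c("initial_score", "full"),
                       include_interactions = TRUE,
                       interaction_whitelist = NULL,
                       mtc = c("none", "benjamini_hochberg"),
                       suppress_n = 10, schema = cohort_schema()) {
  if (is.null(input) == is.null(generator)) {
    stop("supply exactly one of 'input' or 'generator'", call. = FALSE)
  }
  structure(list(input = input, generator = generator, seed = seed,
                 n_boot = n_boot, alpha = alpha, modes = modes,
                 include_interactions = include_interactions,
                 interaction_whitelist = interaction_whitelist,
                 mtc = match.arg(mtc), suppress_n = suppress_n,
                 schema = schema),
            class = "run_config")
}

# Small stable content hash (FNV-style over the serialised object) used only
# as a provenance fingerprint in run metadata.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full inequality-monitoring pipeline
#'
#' Executes ingest -> exclusions -> balance checks -> observational tables
#' -> moderation table -> ordinal probit regression -> interaction report,
#' in order. Failure of one analysis stage is logged in the bundle and the
#' remaining stages still run; an unreadable input is fatal. Given an
#' identical configuration the bundle is reproduced exactly.
#'
#' Balance checks compare the parsed cohort with the post-exclusion cohort
#' on gender and ethnicity, and the adults-only cohort with the
#' post-exclusion cohort on age group (age groups are undefined under 18).
#'
#' @param config A [run_config()].
#' @return A list of class `report_bundle`: `exclusion_log`, `balance`,
#'   `observational` (per category type, plus per-treatment uptake tables),
#'   `moderation`, `coefficients`, `interactions`, `errors` (named stage
#'   failures), `metadata`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- split_seed(config$seed, 4)
  errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      warning("stage '", name, "' failed: ", conditionMessage(e),
              call. = FALSE)
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  cohort0 <- if (!is.null(config$input)) {
    read_cohort(config$input, schema = config$schema)
  } else {
    generate_cohort(config$generator)
  }
  cohort <- apply_exclusions(cohort0)
  adults <- as.data.frame(cohort0)
  adults <- cohort_table(adults[!is.na(adults$age) & adults$age >= 18, ,
                                drop = FALSE],
                         treatments = cohort_treatments(cohort0))

  balance <- run_stage("balance", {
    if (nrow(cohort) == 0) stop("empty cohort after exclusions")
    rows <- lapply(list(c("gender", "full"), c("ethnicity", "full"),
                        c("age_group", "adults")), function(sp) {
      before <- if (sp[2] == "full") cohort0 else adults
      bc <- balance_check(before, cohort, sp[1])
      data.frame(variable = sp[1], statistic = bc$statistic, df = bc$df,
                 p_value = bc$p_value, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  observational <- run_stage("observational", {
    if (nrow(cohort) == 0) stop("empty cohort after exclusions")
    demo <- lapply(c("gender", "age_group", "ethnicity"), function(by) {
      group_outcomes(cohort, by, n_boot = config$n_boot, seed = seeds[[1]],
                     suppress_n = config$suppress_n)
    })
    names(demo) <- c("gender", "age_group", "ethnicity")
    uptake <- lapply(cohort_treatments(cohort), function(tr) {
      group_outcomes(cohort, "treatment", treatment = tr,
                     n_boot = config$n_boot, seed = seeds[[1]],
                     suppress_n = config$suppress_n)
    })
    names(uptake) <- cohort_treatments(cohort)
    c(demo, list(treatment = uptake))
  })

  moderation <- run_stage("moderation", {
    if (nrow(cohort) == 0) stop("empty cohort after exclusions")
    moderation_table(cohort, n_boot = config$n_boot, seed = seeds[[2]],
                     modes = config$modes, suppress_n = config$suppress_n)
  })

  fit <- NULL
  coefficients <- run_stage("regression", {
    if (nrow(cohort) == 0) stop("empty cohort after exclusions")
    design <- build_design(cohort,
                           include_interactions = config$include_interactions,
                           interaction_whitelist = config$interaction_whitelist)
    outcome <- as.data.frame(cohort)$honos6_followup -
      as.data.frame(cohort)$honos6_initial
    fit <- fit_ordinal_probit(design, outcome)
    if (!fit$converged) stop("regression did not converge: ", fit$diagnostic)
    wald_tests(fit, alpha = config$alpha)
  })

  interactions <- run_stage("interactions", {
    if (is.null(coefficients)) stop("no converged regression available")
    significant_interactions(coefficients, alpha = config$alpha,
                             mtc = config$mtc)
  })

  structure(list(exclusion_log = exclusion_log(cohort),
                 balance = balance,
                 observational = observational,
                 moderation = moderation,
                 coefficients = coefficients,
                 interactions = interactions,
                 fit = fit,
                 errors = errors,
                 metadata = list(config = config,
                                 config_hash = config_hash(config),
                                 seed = config$seed,
                                 n_input = nrow(cohort0),
                                 n_analysed = nrow(cohort),
                                 package_version =
                                   as.character(utils::packageVersion("equityaudit")),
                                 r_version = R.version.string)),
            class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> config ", x$metadata$config_hash, ", seed ",
      x$metadata$seed, "\n", sep = "")
  cat("cohort: ", x$metadata$n_input, " -> ", x$metadata$n_analysed,
      " after exclusions\n", sep = "")
  if (length(x$errors) > 0) {
    cat("failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  if (!is.null(x$interactions) && nrow(x$interactions) > 0) {
    cat("significant interactions:\n")
    print.data.frame(x$interactions[, c("term", "estimate", "p_value",
                                        "direction")],
                     row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits plain CSV tables (exclusion flow, balance checks, observational
#' summaries, moderation table, coefficient and interaction tables) plus a
#' Markdown summary with the run metadata, under `dir`.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  put <- function(df, name) {
    if (!is.null(df)) write.csv(df, file.path(dir, name), row.names = FALSE,
                                na = "")
  }
  put(bundle$exclusion_log, "exclusion_log.csv")
  put(bundle$balance, "balance.csv")
  if (!is.null(bundle$observational)) {
    for (by in c("gender", "age_group", "ethnicity")) {
      put(bundle$observational[[by]], paste0("observational_", by, ".csv"))
    }
    upt <- bundle$observational$treatment
    if (!is.null(upt)) {
      all <- do.call(rbind, lapply(names(upt), function(tr) {
        cbind(treatment = tr, upt[[tr]])
      }))
      put(all, "observational_treatment.csv")
    }
  }
  put(bundle$moderation, "moderation.csv")
  put(bundle$coefficients, "coefficients.csv")
  put(bundle$interactions, "interactions.csv")

  md <- c("# Inequality-monitoring run",
          "",
          paste0("- config hash: `", bundle$metadata$config_hash, "`"),
          paste0("- seed: ", bundle$metadata$seed),
          paste0("- package: equityaudit ", bundle$metadata$package_version,
                 " / ", bundle$metadata$r_version),
          paste0("- cohort: ", bundle$metadata$n_input, " parsed, ",
                 bundle$metadata$n_analysed, " analysed after exclusions"),
          "")
  if (length(bundle$errors) > 0) {
    md <- c(md, "## Failed stages", "",
            paste0("- ", names(bundle$errors), ": ",
                   unlist(bundle$errors)), "")
  }
  if (!is.null(bundle$interactions)) {
    md <- c(md, "## Significant interactions", "")
    if (nrow(bundle$interactions) == 0) {
      md <- c(md, "none at the configured alpha", "")
    } else {
      md <- c(md,
              paste0("- ", bundle$interactions$term, ": coefficient ",
                     round(bundle$interactions$estimate, 3), " (",
                     bundle$interactions$direction, ", p = ",
                     signif(bundle$interactions$p_value, 2), ")"),
              "")
    }
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
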