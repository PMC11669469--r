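#' Design matrix for the outcome-change regression
#'
#' Encodes a post-exclusion cohort as the intercept-free feature matrix of
#' the outcome-change model: the initial symptom score (integer covariate),
#' one binarised uptake indicator per treatment, one-hot demographic
#' indicators with reference levels dropped, and optionally interaction
#' columns — elementwise products of a demographic indicator and a treatment
#' indicator, named `"<demographic>:<uptake>"`. Location is absorbed by the
#' model cutpoints, so no intercept column is included. All-zero, constant
#' or duplicated columns (e.g. demographic levels with no members) are
#' dropped with a warning.
#'
#' @param cohort A post-exclusion [cohort_table()].
#' @param include_interactions Add demographic-by-treatment interaction
#'   columns.
#' @param interaction_whitelist Optional character vector restricting which
#'   interaction columns are built (names as above); `NULL` means all pairs.
#' @param reference Named list of reference levels dropped from the one-hot
#'   encoding.
#' @return Numeric matrix with named columns; attribute `interaction_cols`
#'   names the interaction columns.
#' @export
build_design <- function(cohort, include_interactions = FALSE,
                         interaction_whitelist = NULL,
                         reference = list(gender = "Female",
                                          ethnicity = "White",
                                          age_group = "35-44")) {
  df <- as.data.frame(cohort)
  cols <- list(initial_score = as.numeric(df$honos6_initial))
  for (tr in cohort_treatments(cohort)) {
    cols[[uptake_col(tr)]] <- as.numeric(binarise_uptake(df[[uptake_col(tr)]]))
  }
  demo <- list(gender = df$gender, ethnicity = df$ethnicity,
               age_group = as.character(encode_age_group(df$age)))
  lv <- list(gender = gender_levels(), ethnicity = ethnicity_levels(),
             age_group = age_group_levels())
  demo_cols <- character()
  for (v in names(demo)) {
    for (l in setdiff(lv[[v]], reference[[v]])) {
      nm <- paste(v, l, sep = "_")
      cols[[nm]] <- as.numeric(demo[[v]] == l)
      demo_cols <- c(demo_cols, nm)
    }
  }
  interaction_cols <- character()
  if (include_interactions) {
    for (dcol in demo_cols) {
      for (tr in cohort_treatments(cohort)) {
        nm <- paste(dcol, uptake_col(tr), sep = ":")
        if (!is.null(interaction_whitelist) && !(nm %in% interaction_whitelist)) next
        cols[[nm]] <- cols[[dcol]] * cols[[uptake_col(tr)]]
        interaction_cols <- c(interaction_cols, nm)
      }
    }
    if (!is.null(interaction_whitelist)) {
      unmatched <- setdiff(interaction_whitelist, interaction_cols)
      if (length(unmatched) > 0) {
        warning("interaction_whitelist entries not matched: ",
                paste(unmatched, collapse = ", "), call. = FALSE)
      }
    }
  }
  X <- do.call(cbind, cols)

  keep <- rep(TRUE, ncol(X))
  for (j in seq_len(ncol(X))) {
    if (length(unique(X[, j])) < 2) keep[j] <- FALSE
  }
  dup <- duplicated(t(X))
  if (any(dup)) keep[dup] <- FALSE
  if (any(!keep)) {
    warning("dropped constant or duplicated design column(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  attr(X, "interaction_cols") <- intersect(interaction_cols, colnames(X))
  X
}

# Category index (1..J) and sorted category values for an ordinal outcome.
outcome_categories <- function(outcome) {
  cats <- sort(unique(outcome))
  list(idx = match(outcome, cats), categories = cats)
}

#' Negative log-likelihood of the ordinal probit model
#'
#' The model is a cumulative probit: for ordered categories
#' \eqn{j = 1..J} with strictly increasing cutpoints
#' \eqn{\alpha_1 < \dots < \alpha_{J-1}} (\eqn{\alpha_0 = -\infty},
#' \eqn{\alpha_J = +\infty}),
#' \deqn{P(y = j \mid x) = \Phi(\alpha_j - x\beta) - \Phi(\alpha_{j-1} - x\beta).}
#'
#' @param beta Coefficient vector (one per design column).
#' @param cutpoints Increasing cutpoint vector of length J-1.
#' @param design Numeric design matrix.
#' @param outcome Ordinal outcome vector (e.g. score changes -4..4); its
#'   sorted unique values define the categories.
#' @return The negative log-likelihood (scalar).
#' @export
ordinal_probit_nll <- function(beta, cutpoints, design, outcome) {
  oc <- outcome_categories(outcome)
  nll_raw(c(beta, cutpoints), design, oc$idx, length(oc$categories))
}

#' @rdname ordinal_probit_nll
#' @return For `ordinal_probit_grad`: the exact gradient with respect to
#'   `c(beta, cutpoints)`.
#' @export
ordinal_probit_grad <- function(beta, cutpoints, design, outcome) {
  oc <- outcome_categories(outcome)
  grad_raw(c(beta, cutpoints), design, oc$idx, length(oc$categories))
}

# params = c(beta, alpha); y integer 1..J.
nll_raw <- function(params, X, y, J) {
  p <- ncol(X)
  beta <- params[seq_len(p)]
  alpha <- params[p + seq_len(J - 1)]
  if (any(diff(alpha) <= 0)) return(Inf)
  eta <- drop(X %*% beta)
  up <- c(alpha, Inf)[y] - eta
  lo <- c(-Inf, alpha)[y] - eta
  pr <- pnorm(up) - pnorm(lo)
  -sum(log(pmax(pr, 1e-300)))
}

grad_raw <- function(params, X, y, J) {
  p <- ncol(X)
  beta <- params[seq_len(p)]
  alpha <- params[p + seq_len(J - 1)]
  eta <- drop(X %*% beta)
  up <- c(alpha, Inf)[y] - eta
  lo <- c(-Inf, alpha)[y] - eta
  pr <- pmax(pnorm(up) - pnorm(lo), 1e-300)
  phi_u <- dnorm(up)
  phi_l <- dnorm(lo)
  g_beta <- drop(crossprod(X, (phi_u - phi_l) / pr))
  g_alpha <- numeric(J - 1)
  wu <- phi_u / pr   # d nll / d alpha_j gets -wu from rows with y = j
  wl <- phi_l / pr   # and +wl from rows with y = j + 1
  for (j in seq_len(J - 1)) {
    g_alpha[j] <- -sum(wu[y == j]) + sum(wl[y == j + 1])
  }
  c(g_beta, g_alpha)
}

#' Fit the ordinal probit outcome-change model
#'
#' Maximum-likelihood fit of the cumulative probit model described in
#' [ordinal_probit_nll()]. The cutpoints are kept strictly increasing
#' through an unconstrained reparameterisation (first cutpoint free,
#' log-parameterised increments); optimisation is quasi-Newton with the
#' exact analytic gradient, started from zero coefficients and cutpoints at
#' the probit-transformed cumulative category frequencies. The parameter
#' covariance is the inverse observed information at the optimum (in the
#' original parameterisation).
#'
#' @param design Numeric design matrix (e.g. from [build_design()]).
#' @param outcome Ordinal outcome vector; at least two observed categories.
#' @param maxit Maximum quasi-Newton iterations.
#' @param grad_tol Gradient-infinity-norm threshold for declaring
#'   convergence.
#' @return An object of class `ordinal_probit_fit`: `coefficients`,
#'   `cutpoints`, `vcov`, `se`, `loglik`, `converged`, `diagnostic`,
#'   `categories`, `n`.
#' @export
fit_ordinal_probit <- function(design, outcome, maxit = 500, grad_tol = 1e-6) {
  X <- as.matrix(design)
  oc <- outcome_categories(outcome)
  J <- length(oc$categories)
  if (J < 2) stop("need at least 2 observed outcome categories", call. = FALSE)
  p <- ncol(X)
  if (nrow(X) <= p + J - 1) {
    stop("more parameters than observations", call. = FALSE)
  }
  y <- oc$idx

  freq <- cumsum(tabulate(y, J) / length(y))
  alpha0 <- qnorm(freq[-J])
  theta0 <- c(rep(0, p), alpha0[1],
              if (J > 2) log(diff(alpha0)) else numeric())

  to_raw <- function(theta) {
    beta <- theta[seq_len(p)]
    a1 <- theta[p + 1]
    alpha <- if (J > 2) a1 + c(0, cumsum(exp(theta[p + 2:(J - 1)]))) else a1
    c(beta, alpha)
  }
  obj <- function(theta) nll_raw(to_raw(theta), X, y, J)
  gr <- function(theta) {
    g <- grad_raw(to_raw(theta), X, y, J)
    g_beta <- g[seq_len(p)]
    g_alpha <- g[p + seq_len(J - 1)]
    g_theta <- c(g_beta, sum(g_alpha))
    if (J > 2) {
      incr <- exp(theta[p + 2:(J - 1)])
      g_theta <- c(g_theta,
                   vapply(2:(J - 1), function(k) sum(g_alpha[k:(J - 1)]),
                          numeric(1)) * incr)
    }
    g_theta
  }

  res <- nlminb(theta0, obj, gradient = gr,
                control = list(iter.max = maxit, eval.max = 4 * maxit,
                               rel.tol = 1e-12))
  raw <- to_raw(res$par)
  gnorm <- max(abs(grad_raw(raw, X, y, J)))
  # accept soft optimiser exits (e.g. "singular convergence") when the
  # gradient is negligible relative to the objective's scale
  converged <- res$convergence == 0 ||
    gnorm < max(grad_tol, 1e-5 * max(1, abs(res$objective)))
  diagnostic <- res$message
  if (any(abs(raw[seq_len(p)]) > 20)) {
    converged <- FALSE
    diagnostic <- "coefficients diverged (possible perfect separation)"
  }

  vc <- matrix(NA_real_, p + J - 1, p + J - 1)
  if (converged) {
    H <- optimHess(raw, function(pp) nll_raw(pp, X, y, J),
                   function(pp) grad_raw(pp, X, y, J))
    vc <- tryCatch(solve(H), error = function(e) {
      converged <<- FALSE
      diagnostic <<- paste("singular observed information:",
                           conditionMessage(e))
      matrix(NA_real_, p + J - 1, p + J - 1)
    })
  }
  nms <- c(if (p > 0) colnames(X) %||% paste0("x", seq_len(p)),
           paste0("cut_", seq_len(J - 1)))
  dimnames(vc) <- list(nms, nms)
  structure(list(coefficients = setNames(raw[seq_len(p)], nms[seq_len(p)]),
                 cutpoints = setNames(raw[p + seq_len(J - 1)],
                                      nms[p + seq_len(J - 1)]),
                 vcov = vc,
                 se = setNames(suppressWarnings(sqrt(diag(vc))), nms),
                 loglik = -res$objective,
                 converged = converged,
                 diagnostic = diagnostic,
                 grad_norm = gnorm,
                 categories = oc$categories,
                 n = nrow(X),
                 interaction_cols = attr(design, "interaction_cols")),
            class = "ordinal_probit_fit")
}

#' @export
print.ordinal_probit_fit <- function(x, ...) {
  cat("<ordinal_probit_fit> n = ", x$n, ", ", length(x$categories),
      " outcome categories, logLik = ", format(x$loglik, digits = 6),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(round(x$coefficients, 4))
  cat("cutpoints:\n")
  print(round(x$cutpoints, 4))
  invisible(x)
}

#' @export
coef.ordinal_probit_fit <- function(object, ...) object$coefficients

#' @export
vcov.ordinal_probit_fit <- function(object, ...) object$vcov

#' @export
logLik.ordinal_probit_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients) + length(object$cutpoints),
            class = "logLik")
}

#' Predicted category probabilities of an ordinal probit model
#'
#' @param beta,cutpoints Parameters (see [ordinal_probit_nll()]).
#' @param design Numeric design matrix.
#' @return Matrix of per-row category probabilities (rows sum to 1).
#' @export
ordinal_probit_probs <- function(beta, cutpoints, design) {
  eta <- drop(as.matrix(design) %*% beta)
  cum <- vapply(cutpoints, function(a) pnorm(a - eta), numeric(length(eta)))
  cum <- cbind(matrix(cum, ncol = length(cutpoints)), 1)
  cbind(cum[, 1, drop = FALSE], cum[, -1, drop = FALSE] -
          cum[, -ncol(cum), drop = FALSE])
}

#' Wald z-tests for every regression coefficient
#'
#' One two-sided normal test per design-column coefficient (cutpoints are
#' nuisance parameters and excluded), \eqn{z = \hat\beta / SE}.
#'
#' @param fit A converged [fit_ordinal_probit()] result.
#' @param alpha Significance level for the `significant` flag.
#' @return `data.frame`: `term`, `estimate`, `std_error`, `z`, `p_value`,
#'   `significant`.
#' @export
wald_tests <- function(fit, alpha = 0.05) {
  if (!fit$converged) {
    stop("fit did not converge (", fit$diagnostic, "); tests suppressed",
         call. = FALSE)
  }
  est <- fit$coefficients
  se <- fit$se[names(est)]
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  data.frame(term = names(est), estimate = unname(est),
             std_error = unname(se), z = unname(z), p_value = unname(p),
             significant = unname(p < alpha),
             stringsAsFactors = FALSE)
}

#' Statistically significant demographic-by-treatment interactions
#'
#' Filters a [wald_tests()] table to interaction terms passing the
#' significance threshold, optionally after Benjamini-Hochberg adjustment
#' across the interaction terms. Each retained term is annotated with its
#' direction: a negative coefficient means the combination is associated
#' with *more* symptomatic improvement.
#'
#' @param tests A [wald_tests()] table.
#' @param alpha Significance level (default 0.05, two-sided).
#' @param mtc Multiple-testing correction: `"none"` (default) or
#'   `"benjamini_hochberg"`.
#' @return The filtered `data.frame` with added `p_adjusted` and `direction`
#'   (`"improvement"`/`"worsening"`) columns.
#' @export
significant_interactions <- function(tests, alpha = 0.05,
                                     mtc = c("none", "benjamini_hochberg")) {
  mtc <- match.arg(mtc)
  inter <- tests[grepl(":", tests$term, fixed = TRUE), , drop = FALSE]
  if (nrow(inter) == 0) {
    inter$p_adjusted <- numeric()
    inter$direction <- character()
    return(inter)
  }
  inter$p_adjusted <- if (mtc == "benjamini_hochberg") {
    p.adjust(inter$p_value, method = "BH")
  } else inter$p_value
  inter$direction <- ifelse(inter$estimate < 0, "improvement", "worsening")
  out <- inter[inter$p_adjusted < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}
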