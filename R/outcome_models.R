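#' Dichotomize the Glasgow Outcome Scale Extended
#'
#' Complete recovery is GOSE = 8; any score below 8 counts as incomplete
#' recovery.
#'
#' @param gose Integer vector with values in 1..8 (`NA` allowed).
#' @return Integer vector: 0 = complete recovery (GOSE 8), 1 = incomplete
#'   (GOSE < 8).
#' @export
dichotomize_gose <- function(gose) {
  bad <- !is.na(gose) & (!gose %in% 1:8)
  if (any(bad)) {
    stop("GOSE score outside 1..8 (value ", gose[bad][1], ")",
         call. = FALSE)
  }
  out <- ifelse(gose < 8, 1L, 0L)
  out[is.na(gose)] <- NA_integer_
  out
}

.covariate_names <- c("age", "female_sex", "education", "prior_tbi",
                      "psychiatric_history", "ct_positive")
.outcome_names <- c("gose_incomplete", "qolibri", "sf12_pcs", "sf12_mcs")

#' Specify an adjusted outcome regression
#'
#' Fixes the model formula used throughout: the 5 two-week symptom factors
#' plus the 6 adjustment covariates (age, female sex, years of education,
#' prior TBI, psychiatric history, positive head CT), 11 terms in all.
#'
#' @param outcome One of `"gose_incomplete"` (logistic), `"qolibri"`,
#'   `"sf12_pcs"`, `"sf12_mcs"` (linear).
#' @param timepoint Outcome timepoint, `"M6"` or `"M12"`.
#' @return A `regression_spec` list: `outcome`, `timepoint`, `family`,
#'   `predictors`.
#' @export
regression_spec <- function(outcome = .outcome_names,
                            timepoint = c("M6", "M12")) {
  outcome <- match.arg(outcome)
  timepoint <- match.arg(timepoint)
  structure(list(
    outcome = outcome,
    timepoint = timepoint,
    family = if (outcome == "gose_incomplete") "logistic" else "linear",
    predictors = c(factor_labels(), .covariate_names)
  ), class = "regression_spec")
}

#' Fit an adjusted symptom-factor outcome model
#'
#' Associates the five symptom factors at two weeks post-injury with an
#' outcome at 6 or 12 months, adjusting for demographics and clinical
#' covariates. `gose_incomplete` is fitted by logistic regression
#' (iteratively reweighted least squares); estimates are odds ratios per
#' unit increase on the 0-3 factor scale, with Wald 95% confidence
#' intervals. Continuous outcomes are fitted by ordinary least squares;
#' estimates are beta coefficients with t-based 95% intervals. Factors
#' enter on the raw 0-3 scale by default; `standardize = TRUE` scales
#' them to unit variance first.
#'
#' Subjects are used complete-case per model: they need complete W2 items
#' (for the factors), all covariates, and the modeled outcome at the
#' spec's timepoint.
#'
#' @param spec A [regression_spec()].
#' @param cohort Recoded long-format cohort containing W2 item rows,
#'   covariate columns, and outcome columns (`gose`, `qolibri`,
#'   `sf12_pcs`, `sf12_mcs`) on the outcome-timepoint rows.
#' @param standardize Standardize the factor predictors? Default `FALSE`.
#' @return A `regression_result` data frame: `term`, `estimate` (OR or
#'   beta), `conf_low`, `conf_high`, `p_value`; attributes `n`, `family`,
#'   `outcome`, `timepoint`.
#' @export
fit_outcome_model <- function(spec, cohort, standardize = FALSE) {
  stopifnot(inherits(spec, "regression_spec"))
  fac <- build_regression_factors(cohort, "W2")
  out_rows <- cohort[cohort$timepoint == spec$timepoint, , drop = FALSE]
  w2_rows <- cohort[cohort$timepoint == "W2", , drop = FALSE]

  ids <- intersect(rownames(fac), out_rows$subject_id)
  df <- as.data.frame(fac[ids, , drop = FALSE])
  cov <- w2_rows[match(ids, w2_rows$subject_id), .covariate_names,
                 drop = FALSE]
  df[.covariate_names] <- cov

  y_raw <- out_rows[match(ids, out_rows$subject_id), , drop = FALSE]
  y <- switch(spec$outcome,
    gose_incomplete = dichotomize_gose(y_raw$gose),
    qolibri = y_raw$qolibri,
    sf12_pcs = y_raw$sf12_pcs,
    sf12_mcs = y_raw$sf12_mcs
  )
  df$.y <- y
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  n_terms <- length(spec$predictors)
  if (n < 10 * n_terms) {
    stop("only ", n, " complete cases for ", n_terms,
         " terms; need at least ", 10 * n_terms, call. = FALSE)
  }
  if (length(unique(df$.y)) < 2) {
    stop("outcome '", spec$outcome, "' is constant across subjects",
         call. = FALSE)
  }
  if (standardize) {
    for (f in factor_labels()) df[[f]] <- as.numeric(scale(df[[f]]))
  }
  form <- stats::as.formula(paste(".y ~",
                                  paste(spec$predictors, collapse = " + ")))
  if (spec$family == "logistic") {
    fit <- suppressWarnings(glm(form, data = df, family = binomial()))
    cf <- coef(fit)
    if (anyNA(cf)) {
      stop("rank-deficient fit; collinear terms: ",
           paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
    }
    if (!fit$converged || any(abs(cf[-1]) > 15)) {
      worst <- names(which.max(abs(cf[-1])))
      stop("logistic fit failed to converge (possible perfect separation; ",
           "largest coefficient on '", worst, "')", call. = FALSE)
    }
    se <- sqrt(diag(vcov(fit)))
    z <- qnorm(0.975)
    res <- data.frame(
      term = names(cf),
      estimate = exp(cf),
      conf_low = exp(cf - z * se),
      conf_high = exp(cf + z * se),
      p_value = summary(fit)$coefficients[, "Pr(>|z|)"],
      row.names = NULL
    )
  } else {
    fit <- lm(form, data = df)
    cf <- coef(fit)
    if (anyNA(cf)) {
      stop("rank-deficient fit; collinear terms: ",
           paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
    }
    ci <- stats::confint(fit, level = 0.95)
    res <- data.frame(
      term = names(cf),
      estimate = cf,
      conf_low = ci[, 1],
      conf_high = ci[, 2],
      p_value = summary(fit)$coefficients[, "Pr(>|t|)"],
      row.names = NULL
    )
  }
  structure(res,
            n = n, family = spec$family, outcome = spec$outcome,
            timepoint = spec$timepoint, standardized = standardize,
            class = c("regression_result", "data.frame"))
}

#' @export
print.regression_result <- function(x, ...) {
  cat(attr(x, "family"), "model:", attr(x, "outcome"), "at",
      attr(x, "timepoint"), "(n =", attr(x, "n"), ")\n")
  lab <- if (attr(x, "family") == "logistic") "OR" else "beta"
  df <- as.data.frame(x)
  df$estimate <- sprintf("%.3f", df$estimate)
  df$ci <- sprintf("[%.3f, %.3f]", x$conf_low, x$conf_high)
  df$p <- format.pval(x$p_value, digits = 3)
  print(df[, c("term", "estimate", "ci", "p")], row.names = FALSE)
  cat("estimate =", lab, "with 95% CI\n")
  invisible(x)
}
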