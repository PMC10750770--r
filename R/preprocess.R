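#' The 16 RPQ symptom items
#'
#' Canonical column names for the 16 Rivermead Post-Concussion Symptoms
#' Questionnaire items, in instrument order.
#'
#' @return Character vector of length 16.
#' @export
rpq_items <- function() {
  c("headache", "dizziness", "nausea", "noise_sensitivity",
    "sleep_disturbance", "fatigue", "irritable", "depressed",
    "frustrated", "poor_memory", "poor_concentration", "slow_thinking",
    "blurred_vision", "light_sensitivity", "double_vision", "restlessness")
}

#' Network node labels
#'
#' The 10 nodes entering network estimation: three averaged composites
#' (emotional, cognitive, visual) plus the seven remaining single items.
#'
#' @return Character vector of length 10.
#' @export
network_nodes <- function() {
  c("emotional", "cognitive", "visual", "headache", "dizziness", "nausea",
    "noise_sensitivity", "sleep_disturbance", "fatigue", "restlessness")
}

#' Regression factor labels
#' @return Character vector of length 5.
#' @export
factor_labels <- function() {
  c("emotional", "cognitive", "visual", "somatic", "other")
}

# item -> composite membership
.composites <- list(
  emotional = c("irritable", "depressed", "frustrated"),
  cognitive = c("poor_memory", "poor_concentration", "slow_thinking"),
  visual    = c("blurred_vision", "light_sensitivity", "double_vision")
)
.factor_items <- c(.composites, list(
  somatic = c("headache", "dizziness", "nausea"),
  other   = c("noise_sensitivity", "sleep_disturbance", "fatigue",
              "restlessness")
))

.timepoints <- c("W2", "M3", "M6", "M12")

#' Recode raw RPQ item scores to the analysis scale
#'
#' Raw RPQ responses distinguish "not experienced at all" (0) from "no more
#' of a problem than before injury" (1); neither reflects a change in
#' symptom burden, so both map to 0. The remaining categories shift down:
#' 2 (mild) -> 1, 3 (moderate) -> 2, 4 (severe) -> 3.
#'
#' @param raw_scores Integer vector with values in 0..4; `NA` allowed and
#'   propagated.
#' @param item,subject Optional labels used in the error message when a
#'   value is out of range.
#' @return Integer vector of the same length with values in 0..3.
#' @examples
#' recode_rpq(c(0, 1, 2, 3, 4))  # 0 0 1 2 3
#' @export
recode_rpq <- function(raw_scores, item = NULL, subject = NULL) {
  x <- raw_scores
  bad <- !is.na(x) & (!x %in% 0:4)
  if (any(bad)) {
    where <- character(0)
    if (!is.null(item)) where <- c(where, paste0("item '", item, "'"))
    if (!is.null(subject)) {
      subj <- subject[bad][1]
      where <- c(where, paste0("subject '", subj, "'"))
    }
    stop("RPQ score outside 0..4 (value ", x[bad][1], ")",
         if (length(where)) paste0(" for ", paste(where, collapse = ", ")),
         call. = FALSE)
  }
  out <- c(0L, 0L, 1L, 2L, 3L)[as.integer(x) + 1L]
  out[is.na(x)] <- NA_integer_
  out
}

#' Recode all RPQ item columns of a cohort table
#'
#' @param cohort Long-format data frame with one row per subject-timepoint
#'   and the 16 columns named by [rpq_items()] on the raw 0-4 scale.
#' @return The same data frame with item columns recoded to 0-3.
#' @export
recode_cohort <- function(cohort) {
  items <- intersect(rpq_items(), names(cohort))
  if (length(items) == 0L) stop("no RPQ item columns found", call. = FALSE)
  for (it in items) {
    cohort[[it]] <- recode_rpq(cohort[[it]], item = it,
                               subject = cohort[["subject_id"]])
  }
  cohort
}

# shared worker for node/factor construction; `groups` maps output columns
# to their constituent recoded items
.build_composites <- function(cohort, timepoint, groups, passthrough) {
  stopifnot(is.data.frame(cohort))
  if (!timepoint %in% cohort$timepoint) {
    stop("timepoint '", timepoint, "' not present in cohort", call. = FALSE)
  }
  rows <- cohort[cohort$timepoint == timepoint, , drop = FALSE]
  items <- rpq_items()
  miss <- setdiff(items, names(rows))
  if (length(miss)) {
    stop("cohort lacks item columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(rows[, items, drop = FALSE])
  if (any(vals > 3, na.rm = TRUE)) {
    stop("item scores exceed 3; recode the cohort with recode_cohort() ",
         "before building composites", call. = FALSE)
  }
  keep <- complete.cases(vals)
  n_dropped <- sum(!keep)
  rows <- rows[keep, , drop = FALSE]
  vals <- vals[keep, , drop = FALSE]

  out <- matrix(NA_real_, nrow(vals), length(groups) + length(passthrough),
                dimnames = list(rows$subject_id,
                                c(names(groups), passthrough)))
  for (g in names(groups)) {
    out[, g] <- rowMeans(vals[, groups[[g]], drop = FALSE])
  }
  if (length(passthrough)) {
    out[, passthrough] <- vals[, passthrough]
  }
  attr(out, "timepoint") <- timepoint
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Build the 10-node matrix for network estimation at one timepoint
#'
#' Averages the emotional, cognitive and visual item triplets into
#' composites and passes the seven remaining items through unchanged.
#' Subjects with any missing constituent item at the timepoint are dropped
#' (complete-case); the dropped count is attached as attribute
#' `"n_dropped"`.
#'
#' @param cohort Recoded long-format cohort (items on the 0-3 scale).
#' @param timepoint One of `"W2"`, `"M3"`, `"M6"`, `"M12"`.
#' @return Numeric matrix, subjects x 10 nodes, rownames = subject ids,
#'   columns in the fixed [network_nodes()] order.
#' @export
build_network_nodes <- function(cohort, timepoint) {
  pass <- setdiff(network_nodes(), names(.composites))
  .build_composites(cohort, timepoint, .composites, pass)
}

#' Build the 5 regression factors at one timepoint
#'
#' Emotional, cognitive and visual as in [build_network_nodes()]; somatic =
#' mean of headache, dizziness, nausea; other = mean of noise sensitivity,
#' sleep disturbance, fatigue, restlessness. All factors are averages, so a
#' one-unit increase is on the recoded 0-3 item scale.
#'
#' @inheritParams build_network_nodes
#' @return Numeric matrix, subjects x 5 factors.
#' @export
build_regression_factors <- function(cohort, timepoint) {
  .build_composites(cohort, timepoint, .factor_items, character(0))
}

#' Apply the cohort eligibility filter
#'
#' Retains subjects whose emergency-department Glasgow Coma Scale score
#' falls in `gcs_range` (mild TBI: 13-15) and who have complete RPQ items
#' at every timepoint in `required_timepoints`. A CONSORT-style count of
#' retained and dropped subjects is attached as attribute
#' `"filter_report"`.
#'
#' @param records Long-format data frame with columns `subject_id`,
#'   `timepoint`, `gcs` and the 16 RPQ item columns (raw or recoded).
#' @param gcs_range Length-2 inclusive GCS bounds; default `c(13, 15)`.
#' @param required_timepoints Timepoints at which complete RPQ data are
#'   required; default none (GCS filter only).
#' @return Filtered data frame (all rows of retained subjects).
#' @export
filter_cohort <- function(records, gcs_range = c(13, 15),
                          required_timepoints = character(0)) {
  stopifnot(is.data.frame(records), "gcs" %in% names(records))
  items <- intersect(rpq_items(), names(records))
  subj_gcs <- tapply(records$gcs, records$subject_id, function(g) g[1])
  gcs_ok <- names(subj_gcs)[!is.na(subj_gcs) &
                            subj_gcs >= gcs_range[1] &
                            subj_gcs <= gcs_range[2]]
  n_all <- length(subj_gcs)

  complete_ok <- gcs_ok
  if (length(required_timepoints)) {
    ok <- vapply(gcs_ok, function(s) {
      rows <- records[records$subject_id == s, , drop = FALSE]
      all(vapply(required_timepoints, function(tp) {
        r <- rows[rows$timepoint == tp, items, drop = FALSE]
        nrow(r) == 1L && !anyNA(r)
      }, logical(1)))
    }, logical(1))
    complete_ok <- gcs_ok[ok]
  }
  out <- records[records$subject_id %in% complete_ok, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("empty cohort after filtering (GCS ", gcs_range[1], "-",
         gcs_range[2], ", required timepoints: ",
         if (length(required_timepoints))
           paste(required_timepoints, collapse = ", ") else "none", ")",
         call. = FALSE)
  }
  attr(out, "filter_report") <- list(
    n_input = n_all,
    n_dropped_gcs = n_all - length(gcs_ok),
    n_dropped_incomplete = length(gcs_ok) - length(complete_ok),
    n_retained = length(complete_ok)
  )
  out
}
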