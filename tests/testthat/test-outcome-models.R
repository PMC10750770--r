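test_that("GOSE dichotomization splits exactly at complete recovery", {
  expect_identical(dichotomize_gose(8L), 0L)
  expect_identical(dichotomize_gose(7L), 1L)
  expect_identical(dichotomize_gose(1:8), c(rep(1L, 7), 0L))
  expect_identical(dichotomize_gose(c(NA, 8L)), c(NA, 0L))
  expect_error(dichotomize_gose(9L), "outside 1..8")
  expect_error(dichotomize_gose(0L), "outside 1..8")
})

test_that("regression spec pins the 11-term predictor set", {
  sp <- regression_spec("gose_incomplete", "M6")
  expect_equal(length(sp$predictors), 11L)
  expect_identical(sp$family, "logistic")
  expect_identical(regression_spec("qolibri", "M12")$family, "linear")
})

sim_fit_cohort <- function(n = 1500, seed = 31) {
  tr <- make_true_network(seed = 2)
  recode_cohort(simulate_cohort(tr, n, timepoints = c("W2", "M6", "M12"),
                                seed = seed))
}

test_that("logistic and linear fits report estimates, CIs and p-values", {
  co <- sim_fit_cohort()
  lg <- fit_outcome_model(regression_spec("gose_incomplete", "M6"), co)
  expect_s3_class(lg, "regression_result")
  expect_equal(nrow(lg), 12L)   # intercept + 11 terms
  expect_true(all(lg$conf_low > 0))                       # ORs positive
  expect_true(all(lg$estimate >= lg$conf_low &
                  lg$estimate <= lg$conf_high))
  ln <- fit_outcome_model(regression_spec("qolibri", "M6"), co)
  expect_true(all(ln$estimate >= ln$conf_low &
                  ln$estimate <= ln$conf_high))
  expect_true(attr(ln, "n") <= length(unique(co$subject_id)))
})

test_that("flipping the binary outcome inverts the odds ratios", {
  co <- sim_fit_cohort()
  lg <- fit_outcome_model(regression_spec("gose_incomplete", "M6"), co)
  flipped <- co
  m6 <- flipped$timepoint == "M6"
  flipped$gose[m6] <- ifelse(flipped$gose[m6] == 8L, 7L, 8L)
  lg2 <- fit_outcome_model(regression_spec("gose_incomplete", "M6"),
                           flipped)
  expect_equal(lg2$estimate, 1 / lg$estimate, tolerance = 1e-6)
})

test_that("missing covariates drop subjects from that model only", {
  co <- sim_fit_cohort()
  full_n <- attr(fit_outcome_model(regression_spec("qolibri", "M6"), co),
                 "n")
  co$education[co$subject_id %in% unique(co$subject_id)[1:25]] <- NA
  less_n <- attr(fit_outcome_model(regression_spec("qolibri", "M6"), co),
                 "n")
  expect_equal(full_n - less_n, 25L)
})

test_that("degenerate fits raise informative errors", {
  co <- sim_fit_cohort(n = 400, seed = 5)
  const <- co
  const$gose[const$timepoint == "M6"] <- 8L
  expect_error(
    fit_outcome_model(regression_spec("gose_incomplete", "M6"), const),
    "constant")
  tiny <- sim_fit_cohort(n = 60, seed = 6)
  expect_error(
    fit_outcome_model(regression_spec("qolibri", "M6"),
                      tiny[tiny$subject_id %in%
                             unique(tiny$subject_id)[1:55], ]),
    "complete cases")
})

test_that("a known factor effect is recovered at large n", {
  oc <- .default_outcome_coefs_for_test()
  tr <- make_true_network(seed = 3, outcome_coefs = oc)
  co <- recode_cohort(simulate_cohort(tr, 4000,
                                      timepoints = c("W2", "M6"),
                                      seed = 8))
  lg <- fit_outcome_model(regression_spec("gose_incomplete", "M6"), co)
  or_cog <- lg$estimate[lg$term == "cognitive"]
  expect_gt(or_cog, 1.6)
  expect_lt(or_cog, 2.5)
})
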