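test_that("RPQ recoding collapses the two no-problem categories and shifts", {
  expect_identical(recode_rpq(c(0L, 1L, 2L, 3L, 4L)), c(0L, 0L, 1L, 2L, 3L))
  expect_identical(recode_rpq(rep(0L, 16)), rep(0L, 16))
  expect_identical(recode_rpq(c(2L, NA, 4L)), c(1L, NA, 3L))
  expect_error(recode_rpq(c(0L, 5L), item = "headache", subject = c("a", "b")),
               "headache")
  expect_error(recode_rpq(-1L), "outside 0..4")
})

test_that("recoding maps every raw category into the 0-3 range", {
  for (raw in 0:4) expect_true(recode_rpq(raw) %in% 0:3)
})

test_that("network nodes are the three composite means plus seven items", {
  co <- recode_cohort(tiny_cohort())
  nm <- build_network_nodes(co, "W2")
  expect_identical(colnames(nm), network_nodes())
  expect_equal(ncol(nm), 10L)
  w2 <- co[co$timepoint == "W2", ]
  a <- w2[w2$subject_id == "a", ]
  expect_equal(nm["a", "emotional"],
               mean(c(a$irritable, a$depressed, a$frustrated)))
  expect_equal(nm["a", "cognitive"],
               mean(c(a$poor_memory, a$poor_concentration, a$slow_thinking)))
  expect_equal(nm["a", "visual"],
               mean(c(a$blurred_vision, a$light_sensitivity, a$double_vision)))
  expect_equal(nm["a", "headache"], a$headache)
  # composites lie between their constituents
  expect_true(all(nm[, "emotional"] >= pmin(w2$irritable, w2$depressed,
                                            w2$frustrated)))
  expect_true(all(nm[, "emotional"] <= pmax(w2$irritable, w2$depressed,
                                            w2$frustrated)))
})

test_that("an all-constant response gives constant composites", {
  co <- tiny_cohort()
  co[, rpq_items()] <- 3L   # raw 3 -> recoded 2
  co <- recode_cohort(co)
  nm <- build_network_nodes(co, "W2")
  expect_true(all(nm == 2))
})

test_that("raw-scale input is refused before composite construction", {
  expect_error(build_network_nodes(tiny_cohort(), "W2"), "recode")
})

test_that("subjects missing a constituent item are dropped from that timepoint only", {
  co <- recode_cohort(tiny_cohort())
  co$poor_memory[co$subject_id == "b" & co$timepoint == "M3"] <- NA
  m3 <- build_network_nodes(co, "M3")
  w2 <- build_network_nodes(co, "W2")
  expect_false("b" %in% rownames(m3))
  expect_true("b" %in% rownames(w2))
  expect_equal(attr(m3, "n_dropped"), 1L)
})

test_that("regression factors add the somatic and other averages", {
  co <- recode_cohort(tiny_cohort())
  fm <- build_regression_factors(co, "W2")
  expect_identical(colnames(fm), factor_labels())
  expect_equal(ncol(fm), 5L)
  w2 <- co[co$timepoint == "W2", ]
  a <- w2[w2$subject_id == "a", ]
  expect_equal(fm["a", "somatic"],
               mean(c(a$headache, a$dizziness, a$nausea)))
  expect_equal(fm["a", "other"],
               mean(c(a$noise_sensitivity, a$sleep_disturbance, a$fatigue,
                      a$restlessness)))
  # order of constituent items does not matter
  perm <- co
  perm[, c("headache", "nausea")] <- perm[, c("nausea", "headache")]
  names(perm)[names(perm) == "headache"] <- ".tmp"
  names(perm)[names(perm) == "nausea"] <- "headache"
  names(perm)[names(perm) == ".tmp"] <- "nausea"
  expect_equal(build_regression_factors(perm, "W2")[, "somatic"],
               fm[, "somatic"])
})

test_that("cohort filter applies GCS range and RPQ completeness", {
  co <- tiny_cohort()
  co$gcs[co$subject_id == "a"] <- 12L
  co$gcs[co$subject_id == "b"] <- 16L
  out <- filter_cohort(co)
  expect_identical(sort(unique(out$subject_id)), "c")
  rep <- attr(out, "filter_report")
  expect_equal(rep$n_dropped_gcs, 2L)
  expect_equal(rep$n_retained, 1L)

  co2 <- tiny_cohort()
  co2$headache[co2$subject_id == "a" & co2$timepoint == "M3"] <- NA
  out2 <- filter_cohort(co2, required_timepoints = c("W2", "M3"))
  expect_false("a" %in% out2$subject_id)
  out3 <- filter_cohort(co2, required_timepoints = "W2")
  expect_true("a" %in% out3$subject_id)

  expect_error(filter_cohort(co2, gcs_range = c(3, 8)), "empty cohort")
})
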