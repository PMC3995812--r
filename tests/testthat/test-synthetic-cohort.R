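test_that("cohort simulation is deterministic and validates its config", {
  a <- simulate_cohort(cohort_sim_config(n_patients = 200, seed = 9))
  b <- simulate_cohort(cohort_sim_config(n_patients = 200, seed = 9))
  expect_identical(a, b)
  expect_false(identical(
    a, simulate_cohort(cohort_sim_config(n_patients = 200, seed = 10))))
  expect_error(cohort_sim_config(n_patients = 5), "degenerate")
  expect_error(cohort_sim_config(target_event_fraction = 0), "target_event_fraction")
  expect_error(cohort_sim_config(covariate_prevalences = c(
    gender_female = 0, site_floor = 0.5, t_high = 0.5, n_positive = 0.5,
    grade_poor = 0.5, perineural = 0.5, margin_positive = 0.5,
    treatment_rt = 0.5)), "prevalences")
})

test_that("cohort tables satisfy their structural invariants", {
  co <- simulate_cohort(cohort_sim_config(n_patients = 300, seed = 4))
  expect_identical(nrow(co), 300L)
  expect_false(anyDuplicated(co$patient_id) > 0)
  expect_true(all(co$time_to_recurrence > 0))
  expect_true(all(co$event %in% 0:1))
  expect_true(all(co$tbs >= 0))
  # TNM-style nesting: nodal spread implies stage III/IV
  expect_true(all(co$stage[co$n_status == "N+"] != "I-II"))
})

test_that("realized event fraction is calibrated to its target", {
  co <- simulate_cohort(cohort_sim_config(n_patients = 1000, seed = 21))
  expect_lt(abs(mean(co$event) - 0.33), 0.05)
  # Kaplan-Meier check at large n: within Monte-Carlo error of the target
  co5 <- simulate_cohort(cohort_sim_config(n_patients = 5000, seed = 22))
  expect_lt(abs(mean(co5$event) - 0.33), 3 * sqrt(0.33 * 0.67 / 5000))
  # different target is honoured too
  co_h <- simulate_cohort(cohort_sim_config(n_patients = 1000, seed = 23,
                                            target_event_fraction = 0.6))
  expect_lt(abs(mean(co_h$event) - 0.6), 0.05)
})

test_that("null effects produce null Cox coefficients", {
  # a single fitted coefficient at n = 2000 has sampling sd ~0.1, so the
  # zero-effect claim is asserted on the mean over 10 replicates
  coefs <- sapply(31:40, function(s) {
    co <- simulate_cohort(cohort_sim_config(
      n_patients = 2000, preset = "univariate_tertile",
      log_hr_tertile_step = 0, seed = s))
    d <- cbind(co, tertile = assign_tertiles(co$tbs, co$patient_id)$label)
    cox_univariate(d, "tertile")$coef
  })
  expect_true(all(abs(rowMeans(coefs)) < 0.1))
})

test_that("the hazard under the univariate preset depends on the tertile only", {
  co <- simulate_cohort(cohort_sim_config(
    n_patients = 2000, preset = "univariate_tertile", seed = 32))
  d <- cbind(co, tertile = assign_tertiles(co$tbs, co$patient_id)$label)
  # a covariate outside the preset carries no effect
  f <- cox_univariate(d, "perineural")
  expect_gt(f$p[1], 0.01)
  expect_true(f$ci_lower[1] < 1 && f$ci_upper[1] > 1)
})

test_that("a two-observation cohort has a monotone partial likelihood", {
  # with one event per group and no censoring the partial likelihood is
  # monotone in beta: no finite maximizer exists, and the fit says so
  d <- toy_cohort(time = c(1, 2), event = c(1, 1), x = c(1, 0))
  f <- suppressWarnings(cox_univariate(d, "x"))
  expect_false(f$converged)
  expect_true(any(grepl("monotone|separation", f$flags)))
})

test_that("the example clinical table reproduces the published margins", {
  ex <- example_clinical_table()
  expect_identical(nrow(ex), 86L)
  expect_identical(sum(ex$treatment == "surgery"), 68L)
  expect_identical(sum(ex$n_status == "N+"), 21L)
  expect_identical(sum(ex$gender == "male"), 63L)
  expect_identical(sum(ex$perineural == "yes"), 15L)
  expect_identical(as.integer(table(ex$stage)[c("I-II", "III", "IV")]),
                   c(55L, 3L, 28L))
  expect_identical(sum(ex$tbs == 0), 10L)
  expect_true(all(ex$stage[ex$n_status == "N+"] != "I-II"))
  expect_identical(ex, example_clinical_table())  # deterministic
})

test_that("the example selection manifest carries the documented exclusions", {
  m <- example_selection_manifest()
  expect_identical(nrow(m), 111L)
  expect_identical(sum(m$reason == "none"), 86L)
  expect_identical(sum(m$reason == "misclassified"), 10L)
  expect_identical(m, example_selection_manifest())
})

test_that("cohort CSV round trips preserve the analysis columns", {
  co <- simulate_cohort(cohort_sim_config(n_patients = 50, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_identical(back$patient_id, co$patient_id)
  expect_equal(back$tbs, co$tbs, tolerance = 1e-12)
  expect_identical(back$event, co$event)
})
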