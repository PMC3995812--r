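test_that("cohort filtering retains eligible cases and tallies exclusions", {
  m <- example_selection_manifest()
  f <- filter_cohort(m)
  expect_identical(f$n_retained, 86L)
  expect_identical(f$exclusions,
                   c(misclassified = 10L, insufficient_material = 9L,
                     poor_quality = 6L))
  all_in <- data.frame(case_id = 1:12, reason = "none")
  expect_identical(filter_cohort(all_in)$n_retained, 12L)
  expect_error(filter_cohort(data.frame(case_id = integer(0),
                                        reason = character(0))),
               "empty cohort")
  expect_error(filter_cohort(data.frame(case_id = 1, reason = "lost")),
               "unknown exclusion reason")
})

test_that("tertile assignment follows the rank rule", {
  t86 <- assign_tertiles(seq_len(86))
  expect_identical(t86$sizes, c(29L, 28L, 29L))
  expect_identical(assign_tertiles(c(3, 1, 2))$sizes, c(1L, 1L, 1L))
  expect_identical(assign_tertiles(stats::runif(100))$sizes, c(34L, 32L, 34L))
  expect_error(assign_tertiles(c(1, 2)), "at least 3")

  # property: sizes sum to n, lower and upper tertiles are equal in size
  set.seed(55)
  for (n in c(5, 9, 33, 86, 101)) {
    tt <- assign_tertiles(stats::rnorm(n))
    expect_identical(sum(tt$sizes), as.integer(n))
    expect_identical(tt$sizes[1], tt$sizes[3])
    expect_lte(abs(tt$sizes[1] - tt$sizes[2]), 2L)
  }

  # ties broken by id: zeros keep their id order, all landing in 'lower'
  v <- c(0, 0, 0, 0, 5, 6, 7, 8, 9)
  tt <- assign_tertiles(v, ids = as.character(1:9))
  expect_true(all(tt$index[v == 0][1:3] == 0L))
})

test_that("spearman screen matches hand-ranked examples", {
  d5 <- toy_cohort(time = rep(1, 5), event = rep(0, 5),
                   tbs = 1:5, v = c(2, 1, 4, 3, 5))
  out <- spearman_screen(d5, "tbs", "v")
  # hand computation: sum d^2 = 4, rho = 1 - 6*4 / (5 * 24) = 0.8
  expect_equal(out$rho, 0.8, tolerance = 1e-12)

  d_same <- toy_cohort(time = rep(1, 6), event = rep(0, 6),
                       tbs = c(3, 9, 1, 4, 7, 2), v = c(3, 9, 1, 4, 7, 2))
  expect_equal(spearman_screen(d_same, "tbs", "v")$rho, 1, tolerance = 1e-12)

  set.seed(8)
  d_null <- toy_cohort(time = rep(1, 1000), event = rep(0, 1000),
                       tbs = rnorm(1000), v = rnorm(1000))
  expect_lt(abs(spearman_screen(d_null, "tbs", "v")$rho), 0.1)

  d_const <- toy_cohort(time = rep(1, 5), event = rep(0, 5),
                        tbs = 1:5, v = rep(2, 5))
  expect_warning(out_c <- spearman_screen(d_const, "tbs", "v"), "constant")
  expect_true(is.na(out_c$rho))
})

test_that("cox_univariate agrees with brute-force partial-likelihood search", {
  set.seed(12)
  for (k in 1:6) {
    n <- sample(4:8, 1)
    d <- toy_cohort(time = sort(runif(n, 1, 20)),
                    event = rbinom(n, 1, 0.8), x = rnorm(n))
    if (sum(d$event) < 2) d$event[1:2] <- 1
    g <- grid_cox_beta(d$time_to_recurrence, d$event, d$x)
    if (!g$interior) next
    f <- cox_univariate(d, "x")
    expect_lt(abs(unname(f$coef) - g$beta), 1e-3)
  }
})

test_that("a null covariate's confidence interval covers 1", {
  # covering 1 is a 95%-probability event per draw; assert the majority
  # over 10 replicates (a miss in 3+ of 10 has probability < 2e-3)
  covers <- sapply(61:70, function(s) {
    co <- simulate_cohort(cohort_sim_config(
      n_patients = 2000, preset = "univariate_single_factor", seed = s))
    f <- cox_univariate(co, "margin")  # not in the hazard
    f$ci_lower[1] < 1 && f$ci_upper[1] > 1
  })
  expect_gte(sum(covers), 8)
})

test_that("Wald confidence intervals attain nominal coverage", {
  hits <- logical(200)
  for (r in seq_len(200)) {
    co <- simulate_cohort(cohort_sim_config(
      n_patients = 500, preset = "univariate_single_factor", seed = 9000 + r))
    f <- cox_univariate(co, "n_status")
    hits[r] <- f$ci_lower[1] <= 3.0 && f$ci_upper[1] >= 3.0
  }
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 1.00)
})

test_that("errors are raised for unusable survival inputs", {
  d <- toy_cohort(time = c(1, 2, 3, 4), event = c(0, 0, 0, 0), x = c(1, 0, 1, 0))
  expect_error(cox_univariate(d, "x"), "no events")
  d2 <- toy_cohort(time = 1:4, event = c(1, 1, 0, 0), x = rep(1, 4))
  expect_error(cox_univariate(d2, "x"), "distinct")
  expect_error(cox_multivariate_backward(d, character(0)), "empty candidate")
})

test_that("backward elimination removes noise and keeps real factors", {
  co <- simulate_cohort(cohort_sim_config(
    n_patients = 2000, preset = "multivariate", seed = 1))
  d <- cbind(co, score_tertile = assign_tertiles(co$tbs, co$patient_id)$index)
  bw <- cox_multivariate_backward(
    d, c("score_tertile", "perineural", "n_status", "stage", "margin"))
  expect_true(all(c("score_tertile", "perineural", "n_status") %in% bw$retained))
  expect_true(all(c("stage", "margin") %in% bw$trace$removed))
  expect_true(all(bw$trace$p >= 0.10))

  # single candidate already below alpha is returned unchanged
  one <- cox_multivariate_backward(d, "n_status")
  expect_identical(one$retained, "n_status")
  expect_identical(nrow(one$trace), 0L)
})

test_that("the PH diagnostic counts one residual per event", {
  d <- toy_cohort(time = c(1, 3, 5, 7, 9, 11), event = c(1, 1, 1, 0, 0, 0),
                  x = c(1, 0, 1, 0, 1, 0))
  f <- suppressWarnings(cox_univariate(d, "x"))
  ph <- suppressWarnings(ph_test(f))
  expect_identical(attr(ph, "n_events"), 3L)
  d2 <- toy_cohort(time = c(1, 3, 5, 7), event = c(1, 1, 0, 0), x = c(1, 0, 1, 0))
  expect_error(suppressWarnings(ph_test(suppressWarnings(cox_univariate(d2, "x")))),
               "3 events")
})

test_that("the PH diagnostic agrees with the reference implementation", {
  co <- simulate_cohort(cohort_sim_config(
    n_patients = 300, preset = "univariate_single_factor", seed = 11))
  f <- cox_univariate(co, "n_status")
  ours <- ph_test(f)
  ref <- survival::cox.zph(f$fit, transform = "identity")
  expect_equal(ours$p[1], ref$table[1, "p"], tolerance = 0.05)
  expect_identical(ours$p[1] < 0.05, ref$table[1, "p"] < 0.05)
})

test_that("log-rank statistics match hand computation on printed toys", {
  d <- toy_cohort(time = c(1, 2, 3, 4, 5, 6), event = rep(1, 6),
                  g = rep(c("A", "B"), each = 3))
  sc <- suppressWarnings(survival_curves(d, d$g))
  hand <- hand_logrank_chisq(d$time_to_recurrence, d$event, d$g == "A")
  expect_equal(sc$logrank_chisq, hand, tolerance = 1e-6)
  expect_equal(hand, 5.0517, tolerance = 1e-4)

  # identical duplicated groups: chi-square exactly 0, p = 1
  d2 <- toy_cohort(time = rep(c(1, 3, 7, 8, 12), 2),
                   event = rep(c(1, 1, 0, 1, 1), 2),
                   g = rep(c("A", "B"), each = 5))
  sc2 <- survival_curves(d2, d2$g)
  expect_equal(sc2$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(sc2$logrank_p, 1)

  expect_error(survival_curves(d, rep("A", 6)), "2 groups")
})

test_that("survival curves start at 1 and decrease within each group", {
  co <- simulate_cohort(cohort_sim_config(n_patients = 300, seed = 71))
  tert <- assign_tertiles(co$tbs, co$patient_id)
  sc <- survival_curves(co, tert)
  for (g in unique(sc$cox_curves$group)) {
    s <- sc$cox_curves$survival[sc$cox_curves$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(max(s), 1)
  }
  expect_identical(sort(unique(sc$km_curves$group)),
                   c("lower", "middle", "upper"))
})
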