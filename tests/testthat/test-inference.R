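test_that("mixed-model fits are invariant to balanced row duplication", {
  rows <- sim_analysis_rows(n_subjects = 30, b_reading = 0.02,
                            b_duration = 0.5, seed = 2)
  f1 <- fit_lmm("slope", c("reading_score", "duration"), rows, reml = FALSE)
  f2 <- fit_lmm("slope", c("reading_score", "duration"),
                rbind(rows, rows), reml = FALSE)
  expect_equal(lme4::fixef(f1), lme4::fixef(f2), tolerance = 1e-6)
})

test_that("rank-deficient designs fail with the aliased terms named", {
  rows <- sim_analysis_rows(n_subjects = 20)
  rows$reading_copy <- rows$reading_score
  expect_error(fit_lmm("slope", c("reading_score", "reading_copy"), rows),
               "aliased.*reading_copy")
})

test_that("bootstrap LR test handles identical, nested, and rescaled models", {
  rows <- sim_analysis_rows(n_subjects = 24, b_duration = 0.4, seed = 5)
  full <- fit_lmm("slope", c("reading_score", "duration"), rows)
  reduced <- fit_lmm("slope", "duration", rows)

  same <- pb_term_test(full, full, n_boot = 10, seed = 1)
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)

  pt <- pb_term_test(full, reduced, n_boot = 60, seed = 2)
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)

  # LR statistic is invariant to rescaling the outcome
  rows10 <- rows
  rows10$slope <- rows$slope * 10
  full10 <- fit_lmm("slope", c("reading_score", "duration"), rows10)
  reduced10 <- fit_lmm("slope", "duration", rows10)
  pt10 <- pb_term_test(full10, reduced10, n_boot = 60, seed = 2)
  expect_equal(pt$statistic, pt10$statistic, tolerance = 1e-6)
  expect_equal(pt$p_value, pt10$p_value)

  other <- fit_lmm("slope", "adhd", rows)
  expect_error(pb_term_test(full, other, n_boot = 10, seed = 1), "nested")
  expect_error(pb_term_test(fit_lmm("slope", "duration", rows, reml = TRUE),
                            reduced, n_boot = 10, seed = 1), "ML")
})

test_that("a strong effect is detected by the bootstrap test", {
  rows <- sim_analysis_rows(n_subjects = 40, b_duration = 1.2,
                            sd_resid = 0.25, seed = 7)
  full <- fit_lmm("slope", "duration", rows)
  reduced <- fit_lmm("slope", character(0), rows)
  pt <- pb_term_test(full, reduced, n_boot = 200, seed = 3)
  expect_lt(pt$p_value, 0.05)
})

test_that("model selection drops null covariates and interaction, keeps real mains", {
  rows <- sim_analysis_rows(n_subjects = 48, b_reading = 0.03,
                            b_duration = 0.6, sd_resid = 0.25, seed = 34)
  sel <- select_model("slope", rows, n_boot = 120, seed = 10)
  expect_setequal(sel$final_terms, c("reading_score", "duration"))

  # the log covers both covariates, the interaction, and both mains
  expect_equal(sel$selection_log$term[sel$selection_log$stage == "covariates"],
               c("adhd", "nonverbal_iq"))
  expect_true("reading_score:duration" %in%
                sel$selection_log$term[sel$selection_log$stage == "interaction"])
  expect_setequal(sel$selection_log$term[sel$selection_log$stage == "mains"],
                  c("reading_score", "duration"))
  expect_equal(sum(duplicated(sel$selection_log[c("stage", "term")])), 0L)

  # coefficient table comes from the REML refit of the surviving model
  expect_equal(sel$model_table$parameter,
               c("(Intercept)", "reading_score", "duration"))
  expect_true(all(sel$model_table$se > 0))
  expect_equal(unname(coef(summary(sel$final_model))[, "Estimate"]),
               sel$model_table$beta)
  # retention respects the p < 0.1 rule
  expect_true(all(sel$selection_log$retained ==
                    (sel$selection_log$p < 0.1), na.rm = TRUE))
})

test_that("Cohen's d matches hand evaluation and flips sign with group order", {
  es <- cohens_d(c(3, 4, 5), c(1, 2, 3))
  expect_equal(es$d, 2)           # pooled sd = 1, mean difference = 2
  expect_true(es$ci_low <= es$d && es$d <= es$ci_high)
  es_rev <- cohens_d(c(1, 2, 3), c(3, 4, 5))
  expect_equal(es_rev$d, -2)
  expect_equal(abs(es_rev$ci_low), es$ci_high, tolerance = 1e-6)

  # identical distributions: d = 0 with an interval straddling zero
  es0 <- cohens_d(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(es0$d, 0)
  expect_lt(es0$ci_low, 0)
  expect_gt(es0$ci_high, 0)

  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("group contrasts separate dyslexic from above-average readers", {
  rows <- sim_analysis_rows(n_subjects = 50, b_reading = 0.04,
                            sd_resid = 0.3, seed = 12)
  rows$pc1 <- rows$slope
  gc <- group_contrast("pc1", rows, n_boot = 60, seed = 6)
  # reading drives the outcome, so above-average minus dyslexic is positive
  expect_gt(gc$effect_size$d, 0)
  expect_true("groupdyslexic" %in% gc$selection$model_table$parameter)
  expect_lte(gc$effect_size$ci_low, gc$effect_size$d)

  few <- rows[rows$group != "dyslexic" | rows$subject == "s01", ]
  expect_error(group_contrast("pc1", few, n_boot = 10, seed = 1),
               "2 subjects")
})

test_that("demographic rank tests match exact references", {
  subjects <- data.frame(
    subject = sprintf("s%d", 1:9),
    group = rep(c("dyslexic", "below_average", "above_average"), each = 3),
    age = rep(c(9, 10, 11), 3),                    # identical across groups
    adhd = rep(c(1, 0, 0), 3),
    reading_score = c(1, 2, 3, 4, 5, 6, 1, 2, 3),
    nonverbal_iq = c(40, 45, 50, 48, 52, 56, 55, 60, 65))
  out <- demographics_tests(subjects)

  # three identical age samples: Kruskal-Wallis H = 0
  kw_age <- out[out$test == "kruskal_wallis" & out$measure == "age", ]
  expect_equal(kw_age$statistic, 0)
  expect_equal(kw_age$df, 2)

  # {1,2,3} vs {4,5,6}: exact two-sided rank-sum p = 0.1
  w1 <- out[out$measure == "reading_score" &
              out$comparison == "dyslexic_vs_below_average", ]
  expect_equal(w1$p, 0.1)
  # identical samples: p = 1
  w2 <- out[out$measure == "reading_score" &
              out$comparison == "dyslexic_vs_above_average", ]
  expect_equal(w2$p, 1)
  # Bonferroni flag uses alpha / 24
  expect_true(all(out$significant_bonferroni == (out$p < 0.05 / 24)))

  expect_error(demographics_tests(subjects[subjects$group == "dyslexic", ]),
               "2 groups")
})

test_that("analysis rows apply the coding conventions", {
  measures <- data.frame(subject = c("a", "a", "b"),
                         condition = c("short", "long", "short"),
                         slope = c(1, 1.5, 0.7))
  subjects <- data.frame(subject = c("a", "b"),
                         reading_score = c(110, 80), adhd = c(0, 1),
                         nonverbal_iq = c(55, 45))
  rows <- analysis_rows(measures, subjects)
  expect_equal(rows$duration[rows$condition == "long"], 0.5)
  expect_equal(rows$duration[rows$condition == "short"], c(-0.5, -0.5))
  expect_equal(as.character(rows$group[rows$subject == "a"][1]), "above_average")
  expect_equal(as.character(rows$group[rows$subject == "b"][1]), "dyslexic")
  expect_equal(reading_group(c(85, 85.1, 100, 100.1)),
               c("dyslexic", "below_average", "below_average", "above_average"))
})
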