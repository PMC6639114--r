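test_that("the candidate prior set is fixed-zero plus six uniform bounds", {
  pr <- candidate_priors()
  expect_length(pr, 7L)
  expect_equal(pr[[1]]$kind, "fixed_zero")
  expect_equal(sapply(pr[-1], `[[`, "lapse_upper_bound"),
               seq(0.05, 0.30, by = 0.05), ignore_attr = TRUE)
  expect_equal(pr[[4]]$lapse_upper_bound, 0.15)  # third uniform prior
})

make_cv_table <- function(n_subjects = 3, n_blocks = 2, n_per_step = 10,
                          gamma = 0, lambda = 0, w = 2, seed = 5) {
  do.call(rbind, lapply(seq_len(n_subjects), function(s)
    do.call(rbind, lapply(seq_len(n_blocks), function(b)
      sim_block(psychometric_params(4, w, gamma, lambda),
                n_per_step = n_per_step, seed = seed + 31 * s + b,
                subject = sprintf("s%d", s), block = b)))))
}

test_that("cross-validation partitions trials and normalizes against fixed-zero", {
  data <- make_cv_table(n_subjects = 2, n_blocks = 1, n_per_step = 5)
  priors <- candidate_priors()[c(1, 4)]
  cv <- crossval_prior_score(data, priors, n_folds = 10, seed = 3,
                             grid = coarse_grid(n_m = 15, n_w = 11, n_lapse = 5))

  # every subject x block x prior has exactly n_folds held-out records
  counts <- table(cv$scores$subject, cv$scores$prior_id)
  expect_true(all(counts == 10))
  # held-out log-likelihoods are log-probabilities
  expect_true(all(cv$scores$heldout_ll <= 0))
  # the fixed-zero baseline normalizes to exactly zero against itself
  expect_true(all(cv$summary$normalized[cv$summary$prior_id == "fixed_zero"] == 0))
  # deterministic under the seed
  cv2 <- crossval_prior_score(data, priors, n_folds = 10, seed = 3,
                              grid = coarse_grid(n_m = 15, n_w = 11, n_lapse = 5))
  expect_equal(cv$scores$heldout_ll, cv2$scores$heldout_ll)

  expect_error(crossval_prior_score(data[data$step < 3, ], priors,
                                    n_folds = 30, seed = 1,
                                    grid = coarse_grid()),
               "fewer trials")
})

test_that("the one-standard-error rule picks the smallest bound clearing zero", {
  fake_table <- function(by_prior) {
    # by_prior: named list bound -> per-subject normalized scores
    rows <- do.call(rbind, lapply(names(by_prior), function(b) {
      v <- by_prior[[b]]
      data.frame(subject = sprintf("s%d", seq_along(v)),
                 prior_id = if (b == "0") "fixed_zero"
                            else sprintf("uniform_%02d", round(100 * as.numeric(b))),
                 lapse_bound = as.numeric(b), median_ll = v, baseline_ll = 0,
                 normalized = v)
    }))
    structure(list(summary = rows, scores = NULL, n_folds = 10, seed = 1),
              class = "prior_score_table")
  }

  # one prior clears the rule: mean 1.0, se 0.2; smaller bounds do not
  t1 <- fake_table(list(`0` = c(0, 0, 0, 0),
                        `0.05` = c(0.3, -0.3, 0.2, -0.2),
                        `0.1` = c(1.2, 0.8, 1.2, 0.8),
                        `0.15` = c(1.3, 0.9, 1.3, 0.9)))
  sel <- select_prior(t1)
  expect_equal(sel$lapse_upper_bound, 0.10)
  rule <- attr(sel, "rule_table")
  expect_equal(rule$mean[rule$lapse_bound == 0.1], 1.0)
  expect_equal(rule$se[rule$lapse_bound == 0.1], sd(c(1.2, .8, 1.2, .8)) / 2)

  # nothing clears the rule: fall back to fixed-zero
  t2 <- fake_table(list(`0` = c(0, 0, 0), `0.05` = c(-1, 0, -2),
                        `0.1` = c(0.5, -0.5, 0.1)))
  expect_equal(select_prior(t2)$kind, "fixed_zero")

  # single-subject tables have no across-subject standard error
  t3 <- fake_table(list(`0` = 0, `0.05` = 1))
  expect_error(select_prior(t3), "2 subjects")
})

test_that("selection is invariant to per-subject score offsets", {
  data <- make_cv_table(n_subjects = 3, n_blocks = 1, n_per_step = 8,
                        gamma = 0.15, lambda = 0.15)
  cv <- crossval_prior_score(data, candidate_priors()[c(1, 3, 5)],
                             n_folds = 5, seed = 9,
                             grid = coarse_grid(n_m = 15, n_w = 11, n_lapse = 5))
  sel1 <- select_prior(cv)
  shifted <- cv
  off <- stats::setNames(c(5, -3, 40), unique(cv$summary$subject))
  shifted$summary$median_ll <- cv$summary$median_ll + off[cv$summary$subject]
  shifted$summary$baseline_ll <- cv$summary$baseline_ll + off[cv$summary$subject]
  # normalized scores are already offset-free; recompute to prove it
  shifted$summary$normalized <- shifted$summary$median_ll - shifted$summary$baseline_ll
  sel2 <- select_prior(shifted)
  expect_equal(sel1$lapse_upper_bound, sel2$lapse_upper_bound)
})

test_that("observers with a real lapse rate favor a lapse-permitting prior", {
  # generative common lapse 0.20 with generous trials: the 0.20-bound prior
  # must beat fixed-zero on held-out likelihood
  data <- make_cv_table(n_subjects = 3, n_blocks = 2, n_per_step = 25,
                        gamma = 0.2, lambda = 0.2, seed = 11)
  cv <- crossval_prior_score(data, candidate_priors()[c(1, 5)],  # zero, 0.20
                             n_folds = 10, seed = 4,
                             grid = coarse_grid(n_m = 15, n_w = 11, n_lapse = 6))
  s <- cv$summary
  expect_gt(mean(s$normalized[s$prior_id == "uniform_20"]),
            mean(s$normalized[s$prior_id == "fixed_zero"]))
})
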