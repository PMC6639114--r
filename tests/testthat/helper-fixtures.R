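# shared fixtures built in code

# response table simulated from known psychometric parameters, one block
sim_block <- function(params, n_per_step = 5, steps = 1:7, seed = 1,
                      subject = "s1", condition = "short", block = 1) {
  set.seed(seed)
  psi <- psychometric_value(params, steps)
  k <- stats::rbinom(length(steps), n_per_step, psi)
  response_table(subject, condition, block, steps,
                 rep(n_per_step, length(steps)), k)
}

# small coarse grid for fast fitting in tests
coarse_grid <- function(n_m = 21, n_w = 15, n_lapse = 6) {
  grid_spec(n_m = n_m, n_w = n_w, n_lapse = n_lapse)
}

# analysis rows drawn directly from a linear outcome model (no psychometric
# fitting), for mixed-model tests: outcome = b0 + br*reading + bd*duration +
# subject intercept + residual
sim_analysis_rows <- function(n_subjects = 40, b_reading = 0, b_duration = 0,
                              sd_subject = 0.3, sd_resid = 0.3, seed = 1) {
  set.seed(seed)
  reading <- runif(n_subjects, 60, 130)
  u <- rnorm(n_subjects, 0, sd_subject)
  rows <- expand.grid(subject = sprintf("s%02d", seq_len(n_subjects)),
                      condition = c("short", "long"),
                      stringsAsFactors = FALSE)
  i <- match(rows$subject, sprintf("s%02d", seq_len(n_subjects)))
  rows$duration <- ifelse(rows$condition == "long", 0.5, -0.5)
  rows$reading_score <- reading[i]
  rows$adhd <- rbinom(nrow(rows), 1, 0.25)[i]
  rows$nonverbal_iq <- rnorm(n_subjects, 50, 8)[i]
  rows$group <- reading_group(rows$reading_score)
  rows$slope <- 1 + b_reading * rows$reading_score +
    b_duration * rows$duration + u[i] + rnorm(nrow(rows), 0, sd_resid)
  rows
}
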