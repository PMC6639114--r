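#' Generative model for a synthetic cohort
#'
#' Defines how true psychometric parameters and covariates are generated for
#' simulated subjects. The slope of the psychometric function depends
#' linearly on the composite reading score and on cue duration (sum-coded
#' +0.5 long / -0.5 short); the average asymptote offset depends linearly on
#' reading score; thresholds are Gaussian in step units. Default coefficients
#' are the selected-model estimates for the slope and asymptote measures
#' (reading 0.027 and duration 0.509 for slope; reading -0.0008 for
#' asymptote); the intercepts, which the selected models do not pin down, are
#' set so a reading score of 100 yields a mid-range slope (1.4 probability
#' per step in the short condition) and a small asymptote offset.
#'
#' @param slope_intercept,slope_beta_reading,slope_beta_duration linear model
#'   of slope (probability per continuum step).
#' @param asym_intercept,asym_beta_reading linear model of the average
#'   asymptote offset (gamma + lambda)/2.
#' @param threshold_mean,threshold_sd Gaussian threshold distribution, step
#'   units.
#' @param slope_noise_sd,asym_noise_sd SD of per-subject random deviations
#'   (shared across conditions, so they act as subject random effects).
#' @param lapse_jitter_sd SD of independent jitter applied to gamma and
#'   lambda around the common asymptote value, so the two asymptotes differ.
#' @param min_slope,max_avg_asym clamping limits keeping generated parameters
#'   valid.
#' @param reading_distribution `"uniform"` (uniform over `reading_range`,
#'   maximizing identifiability across the skill continuum) or `"trimodal"`
#'   (three-component Gaussian mixture matching the study groups' composite
#'   means/SDs and sizes).
#' @param reading_range range of the uniform reading-score distribution.
#' @param group_weights,group_reading_mean,group_reading_sd trimodal mixture
#'   settings, in group order dyslexic / below_average / above_average.
#' @param niq_mean,niq_sd group-conditional nonverbal IQ (t-score units).
#' @param adhd_prev group-conditional ADHD prevalence.
#' @param age_mean,age_sd group-conditional age (years).
#' @return an object of class `generative_model`.
#' @export
generative_model <- function(slope_intercept = 1.4 - 0.027 * 100 + 0.509 / 2,
                             slope_beta_reading = 0.027,
                             slope_beta_duration = 0.509,
                             asym_intercept = 0.12,
                             asym_beta_reading = -0.0008,
                             threshold_mean = 4,
                             threshold_sd = 0.5,
                             slope_noise_sd = 0.2,
                             asym_noise_sd = 0.02,
                             lapse_jitter_sd = 0.01,
                             min_slope = 0.05,
                             max_avg_asym = 0.25,
                             reading_distribution = c("uniform", "trimodal"),
                             reading_range = c(60, 130),
                             group_weights = c(36, 17, 19) / 72,
                             group_reading_mean = c(73.2, 93.6, 111.1),
                             group_reading_sd = c(9, 4.5, 8.5),
                             niq_mean = c(46.5, 52.0, 60.0),
                             niq_sd = c(6.4, 8.0, 11.8),
                             adhd_prev = c(11 / 36, 5 / 17, 4 / 19),
                             age_mean = c(9.7, 9.5, 10.3),
                             age_sd = c(1.3, 1.2, 1.7)) {
  reading_distribution <- match.arg(reading_distribution)
  check_scalar(threshold_sd, "threshold_sd", lower = 0)
  check_scalar(slope_noise_sd, "slope_noise_sd", lower = 0)
  check_scalar(min_slope, "min_slope", lower = 0, strict_lower = TRUE)
  check_scalar(max_avg_asym, "max_avg_asym", lower = 0, upper = 0.5,
               strict_upper = TRUE)
  if (any(adhd_prev < 0 | adhd_prev > 1))
    stop("'adhd_prev' must be probabilities", call. = FALSE)
  if (diff(reading_range) <= 0)
    stop("'reading_range' must be increasing", call. = FALSE)
  structure(as.list(environment()), class = "generative_model")
}

#' True psychometric parameters implied by reading score and condition
#'
#' Evaluates the generative linear models for one subject: slope and average
#' asymptote follow their linear predictors plus the supplied per-subject
#' deviations, are clamped to valid ranges, and are converted to the
#' four-parameter representation (width from [slope_to_width()], the average
#' asymptote split into gamma and lambda with the subject's jitter).
#'
#' @param reading_score composite reading score.
#' @param condition `"short"` or `"long"`.
#' @param model a [generative_model()].
#' @param deviation named list of per-subject deviations: `slope`, `asym`,
#'   `gamma_jitter`, `lambda_jitter`, `threshold` (each defaulting to 0).
#' @return a [psychometric_params()].
#' @export
true_params_from_reading <- function(reading_score, condition, model,
                                     deviation = list()) {
  stopifnot(inherits(model, "generative_model"))
  if (!condition %in% c("short", "long"))
    stop("'condition' must be 'short' or 'long'", call. = FALSE)
  dev <- utils::modifyList(list(slope = 0, asym = 0, gamma_jitter = 0,
                                lambda_jitter = 0, threshold = 0), deviation)
  dur <- if (condition == "long") 0.5 else -0.5
  slope <- model$slope_intercept + model$slope_beta_reading * reading_score +
    model$slope_beta_duration * dur + dev$slope
  slope <- max(slope, model$min_slope)
  avg_asym <- model$asym_intercept + model$asym_beta_reading * reading_score +
    dev$asym
  avg_asym <- min(max(avg_asym, 0), model$max_avg_asym)
  lapse_cap <- model$max_avg_asym + 0.1  # each asymptote; keeps gamma+lambda < 1
  gamma <- min(max(avg_asym + dev$gamma_jitter, 0), lapse_cap)
  lambda <- min(max(avg_asym + dev$lambda_jitter, 0), lapse_cap)
  m <- model$threshold_mean + dev$threshold
  psychometric_params(m = m, w = slope_to_width(slope, gamma, lambda),
                      gamma = gamma, lambda = lambda)
}

#' Generate a synthetic cohort
#'
#' Draws reading scores, group-conditional covariates (nonverbal IQ, ADHD,
#' age) and per-subject parameter deviations from the generative model, and
#' derives each subject's true psychometric parameters for both duration
#' conditions. Deterministic under `seed`.
#'
#' @param n_subjects number of subjects (>= 4).
#' @param model a [generative_model()].
#' @param seed integer seed.
#' @return an object of class `cohort`: a list of subject records, each with
#'   `subject`, `reading_score`, `group`, `adhd`, `nonverbal_iq`, `age`, and
#'   `params` (a list with `short` and `long` [psychometric_params()]).
#' @export
generate_cohort <- function(n_subjects, model = generative_model(), seed) {
  stopifnot(inherits(model, "generative_model"))
  check_scalar(n_subjects, "n_subjects", lower = 4)
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for a reproducible cohort", call. = FALSE)
  groups <- c("dyslexic", "below_average", "above_average")
  with_seed(seed, {
    reading <- if (model$reading_distribution == "uniform") {
      stats::runif(n_subjects, model$reading_range[1], model$reading_range[2])
    } else {
      comp <- sample.int(3, n_subjects, replace = TRUE,
                         prob = model$group_weights)
      stats::rnorm(n_subjects, model$group_reading_mean[comp],
                   model$group_reading_sd[comp])
    }
    grp <- reading_group(reading)
    gi <- match(grp, groups)
    records <- lapply(seq_len(n_subjects), function(i) {
      dev <- list(slope = stats::rnorm(1, 0, model$slope_noise_sd),
                  asym = stats::rnorm(1, 0, model$asym_noise_sd),
                  gamma_jitter = stats::rnorm(1, 0, model$lapse_jitter_sd),
                  lambda_jitter = stats::rnorm(1, 0, model$lapse_jitter_sd),
                  threshold = stats::rnorm(1, 0, model$threshold_sd))
      list(subject = sprintf("s%03d", i),
           reading_score = reading[i],
           group = grp[i],
           adhd = as.integer(stats::runif(1) < model$adhd_prev[gi[i]]),
           nonverbal_iq = stats::rnorm(1, model$niq_mean[gi[i]],
                                       model$niq_sd[gi[i]]),
           age = stats::rnorm(1, model$age_mean[gi[i]], model$age_sd[gi[i]]),
           params = list(
             short = true_params_from_reading(reading[i], "short", model, dev),
             long = true_params_from_reading(reading[i], "long", model, dev)))
    })
    structure(records, class = "cohort", model = model)
  })
}

#' Per-subject covariate table of a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame with one row per subject.
#' @export
cohort_subjects <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort, function(s)
    data.frame(subject = s$subject, reading_score = s$reading_score,
               group = s$group, adhd = s$adhd,
               nonverbal_iq = s$nonverbal_iq, age = s$age)))
}

#' True parameter table of a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame with one row per subject x condition and columns for
#'   the four parameters plus the derived slope and average asymptote.
#' @export
cohort_true_params <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  do.call(rbind, lapply(cohort, function(s)
    do.call(rbind, lapply(c("short", "long"), function(cd) {
      p <- s$params[[cd]]
      data.frame(subject = s$subject, condition = cd, m = p$m, w = p$w,
                 gamma = p$gamma, lambda = p$lambda, slope = p$slope,
                 avg_asymptote = (p$gamma + p$lambda) / 2)
    }))))
}

#' Simulate a subject's responses to a trial schedule
#'
#' Each trial is an independent Bernoulli draw with success probability
#' `psi(step)` under the subject's true parameters for the trial's
#' condition; draws are aggregated into response-table rows per block x step.
#'
#' @param subject one subject record from a [generate_cohort()] cohort.
#' @param schedule a [make_session_schedule()] data.frame.
#' @param seed integer seed.
#' @return a `response_table` data.frame.
#' @export
simulate_responses <- function(subject, schedule, seed) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for reproducible responses", call. = FALSE)
  conds <- unique(schedule$condition)
  if (!all(conds %in% names(subject$params)))
    stop("subject lacks true parameters for condition(s): ",
         paste(setdiff(conds, names(subject$params)), collapse = ", "),
         call. = FALSE)
  psi <- numeric(nrow(schedule))
  for (cd in conds) {
    i <- schedule$condition == cd
    psi[i] <- psychometric_value(subject$params[[cd]], schedule$step[i])
  }
  resp <- with_seed(seed, as.integer(stats::runif(nrow(schedule)) < psi))
  agg <- stats::aggregate(resp, list(block = schedule$block,
                                     condition = schedule$condition,
                                     step = schedule$step),
                          function(r) c(n = length(r), k = sum(r)))
  response_table(subject = subject$subject, condition = agg$condition,
                 block = agg$block, step = agg$step,
                 n_trials = agg$x[, "n"], n_target = agg$x[, "k"])
}

#' Simulate the full experiment for a cohort
#'
#' Builds each subject a 6-block alternating schedule (start condition
#' counterbalanced across subjects) and simulates all trials.
#'
#' @param cohort a [generate_cohort()] cohort.
#' @param seed integer seed.
#' @param spec a [continuum_spec()] (for `n_steps`).
#' @param reps_per_step,n_blocks schedule settings.
#' @return a `response_table` covering all subjects.
#' @export
simulate_cohort <- function(cohort, seed, spec = continuum_spec(),
                            reps_per_step = 5, n_blocks = 6) {
  stopifnot(inherits(cohort, "cohort"))
  out <- lapply(seq_along(cohort), function(i) {
    start <- if (i %% 2 == 1) "short" else "long"
    sched <- make_session_schedule(spec, start, reps_per_step, n_blocks,
                                   seed = seed + 7919L * i)
    simulate_responses(cohort[[i]], sched, seed = seed + 7919L * i + 1L)
  })
  validate_response_table(do.call(rbind, out))
}
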