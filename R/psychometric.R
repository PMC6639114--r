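#' Four-parameter logistic psychometric function
#'
#' The psychometric model is
#' \deqn{\psi(x) = \gamma + (1 - \gamma - \lambda)\, S(x; m, w)}
#' where \eqn{S} is a logistic sigmoid parameterized by its threshold `m`
#' (the point where \eqn{S = 0.5}) and width `w`, the interval between the 5%
#' and 95% points of \eqn{S}: \eqn{S(x) = 1/(1 + e^{-2\ln(19)(x-m)/w})}, so
#' that \eqn{S(m \pm w/2) = 0.95/0.05}. `gamma` is the lower asymptote and
#' `lambda` the upper-asymptote offset (upper asymptote \eqn{1 - \lambda}); a
#' common lapse rate of 0.1 makes the asymptotes 0.1 and 0.9.
#'
#' @param m threshold, in continuum-step units.
#' @param w width (5%-95% interval of the sigmoid), in continuum-step units;
#'   must be positive.
#' @param gamma lower asymptote, a probability.
#' @param lambda upper-asymptote offset, a probability; `gamma + lambda` must
#'   be < 1.
#' @return an object of class `psychometric_params` with fields `m`, `w`,
#'   `gamma`, `lambda` and the derived `slope` (see [width_to_slope()]).
#' @export
psychometric_params <- function(m, w, gamma = 0, lambda = 0) {
  check_scalar(m, "m")
  check_scalar(w, "w", lower = 0, strict_lower = TRUE)
  check_scalar(gamma, "gamma", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(lambda, "lambda", lower = 0, upper = 1, strict_upper = TRUE)
  if (gamma + lambda >= 1)
    stop("'gamma' + 'lambda' must be < 1", call. = FALSE)
  p <- structure(list(m = m, w = w, gamma = gamma, lambda = lambda),
                 class = "psychometric_params")
  p$slope <- width_to_slope(p)
  p
}

#' @exportS3Method base::print
print.psychometric_params <- function(x, ...) {
  cat(sprintf(
    "psychometric_params: m = %.3f, w = %.3f, gamma = %.3f, lambda = %.3f, slope = %.3f\n",
    x$m, x$w, x$gamma, x$lambda, x$slope))
  invisible(x)
}

#' Evaluate the psychometric function
#'
#' @param params a [psychometric_params()].
#' @param x continuum position(s), in step units.
#' @return probability of the target ("s"-like) response at each `x`.
#' @export
psychometric_value <- function(params, x) {
  stopifnot(inherits(params, "psychometric_params"))
  s <- stats::plogis(2 * log(19) * (x - params$m) / params$w)
  params$gamma + (1 - params$gamma - params$lambda) * s
}

#' Slope at threshold
#'
#' Converts the width parameter to the derivative of the psychometric
#' function at the threshold:
#' \eqn{d\psi/dx |_{x=m} = (1-\gamma-\lambda)\ln(19)/(2w)}.
#'
#' @param params a [psychometric_params()].
#' @return slope in probability per continuum step.
#' @export
width_to_slope <- function(params) {
  stopifnot(inherits(params, "psychometric_params"))
  if (params$w <= 0) stop("'w' must be positive", call. = FALSE)
  (1 - params$gamma - params$lambda) * log(19) / (2 * params$w)
}

#' Width from slope
#'
#' Inverse of [width_to_slope()]: the width that yields a given slope at
#' threshold for given asymptote parameters. Used by the synthetic-cohort
#' generator, where the generative model is expressed on the slope scale.
#'
#' @param slope target slope at threshold (probability per step); positive.
#' @param gamma,lambda asymptote parameters.
#' @return width `w` in continuum-step units.
#' @export
slope_to_width <- function(slope, gamma = 0, lambda = 0) {
  check_scalar(slope, "slope", lower = 0, strict_lower = TRUE)
  (1 - gamma - lambda) * log(19) / (2 * slope)
}

#' Assemble / validate a response table
#'
#' The response table is the trial-aggregated record of a two-alternative
#' categorization session: one row per subject x condition x block x step
#' with the number of trials and the number of target ("s"-like) responses.
#'
#' @param subject subject identifiers.
#' @param condition `"short"` or `"long"`.
#' @param block block index.
#' @param step continuum step index.
#' @param n_trials trials presented.
#' @param n_target target responses observed; `0 <= n_target <= n_trials`.
#' @return a validated data.frame of class `response_table`.
#' @export
response_table <- function(subject, condition, block, step, n_trials, n_target) {
  out <- data.frame(subject = subject, condition = as.character(condition),
                    block = as.integer(block), step = as.integer(step),
                    n_trials = as.integer(n_trials),
                    n_target = as.integer(n_target))
  validate_response_table(out)
}

validate_response_table <- function(data) {
  need <- c("subject", "condition", "block", "step", "n_trials", "n_target")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    stop("response table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0L) stop("response table is empty", call. = FALSE)
  if (!all(data$condition %in% c("short", "long")))
    stop("'condition' must be 'short' or 'long'", call. = FALSE)
  if (any(data$step < 1L))
    stop("'step' indices must be >= 1", call. = FALSE)
  if (any(data$n_target < 0L | data$n_target > data$n_trials))
    stop("'n_target' must lie in [0, n_trials]", call. = FALSE)
  class(data) <- unique(c("response_table", class(data)))
  data
}

#' Binomial log-likelihood of a psychometric function
#'
#' Sum over response-table rows of the log-probability of the observed
#' target-response counts under independent Bernoulli trials with success
#' probability \eqn{\psi(\mathrm{step})}. The binomial coefficient is omitted
#' so the value equals the log product of per-trial Bernoulli probabilities.
#' Observations that contradict a saturated prediction (\eqn{\psi} exactly 0
#' or 1) give `-Inf` rather than an error.
#'
#' @param params a [psychometric_params()].
#' @param data a response table (or subset) with columns `step`, `n_trials`,
#'   `n_target`.
#' @return log-likelihood in nats; `<= 0` whenever at least one trial is
#'   present.
#' @export
log_likelihood <- function(params, data) {
  if (is.null(data) || nrow(data) == 0L)
    stop("response data subset is empty", call. = FALSE)
  psi <- psychometric_value(params, data$step)
  bernoulli_loglik(psi, data$n_target, data$n_trials)
}

# k successes out of n at probability p, log scale, no binomial coefficient;
# 0*log(0) treated as 0 so saturated predictions only fail on contradiction.
bernoulli_loglik <- function(p, k, n) {
  t1 <- ifelse(k == 0, 0, k * log(p))
  t2 <- ifelse(n - k == 0, 0, (n - k) * log1p(-p))
  sum(t1 + t2)
}
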