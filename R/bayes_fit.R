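#' Lapse-rate prior specification
#'
#' Priors for the asymptote parameters of the psychometric function. The
#' `fixed_zero` prior pins both asymptote parameters at zero (the classical
#' two-parameter fit); a `uniform_lapse` prior lets each asymptote parameter
#' vary uniformly on `[0, lapse_upper_bound]`.
#'
#' @param kind `"fixed_zero"` or `"uniform_lapse"`.
#' @param lapse_upper_bound upper bound of the uniform lapse prior (0 for
#'   `fixed_zero`); `2 * lapse_upper_bound` must be < 1.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(kind = c("fixed_zero", "uniform_lapse"),
                       lapse_upper_bound = 0) {
  kind <- match.arg(kind)
  check_scalar(lapse_upper_bound, "lapse_upper_bound", lower = 0, upper = 0.5,
               strict_upper = TRUE)
  if (kind == "fixed_zero" && lapse_upper_bound != 0)
    stop("'fixed_zero' prior must have lapse_upper_bound = 0", call. = FALSE)
  if (kind == "uniform_lapse" && lapse_upper_bound <= 0)
    stop("'uniform_lapse' prior needs a positive lapse_upper_bound", call. = FALSE)
  structure(list(kind = kind, lapse_upper_bound = lapse_upper_bound),
            class = "prior_spec")
}

#' Posterior evaluation grid
#'
#' Rectangular grid over (threshold m, width w, lower asymptote gamma,
#' upper-asymptote offset lambda) on which likelihood x prior is evaluated.
#' The threshold grid spans the stimulus range padded by half the range on
#' each side; the width grid is log-spaced (widths span orders of magnitude,
#' and log spacing resolves steep and shallow functions equally well). The
#' prior places equal mass on every node: uniform over the m grid, uniform in
#' log w over the width grid, and uniform over the asymptote nodes spanning
#' `[0, lapse_upper_bound]` of the prior in use.
#'
#' @param step_range numeric length-2, the stimulus continuum range.
#' @param n_m,n_w nodes for threshold and width.
#' @param n_lapse nodes per asymptote dimension (for `uniform_lapse` priors).
#' @param m_range,w_range optional explicit ranges; defaults derive from
#'   `step_range` as described above.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(step_range = c(1, 7), n_m = 40, n_w = 40, n_lapse = 20,
                      m_range = NULL, w_range = NULL) {
  span <- diff(range(step_range))
  if (span <= 0) stop("'step_range' must have positive width", call. = FALSE)
  if (is.null(m_range))
    m_range <- c(min(step_range) - span / 2, max(step_range) + span / 2)
  if (is.null(w_range)) w_range <- c(0.1, 3 * span)
  structure(list(
    step_range = range(step_range),
    m_nodes = seq(m_range[1], m_range[2], length.out = n_m),
    w_nodes = exp(seq(log(w_range[1]), log(w_range[2]), length.out = n_w)),
    n_lapse = as.integer(n_lapse),
    cache = new.env(parent = emptyenv())
  ), class = "grid_spec")
}

# sigmoid S(x; m, w) tabulated for every (m, w) node at each step; cached in
# the grid object so repeated fits on the same steps reuse it.
sigmoid_table <- function(grid, steps) {
  key <- paste(steps, collapse = ",")
  if (!is.null(grid$cache[[key]])) return(grid$cache[[key]])
  mw <- expand.grid(m = grid$m_nodes, w = grid$w_nodes)
  S <- vapply(steps, function(x)
    stats::plogis(2 * log(19) * (x - mw$m) / mw$w), numeric(nrow(mw)))
  out <- list(S = S, m = mw$m, w = mw$w)
  grid$cache[[key]] <- out
  out
}

# asymptote node pairs implied by a prior: a data.frame of (gamma, lambda)
lapse_nodes <- function(prior, grid, common_lapse = FALSE) {
  if (prior$kind == "fixed_zero")
    return(data.frame(gamma = 0, lambda = 0))
  g <- seq(0, prior$lapse_upper_bound, length.out = grid$n_lapse)
  if (common_lapse) data.frame(gamma = g, lambda = g)
  else expand.grid(gamma = g, lambda = g)
}

#' Fit a psychometric function by grid-based Bayesian inference
#'
#' Evaluates likelihood x prior over the full parameter grid, normalizes, and
#' returns marginal posterior means as point estimates together with marginal
#' 95% credible intervals and the log marginal likelihood (the prior places
#' equal mass on each grid node). With a `fixed_zero` prior only (m, w) are
#' free; with `common_lapse = TRUE` the two asymptote parameters are
#' constrained equal (one common lapse rate), as used during cross-validated
#' prior selection.
#'
#' @param data a response table subset (single subject/condition, one or more
#'   blocks) covering at least two distinct steps.
#' @param prior a [prior_spec()].
#' @param grid a [grid_spec()].
#' @param common_lapse constrain gamma == lambda.
#' @return an object of class `psychometric_fit`: list with `params`
#'   ([psychometric_params()] point estimates), `prior`, `log_marginal_likelihood`,
#'   `posterior` (per-parameter marginal nodes/mass/mean/CI), `qc_flags`, and
#'   the observed endpoint proportions used for reversal checks.
#' @export
fit_bayesian <- function(data, prior, grid, common_lapse = FALSE) {
  stopifnot(inherits(prior, "prior_spec"), inherits(grid, "grid_spec"))
  data <- validate_response_table(data)
  agg <- stats::aggregate(cbind(n_trials, n_target) ~ step, data, sum)
  if (nrow(agg) < 2L)
    stop("need responses at two or more distinct steps", call. = FALSE)

  tab <- sigmoid_table(grid, agg$step)
  pairs <- lapse_nodes(prior, grid, common_lapse)
  n_mw <- nrow(tab$S)
  LL <- matrix(0, n_mw, nrow(pairs))
  k <- agg$n_target
  n <- agg$n_trials
  for (j in seq_len(nrow(pairs))) {
    g <- pairs$gamma[j]
    l <- pairs$lambda[j]
    acc <- numeric(n_mw)
    for (s in seq_along(k)) {
      psi <- g + (1 - g - l) * tab$S[, s]
      if (k[s] > 0) acc <- acc + k[s] * log(psi)
      if (n[s] - k[s] > 0) acc <- acc + (n[s] - k[s]) * log1p(-psi)
    }
    LL[, j] <- acc
  }

  n_nodes <- length(LL)
  log_ml <- logsumexp(LL) - log(n_nodes)
  post <- exp(LL - max(LL))
  post <- post / sum(post)

  w_mw <- rowSums(post)            # marginal over (m, w) nodes
  w_pair <- colSums(post)          # marginal over asymptote pairs
  marg <- list(
    m = collapse_marginal(tab$m, w_mw),
    w = collapse_marginal(tab$w, w_mw),
    gamma = collapse_marginal(pairs$gamma, w_pair),
    lambda = collapse_marginal(pairs$lambda, w_pair)
  )
  est <- psychometric_params(m = marg$m$mean, w = marg$w$mean,
                             gamma = marg$gamma$mean, lambda = marg$lambda$mean)
  # posterior mean of the derived slope itself (Bayes estimate of slope):
  # E[(1 - g - l) ln(19) / (2w)] taken over the full grid posterior
  inv_w <- as.numeric(crossprod(post, 1 / tab$w))     # E[1/w | pair j] * P(j)
  slope_pm <- log(19) / 2 * sum((1 - pairs$gamma - pairs$lambda) * inv_w)

  p_first <- agg$n_target[1] / agg$n_trials[1]
  p_last <- agg$n_target[nrow(agg)] / agg$n_trials[nrow(agg)]
  flags <- character(0)
  if (length(unique(agg$n_target / agg$n_trials)) == 1L)
    flags <- c(flags, "ill_fit")
  if (est$m < grid$step_range[1] || est$m > grid$step_range[2])
    flags <- c(flags, "threshold_out_of_range")

  structure(list(params = est, slope_posterior_mean = slope_pm,
                 prior = prior,
                 log_marginal_likelihood = log_ml,
                 posterior = marg, qc_flags = flags,
                 endpoint_proportions = c(first = p_first, last = p_last),
                 n_trials = sum(agg$n_trials)),
            class = "psychometric_fit")
}

# marginal mean and central 95% credible interval from node values + weights
collapse_marginal <- function(values, weights) {
  agg <- rowsum(weights, values)
  v <- as.numeric(rownames(agg))
  p <- as.numeric(agg)
  mean_v <- sum(v * p)
  cdf <- cumsum(p)
  ci <- c(v[which(cdf >= 0.025)[1]], v[which(cdf >= 0.975)[1]])
  list(nodes = v, mass = p, mean = mean_v, ci = ci)
}

#' @exportS3Method base::print
print.psychometric_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("prior: %s (bound %.2f), log marginal likelihood %.2f\n",
              x$prior$kind, x$prior$lapse_upper_bound,
              x$log_marginal_likelihood))
  if (length(x$qc_flags)) cat("qc flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Quality-control filter for fitted psychometric functions
#'
#' Excludes fits whose estimated threshold lies outside the stimulus range and
#' fits whose observed endpoint proportions run backwards (target-response
#' proportion at the last step below the first step by more than
#' `reversal_margin`, the signature of consistently reversed labeling).
#'
#' @param fits a list of [fit_bayesian()] results (optionally named).
#' @param step_range continuum range for the threshold criterion.
#' @param reversal_margin minimum decrease in endpoint proportions that counts
#'   as reversed labeling.
#' @return list with `included` and `excluded` sublists and a `reasons`
#'   data.frame (`fit`, `reason`) covering every excluded fit.
#' @export
qc_filter <- function(fits, step_range = c(1, 7), reversal_margin = 0.1) {
  if (length(fits) == 0L) stop("'fits' is empty", call. = FALSE)
  ids <- if (is.null(names(fits))) as.character(seq_along(fits)) else names(fits)
  reasons <- data.frame(fit = character(0), reason = character(0))
  keep <- logical(length(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    why <- character(0)
    if (f$params$m < step_range[1] || f$params$m > step_range[2])
      why <- c(why, "threshold_out_of_range")
    ep <- f$endpoint_proportions
    if (ep["last"] < ep["first"] - reversal_margin)
      why <- c(why, "reversed")
    keep[i] <- length(why) == 0L
    if (length(why))
      reasons <- rbind(reasons, data.frame(fit = ids[i], reason = why))
  }
  list(included = fits[keep], excluded = fits[!keep], reasons = reasons)
}
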