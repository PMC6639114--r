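#' Canonical candidate lapse-rate priors
#'
#' The candidate set for prior selection: a prior fixing the lapse rate at
#' zero, then six uniform priors with upper bounds 0.05 to 0.30 in steps of
#' 0.05.
#'
#' @return a named list of seven [prior_spec()] objects.
#' @export
candidate_priors <- function() {
  bounds <- seq(0.05, 0.30, by = 0.05)
  out <- c(list(prior_spec("fixed_zero")),
           lapply(bounds, function(b) prior_spec("uniform_lapse", b)))
  names(out) <- c("fixed_zero", sprintf("uniform_%02d", round(100 * bounds)))
  out
}

prior_id <- function(prior) {
  if (prior$kind == "fixed_zero") "fixed_zero"
  else sprintf("uniform_%02d", round(100 * prior$lapse_upper_bound))
}

# expand an aggregated response-table block into one row per trial
expand_trials <- function(block_data) {
  idx <- rep(seq_len(nrow(block_data)), block_data$n_trials)
  trials <- block_data[idx, c("subject", "condition", "block", "step")]
  trials$response <- unlist(mapply(function(k, n) {
    c(rep(1L, k), rep(0L, n - k))
  }, block_data$n_target, block_data$n_trials, SIMPLIFY = FALSE))
  rownames(trials) <- NULL
  trials
}

# re-aggregate trial rows to response-table counts
aggregate_trials <- function(trials) {
  agg <- stats::aggregate(response ~ subject + condition + block + step,
                          trials, function(r) c(n = length(r), k = sum(r)))
  out <- data.frame(subject = agg$subject, condition = agg$condition,
                    block = agg$block, step = agg$step,
                    n_trials = agg$response[, "n"],
                    n_target = agg$response[, "k"])
  validate_response_table(out)
}

#' Cross-validated held-out likelihood scores for candidate priors
#'
#' For every subject x block and every candidate prior, the block's trials
#' are partitioned into `n_folds` disjoint folds (seeded); the psychometric
#' function is fit to the complement of each fold under the common-lapse
#' constraint (gamma == lambda) and the summed log-likelihood of the held-out
#' trials at the fitted parameters is recorded. Per-subject scores are the
#' medians over block x fold, normalized by subtracting that subject's
#' fixed-zero (two-parameter) median.
#'
#' @param data a response table covering one or more subjects.
#' @param priors list of candidate [prior_spec()]s; must include the
#'   fixed-zero prior, which doubles as the normalization baseline.
#' @param n_folds number of cross-validation folds.
#' @param seed integer seed for fold assignment.
#' @param grid a [grid_spec()]; a coarse grid is adequate here because only
#'   relative held-out likelihood is consumed.
#' @return list of class `prior_score_table` with `scores` (one row per
#'   subject x block x prior x fold: `heldout_ll`), `summary` (one row per
#'   subject x prior: `median_ll`, `normalized`), `n_folds`, `seed`.
#' @export
crossval_prior_score <- function(data, priors = candidate_priors(),
                                 n_folds = 10, seed, grid = grid_spec()) {
  data <- validate_response_table(data)
  check_scalar(n_folds, "n_folds", lower = 2)
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for reproducible folds", call. = FALSE)
  if (!any(vapply(priors, function(p) p$kind == "fixed_zero", logical(1))))
    stop("'priors' must include the fixed_zero baseline", call. = FALSE)

  keys <- unique(data[, c("subject", "condition", "block")])
  rows <- vector("list", nrow(keys) * length(priors) * n_folds)
  ri <- 1L
  for (b in seq_len(nrow(keys))) {
    bd <- merge(data, keys[b, , drop = FALSE])
    trials <- expand_trials(bd)
    if (nrow(trials) < n_folds)
      stop(sprintf("block %s of subject %s has fewer trials (%d) than folds (%d)",
                   keys$block[b], keys$subject[b], nrow(trials), n_folds),
           call. = FALSE)
    fold <- with_seed(seed + b, {
      sample(rep(seq_len(n_folds), length.out = nrow(trials)))
    })
    for (p in seq_along(priors)) {
      for (f in seq_len(n_folds)) {
        train <- aggregate_trials(trials[fold != f, , drop = FALSE])
        heldout <- aggregate_trials(trials[fold == f, , drop = FALSE])
        fit <- fit_bayesian(train, priors[[p]], grid, common_lapse = TRUE)
        rows[[ri]] <- data.frame(
          subject = keys$subject[b], condition = keys$condition[b],
          block = keys$block[b], prior_id = prior_id(priors[[p]]),
          lapse_bound = priors[[p]]$lapse_upper_bound, fold = f,
          heldout_ll = log_likelihood(fit$params, heldout))
        ri <- ri + 1L
      }
    }
  }
  scores <- do.call(rbind, rows)

  med <- stats::aggregate(heldout_ll ~ subject + prior_id + lapse_bound,
                          scores, stats::median)
  names(med)[names(med) == "heldout_ll"] <- "median_ll"
  base <- med[med$prior_id == "fixed_zero", c("subject", "median_ll")]
  names(base)[2] <- "baseline_ll"
  summary <- merge(med, base, by = "subject")
  summary$normalized <- summary$median_ll - summary$baseline_ll
  summary <- summary[order(summary$subject, summary$lapse_bound), ]
  rownames(summary) <- NULL

  structure(list(scores = scores, summary = summary,
                 n_folds = n_folds, seed = seed),
            class = "prior_score_table")
}

#' Select the lapse-rate prior by the one-standard-error rule
#'
#' Computes the across-subject mean and standard error of the normalized
#' held-out score for each candidate prior and returns the most restrictive
#' (smallest-bound) prior whose mean minus one standard error stays above
#' zero. If no prior clears the rule the fixed-zero prior is returned.
#'
#' @param table a `prior_score_table` from [crossval_prior_score()].
#' @param se_over compute the standard error across `"subjects"` (default) or
#'   across `"folds"` (all block x fold scores pooled).
#' @return the selected [prior_spec()], with attribute `rule_table` holding
#'   the per-prior mean, SE and decision.
#' @export
select_prior <- function(table, se_over = c("subjects", "folds")) {
  stopifnot(inherits(table, "prior_score_table"))
  se_over <- match.arg(se_over)
  if (se_over == "subjects") {
    df <- table$summary
    if (length(unique(df$subject)) < 2L)
      stop("standard error across subjects needs at least 2 subjects",
           call. = FALSE)
    value <- df$normalized
    group <- df[, c("prior_id", "lapse_bound")]
  } else {
    sc <- table$scores
    base <- stats::aggregate(heldout_ll ~ subject,
                             sc[sc$prior_id == "fixed_zero", ], stats::median)
    names(base)[2] <- "baseline_ll"
    sc <- merge(sc, base, by = "subject")
    value <- sc$heldout_ll - sc$baseline_ll
    group <- sc[, c("prior_id", "lapse_bound")]
  }
  stat <- stats::aggregate(value, group, function(v)
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v)))
  rule <- data.frame(prior_id = stat$prior_id, lapse_bound = stat$lapse_bound,
                     mean = stat$x[, "mean"], se = stat$x[, "se"],
                     n = stat$x[, "n"])
  rule <- rule[order(rule$lapse_bound), ]
  rule$clears_rule <- rule$lapse_bound > 0 & (rule$mean - rule$se) > 0
  rownames(rule) <- NULL

  winner <- rule[rule$clears_rule, ]
  sel <- if (nrow(winner) == 0L) prior_spec("fixed_zero")
  else prior_spec("uniform_lapse", min(winner$lapse_bound))
  attr(sel, "rule_table") <- rule
  sel
}
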