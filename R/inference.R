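#' Assemble the analysis table
#'
#' Joins per-subject covariates to per-condition psychometric measures and
#' applies the coding conventions used throughout the models: condition is
#' sum-coded (`long` = +0.5, `short` = -0.5, so a positive duration
#' coefficient means steeper/better with the long cue), ADHD is 0/1 treatment
#' coded, and reading group labels follow the score thresholds (dyslexic
#' <= 85, above_average > 100, otherwise below_average).
#'
#' @param measures data.frame with columns `subject`, `condition`, `slope`,
#'   `avg_asymptote`, `pc1` (one row per subject x condition).
#' @param subjects data.frame with columns `subject`, `reading_score`,
#'   `adhd`, `nonverbal_iq` (and optionally `age`, `group`).
#' @return data.frame of analysis rows with numeric `duration` and a `group`
#'   factor.
#' @export
analysis_rows <- function(measures, subjects) {
  need_m <- c("subject", "condition")
  need_s <- c("subject", "reading_score", "adhd", "nonverbal_iq")
  if (!all(need_m %in% names(measures)))
    stop("'measures' needs columns subject, condition", call. = FALSE)
  if (!all(need_s %in% names(subjects)))
    stop("'subjects' needs columns subject, reading_score, adhd, nonverbal_iq",
         call. = FALSE)
  out <- merge(measures, subjects, by = "subject")
  out$duration <- ifelse(out$condition == "long", 0.5, -0.5)
  out$adhd <- as.integer(out$adhd)
  if (is.null(out$group)) out$group <- reading_group(out$reading_score)
  out$group <- factor(out$group,
                      levels = c("above_average", "below_average", "dyslexic"))
  out
}

#' @rdname analysis_rows
#' @param reading_score numeric composite reading scores.
#' @export
reading_group <- function(reading_score) {
  ifelse(reading_score <= 85, "dyslexic",
         ifelse(reading_score > 100, "above_average", "below_average"))
}

#' Fit a linear mixed model for one psychometric measure
#'
#' Gaussian linear mixed model with the requested fixed effects and a random
#' intercept per subject, fit with `lme4::lmer`. ML is used when models will
#' be compared by likelihood ratio; REML for final coefficient reporting.
#'
#' @param outcome name of the outcome column (`"slope"`, `"avg_asymptote"`,
#'   `"pc1"`, ...).
#' @param terms character vector of fixed-effect terms, e.g.
#'   `c("reading_score", "duration", "reading_score:duration")`; may be empty
#'   for an intercept-only model.
#' @param data analysis rows from [analysis_rows()].
#' @param reml logical; REML (TRUE) or ML (FALSE).
#' @return a fitted `lmerMod`.
#' @export
fit_lmm <- function(outcome, terms, data, reml = FALSE) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste0(outcome, " ~ ", rhs, " + (1 | subject)"))
  fixed_fml <- stats::as.formula(paste0(outcome, " ~ ", rhs))
  mm <- stats::model.matrix(fixed_fml, data)
  if (qr(mm)$rank < ncol(mm)) {
    qrm <- qr(mm)
    aliased <- colnames(mm)[qrm$pivot[seq(qrm$rank + 1, ncol(mm))]]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  lme4::lmer(fml, data = data, REML = reml,
             control = lme4::lmerControl(check.conv.singular = "ignore",
                                         calc.derivs = FALSE))
}

# fixed-effect term labels of a fitted lmerMod
fixed_terms <- function(model) {
  attr(stats::terms(stats::formula(model, fixed.only = TRUE)), "term.labels")
}

#' Parametric-bootstrap likelihood-ratio test of nested mixed models
#'
#' Simulates `n_boot` response vectors from the reduced (null) model —
#' Gaussian random intercepts and residuals at the reduced-model ML
#' estimates — refits both models to each, and compares the observed
#' likelihood-ratio statistic to the bootstrap reference distribution:
#' `p = (1 + #\{LR* >= LR_obs\}) / (n_boot + 1)`. Robust to non-normal
#' residual distributions of the original data.
#'
#' @param full,reduced ML-fitted `lmerMod` objects on the same data; the
#'   reduced model's fixed effects must nest within the full model's.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed for the simulations.
#' @return list of class `pb_test`: `statistic` (observed LR), `p_value`,
#'   `n_boot_used` (replicates that refit successfully).
#' @export
pb_term_test <- function(full, reduced, n_boot = 1000, seed) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for the bootstrap", call. = FALSE)
  tf <- fixed_terms(full)
  tr <- fixed_terms(reduced)
  if (!all(tr %in% tf))
    stop("'reduced' is not nested in 'full'", call. = FALSE)
  if (stats::nobs(full) != stats::nobs(reduced))
    stop("models were fitted to different data", call. = FALSE)
  if (lme4::isREML(full) || lme4::isREML(reduced))
    stop("bootstrap LR tests require ML fits (reml = FALSE)", call. = FALSE)

  lr_obs <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                          as.numeric(stats::logLik(reduced))))
  if (identical(sort(tf), sort(tr)))
    return(structure(list(statistic = 0, p_value = 1, n_boot_used = 0L),
                     class = "pb_test"))

  sims <- with_seed(seed, stats::simulate(reduced, nsim = n_boot))
  lr_boot <- vapply(sims, function(y) {
    tryCatch({
      f2 <- suppressWarnings(suppressMessages(lme4::refit(full, y)))
      r2 <- suppressWarnings(suppressMessages(lme4::refit(reduced, y)))
      max(0, 2 * (as.numeric(stats::logLik(f2)) -
                    as.numeric(stats::logLik(r2))))
    }, error = function(e) NA_real_)
  }, numeric(1))
  lr_boot <- lr_boot[!is.na(lr_boot)]
  p <- (1 + sum(lr_boot >= lr_obs)) / (length(lr_boot) + 1)
  structure(list(statistic = lr_obs, p_value = p,
                 n_boot_used = length(lr_boot)), class = "pb_test")
}

#' Backward model selection by parametric-bootstrap term tests
#'
#' Starts from the fully specified model — predictor of interest, duration,
#' their interaction, the ADHD and nonverbal-IQ covariates, and a subject
#' random intercept — and tests terms by parametric-bootstrap likelihood
#' ratio in three stages: first the covariates, then the interaction, then
#' the main terms. A term is retained when its bootstrap p-value is below
#' `alpha` (0.1); retained interactions protect their main effects from
#' removal. Final coefficients are reported from a REML refit of the
#' surviving model.
#'
#' @param outcome outcome column name.
#' @param data analysis rows.
#' @param n_boot bootstrap replicates per term test.
#' @param seed integer seed.
#' @param predictor the continuous or categorical predictor of interest
#'   (`"reading_score"`, or `"group"` for group contrasts).
#' @param covariates covariate terms tested (and usually dropped) first; use
#'   `character(0)` to skip the covariate stage.
#' @param alpha retention threshold on the bootstrap p-value.
#' @return list of class `model_selection`: `model_table` (parameter, beta,
#'   SE, p), `selection_log` (stage, term, p, retained), `final_terms`,
#'   `final_model` (REML `lmerMod`).
#' @export
select_model <- function(outcome, data, n_boot = 1000, seed,
                         predictor = "reading_score",
                         covariates = c("adhd", "nonverbal_iq"),
                         alpha = 0.1) {
  interaction_term <- paste0(predictor, ":duration")
  mains <- c(predictor, "duration")
  terms <- c(mains, interaction_term, covariates)
  log_rows <- list()
  term_p <- c()
  boot_seed <- seed

  test_drop <- function(term, current, stage) {
    full <- fit_lmm(outcome, current, data, reml = FALSE)
    reduced <- fit_lmm(outcome, setdiff(current, term), data, reml = FALSE)
    boot_seed <<- boot_seed + 1L
    pt <- pb_term_test(full, reduced, n_boot = n_boot, seed = boot_seed)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      stage = stage, term = term, p = pt$p_value,
      retained = pt$p_value < alpha)
    term_p[term] <<- pt$p_value
    pt$p_value < alpha
  }

  # stage 1: covariates, each tested against the current full model
  for (cv in covariates) {
    if (!test_drop(cv, terms, "covariates")) terms <- setdiff(terms, cv)
  }
  # stage 2: interaction
  if (!test_drop(interaction_term, terms, "interaction"))
    terms <- setdiff(terms, interaction_term)
  # stage 3: main terms (protected while their interaction is retained)
  if (interaction_term %in% terms) {
    for (m in mains) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        stage = "mains", term = m, p = NA_real_, retained = TRUE)
    }
  } else {
    for (m in mains) {
      if (!test_drop(m, terms, "mains")) terms <- setdiff(terms, m)
    }
  }
  selection_log <- do.call(rbind, log_rows)

  final <- fit_lmm(outcome, terms, data, reml = TRUE)
  coefs <- summary(final)$coefficients
  model_table <- data.frame(
    model = outcome,
    parameter = rownames(coefs),
    beta = coefs[, "Estimate"],
    se = coefs[, "Std. Error"],
    p = NA_real_)
  for (tm in names(term_p)) {
    hit <- which(vapply(model_table$parameter, function(pn)
      pn %in% colnames(stats::model.matrix(
        stats::as.formula(paste("~", tm)), data)), logical(1)) &
        model_table$parameter != "(Intercept)")
    model_table$p[hit] <- term_p[[tm]]
  }
  rownames(model_table) <- NULL

  structure(list(model_table = model_table, selection_log = selection_log,
                 final_terms = terms, final_model = final),
            class = "model_selection")
}

#' Cohen's d with a noncentral-t confidence interval
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' pooled standard deviation
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`, and a 95% interval
#' obtained by inverting the noncentral-t distribution of the two-sample t
#' statistic.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param conf confidence level.
#' @return list of class `effect_size`: `d`, `ci_low`, `ci_high`, `n1`, `n2`.
#' @export
cohens_d <- function(x, y, conf = 0.95) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  d <- (mean(x) - mean(y)) / sp
  scale <- sqrt(n1 * n2 / (n1 + n2))
  t_obs <- d * scale
  df <- n1 + n2 - 2
  a <- (1 - conf) / 2
  ncp_bound <- function(prob) {
    # pt() warns about precision for large noncentrality; harmless here
    f <- function(ncp) suppressWarnings(stats::pt(t_obs, df, ncp)) - prob
    lo <- t_obs - 10 - 10 * abs(t_obs)
    hi <- t_obs + 10 + 10 * abs(t_obs)
    stats::uniroot(f, c(lo, hi), extendInt = "yes")$root
  }
  structure(list(d = d,
                 ci_low = ncp_bound(1 - a) / scale,
                 ci_high = ncp_bound(a) / scale,
                 n1 = n1, n2 = n2),
            class = "effect_size")
}

#' Two-group contrast of a psychometric measure
#'
#' Restricts the analysis rows to the dyslexic and above-average groups,
#' runs the same bootstrap model-selection procedure with group (treatment
#' coded, above-average reference) in place of reading score, and computes
#' Cohen's d for the group separation. For PC1 the per-subject values are
#' averaged across the two duration conditions before computing d; for other
#' measures the per-condition rows are pooled.
#'
#' @param outcome outcome column name.
#' @param data analysis rows (any groups; others are dropped).
#' @param n_boot,seed bootstrap settings.
#' @param average_conditions average the outcome per subject across
#'   conditions before computing d (default TRUE for `"pc1"`).
#' @param covariates covariates for the selection procedure's first stage.
#' @return list with `selection` (a `model_selection`) and `effect_size` (an
#'   `effect_size`), d oriented as above-average minus dyslexic.
#' @export
group_contrast <- function(outcome, data, n_boot = 1000, seed,
                           average_conditions = identical(outcome, "pc1"),
                           covariates = c("adhd", "nonverbal_iq")) {
  d2 <- data[data$group %in% c("dyslexic", "above_average"), , drop = FALSE]
  d2$group <- factor(as.character(d2$group),
                     levels = c("above_average", "dyslexic"))
  counts <- table(unique(d2[, c("subject", "group")])$group)
  if (any(counts < 2))
    stop("each group needs at least 2 subjects", call. = FALSE)

  sel <- select_model(outcome, d2, n_boot = n_boot, seed = seed,
                      predictor = "group", covariates = covariates)

  if (average_conditions) {
    per <- stats::aggregate(d2[[outcome]],
                            list(subject = d2$subject, group = d2$group), mean)
    vals <- stats::setNames(per$x, per$group)
    es <- cohens_d(per$x[per$group == "above_average"],
                   per$x[per$group == "dyslexic"])
  } else {
    es <- cohens_d(d2[[outcome]][d2$group == "above_average"],
                   d2[[outcome]][d2$group == "dyslexic"])
  }
  list(selection = sel, effect_size = es)
}

#' Group comparisons on demographic and cognitive measures
#'
#' Kruskal-Wallis tests across the three reading groups for age and ADHD
#' prevalence, and pairwise two-sided Wilcoxon rank-sum tests (dyslexic vs
#' below-average and dyslexic vs above-average) for every supplied measure,
#' with a Bonferroni significance flag at `alpha / n_comparisons`.
#'
#' @param subjects per-subject table with a `group` column and the measure
#'   columns.
#' @param measures character vector of column names for the pairwise tests.
#' @param n_comparisons Bonferroni family size (the study design compares 24).
#' @param alpha family-wise significance level.
#' @return data.frame with columns `test`, `measure`, `comparison`,
#'   `statistic`, `df`, `p`, `significant_bonferroni`.
#' @export
demographics_tests <- function(subjects,
                               measures = c("reading_score", "nonverbal_iq"),
                               n_comparisons = 24, alpha = 0.05) {
  if (!"group" %in% names(subjects))
    stop("'subjects' needs a 'group' column", call. = FALSE)
  groups <- unique(as.character(subjects$group))
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(subjects$group) == 0L)) stop("empty group", call. = FALSE)
  rows <- list()
  add <- function(test, measure, comparison, statistic, df, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, measure = measure, comparison = comparison,
      statistic = statistic, df = df, p = p,
      significant_bonferroni = p < alpha / n_comparisons)
  }
  for (v in intersect(c("age", "adhd"), names(subjects))) {
    kw <- stats::kruskal.test(subjects[[v]], factor(subjects$group))
    add("kruskal_wallis", v, "all_groups",
        unname(kw$statistic), unname(kw$parameter), kw$p.value)
  }
  pairs <- list(c("dyslexic", "below_average"), c("dyslexic", "above_average"))
  for (v in measures) {
    for (pr in pairs) {
      if (!all(pr %in% groups)) next
      a <- subjects[[v]][subjects$group == pr[1]]
      b <- subjects[[v]][subjects$group == pr[2]]
      wt <- suppressWarnings(stats::wilcox.test(a, b))
      add("wilcoxon_rank_sum", v, paste(pr, collapse = "_vs_"),
          unname(wt$statistic), NA_real_, wt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
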