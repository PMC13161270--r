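#' Pooled two-sample t test from summary statistics
#'
#' Student's independent-samples t with the pooled-variance estimator, plus
#' Cohen's d on the pooled SD and the confidence interval of the mean
#' difference. Works from printed group summaries (n, mean, SD), so published
#' descriptive tables can be re-analyzed directly; [pooled_t_from_data()]
#' wraps raw vectors.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @param conf confidence level for the MD interval.
#' @return one-row tibble: `t`, `df`, `p`, `md`, `ci_lo`, `ci_hi`,
#'   `cohens_d`, `pooled_sd`.
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2, conf = 0.95) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  md <- mean1 - mean2
  se <- sp * sqrt(1 / n1 + 1 / n2)
  if (sp == 0) {
    if (md == 0) { t <- 0; p <- 1; d <- 0 }
    else stop("zero pooled variance with unequal means: degenerate contrast",
              call. = FALSE)
  } else {
    t <- md / se
    p <- 2 * stats::pt(-abs(t), df)
    d <- md / sp
  }
  half <- if (sp == 0) 0 else stats::qt(1 - (1 - conf) / 2, df) * se
  tibble::tibble(t = t, df = df, p = p, md = md,
                 ci_lo = md - half, ci_hi = md + half,
                 cohens_d = d, pooled_sd = sp)
}

#' @rdname pooled_t_test
#' @param x,y raw observations for the two groups.
#' @export
pooled_t_from_data <- function(x, y, conf = 0.95) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  pooled_t_test(mean(x), stats::sd(x), length(x),
                mean(y), stats::sd(y), length(y), conf = conf)
}

#' Sidak family-wise adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for a family of `m` comparisons. Monotone
#' non-decreasing in `m`, equal to the raw p when `m = 1`, never above 1.
#'
#' @param p raw p-value(s).
#' @param m family size (default: `length(p)`).
#' @return adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

#' Fit the study's linear mixed model
#'
#' REML fit of `value ~ group * condition * stage + (1 | participant)` (or any
#' supplied fixed-effect structure) with sum-to-zero contrasts on all factor
#' predictors, so main effects are marginal (ANOVA-style) effects. Random
#' slopes are deliberately not included. A singular fit (zero subject
#' variance) is retained with a warning; if the mixed fit fails outright the
#' function falls back to an ordinary least-squares fit, also with a warning.
#'
#' @param data long-format data frame; the response plus factor columns.
#' @param formula model formula (default
#'   `value ~ group * condition * stage + (1 | participant)`).
#' @return a fitted `lmerModLmerTest` (or `lm` fallback).
#' @export
fit_lmm <- function(data,
                    formula = value ~ group * condition * stage + (1 | participant)) {
  fixed_terms <- all.vars(lme4::nobars(formula))
  for (v in setdiff(fixed_terms, as.character(formula[[2]])))
    if (!is.numeric(data[[v]])) data[[v]] <- factor(data[[v]])
  fac <- names(Filter(is.factor, data))
  contr <- stats::setNames(rep(list("contr.sum"), length(fac)), fac)
  fit <- tryCatch(
    withCallingHandlers(
      lmerTest::lmer(formula, data = data, REML = TRUE,
                     contrasts = contr[intersect(fac, fixed_terms)]),
      message = function(m) invokeRestart("muffleMessage")),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("mixed fit failed (", conditionMessage(fit),
            "); falling back to ordinary least squares", call. = FALSE)
    fixed <- lme4::nobars(formula)
    return(stats::lm(fixed, data = data,
                     contrasts = contr[intersect(fac, all.vars(fixed[[3]]))]))
  }
  if (lme4::isSingular(fit))
    warning("singular mixed fit (near-zero variance component); fit retained",
            call. = FALSE)
  fit
}

#' Mixed-model ANOVA with Satterthwaite degrees of freedom
#'
#' Type III F tests with Satterthwaite denominator df for mixed fits; for the
#' `lm` fallback, classical F tests from `drop1`-style marginal comparisons.
#' On balanced designs with intercept-only random effects the Satterthwaite
#' df reproduce the classical between/within df (e.g. 29 between-subject df
#' for 31 subjects, 87 within df for 31 subjects x 4 cells).
#'
#' @param model a fit from [fit_lmm()].
#' @return tibble `effect`, `F`, `df1`, `df2`, `p`.
#' @export
lmm_anova <- function(model) {
  if (inherits(model, "lmerModLmerTest")) {
    a <- stats::anova(model, type = 3, ddf = "Satterthwaite")
    tibble::tibble(effect = rownames(a), F = a$`F value`,
                   df1 = a$NumDF, df2 = a$DenDF, p = a$`Pr(>F)`)
  } else {
    a <- stats::drop1(model, scope = stats::terms(model), test = "F")
    a <- a[-1, , drop = FALSE]
    tibble::tibble(effect = rownames(a), F = a$`F value`,
                   df1 = a$Df, df2 = stats::df.residual(model), p = a$`Pr(>F)`)
  }
}

#' Satterthwaite test of a single fixed-effect contrast
#'
#' One-degree-of-freedom F (equivalently t) test of `L' beta = 0` with
#' Satterthwaite denominator df, via the model's `contest` machinery.
#'
#' @param model a `lmerModLmerTest` fit.
#' @param L numeric contrast vector over the fixed effects.
#' @return tibble `estimate`, `F`, `df1`, `df2`, `t`, `p`.
#' @export
satterthwaite_contrast <- function(model, L) {
  stopifnot(inherits(model, "lmerModLmerTest"))
  est <- sum(L * lme4::fixef(model))
  ct <- lmerTest::contest(model, L, joint = TRUE)
  tibble::tibble(estimate = est, F = ct$`F value`, df1 = ct$NumDF,
                 df2 = ct$DenDF, t = sign(est) * sqrt(ct$`F value`),
                 p = ct$`Pr(>F)`)
}

#' Sidak-adjusted pairwise estimated marginal means
#'
#' Estimated marginal means of one factor (averaged over the other design
#' factors with equal cell weights), all pairwise differences, Satterthwaite
#' df, Sidak-adjusted p-values (family = the pairwise comparisons of the
#' tested term) and Sidak-adjusted confidence intervals.
#'
#' @param model a fit from [fit_lmm()].
#' @param factor_name factor whose levels are compared (may be an interaction
#'   of factors, e.g. `"condition:stage"`).
#' @param conf confidence level before adjustment.
#' @return tibble `contrast`, `md`, `se`, `df`, `t`, `p_raw`, `p_sidak`,
#'   `ci_lo`, `ci_hi`, `m` (family size).
#' @export
emm_pairwise <- function(model, factor_name, conf = 0.95) {
  spec <- stats::as.formula(paste("~", factor_name))
  emm <- suppressMessages(
    emmeans::emmeans(model, spec, lmer.df = "satterthwaite"))
  prs <- emmeans::contrast(emm, "pairwise", adjust = "none")
  s <- summary(prs, infer = c(FALSE, TRUE), adjust = "none", level = conf)
  m <- nrow(s)
  # Sidak-adjusted CI: per-comparison level whose family coverage equals conf
  ci <- summary(prs, infer = c(TRUE, FALSE), level = conf^(1 / m),
                adjust = "none")
  tibble::tibble(
    contrast = as.character(s$contrast),
    md = s$estimate, se = s$SE, df = s$df, t = s$t.ratio,
    p_raw = s$p.value,
    p_sidak = sidak_adjust(s$p.value, m = m),
    ci_lo = ci$lower.CL, ci_hi = ci$upper.CL, m = m)
}

#' Cohen's d for a mixed-model contrast
#'
#' Standardizes a marginal mean difference by the total model SD, the square
#' root of the sum of all variance components (subject + residual). This
#' total-variance standardizer is one of several conventions for mixed
#' models and is labeled as such wherever it is reported.
#'
#' @param model a fit from [fit_lmm()].
#' @param md mean difference to standardize.
#' @return unitless d (`NA` with a warning if total variance is zero).
#' @export
lmm_cohens_d <- function(model, md) {
  if (inherits(model, "lmerMod")) {
    vc <- as.data.frame(lme4::VarCorr(model))
    total <- sum(vc$vcov)
  } else {
    total <- summary(model)$sigma^2
  }
  if (total <= 0) {
    warning("zero total variance: d undefined", call. = FALSE)
    return(NA_real_)
  }
  md / sqrt(total)
}

#' Run the full study analysis over a cohort
#'
#' Reproduces the study's statistical layer end to end:
#' \itemize{
#'   \item demographics: pooled t tests (age, EHI, state/trait STAI) with
#'     Cohen's d;
#'   \item behavior: Group x Condition x Stage mixed models on the early/late
#'     stage means of hand angle, response time and peak velocity, Adaptation
#'     and Retention conditions only;
#'   \item workload: Group x Condition mixed models on the overall NASA-TLX
#'     score and its task- and behavior-related subscales;
#'   \item EEG: Group x Condition x Stage mixed models on the readiness
#'     potential, negative slope and motor potential component amplitudes;
#'   \item Sidak-adjusted pairwise estimated-marginal-mean contrasts for each
#'     main effect, with total-SD Cohen's d.
#' }
#'
#' @param cohort a `cohort_bundle` carrying trajectories, epochs and TLX data.
#' @param ... thresholds forwarded to [build_trial_table()] / [extract_mrp()].
#' @return list of class `study_results`: `trial_table`, `cleaning_report`,
#'   `mrp`, `rejection`, `tlx`, `demographics`, and `models` — a named list
#'   (per dependent measure) of `anova`, `pairwise`, and the fitted `model`.
#' @export
run_study <- function(cohort, ...) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  groups <- cohort$participants[, c("participant", "group")]

  kin <- build_trial_table(cohort, ...)
  tt <- kin$trial_table

  demo <- dplyr::bind_rows(lapply(
    c(age = "age", handedness = "ehi", stai_state = "stai_state",
      stai_trait = "stai_trait"),
    function(v) {
      a <- cohort$participants[[v]][cohort$participants$group == "anxiety"]
      c0 <- cohort$participants[[v]][cohort$participants$group == "control"]
      tryCatch(pooled_t_from_data(a, c0), error = function(e) {
        # zero-spread groups with unequal means: report the MD, flag the test
        tibble::tibble(t = NA_real_, df = length(a) + length(c0) - 2,
                       p = NA_real_, md = mean(a) - mean(c0),
                       ci_lo = NA_real_, ci_hi = NA_real_,
                       cohens_d = NA_real_, pooled_sd = 0)
      })
    }), .id = "measure")

  behav_measures <- c(hand_angle = "hand_theta",
                      response_time = "response_time",
                      peak_velocity = "peak_velocity")
  models <- list()
  for (nm in names(behav_measures)) {
    ss <- stage_summary(tt[tt$condition %in% c("adaptation", "retention"), ],
                        behav_measures[[nm]])
    ss <- dplyr::inner_join(ss, groups, by = "participant")
    ss$value <- ss$mean
    models[[nm]] <- fit_measure(ss, c("group", "condition", "stage"))
  }

  mrp_tbl <- NULL; rejection <- NULL
  if (length(cohort$epochs)) {
    mrp_tbl <- dplyr::bind_rows(lapply(cohort$epochs, extract_mrp))
    mrp_tbl <- dplyr::inner_join(mrp_tbl, groups, by = "participant")
    rej <- lapply(cohort$epochs, function(ep) {
      ep2 <- reject_trials(baseline_correct(ep))
      dplyr::bind_cols(tibble::tibble(participant = ep$participant,
                                      condition = ep$condition),
                       attr(ep2, "rejection"))
    })
    rej <- dplyr::bind_rows(rej)
    rejection <- dplyr::summarise(
      dplyr::group_by(rej, condition),
      n_total = n_total[1],
      mean_rejected = mean(n_rejected),
      retained_pct = retained_percentage(n_total[1], mean(n_rejected)),
      .groups = "drop")
    for (comp in c("rp", "ns", "mp")) {
      d <- mrp_tbl
      d$value <- d[[paste0(comp, "_mean")]]
      models[[comp]] <- fit_measure(d, c("group", "condition", "stage"))
    }
  }

  tlx_scored <- NULL
  if (!is.null(cohort$tlx)) {
    tlx_scored <- dplyr::inner_join(score_tlx(cohort$tlx), groups,
                                    by = "participant")
    for (sc in c("overall", "task_related", "behavior_related")) {
      d <- tlx_scored
      d$value <- d[[sc]]
      models[[paste0("tlx_", sc)]] <-
        fit_measure(d, c("group", "condition"),
                    formula = value ~ group * condition + (1 | participant))
    }
  }

  structure(list(trial_table = tt, cleaning_report = kin$cleaning_report,
                 mrp = mrp_tbl, rejection = rejection, tlx = tlx_scored,
                 demographics = demo, models = models),
            class = "study_results")
}

fit_measure <- function(data, factors,
                        formula = value ~ group * condition * stage + (1 | participant)) {
  model <- suppressWarnings(fit_lmm(data, formula))
  an <- lmm_anova(model)
  if (all(c("condition", "stage") %in% factors))
    factors <- c(factors, "condition:stage")
  pw <- lapply(stats::setNames(factors, factors), function(f) {
    out <- tryCatch(emm_pairwise(model, f), error = function(e) NULL)
    if (!is.null(out))
      out$cohens_d <- vapply(out$md, function(m)
        suppressWarnings(lmm_cohens_d(model, m)), numeric(1))
    out
  })
  list(model = model, anova = an, pairwise = dplyr::bind_rows(pw, .id = "factor"))
}

#' @export
print.study_results <- function(x, ...) {
  cat("<study_results>\n")
  cat(sprintf("  trial table: %d rows; models: %s\n",
              nrow(x$trial_table), paste(names(x$models), collapse = ", ")))
  if (!is.null(x$rejection)) {
    for (i in seq_len(nrow(x$rejection)))
      cat(sprintf("  %s: mean %.2f of %d trials rejected, %.2f%% retained\n",
                  x$rejection$condition[i], x$rejection$mean_rejected[i],
                  x$rejection$n_total[i], x$rejection$retained_pct[i]))
  }
  invisible(x)
}

utils::globalVariables(c("n_rejected", "n_total"))
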