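#' Compare practice effects between groups
#'
#' For each test (and the composite), fits an ordinary least-squares model
#' with the oriented SRB z-score as outcome and group (PD = 1, HC = 0),
#' age, sex and education as predictors. The group coefficient estimates
#' the mean PD shortfall in practice effects in residual-SD units, after
#' demographic adjustment.
#'
#' @param scores Score table from \code{\link{score_battery}} (must
#'   contain both groups).
#' @param tests Tests to analyze; defaults to every \code{z_} column plus
#'   the composite.
#' @return Data frame with one row per analyzed score: \code{test},
#'   \code{beta_group}, \code{se}, \code{p}, \code{n}; rows where a group
#'   is absent among complete cases carry \code{NA} estimates. A
#'   \code{q} column is left for \code{\link{fdr_adjust}} at the family
#'   level.
#' @export
compare_groups <- function(scores, tests = NULL) {
  if (is.null(tests)) {
    tests <- c(sub("^z_", "", grep("^z_", names(scores), value = TRUE)),
               "composite")
  }
  if (length(unique(scores$group)) < 2L) {
    stop("both groups must be present in the score table", call. = FALSE)
  }
  rows <- lapply(tests, function(t) {
    col <- if (t == "composite") "composite" else paste0("z_", t)
    d <- data.frame(z = scores[[col]],
                    group = as.integer(scores$group == "PD"),
                    age = scores$age, sex = scores$sex,
                    education = scores$education)
    d <- d[stats::complete.cases(d), ]
    na_row <- data.frame(test = t, beta_group = NA_real_, se = NA_real_,
                         p = NA_real_, n = nrow(d))
    if (nrow(d) < 6L || length(unique(d$group)) < 2L) return(na_row)
    if (stats::var(d$z) == 0) {
      # Constant outcome: every coefficient is exactly zero.
      return(data.frame(test = t, beta_group = 0, se = 0, p = NA_real_,
                        n = nrow(d)))
    }
    fit <- stats::lm(z ~ group + age + sex + education, data = d)
    sm <- summary(fit)$coefficients
    if (!"group" %in% rownames(sm)) return(na_row)
    data.frame(test = t, beta_group = sm["group", 1], se = sm["group", 2],
               p = sm["group", 4], n = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chi-square test of the change-category distribution
#'
#' Pearson goodness-of-fit test of the PD decline / no-change /
#' improvement counts against expected counts formed from a reference
#' distribution: either the observed HC category proportions
#' (\code{mode = "hc"}) or the theoretical standard-normal tail
#' proportions 0.05 / 0.90 / 0.05 (\code{mode = "theoretical"}). In HC
#' mode, a reference category with zero proportion but a non-zero PD
#' observation makes the statistic undefined; the result is flagged
#' not-computable and the caller may fall back to the theoretical mode.
#'
#' @param pd_counts Integer vector of PD counts, in category order
#'   (decline, no_change, improvement).
#' @param hc_counts Reference HC counts (required for \code{mode = "hc"}).
#' @param mode Reference distribution.
#' @return List of class \code{"chisq_change"}: \code{statistic},
#'   \code{df}, \code{p}, \code{observed}, \code{expected}, \code{mode},
#'   \code{computable}, \code{note}.
#' @export
chisq_change <- function(pd_counts, hc_counts = NULL,
                         mode = c("hc", "theoretical")) {
  mode <- match.arg(mode)
  pd_counts <- as.numeric(pd_counts)
  if (any(pd_counts < 0) || sum(pd_counts) <= 0) {
    stop("PD counts must be non-negative with a positive total",
         call. = FALSE)
  }
  if (mode == "hc") {
    if (is.null(hc_counts)) {
      stop("hc_counts required for HC-reference mode", call. = FALSE)
    }
    ref <- as.numeric(hc_counts) / sum(hc_counts)
  } else {
    ref <- c(0.05, 0.90, 0.05)
  }
  n <- sum(pd_counts)
  expected <- n * ref
  if (any(ref == 0 & pd_counts > 0)) {
    return(structure(list(statistic = NA_real_, df = NA_integer_,
                          p = NA_real_, observed = pd_counts,
                          expected = expected, mode = mode,
                          computable = FALSE,
                          note = paste("reference category with zero",
                                       "proportion observed in PD; use",
                                       "theoretical mode")),
                     class = "chisq_change"))
  }
  # Categories empty in both observed and expected contribute nothing and
  # do not count toward the degrees of freedom.
  keep <- !(ref == 0 & pd_counts == 0)
  stat <- sum((pd_counts[keep] - expected[keep])^2 / expected[keep])
  df <- sum(keep) - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p = p, observed = pd_counts,
                 expected = expected, mode = mode, computable = TRUE,
                 note = NA_character_),
            class = "chisq_change")
}

#' @export
print.chisq_change <- function(x, ...) {
  if (!x$computable) {
    cat("Change-category chi-square: not computable (", x$note, ")\n")
  } else {
    cat(sprintf("Change-category chi-square: X2 = %.3f, df = %d, p = %.4g (%s reference)\n",
                x$statistic, x$df, x$p, x$mode))
  }
  invisible(x)
}

#' Mean-center a predictor
#'
#' Subtracts the sample mean (of the non-missing values) when enabled.
#' Centering is the standard remedy when a martingale-residual check
#' suggests non-linearity; the Cox hazard ratio for the predictor is
#' invariant to this location shift.
#'
#' @param z Numeric vector.
#' @param enabled Apply centering? (default \code{TRUE}).
#' @return Centered (or unchanged) vector.
#' @export
center_predictor <- function(z, enabled = TRUE) {
  if (!enabled) return(z)
  z - mean(z, na.rm = TRUE)
}

#' Cox proportional-hazards prognosis model
#'
#' Fits the partial-likelihood Cox model for time to CI or PDD within the
#' PD group, with the oriented SRB z-score (one test or the composite) as
#' the predictor of interest and age and sex as covariates. The hazard
#' ratio is per 1-unit increase in z, so HR < 1 means smaller practice
#' effects carry higher risk. Ties use the Efron approximation (annual
#' visit months produce heavy ties). Wald 95\% confidence bounds are
#' reported. Models with fewer than two events among complete cases, or a
#' constant predictor, are flagged not-estimable instead of failing.
#'
#' @param outcomes Outcome table from \code{\link{derive_event_times}}.
#' @param scores Score table from \code{\link{score_battery}} restricted
#'   to the same subjects (matched on \code{subject_id}).
#' @param predictor \code{"composite"} or a test name.
#' @param outcome_type \code{"CI"} or \code{"PDD"}.
#' @param center Mean-center the predictor before fitting (the HR is
#'   invariant; centering aids the linearity diagnostic).
#' @return List of class \code{"cox_result"}: \code{outcome},
#'   \code{predictor}, \code{hr}, \code{ci_low}, \code{ci_high}, \code{p},
#'   \code{ph_test_p}, \code{n}, \code{n_events}, \code{estimable},
#'   \code{reason}, \code{centered}, and \code{fit} (the underlying
#'   \code{coxph} object when estimable).
#' @export
fit_cox <- function(outcomes, scores, predictor = "composite",
                    outcome_type = c("CI", "PDD"), center = FALSE) {
  outcome_type <- match.arg(outcome_type)
  col <- if (predictor == "composite") "composite"
         else paste0("z_", predictor)
  if (!col %in% names(scores)) {
    stop("score table has no column for predictor '", predictor, "'",
         call. = FALSE)
  }
  m <- match(outcomes$subject_id, scores$subject_id)
  d <- data.frame(
    time = if (outcome_type == "CI") outcomes$ci_time else outcomes$pdd_time,
    event = if (outcome_type == "CI") outcomes$ci_event
            else outcomes$pdd_event,
    z = scores[[col]][m], age = scores$age[m], sex = scores$sex[m]
  )
  d <- d[stats::complete.cases(d), ]
  base <- list(outcome = outcome_type, predictor = predictor,
               hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               p = NA_real_, ph_test_p = NA_real_, n = nrow(d),
               n_events = sum(d$event), estimable = FALSE,
               reason = NA_character_, centered = center, fit = NULL)
  if (sum(d$event) < 2L) {
    base$reason <- "no_events"
    return(structure(base, class = "cox_result"))
  }
  if (stats::var(d$z) == 0) {
    base$reason <- "constant_predictor"
    return(structure(base, class = "cox_result"))
  }
  d$z <- center_predictor(d$z, center)
  fit <- survival::coxph(survival::Surv(time, event) ~ z + age + sex,
                         data = d, ties = "efron")
  sm <- summary(fit)
  base$hr <- unname(sm$conf.int["z", "exp(coef)"])
  base$ci_low <- unname(sm$conf.int["z", "lower .95"])
  base$ci_high <- unname(sm$conf.int["z", "upper .95"])
  base$p <- unname(sm$coefficients["z", "Pr(>|z|)"])
  base$estimable <- TRUE
  base$fit <- fit
  base$ph_test_p <- check_ph_assumption(structure(base,
                                                  class = "cox_result"))
  structure(base, class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("Cox model (%s ~ %s): not estimable (%s)\n",
                x$outcome, x$predictor, x$reason))
  } else {
    cat(sprintf(
      "Cox model (%s ~ %s): HR = %.2f (95%% CI %.2f-%.2f), p = %.4g, events = %d\n",
      x$outcome, x$predictor, x$hr, x$ci_low, x$ci_high, x$p, x$n_events))
  }
  invisible(x)
}

#' Schoenfeld-residual check of the proportional-hazards assumption
#'
#' Global test based on scaled Schoenfeld residuals
#' (\code{survival::cox.zph}); a small p indicates a time-varying effect.
#' Skipped (returns \code{NA}) for non-estimable models or fewer than two
#' events.
#'
#' @param result A \code{cox_result} from \code{\link{fit_cox}}.
#' @return Global test p-value, or \code{NA} when skipped.
#' @export
check_ph_assumption <- function(result) {
  if (is.null(result$fit) || result$n_events < 2L) return(NA_real_)
  zp <- tryCatch(survival::cox.zph(result$fit), error = function(e) NULL)
  if (is.null(zp)) return(NA_real_)
  unname(zp$table["GLOBAL", "p"])
}

#' Martingale-residual linearity check
#'
#' Tests whether the martingale residuals of a null Cox model carry
#' curvature in the predictor by regressing them on the predictor and its
#' square; the p-value of the quadratic term flags non-linearity, the
#' standard trigger for mean-centering.
#'
#' @param result An estimable \code{cox_result}.
#' @return p-value of the quadratic term, or \code{NA} when unavailable.
#' @export
check_linearity <- function(result) {
  if (is.null(result$fit)) return(NA_real_)
  fit <- result$fit
  mf <- stats::model.frame(fit)
  res <- stats::residuals(fit, type = "martingale")
  z <- mf$z
  if (stats::var(z) == 0) return(NA_real_)
  lf <- stats::lm(res ~ z + I(z^2))
  sm <- summary(lf)$coefficients
  if (nrow(sm) < 3L) return(NA_real_)
  unname(sm[3, 4])
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment applied to one flat array of p-values (one family),
#' e.g. all linear and Cox p-values of the CI analyses pooled together.
#'
#' @param p Numeric vector of p-values in [0, 1] (\code{NA} allowed and
#'   preserved).
#' @return Vector of q-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Cumulative incidence by median split of the practice-effect score
#'
#' Splits subjects into low and high practice-effect halves at the median
#' oriented z (ties assigned to the low half), fits Kaplan-Meier survival
#' per half and returns the reversed curves, 1 - S(t), i.e. the cumulative
#' proportion having developed the outcome. Intended for visualization
#' only; inference comes from the Cox models.
#'
#' @param outcomes Outcome table from \code{\link{derive_event_times}}.
#' @param scores Score table (matched on \code{subject_id}).
#' @param predictor \code{"composite"} or a test name.
#' @param outcome_type \code{"CI"} or \code{"PDD"}.
#' @return Data frame of curve coordinates: \code{half} (\code{"low"} /
#'   \code{"high"}), \code{time}, \code{cum_incidence}, \code{n_risk}.
#'   With a constant predictor a single \code{"all"} curve is returned
#'   with a warning.
#' @export
cumulative_incidence_by_split <- function(outcomes, scores,
                                          predictor = "composite",
                                          outcome_type = c("CI", "PDD")) {
  outcome_type <- match.arg(outcome_type)
  col <- if (predictor == "composite") "composite"
         else paste0("z_", predictor)
  m <- match(outcomes$subject_id, scores$subject_id)
  d <- data.frame(
    time = if (outcome_type == "CI") outcomes$ci_time else outcomes$pdd_time,
    event = if (outcome_type == "CI") outcomes$ci_event
            else outcomes$pdd_event,
    z = scores[[col]][m]
  )
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) == 0L) {
    return(data.frame(half = character(0), time = numeric(0),
                      cum_incidence = numeric(0), n_risk = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (stats::var(d$z) == 0) {
    warning("constant predictor: returning a single overall curve",
            call. = FALSE)
    d$half <- "all"
  } else {
    med <- stats::median(d$z)
    d$half <- ifelse(d$z <= med, "low", "high")
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ half, data = d)
  strata <- if (is.null(sf$strata)) {
    rep(unique(d$half), length(sf$time))
  } else {
    rep(sub("^half=", "", names(sf$strata)), sf$strata)
  }
  data.frame(half = strata, time = sf$time,
             cum_incidence = 1 - sf$surv, n_risk = sf$n.risk,
             stringsAsFactors = FALSE)
}

#' Run the full inferential battery on a scored cohort
#'
#' Convenience wrapper reproducing the analysis sequence: group
#' comparisons per test and composite; change-category chi-square tests
#' per test (HC reference with automatic fallback to the theoretical
#' normal proportions when an HC category is empty); Cox models for CI
#' and PDD per test and composite, with Schoenfeld and linearity
#' diagnostics and automatic mean-centering when the linearity check
#' fails; and per-family FDR over the pooled linear and Cox p-values (one
#' family for CI, one for PDD).
#'
#' @param scores Score table (both groups).
#' @param outcomes Outcome table for the PD subjects.
#' @param alpha Significance threshold used only for the linearity
#'   centering trigger (default 0.05).
#' @return List with data frames \code{group_comparisons} (with \code{q}),
#'   \code{chisq} and \code{cox} (with \code{q}).
#' @export
run_inference <- function(scores, outcomes, alpha = 0.05) {
  tests <- sub("^z_", "", grep("^z_", names(scores), value = TRUE))
  gc <- compare_groups(scores, tests = c(tests, "composite"))

  chi_rows <- lapply(tests, function(t) {
    cat_col <- paste0("cat_", t)
    pd <- table(scores[[cat_col]][scores$group == "PD"])
    hc <- table(scores[[cat_col]][scores$group == "HC"])
    res <- chisq_change(as.integer(pd), as.integer(hc), mode = "hc")
    used <- "hc"
    if (!res$computable) {
      res <- chisq_change(as.integer(pd), mode = "theoretical")
      used <- "theoretical_fallback"
    }
    data.frame(test = t, statistic = res$statistic, df = res$df,
               p = res$p, reference = used,
               pd_decline = pd[["decline"]],
               pd_no_change = pd[["no_change"]],
               pd_improvement = pd[["improvement"]])
  })
  chi <- do.call(rbind, chi_rows)
  rownames(chi) <- NULL

  pd_scores <- scores[scores$group == "PD", , drop = FALSE]
  cox_rows <- list()
  for (ot in c("CI", "PDD")) {
    for (pr in c("composite", tests)) {
      fit <- fit_cox(outcomes, pd_scores, predictor = pr,
                     outcome_type = ot, center = FALSE)
      if (fit$estimable) {
        lin_p <- check_linearity(fit)
        if (!is.na(lin_p) && lin_p < alpha) {
          fit <- fit_cox(outcomes, pd_scores, predictor = pr,
                         outcome_type = ot, center = TRUE)
        }
      }
      cox_rows[[length(cox_rows) + 1L]] <- data.frame(
        outcome = ot, predictor = pr, hr = fit$hr, ci_low = fit$ci_low,
        ci_high = fit$ci_high, p = fit$p, ph_test_p = fit$ph_test_p,
        n = fit$n, n_events = fit$n_events, estimable = fit$estimable,
        reason = if (is.na(fit$reason)) "" else fit$reason,
        centered = fit$centered)
    }
  }
  cox <- do.call(rbind, cox_rows)
  rownames(cox) <- NULL

  # One FDR family per outcome, each pooling the linear group-comparison
  # p-values with that outcome's Cox p-values in a single flat array. The
  # linear q-values reported come from the CI family.
  gc$q <- NA_real_
  cox$q <- NA_real_
  for (ot in c("CI", "PDD")) {
    cox_idx <- which(cox$outcome == ot)
    pool <- c(gc$p, cox$p[cox_idx])
    q <- fdr_adjust(pool)
    if (ot == "CI") gc$q <- q[seq_len(nrow(gc))]
    cox$q[cox_idx] <- q[-seq_len(nrow(gc))]
  }
  list(group_comparisons = gc, chisq = chi, cox = cox)
}
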