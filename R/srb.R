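#' Fit a normative SRB prediction equation for one test
#'
#' Fits the standardized regression-based (SRB) change-score model for a
#' single test: ordinary least squares predicting the one-year follow-up
#' score from the baseline score, age, sex, education and retest interval,
#' using normative (healthy control) data only. The fitted constant, beta
#' weights and residual standard deviation are the reusable normative
#' artifact; they are later applied to any subject to obtain an SRB
#' z-score.
#'
#' The residual standard deviation uses the unbiased denominator
#' \code{n - 6} (six estimated parameters). Complete cases for this test's
#' baseline/follow-up pair and the five predictors are used; subjects
#' missing this test still contribute to other tests' models.
#'
#' @param paired Per-subject paired table as returned by
#'   \code{\link{pair_battery}}: columns \code{<test>_baseline},
#'   \code{<test>_followup}, \code{age}, \code{sex} (0 = female,
#'   1 = male), \code{education} (years), \code{retest_interval} (months).
#' @param test Test identifier (see \code{\link{battery_tests}}).
#' @return An object of class \code{"srb_model"}: list with \code{test},
#'   \code{intercept}, \code{coefficients} (baseline, age, sex, education,
#'   retest_interval), \code{residual_sd}, \code{n_fit}, \code{df_resid}.
#' @seealso \code{\link{apply_srb}}, \code{\link{fit_srb_battery}}
#' @export
fit_srb_model <- function(paired, test) {
  spec <- test_spec(test)
  b_col <- paste0(test, "_baseline")
  f_col <- paste0(test, "_followup")
  need <- c(b_col, f_col, "age", "sex", "education", "retest_interval")
  miss <- setdiff(need, names(paired))
  if (length(miss)) {
    stop("paired table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- paired[stats::complete.cases(paired[, need]), need]
  n <- nrow(d)
  if (n < 8L) {
    stop("too few complete normative rows for ", test, ": ", n,
         " (need at least 8)", call. = FALSE)
  }
  names(d)[1:2] <- c("baseline", "followup")
  fit <- stats::lm(followup ~ baseline + age + sex + education +
                     retest_interval, data = d)
  if (fit$rank < 6L) {
    stop("rank-deficient design for ", test,
         ": predictors are collinear (rank ", fit$rank, " of 6)",
         call. = FALSE)
  }
  df_resid <- n - 6L
  rss <- sum(stats::residuals(fit)^2)
  residual_sd <- sqrt(rss / df_resid)
  cf <- stats::coef(fit)
  # Perfect fit means the follow-up score is an exact linear function of
  # the predictors; the z-score would divide by zero.
  if (residual_sd < 1e-10 * max(1, stats::sd(d$followup))) {
    stop("degenerate SRB fit for ", test,
         ": residual SD is zero (intercept ", format(cf[[1]]),
         ", baseline coefficient ", format(cf[["baseline"]]), ")",
         call. = FALSE)
  }
  structure(list(
    test = test,
    direction = spec$direction,
    intercept = unname(cf[1]),
    coefficients = c(baseline = unname(cf[["baseline"]]),
                     age = unname(cf[["age"]]),
                     sex = unname(cf[["sex"]]),
                     education = unname(cf[["education"]]),
                     retest_interval = unname(cf[["retest_interval"]])),
    residual_sd = residual_sd,
    n_fit = n,
    df_resid = df_resid
  ), class = "srb_model")
}

#' @export
print.srb_model <- function(x, ...) {
  cat("SRB normative model for", x$test, "\n")
  cat("  n =", x$n_fit, " residual SD =", format(x$residual_sd, digits = 4),
      "\n")
  cat("  intercept:", format(x$intercept, digits = 4), "\n")
  for (nm in names(x$coefficients)) {
    cat("  ", nm, ":", format(x$coefficients[[nm]], digits = 4), "\n")
  }
  invisible(x)
}

#' Fit SRB models for every battery test
#'
#' @param paired Paired table of normative (HC) subjects.
#' @param tests Tests to fit; defaults to the full battery.
#' @return Named list of \code{srb_model} objects, class
#'   \code{"srb_battery"}. Tests whose normative sample is too small are
#'   dropped with a warning rather than failing the whole battery.
#' @export
fit_srb_battery <- function(paired, tests = battery_tests()) {
  models <- list()
  for (t in tests) {
    m <- tryCatch(fit_srb_model(paired, t), error = function(e) e)
    if (inherits(m, "error")) {
      warning("skipping ", t, ": ", conditionMessage(m), call. = FALSE)
    } else {
      models[[t]] <- m
    }
  }
  structure(models, class = "srb_battery")
}

#' Apply a fitted SRB model to obtain raw z-scores
#'
#' Computes, for each subject, the difference between the observed and the
#' model-predicted one-year follow-up score, divided by the normative
#' residual standard deviation. Applies identically to normative and
#' patient records. Subjects missing the observed follow-up or any
#' predictor get \code{NA} (excluded from this test only).
#'
#' @param model An \code{srb_model}.
#' @param paired Paired table (any group).
#' @return Numeric vector of raw (unoriented) SRB z-scores, one per row.
#' @export
apply_srb <- function(model, paired) {
  stopifnot(inherits(model, "srb_model"))
  b <- paired[[paste0(model$test, "_baseline")]]
  f <- paired[[paste0(model$test, "_followup")]]
  if (is.null(b) || is.null(f)) {
    stop("paired table lacks score columns for ", model$test, call. = FALSE)
  }
  cf <- model$coefficients
  pred <- model$intercept + cf[["baseline"]] * b + cf[["age"]] * paired$age +
    cf[["sex"]] * paired$sex + cf[["education"]] * paired$education +
    cf[["retest_interval"]] * paired$retest_interval
  (f - pred) / model$residual_sd
}

#' Orient an SRB z-score so that positive means better-than-expected
#'
#' Raw SRB z-scores for timed tests (TMT-A, TMT-B, where lower scores are
#' better) have their sign reversed so that across the whole battery a
#' positive z means a larger-than-expected practice effect and a negative
#' z a smaller one.
#'
#' @param z_raw Numeric vector of raw SRB z-scores.
#' @param test Test identifier.
#' @return Oriented z-scores.
#' @export
orient_z <- function(z_raw, test) {
  spec <- test_spec(test)
  if (spec$direction == "lower_is_better") -z_raw else z_raw
}

#' Trichotomize oriented SRB z-scores into change categories
#'
#' Classifies each oriented z against the 5\% tails of the standard
#' normal: decline if \code{z <= -1.645}, improvement if
#' \code{z >= 1.645}, otherwise no change. The closed symmetric 90\%
#' central band makes the partition exhaustive; the cut point is
#' configurable.
#'
#' @param z Numeric vector of oriented SRB z-scores (finite or \code{NA}).
#' @param cut Positive cut point, default \code{1.645}.
#' @return Factor with levels \code{decline}, \code{no_change},
#'   \code{improvement}; \code{NA} propagates.
#' @export
trichotomize <- function(z, cut = 1.645) {
  stopifnot(is.numeric(z), length(cut) == 1L, cut > 0)
  if (any(is.infinite(z) | is.nan(z), na.rm = TRUE)) {
    stop("non-finite z-score supplied to trichotomize()", call. = FALSE)
  }
  out <- ifelse(z <= -cut, "decline",
                ifelse(z >= cut, "improvement", "no_change"))
  factor(out, levels = c("decline", "no_change", "improvement"))
}

#' Composite practice-effect score
#'
#' Arithmetic mean of the available oriented SRB z-scores over the six
#' composite members (LNST, SDMT, SFT, JoLO, HVLT-R immediate, HVLT-R
#' delayed). BNT and the TMT pair never contribute. Subjects with fewer
#' than \code{min_tests} available members get \code{NA}.
#'
#' @param z Data frame or matrix of oriented z-scores with columns named
#'   by test (extra columns are ignored).
#' @param min_tests Minimum number of composite members required
#'   (default 4).
#' @return Numeric vector of composite z-scores, one per row.
#' @export
composite_srb <- function(z, min_tests = 4L) {
  members <- battery_specs()$test[battery_specs()$composite_member]
  have <- intersect(members, colnames(z))
  zm <- as.matrix(as.data.frame(z)[, have, drop = FALSE])
  n_avail <- rowSums(!is.na(zm))
  comp <- rowMeans(zm, na.rm = TRUE)
  comp[n_avail < min_tests] <- NA_real_
  comp[is.nan(comp)] <- NA_real_
  comp
}

#' Score a cohort against fitted SRB norms
#'
#' Applies every fitted normative model to a paired table, orients the
#' z-scores, assigns change categories and computes the composite.
#'
#' @param models An \code{srb_battery} (named list of \code{srb_model}).
#' @param paired Paired table (HC and/or PD rows).
#' @param min_tests Minimum composite members, passed to
#'   \code{\link{composite_srb}}.
#' @param cut Trichotomization cut point.
#' @return Data frame with one row per subject: identifying columns
#'   (\code{subject_id}, \code{group}, \code{age}, \code{sex},
#'   \code{education}), one \code{z_<test>} and \code{cat_<test>} column
#'   per fitted test (oriented z), and \code{composite}.
#' @export
score_battery <- function(models, paired, min_tests = 4L, cut = 1.645) {
  stopifnot(inherits(models, "srb_battery"))
  id_cols <- intersect(c("subject_id", "group", "age", "sex", "education"),
                       names(paired))
  out <- paired[, id_cols, drop = FALSE]
  zmat <- matrix(NA_real_, nrow(paired), length(models),
                 dimnames = list(NULL, names(models)))
  for (t in names(models)) {
    zmat[, t] <- orient_z(apply_srb(models[[t]], paired), t)
  }
  for (t in colnames(zmat)) {
    out[[paste0("z_", t)]] <- zmat[, t]
    out[[paste0("cat_", t)]] <- trichotomize(zmat[, t], cut = cut)
  }
  out$composite <- composite_srb(zmat, min_tests = min_tests)
  out
}

#' Serialize fitted SRB models to JSON
#'
#' Normative equations are the reusable artifact of the scoring stage;
#' they are written with full-precision floats so a reloaded model
#' reproduces z-scores bit-exactly.
#'
#' @param models An \code{srb_battery}.
#' @param path File to write.
#' @return \code{path}, invisibly.
#' @export
write_srb_models <- function(models, path) {
  stopifnot(inherits(models, "srb_battery"))
  payload <- lapply(unclass(models), function(m) {
    list(test = m$test, direction = m$direction, intercept = m$intercept,
         coefficients = as.list(m$coefficients),
         residual_sd = m$residual_sd, n_fit = m$n_fit,
         df_resid = m$df_resid)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read SRB models back from JSON
#'
#' @param path File written by \code{\link{write_srb_models}}.
#' @return An \code{srb_battery}.
#' @export
read_srb_models <- function(path) {
  payload <- jsonlite::read_json(path)
  models <- lapply(payload, function(m) {
    structure(list(
      test = m$test, direction = m$direction, intercept = m$intercept,
      coefficients = unlist(m$coefficients),
      residual_sd = m$residual_sd, n_fit = as.integer(m$n_fit),
      df_resid = as.integer(m$df_resid)
    ), class = "srb_model")
  })
  names(models) <- vapply(models, `[[`, "", "test")
  structure(models, class = "srb_battery")
}
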