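#' Cognitive-status thresholds
#'
#' MoCA cut-offs used throughout: adjusted MoCA >= 26 reflects intact
#' cognition, <= 25 cognitive impairment (CI) and <= 21 dementia (PDD),
#' with the recommended education correction of +1 point for 12 or fewer
#' years of education, capped at the instrument ceiling of 30.
#'
#' @param intact_min Minimum adjusted MoCA counted as intact (default 26).
#' @param ci_max Maximum adjusted MoCA counted as CI (default 25).
#' @param pdd_max Maximum adjusted MoCA counted as PDD (default 21).
#' @param education_correction_years Education at or below which the
#'   correction applies (default 12 years).
#' @param education_correction_points Points added (default 1).
#' @param moca_ceiling Instrument ceiling (default 30).
#' @return A list of class \code{"status_thresholds"}.
#' @export
status_thresholds <- function(intact_min = 26L, ci_max = 25L, pdd_max = 21L,
                              education_correction_years = 12L,
                              education_correction_points = 1L,
                              moca_ceiling = 30L) {
  if (!(pdd_max < ci_max && ci_max < intact_min)) {
    stop("thresholds must satisfy pdd_max < ci_max < intact_min",
         call. = FALSE)
  }
  if (intact_min != ci_max + 1L) {
    stop("intact_min must equal ci_max + 1 (the cut-offs partition the scale)",
         call. = FALSE)
  }
  structure(list(intact_min = intact_min, ci_max = ci_max,
                 pdd_max = pdd_max,
                 education_correction_years = education_correction_years,
                 education_correction_points = education_correction_points,
                 moca_ceiling = moca_ceiling),
            class = "status_thresholds")
}

#' Education-correct a raw MoCA score
#'
#' Adds the education correction (+1 point for <= 12 years of schooling by
#' default) and caps the result at the instrument ceiling of 30.
#'
#' @param raw Raw MoCA score(s), 0--30.
#' @param education_years Years of education (same length or scalar).
#' @param thresholds A \code{\link{status_thresholds}} object.
#' @return Adjusted MoCA score(s).
#' @export
adjust_moca <- function(raw, education_years,
                        thresholds = status_thresholds()) {
  bad <- !is.na(raw) & (raw < 0 | raw > thresholds$moca_ceiling)
  if (any(bad)) {
    stop("raw MoCA out of range [0, ", thresholds$moca_ceiling, "]: ",
         paste(utils::head(raw[bad], 3), collapse = ", "), call. = FALSE)
  }
  corr <- ifelse(education_years <= thresholds$education_correction_years,
                 thresholds$education_correction_points, 0L)
  pmin(raw + corr, thresholds$moca_ceiling)
}

#' Classify cognitive status from an adjusted MoCA score
#'
#' @param adjusted Adjusted MoCA score(s).
#' @param thresholds A \code{\link{status_thresholds}} object.
#' @return Factor with levels \code{intact}, \code{CI}, \code{PDD}. PDD
#'   implies CI for event-derivation purposes; the label reports the most
#'   severe state.
#' @export
classify_status <- function(adjusted, thresholds = status_thresholds()) {
  out <- ifelse(adjusted <= thresholds$pdd_max, "PDD",
                ifelse(adjusted <= thresholds$ci_max, "CI", "intact"))
  factor(out, levels = c("intact", "CI", "PDD"))
}

#' Baseline-intact inclusion filter
#'
#' Keeps subjects whose education-adjusted baseline MoCA is in the intact
#' range and who have a follow-up battery about one year later, mirroring
#' the cohort inclusion criteria. Exclusions are tallied by reason.
#'
#' @param visits Visit table (see \code{\link{read_visits}}).
#' @param thresholds A \code{\link{status_thresholds}} object.
#' @return List with \code{included} (character vector of subject ids) and
#'   \code{exclusions} (data frame subject_id, reason). Reasons:
#'   \code{no_baseline_moca}, \code{baseline_not_intact},
#'   \code{no_followup_battery}.
#' @export
filter_baseline_intact <- function(visits, thresholds = status_thresholds()) {
  check_visit_columns(visits)
  score_cols <- intersect(battery_tests(), names(visits))
  subjects <- unique(visits$subject_id)
  reasons <- character(0); who <- character(0)
  included <- character(0)
  for (s in subjects) {
    v <- visits[visits$subject_id == s, , drop = FALSE]
    base <- v[v$visit == 0L, , drop = FALSE]
    if (nrow(base) == 0L || all(is.na(base$moca_raw))) {
      who <- c(who, s); reasons <- c(reasons, "no_baseline_moca"); next
    }
    adj <- adjust_moca(base$moca_raw[1], base$education[1], thresholds)
    if (adj < thresholds$intact_min) {
      who <- c(who, s); reasons <- c(reasons, "baseline_not_intact"); next
    }
    fup <- v[v$visit == 1L, , drop = FALSE]
    has_battery <- nrow(fup) > 0L && length(score_cols) > 0L &&
      any(!is.na(unlist(fup[1, score_cols])))
    if (!has_battery) {
      who <- c(who, s); reasons <- c(reasons, "no_followup_battery"); next
    }
    included <- c(included, s)
  }
  list(included = included,
       exclusions = data.frame(subject_id = who, reason = reasons,
                               stringsAsFactors = FALSE))
}

#' Derive CI and PDD event indicators and onset times from MoCA series
#'
#' Scans each subject's education-adjusted MoCA trajectory in visit order.
#' CI onset is the month of the first visit at or below the CI cut-off;
#' PDD onset the month of the first visit at or below the PDD cut-off. A
#' first crossing directly into the PDD range sets both events at the same
#' month. Subjects who never cross are right-censored at their last MoCA
#' visit. A single sub-threshold visit counts as onset (first-crossing
#' rule) unless \code{sustained} asks for k consecutive sub-threshold
#' visits.
#'
#' @param visits Visit table for the subjects of interest (typically PD
#'   only). Baseline is assumed intact; apply
#'   \code{\link{filter_baseline_intact}} first.
#' @param thresholds A \code{\link{status_thresholds}} object.
#' @param sustained Number of consecutive sub-threshold visits required to
#'   call onset (default 1, i.e. plain first crossing). Onset is dated to
#'   the first visit of the run.
#' @return Data frame with one row per subject: \code{subject_id},
#'   \code{ci_event}, \code{ci_time}, \code{pdd_event}, \code{pdd_time},
#'   \code{censor_time} (months of the last MoCA visit). For non-events
#'   the time columns carry the censoring time.
#' @export
derive_event_times <- function(visits, thresholds = status_thresholds(),
                               sustained = 1L) {
  check_visit_columns(visits)
  visits <- visits[!is.na(visits$moca_raw), , drop = FALSE]
  if (nrow(visits) == 0L) stop("empty MoCA series", call. = FALSE)
  ord <- order(visits$subject_id, visits$month)
  visits <- visits[ord, , drop = FALSE]
  res <- lapply(split(visits, visits$subject_id), function(v) {
    if (is.unsorted(v$month, strictly = TRUE)) {
      stop("duplicate or unsorted visit months for subject ",
           v$subject_id[1], call. = FALSE)
    }
    adj <- adjust_moca(v$moca_raw, v$education, thresholds)
    ci_t <- first_crossing(v$month, adj <= thresholds$ci_max, sustained)
    pdd_t <- first_crossing(v$month, adj <= thresholds$pdd_max, sustained)
    censor <- max(v$month)
    data.frame(subject_id = v$subject_id[1],
               ci_event = !is.na(ci_t),
               ci_time = if (is.na(ci_t)) censor else ci_t,
               pdd_event = !is.na(pdd_t),
               pdd_time = if (is.na(pdd_t)) censor else pdd_t,
               censor_time = censor,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Month of the first run of `sustained` consecutive TRUEs, else NA.
first_crossing <- function(months, below, sustained = 1L) {
  n <- length(below)
  if (sustained <= 1L) {
    i <- which(below)[1]
    return(if (is.na(i)) NA_real_ else months[i])
  }
  for (i in seq_len(n - sustained + 1L)) {
    if (all(below[i:(i + sustained - 1L)])) return(months[i])
  }
  NA_real_
}
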