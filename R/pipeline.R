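MANDATORY_VISIT_COLUMNS <- c("subject_id", "group", "age", "sex",
                             "education", "visit", "month",
                             "retest_interval", "moca_raw")

check_visit_columns <- function(visits) {
  miss <- setdiff(MANDATORY_VISIT_COLUMNS, names(visits))
  if (length(miss)) {
    stop("visit table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  invisible(visits)
}

#' Read a visit table from CSV
#'
#' One row per subject-visit. Mandatory columns: \code{subject_id},
#' \code{group} (\code{"PD"} / \code{"HC"}), \code{age}, \code{sex}
#' (0 = female, 1 = male), \code{education} (years), \code{visit} (0 =
#' baseline), \code{month}, \code{retest_interval} (months),
#' \code{moca_raw}; battery scores in columns named by test. Empty fields
#' are missing values; unknown columns are preserved.
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_visits <- function(path) {
  visits <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
  check_visit_columns(visits)
  visits
}

#' Write a table to CSV
#'
#' Plain UTF-8 CSV with empty fields for missing values, so that
#' write-then-read round-trips on the canonical form and outputs diff
#' cleanly.
#'
#' @param records Data frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pivot a visit table into the per-subject paired battery form
#'
#' Extracts, for every subject, the baseline (visit 0) and one-year
#' (visit 1) battery scores into \code{<test>_baseline} /
#' \code{<test>_followup} columns together with the demographics and
#' retest interval, the layout consumed by the SRB fitting and scoring
#' functions.
#'
#' @param visits Visit table.
#' @return Data frame with one row per subject that has a baseline visit.
#' @export
pair_battery <- function(visits) {
  check_visit_columns(visits)
  tests <- intersect(battery_tests(), names(visits))
  base <- visits[visits$visit == 0L, , drop = FALSE]
  fup <- visits[visits$visit == 1L, , drop = FALSE]
  out <- base[, c("subject_id", "group", "age", "sex", "education",
                  "retest_interval")]
  m <- match(out$subject_id, fup$subject_id)
  for (t in tests) {
    out[[paste0(t, "_baseline")]] <- base[[t]]
    out[[paste0(t, "_followup")]] <- fup[[t]][m]
  }
  rownames(out) <- NULL
  out
}

#' Derive per-stage seeds from a root seed
#'
#' Stage seeds are \code{root * 8 + offset} reduced modulo 2^31 - 1, a
#' documented splitting rule keeping every stage reproducible from one
#' root integer.
#'
#' @param root Root seed.
#' @param stage Stage index (0-based).
#' @return Integer seed.
#' @keywords internal
stage_seed <- function(root, stage) {
  as.integer((as.numeric(root) * 8 + stage) %% (2^31 - 1))
}

#' Run the full pipeline: simulate, fit norms, score, classify, analyze
#'
#' Orchestrates one reproducible end-to-end run. Stages: (1) simulate a
#' cohort from the configuration; (2) apply the baseline-intact inclusion
#' filter; (3) fit SRB norms on the included HC subjects and score
#' everyone; (4) derive CI/PDD outcomes for the included PD subjects;
#' (5) run the inferential battery and export median-split incidence
#' curves. All tables are written as plain CSV with a JSON manifest
#' carrying the seed, row counts, exclusion tallies and output checksums.
#'
#' @param config A \code{\link{sim_config}} (or path to a YAML/JSON file
#'   of overrides for \code{sim_config}).
#' @param out_dir Output directory (created if needed). \code{NULL} skips
#'   all file output and just returns the results.
#' @param seed Root seed overriding the configuration seed.
#' @param verbose Log stage progress to standard error.
#' @return List with \code{visits}, \code{truth}, \code{inclusion},
#'   \code{models}, \code{scores}, \code{outcomes}, \code{analysis},
#'   \code{curves}, \code{manifest}.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL, seed = NULL,
                         verbose = FALSE) {
  if (is.character(config)) config <- load_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- stage_seed(seed, 0L)
  log_msg <- function(...) if (verbose) message("[practicefx] ", ...)

  log_msg("simulate: n_hc=", config$n_hc, " n_pd=", config$n_pd,
          " seed=", config$seed)
  sim <- simulate_cohort(config)
  visits <- sim$visits

  incl <- filter_baseline_intact(visits)
  log_msg("classify: included ", length(incl$included), " of ",
          length(unique(visits$subject_id)), " subjects")
  visits_in <- visits[visits$subject_id %in% incl$included, , drop = FALSE]
  paired <- pair_battery(visits_in)

  hc_paired <- paired[paired$group == "HC", , drop = FALSE]
  if (nrow(hc_paired) == 0L) stop("no HC subjects to fit norms on",
                                  call. = FALSE)
  tests_present <- intersect(battery_tests(),
                             sub("_baseline$", "",
                                 grep("_baseline$", names(paired),
                                      value = TRUE)))
  models <- fit_srb_battery(hc_paired, tests = tests_present)
  scores <- score_battery(models, paired)

  pd_visits <- visits_in[visits_in$group == "PD", , drop = FALSE]
  if (nrow(pd_visits) == 0L) {
    stop("classify stage failed: no PD subjects", call. = FALSE)
  }
  outcomes <- derive_event_times(pd_visits)

  log_msg("analyze: ", sum(outcomes$ci_event), " CI events, ",
          sum(outcomes$pdd_event), " PDD events")
  analysis <- run_inference(scores, outcomes)
  curve_for <- function(ot) {
    cv <- cumulative_incidence_by_split(outcomes,
                                        scores[scores$group == "PD", ],
                                        outcome_type = ot)
    if (nrow(cv)) cbind(outcome = ot, cv)
    else cbind(data.frame(outcome = character(0)), cv)
  }
  curves <- rbind(curve_for("CI"), curve_for("PDD"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("practicefx")),
    seed = config$seed,
    n_hc = config$n_hc, n_pd = config$n_pd,
    n_subjects = length(unique(visits$subject_id)),
    n_included = length(incl$included),
    exclusions = as.list(table(incl$exclusions$reason)),
    n_visit_rows = nrow(visits),
    n_ci_events = sum(outcomes$ci_event),
    n_pdd_events = sum(outcomes$pdd_event)
  )

  result <- list(visits = visits, truth = sim$truth, inclusion = incl,
                 models = models, scores = scores, outcomes = outcomes,
                 analysis = analysis, curves = curves, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(visits = "visits.csv", truth = "truth.csv",
               scores = "scores.csv", outcomes = "outcomes.csv",
               group_comparisons = "group_comparisons.csv",
               chisq = "chisq.csv", cox = "cox.csv", curves = "curves.csv")
    write_table(visits, file.path(out_dir, files["visits"]))
    write_table(sim$truth, file.path(out_dir, files["truth"]))
    write_table(scores, file.path(out_dir, files["scores"]))
    write_table(outcomes, file.path(out_dir, files["outcomes"]))
    write_table(analysis$group_comparisons,
                file.path(out_dir, files["group_comparisons"]))
    write_table(analysis$chisq, file.path(out_dir, files["chisq"]))
    write_table(analysis$cox, file.path(out_dir, files["cox"]))
    write_table(curves, file.path(out_dir, files["curves"]))
    write_srb_models(models, file.path(out_dir, "srb_models.json"))
    paths <- file.path(out_dir, files)
    manifest$checksums <- as.list(stats::setNames(
      unname(tools::md5sum(paths)), files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$manifest <- manifest
    log_msg("report written to ", out_dir)
  }
  result
}

#' Load a simulation configuration from YAML or JSON
#'
#' The file holds overrides for \code{\link{sim_config}} arguments
#' (scalar fields only; the battery calibration table stays at its
#' default unless supplied programmatically).
#'
#' @param path YAML or JSON file.
#' @return A \code{sim_config}.
#' @export
load_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, raw)
}
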