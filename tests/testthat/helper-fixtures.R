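# Shared fixtures, built in code.

# Small, fast simulation configuration: full test availability so every
# test's normative model is fittable at modest n.
small_config <- function(n_hc = 80, n_pd = 100, seed = 1, ...) {
  cal <- practicefx::default_battery_calibration()
  cal$avail_hc <- 1
  cal$avail_pd <- 1
  practicefx::sim_config(n_hc = n_hc, n_pd = n_pd, seed = seed,
                         battery = cal, ...)
}

# Single-test configuration (SDMT only) for replicate-heavy studies.
sdmt_config <- function(n_hc, n_pd, seed, deficit = 0.36, ...) {
  cal <- practicefx::default_battery_calibration()
  cal <- cal[cal$test == "SDMT", ]
  cal$deficit <- deficit
  cal$avail_hc <- 1
  cal$avail_pd <- 1
  practicefx::sim_config(n_hc = n_hc, n_pd = n_pd, seed = seed,
                         battery = cal, ...)
}

sdmt_null_config <- function(n_hc, n_pd, seed, ...) {
  cal <- practicefx::default_battery_calibration()
  cal <- cal[cal$test == "SDMT", ]
  cal$deficit <- 0
  cal$pd_m0 <- cal$hc_m0
  cal$pd_sd0 <- cal$hc_sd0
  cal$avail_hc <- 1
  cal$avail_pd <- 1
  practicefx::null_sim_config(n_hc = n_hc, n_pd = n_pd, seed = seed,
                              battery = cal, ...)
}

# Hand-built paired table with exactly controllable predictors.
toy_paired <- function(n = 10, seed = 99, test = "SDMT") {
  set.seed(seed)
  d <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = "HC",
    age = round(runif(n, 45, 80)),
    sex = rep_len(c(0, 1), n),
    education = round(runif(n, 8, 20)),
    retest_interval = round(runif(n, 11, 13), 1)
  )
  d[[paste0(test, "_baseline")]] <- round(runif(n, 30, 60))
  d[[paste0(test, "_followup")]] <-
    round(0.8 * d[[paste0(test, "_baseline")]] + 0.1 * d$age -
            0.2 * d$education + rnorm(n, 8, 4))
  d
}

# Minimal visit table for status/pipeline tests: one subject trajectory.
visit_rows <- function(subject_id, months, moca, education = 16,
                       group = "PD", scores = NULL) {
  d <- data.frame(
    subject_id = subject_id, group = group, age = 65, sex = 1,
    education = education, visit = seq_along(months) - 1L,
    month = months, retest_interval = 12, moca_raw = moca,
    stringsAsFactors = FALSE
  )
  if (!is.null(scores)) for (nm in names(scores)) d[[nm]] <- scores[[nm]]
  d
}
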