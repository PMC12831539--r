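#' Default battery calibration for the synthetic cohort
#'
#' Per-test generative parameters: baseline score means/SDs per group,
#' the follow-up regression (baseline slope, small demographic effects,
#' residual noise) and the PD practice-gain deficit in oriented
#' residual-SD units. Baseline means/SDs and deficits follow the
#' descriptive statistics of the PPMI-like cohort the simulator emulates;
#' the follow-up model assumes a test-retest correlation of 0.75, so the
#' baseline slope is \code{0.75 * sd1/sd0} and the residual noise SD is
#' \code{sd1 * sqrt(1 - 0.75^2)}.
#'
#' @return Data frame with one row per battery test.
#' @export
default_battery_calibration <- function() {
  spec <- battery_specs()
  cal <- data.frame(
    test = spec$test,
    hc_m0 = c(10.85, 55.46, 47.10, 22.16, 13.08, 28.40, 56.86, 26.25, 9.33),
    hc_sd0 = c(2.59, 8.14, 10.26, 5.28, 2.01, 10.27, 20.53, 4.56, 2.34),
    pd_m0 = c(10.81, 54.09, 42.36, 21.84, 12.77, 34.57, 73.03, 25.37, 8.86),
    pd_sd0 = c(2.65, 10.88, 9.96, 5.34, 2.17, 10.92, 26.79, 4.78, 2.44),
    m1 = c(10.90, 55.06, 47.62, 22.66, 12.65, 28.13, 59.90, 26.14, 9.08),
    sd1 = c(2.66, 9.56, 10.55, 5.19, 2.45, 5.65, 15.68, 4.70, 2.47),
    deficit = c(0.20, -0.11, 0.36, 0.13, 0.00, 0.95, 1.15, 0.25, 0.04),
    avail_hc = c(185, 30, 214, 214, 185, 30, 30, 214, 214) / 214,
    avail_pd = c(435, 103, 547, 546, 542, 104, 104, 546, 546) / 547,
    stringsAsFactors = FALSE
  )
  r <- 0.75                      # assumed test-retest correlation
  s <- ifelse(spec$direction == "lower_is_better", -1, 1)
  cal$dir_sign <- s
  cal$gamma1 <- r * cal$sd1 / cal$hc_sd0
  cal$sigma <- cal$sd1 * sqrt(1 - r^2)
  # Small demographic effects in score units (oriented by direction):
  # older age and longer retest interval reduce the expected gain,
  # more education increases it.
  cal$gamma_age <- -0.010 * cal$sd1 * s
  cal$gamma_sex <- 0
  cal$gamma_education <- 0.015 * cal$sd1 * s
  cal$gamma_interval <- -0.020 * cal$sd1 * s
  cal
}

#' Convert an oriented z-scale deficit to a latent-ability loading
#'
#' The simulator writes each subject's practice gain as
#' \code{sigma * (lambda * a + e) / sqrt(1 + lambda^2)} with latent
#' ability \code{a} and unit noise \code{e}, so the expected PD deficit in
#' residual-SD units is \code{lambda / sqrt(1 + lambda^2)} times the PD
#' ability shift. This inverts that relation.
#'
#' @param deficit Target mean PD deficit in oriented residual-SD units.
#' @param shift PD latent-ability shift (positive; see
#'   \code{\link{sim_config}}).
#' @return Loading \code{lambda}.
#' @keywords internal
deficit_loading <- function(deficit, shift) {
  if (shift == 0) {
    if (any(deficit != 0)) {
      stop("non-zero deficit requires a positive pd_ability_shift",
           call. = FALSE)
    }
    return(rep(0, length(deficit)))
  }
  g <- deficit / shift
  if (any(abs(g) >= 0.999)) {
    stop("deficit of ", max(abs(deficit)),
         " not reachable with pd_ability_shift ", shift, call. = FALSE)
  }
  g / sqrt(1 - g^2)
}

#' Build a simulation configuration
#'
#' Assembles and validates the configuration of the synthetic cohort
#' generator. The defaults emulate the structure of the PPMI-like study
#' cohort: 214 controls and 547 PD subjects, a baseline plus one-year
#' neuropsychological battery with per-test availability matching the
#' published participant counts, and approximately annual MoCA visits to
#' 132 months with per-visit dropout. A single standardized latent
#' practice ability per subject drives both the per-test gain deficits in
#' PD and the progression hazard, so the practice-effect/outcome
#' association exists with known ground truth.
#'
#' @param n_hc,n_pd Group sizes.
#' @param visit_months Nominal MoCA visit months, strictly increasing from
#'   0 (default 0, 12, ..., 132).
#' @param visit_jitter Uniform jitter half-width (months) on visits after
#'   year 1 (default 2).
#' @param interval_range Range of the battery retest interval in months
#'   (default 11--13); the year-1 visit occurs at the drawn interval.
#' @param age,education Lists with \code{mean}, \code{sd}, \code{range}.
#' @param p_male Named vector \code{c(hc = , pd = )} of male proportions
#'   (sex coded 0 = female, 1 = male).
#' @param battery Calibration table, see
#'   \code{\link{default_battery_calibration}}.
#' @param pd_ability_shift Mean latent-ability deficit of PD subjects in
#'   SD units (HC ability is standard normal; PD ability is normal with
#'   mean \code{-pd_ability_shift}, SD 1).
#' @param hazard List: \code{shape}, \code{scale} (Weibull baseline for
#'   the CI onset time, months), \code{beta_sim} (log-hazard per SD of
#'   latent practice \emph{deficit}, i.e. the linear predictor is
#'   \code{beta_sim * (-ability)}), \code{gap_shape}, \code{gap_scale}
#'   (Weibull law of the CI-to-PDD gap, months).
#' @param retention Per-visit retention probability after year 1.
#' @param moca_noise SD of integer-rounded Gaussian fluctuation added to
#'   rendered MoCA values (default 0: threshold crossings reproduce the
#'   generative event times exactly).
#' @param seed Integer seed; identical configurations and seeds give
#'   byte-identical cohorts.
#' @return A validated list of class \code{"sim_config"}.
#' @seealso \code{\link{simulate_cohort}}
#' @export
sim_config <- function(n_hc = 214L, n_pd = 547L,
                       visit_months = seq(0, 132, by = 12),
                       visit_jitter = 2,
                       interval_range = c(11, 13),
                       age = list(mean = 61.3, sd = 10.5, range = c(29, 83)),
                       p_male = c(hc = 0.636, pd = 0.592),
                       education = list(mean = 15.5, sd = 2.9,
                                        range = c(5, 20)),
                       battery = default_battery_calibration(),
                       pd_ability_shift = 1.5,
                       hazard = list(shape = 0.65, scale = 3000,
                                     beta_sim = 1.0,
                                     gap_shape = 0.5, gap_scale = 700),
                       retention = 0.92,
                       moca_noise = 0,
                       seed = 1L) {
  p_male <- unlist(p_male)          # tolerate YAML/JSON configs
  interval_range <- unlist(interval_range)
  visit_months <- unlist(visit_months)
  cfg <- list(n_hc = as.integer(n_hc), n_pd = as.integer(n_pd),
              visit_months = visit_months, visit_jitter = visit_jitter,
              interval_range = interval_range, age = age, p_male = p_male,
              education = education, battery = battery,
              pd_ability_shift = pd_ability_shift, hazard = hazard,
              retention = retention, moca_noise = moca_noise,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  err <- function(field, why) {
    stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  }
  if (cfg$n_hc < 0L || cfg$n_pd < 0L) err("n_hc/n_pd", "must be >= 0")
  vm <- cfg$visit_months
  if (length(vm) < 2L || vm[1] != 0 || is.unsorted(vm, strictly = TRUE)) {
    err("visit_months", "must be strictly increasing and start at 0")
  }
  if (cfg$retention < 0 || cfg$retention > 1) {
    err("retention", "must be a probability in [0, 1]")
  }
  if (any(cfg$p_male < 0 | cfg$p_male > 1)) {
    err("p_male", "must be probabilities in [0, 1]")
  }
  b <- cfg$battery
  needed <- c("test", "hc_m0", "hc_sd0", "pd_m0", "pd_sd0", "gamma1",
              "sigma", "deficit", "avail_hc", "avail_pd", "dir_sign",
              "gamma_age", "gamma_sex", "gamma_education", "gamma_interval",
              "m1")
  if (!all(needed %in% names(b))) {
    err("battery", paste("missing columns:",
                         paste(setdiff(needed, names(b)), collapse = ", ")))
  }
  if (any(b$hc_sd0 <= 0 | b$pd_sd0 <= 0 | b$sigma <= 0)) {
    err("battery", "score SDs must be > 0")
  }
  if (any(b$avail_hc < 0 | b$avail_hc > 1 | b$avail_pd < 0 |
            b$avail_pd > 1)) {
    err("battery", "availability probabilities must be in [0, 1]")
  }
  hz <- cfg$hazard
  if (any(!c("shape", "scale", "beta_sim", "gap_shape",
             "gap_scale") %in% names(hz))) {
    err("hazard", "needs shape, scale, beta_sim, gap_shape, gap_scale")
  }
  if (hz$shape <= 0 || hz$scale <= 0 || hz$gap_shape <= 0 ||
        hz$gap_scale <= 0) {
    err("hazard", "shape/scale parameters must be > 0")
  }
  if (cfg$moca_noise < 0) err("moca_noise", "must be >= 0")
  if (cfg$pd_ability_shift < 0) err("pd_ability_shift", "must be >= 0")
  # Fails early if a configured deficit is unreachable for the shift.
  deficit_loading(b$deficit, cfg$pd_ability_shift)
  invisible(cfg)
}

#' Null (no-effect) simulation configuration
#'
#' Convenience configuration in which PD and HC are generated from an
#' identical process: no practice-gain deficit on any test, no latent
#' ability shift, and no ability effect on the hazard
#' (\code{beta_sim = 0}). Used for type-I-error and coverage studies.
#'
#' @param ... Overrides passed on to \code{\link{sim_config}}.
#' @return A \code{sim_config}.
#' @export
null_sim_config <- function(...) {
  b <- default_battery_calibration()
  b$deficit <- 0
  b$pd_m0 <- b$hc_m0
  b$pd_sd0 <- b$hc_sd0
  defaults <- list(battery = b, pd_ability_shift = 0,
                   p_male = c(hc = 0.6, pd = 0.6),
                   hazard = list(shape = 0.65, scale = 3000, beta_sim = 0,
                                 gap_shape = 0.5, gap_scale = 700))
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Draw CI and PDD onset times from the proportional-hazards law
#'
#' The CI onset time follows a Weibull baseline hazard scaled by
#' \code{exp(beta_sim * (-ability))}, so lower latent practice ability
#' means a proportionally higher hazard. The PDD onset is the CI onset
#' plus an independent positive Weibull gap. Times beyond the last
#' scheduled visit (plus jitter) are recorded as infinite: they can never
#' be observed.
#'
#' @param config A \code{\link{sim_config}}.
#' @param ability Numeric vector of latent ability values (finite).
#' @return Data frame with \code{ci_time} and \code{pdd_time} in months
#'   (\code{Inf} when beyond the observation horizon).
#' @export
simulate_event_times <- function(config, ability) {
  stopifnot(inherits(config, "sim_config"))
  if (any(!is.finite(ability))) {
    stop("latent ability values must be finite", call. = FALSE)
  }
  hz <- config$hazard
  n <- length(ability)
  lp <- hz$beta_sim * (-ability)
  # Inverse-CDF sampling: S(t) = exp(-(t/scale)^shape * exp(lp)).
  u <- stats::runif(n)
  ci <- hz$scale * (-log(u) * exp(-lp))^(1 / hz$shape)
  gap <- hz$gap_scale * (-log(stats::runif(n)))^(1 / hz$gap_shape)
  pdd <- ci + gap
  horizon <- max(config$visit_months) + config$visit_jitter
  ci[ci > horizon] <- Inf
  pdd[pdd > horizon] <- Inf
  pdd[is.infinite(ci)] <- Inf
  data.frame(ci_time = ci, pdd_time = pdd)
}

#' Render a per-visit adjusted MoCA series from event times
#'
#' Produces education-adjusted MoCA values consistent with the threshold
#' rules: visits before CI onset draw from the intact range (26--30),
#' visits from CI onset to just before PDD onset from the impaired range
#' (22--25), and visits from PDD onset on from the dementia range
#' (at most 21). With \code{moca_noise = 0} the first threshold crossings
#' therefore reproduce the generative onset times exactly; positive noise
#' adds integer-rounded Gaussian fluctuation before clipping to [0, 30].
#'
#' @param months Visit months for one subject (sorted).
#' @param ci_time,pdd_time Onset times in months (\code{Inf} for never);
#'   \code{pdd_time} must not precede \code{ci_time}.
#' @param moca_noise Fluctuation SD (default 0).
#' @return Integer vector of adjusted MoCA values, one per visit.
#' @export
render_moca_series <- function(months, ci_time, pdd_time, moca_noise = 0) {
  if (pdd_time < ci_time) {
    stop("invariant violation: PDD onset precedes CI onset", call. = FALSE)
  }
  n <- length(months)
  state <- ifelse(months >= pdd_time, 3L, ifelse(months >= ci_time, 2L, 1L))
  vals <- integer(n)
  vals[state == 1L] <- sample(26:30, sum(state == 1L), replace = TRUE,
                              prob = c(0.10, 0.20, 0.30, 0.25, 0.15))
  vals[state == 2L] <- sample(22:25, sum(state == 2L), replace = TRUE,
                              prob = c(0.15, 0.25, 0.30, 0.30))
  n3 <- sum(state == 3L)
  vals[state == 3L] <- pmin(pmax(round(stats::rnorm(n3, 18.5, 2)), 0L), 21L)
  if (moca_noise > 0) {
    vals <- vals + round(stats::rnorm(n, 0, moca_noise))
    vals <- pmin(pmax(vals, 0L), 30L)
  }
  as.integer(vals)
}

#' Simulate a longitudinal HC + PD cohort with known ground truth
#'
#' Generates demographics, a baseline and one-year neuropsychological
#' battery, annual MoCA visits with dropout, and latent truth (ability and
#' generative onset times) for every subject. HC latent ability is
#' standard normal; PD ability is shifted down by
#' \code{pd_ability_shift}. The same ability drives the per-test practice
#' gains (through the configured deficit loadings) and the CI hazard, so
#' downstream scoring and survival models have a recoverable signal.
#'
#' Scores are rounded to integer points (seconds for the timed tests) and
#' truncated to each test's legal range. Per-test availability follows
#' the configured probabilities: an unavailable test is missing at both
#' time points for that subject.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{visits} (one row per retained subject-visit;
#'   battery scores on visits 0 and 1, MoCA on every visit) and
#'   \code{truth} (one row per subject: group, ability, generative
#'   \code{ci_time}/\code{pdd_time}, observable onsets
#'   \code{ci_onset_obs}/\code{pdd_onset_obs} given the realized visit
#'   schedule, and \code{censor_month}).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  hc <- simulate_group(config, "HC", config$n_hc)
  pd <- simulate_group(config, "PD", config$n_pd)
  visits <- rbind(hc$visits, pd$visits)
  truth <- rbind(hc$truth, pd$truth)
  rownames(visits) <- rownames(truth) <- NULL
  list(visits = visits, truth = truth)
}

simulate_group <- function(config, group, n) {
  if (n == 0L) {
    return(list(visits = NULL, truth = NULL))
  }
  b <- config$battery
  tests <- b$test
  spec <- battery_specs()
  spec <- spec[match(tests, spec$test), ]
  grp <- tolower(group)
  ids <- sprintf("%s%04d", grp, seq_len(n))

  ages <- round(pmin(pmax(stats::rnorm(n, config$age$mean, config$age$sd),
                          config$age$range[1]), config$age$range[2]))
  sex <- stats::rbinom(n, 1L, config$p_male[[grp]])
  edu <- round(pmin(pmax(stats::rnorm(n, config$education$mean,
                                      config$education$sd),
                         config$education$range[1]),
                    config$education$range[2]))
  interval <- round(stats::runif(n, config$interval_range[1],
                                 config$interval_range[2]), 1)
  shift <- if (group == "PD") config$pd_ability_shift else 0
  ability <- stats::rnorm(n, -shift, 1)

  lambda <- deficit_loading(b$deficit, max(config$pd_ability_shift, 1e-12))
  if (config$pd_ability_shift == 0) lambda <- rep(0, nrow(b))

  m0 <- if (group == "PD") b$pd_m0 else b$hc_m0
  sd0 <- if (group == "PD") b$pd_sd0 else b$hc_sd0
  # Intercept chosen so HC follow-up means match the calibration targets
  # at the population covariate means.
  gamma0 <- b$m1 - b$gamma1 * b$hc_m0 - b$gamma_age * config$age$mean -
    b$gamma_sex * mean(config$p_male) -
    b$gamma_education * config$education$mean - b$gamma_interval * 12

  base <- matrix(NA_real_, n, length(tests), dimnames = list(NULL, tests))
  fup <- base
  for (j in seq_along(tests)) {
    avail_p <- if (group == "PD") b$avail_pd[j] else b$avail_hc[j]
    avail <- stats::runif(n) < avail_p
    y0 <- stats::rnorm(n, m0[j], sd0[j])
    y0 <- clip_round(y0, spec$score_min[j], spec$score_max[j])
    pred <- gamma0[j] + b$gamma1[j] * y0 + b$gamma_age[j] * ages +
      b$gamma_sex[j] * sex + b$gamma_education[j] * edu +
      b$gamma_interval[j] * interval
    lam <- if (group == "PD") lambda[j] else 0
    dev <- b$sigma[j] * (lam * ability + stats::rnorm(n)) /
      sqrt(1 + lam^2)
    y1 <- clip_round(pred + b$dir_sign[j] * dev,
                     spec$score_min[j], spec$score_max[j])
    y0[!avail] <- NA_real_
    y1[!avail] <- NA_real_
    base[, j] <- y0
    fup[, j] <- y1
  }

  times <- simulate_event_times(config, ability)

  # Visit schedule: month 0, the battery retest visit at the drawn
  # interval, then jittered annual visits with sequential retention.
  vm <- config$visit_months
  k <- length(vm)
  months <- matrix(NA_real_, n, k)
  months[, 1] <- 0
  months[, 2] <- interval
  if (k > 2L) {
    for (j in 3:k) {
      months[, j] <- vm[j] + stats::runif(n, -config$visit_jitter,
                                          config$visit_jitter)
    }
  }
  retained <- matrix(TRUE, n, k)
  if (k > 2L) {
    for (j in 3:k) {
      retained[, j] <- retained[, j - 1] &
        (stats::runif(n) < config$retention)
    }
  }

  rows <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- which(retained[i, ])
    mo <- months[i, keep]
    moca_adj <- render_moca_series(mo, times$ci_time[i], times$pdd_time[i],
                                   config$moca_noise)
    corr <- as.integer(edu[i] <= 12)
    moca_raw <- pmax(moca_adj - corr, 0L)
    sub <- data.frame(
      subject_id = ids[i], group = group, age = ages[i], sex = sex[i],
      education = edu[i], visit = keep - 1L, month = mo,
      retest_interval = interval[i], moca_raw = moca_raw,
      stringsAsFactors = FALSE
    )
    for (j in seq_along(tests)) {
      v <- rep(NA_real_, length(keep))
      v[sub$visit == 0L] <- base[i, j]
      v[sub$visit == 1L] <- fup[i, j]
      sub[[tests[j]]] <- v
    }
    rows[[i]] <- sub
    censor <- max(mo)
    ci_obs <- first_visit_at_or_after(mo, times$ci_time[i])
    pdd_obs <- first_visit_at_or_after(mo, times$pdd_time[i])
    truth_rows[[i]] <- data.frame(
      subject_id = ids[i], group = group, ability = ability[i],
      ci_time = times$ci_time[i], pdd_time = times$pdd_time[i],
      ci_onset_obs = ci_obs, pdd_onset_obs = pdd_obs,
      censor_month = censor, stringsAsFactors = FALSE
    )
  }
  list(visits = do.call(rbind, rows), truth = do.call(rbind, truth_rows))
}

first_visit_at_or_after <- function(months, t) {
  if (!is.finite(t)) return(NA_real_)
  i <- which(months >= t)[1]
  if (is.na(i)) NA_real_ else months[i]
}

clip_round <- function(x, lo, hi) {
  pmin(pmax(round(x), lo), hi)
}
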