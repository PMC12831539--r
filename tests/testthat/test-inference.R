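test_that("Pearson statistic matches the long-form hand computation", {
  res <- chisq_change(c(31, 69, 0), mode = "theoretical")
  hand <- (31 - 5)^2 / 5 + (69 - 90)^2 / 90 + (0 - 5)^2 / 5
  expect_equal(res$statistic, hand, tolerance = 1e-9)
  expect_equal(res$statistic, 145.1, tolerance = 1e-9)
  expect_equal(res$df, 2L)
  expect_true(res$computable)

  # Identity: observed proportions equal to the reference.
  id <- chisq_change(c(5, 90, 5), hc_counts = c(10, 180, 10), mode = "hc")
  expect_equal(id$statistic, 0)
  expect_equal(id$p, 1)

  # HC category empty but PD observations present: not computable.
  deg <- chisq_change(c(31, 69, 0), hc_counts = c(0, 95, 5), mode = "hc")
  expect_false(deg$computable)
  expect_match(deg$note, "theoretical")
  expect_error(chisq_change(c(0, 0, 0)), "positive total")
})

test_that("group comparison recovers an injected deficit and nulls a constant", {
  betas <- vapply(1:25, function(seed) {
    cfg <- sdmt_config(n_hc = 214, n_pd = 547, seed = 2000 + seed,
                       deficit = 0.36)
    sim <- simulate_cohort(cfg)
    paired <- pair_battery(sim$visits)
    models <- fit_srb_battery(paired[paired$group == "HC", ],
                              tests = "SDMT")
    scores <- score_battery(models, paired)
    compare_groups(scores, tests = "SDMT")$beta_group
  }, 0)
  expect_equal(mean(betas), -0.36, tolerance = 0.05)

  # Constant outcome: exact zero coefficient.
  sc <- data.frame(subject_id = sprintf("s%d", 1:40),
                   group = rep(c("PD", "HC"), 20),
                   age = rnorm(40, 60, 8), sex = rep_len(0:1, 40),
                   education = round(runif(40, 8, 20)), z_SDMT = 0.7)
  res <- compare_groups(sc, tests = "SDMT")
  expect_equal(res$beta_group, 0)
})

test_that("Cox hazard ratio matches the grid-search partial-likelihood oracle", {
  d <- data.frame(subject_id = c("a", "b", "c", "d"),
                  ci_event = c(TRUE, TRUE, FALSE, FALSE),
                  ci_time = c(5, 8, 12, 15),
                  pdd_event = FALSE, pdd_time = c(5, 8, 12, 15),
                  censor_time = c(5, 8, 12, 15))
  sc <- data.frame(subject_id = c("a", "b", "c", "d"),
                   group = "PD", age = 60, sex = 1, education = 16,
                   z_SDMT = c(0, 1, 0, 1))
  fit <- suppressWarnings(fit_cox(d, sc, predictor = "SDMT",
                                  outcome_type = "CI"))
  oracle <- cox_grid_mle(d$ci_time, as.integer(d$ci_event), sc$z_SDMT)
  expect_equal(log(fit$hr), oracle, tolerance = 1e-4)
})

test_that("non-estimable Cox models are flagged, not fitted", {
  d <- data.frame(subject_id = c("a", "b", "c"),
                  ci_event = FALSE, ci_time = c(12, 24, 36),
                  pdd_event = FALSE, pdd_time = c(12, 24, 36),
                  censor_time = c(12, 24, 36))
  sc <- data.frame(subject_id = c("a", "b", "c"), group = "PD",
                   age = c(55, 60, 65), sex = c(0, 1, 0), education = 16,
                   z_SDMT = c(-1, 0, 1))
  none <- fit_cox(d, sc, predictor = "SDMT", outcome_type = "CI")
  expect_false(none$estimable)
  expect_equal(none$reason, "no_events")
  expect_true(is.na(none$hr))

  d$ci_event <- c(TRUE, TRUE, FALSE)
  sc$z_SDMT <- 1
  const <- fit_cox(d, sc, predictor = "SDMT", outcome_type = "CI")
  expect_false(const$estimable)
  expect_equal(const$reason, "constant_predictor")
})

test_that("centering shifts values but leaves the Cox hazard ratio unchanged", {
  expect_equal(center_predictor(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(center_predictor(c(-1, 0, 1)), c(-1, 0, 1))
  expect_equal(center_predictor(c(5, 7), enabled = FALSE), c(5, 7))

  cfg <- sdmt_config(n_hc = 60, n_pd = 250, seed = 31)
  sim <- simulate_cohort(cfg)
  paired <- pair_battery(sim$visits)
  models <- fit_srb_battery(paired[paired$group == "HC", ], tests = "SDMT")
  scores <- score_battery(models, paired)
  pd <- scores[scores$group == "PD", ]
  out <- derive_event_times(sim$visits[sim$visits$group == "PD", ])
  f0 <- fit_cox(out, pd, predictor = "SDMT", outcome_type = "CI",
                center = FALSE)
  f1 <- fit_cox(out, pd, predictor = "SDMT", outcome_type = "CI",
                center = TRUE)
  expect_equal(f0$hr, f1$hr, tolerance = 1e-8)
  expect_equal(f0$ci_low, f1$ci_low, tolerance = 1e-8)
})

test_that("the Schoenfeld check is skipped for degenerate fits and detects a time-varying effect", {
  skipped <- structure(list(fit = NULL, n_events = 1L),
                       class = "cox_result")
  expect_true(is.na(check_ph_assumption(skipped)))

  # Piecewise hazard whose covariate effect flips sign mid-follow-up
  # violates proportionality; the scaled-Schoenfeld test should usually
  # reject it.
  set.seed(77)
  rej <- vapply(1:50, function(i) {
    n <- 400
    x <- rbinom(n, 1, 0.5)
    t0 <- 12
    # rate 0.05*exp(x) before t0, 0.05*exp(-x) after
    t1 <- rexp(n, 0.05 * exp(x))
    tt <- ifelse(t1 < t0, t1, t0 + rexp(n, 0.05 * exp(-x)))
    cens <- runif(n, 30, 80)
    d <- data.frame(subject_id = as.character(seq_len(n)),
                    ci_event = tt <= cens, ci_time = pmin(tt, cens),
                    pdd_event = FALSE, pdd_time = pmin(tt, cens),
                    censor_time = cens)
    sc <- data.frame(subject_id = as.character(seq_len(n)), group = "PD",
                     age = rnorm(n, 60, 5), sex = rbinom(n, 1, 0.5),
                     education = 16, z_SDMT = x)
    fit <- fit_cox(d, sc, predictor = "SDMT", outcome_type = "CI")
    fit$ph_test_p < 0.05
  }, NA)
  expect_gt(mean(rej), 0.5)
})

test_that("BH adjustment matches the brute-force step-up on random arrays", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdr_adjust(c(1, 1)), c(1, 1))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(123)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- fdr_adjust(p)
    expect_equal(q, bh_stepup(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("median-split incidence curves match the product-limit hand oracle", {
  d <- data.frame(subject_id = sprintf("s%d", 1:7),
                  ci_event = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
                  ci_time = c(2, 4, 6, 8, 10, 1, 1),
                  pdd_event = FALSE,
                  pdd_time = c(2, 4, 6, 8, 10, 1, 1),
                  censor_time = c(2, 4, 6, 8, 10, 1, 1))
  sc <- data.frame(subject_id = sprintf("s%d", 1:7), group = "PD",
                   age = 60, sex = 1, education = 16,
                   composite = c(0, 0, 0, 0, 0, 10, 10))
  curves <- cumulative_incidence_by_split(d, sc, outcome_type = "CI")
  low <- curves[curves$half == "low", ]
  oracle <- km_long_form(c(2, 4, 6, 8, 10),
                         c(1, 0, 1, 1, 0))
  got <- low$cum_incidence[match(oracle$time, low$time)]
  expect_equal(got, 1 - oracle$surv)
  # Median split with ties going low: five subjects at the median.
  expect_equal(max(low$n_risk), 5)
  # No events anywhere: curves identically zero.
  d0 <- d; d0$ci_event <- FALSE
  c0 <- cumulative_incidence_by_split(d0, sc, outcome_type = "CI")
  expect_true(all(c0$cum_incidence == 0))
  sc0 <- sc; sc0$composite <- 1
  expect_warning(cumulative_incidence_by_split(d, sc0, outcome_type = "CI"),
                 "constant")
})

test_that("a strong simulated effect separates the median-split halves", {
  cfg <- sdmt_config(n_hc = 60, n_pd = 400, seed = 55, deficit = 1.0,
                     hazard = list(shape = 0.65, scale = 1000,
                                   beta_sim = 2.0, gap_shape = 0.5,
                                   gap_scale = 700))
  sim <- simulate_cohort(cfg)
  paired <- pair_battery(sim$visits)
  models <- fit_srb_battery(paired[paired$group == "HC", ], tests = "SDMT")
  scores <- score_battery(models, paired)
  pd <- scores[scores$group == "PD", ]
  out <- derive_event_times(sim$visits[sim$visits$group == "PD", ])
  curves <- cumulative_incidence_by_split(out, pd, predictor = "SDMT",
                                          outcome_type = "CI")
  # Evaluate both step functions on a common time grid.
  step_at <- function(cv, t) {
    vapply(t, function(ti) {
      i <- which(cv$time <= ti)
      if (!length(i)) 0 else cv$cum_incidence[max(i)]
    }, 0)
  }
  # From the first annual follow-up window onwards the low-practice
  # curve must dominate (the first few months only contain ties from
  # the earliest visit).
  grid <- seq(13, 130, by = 1)
  lo <- step_at(curves[curves$half == "low", ], grid)
  hi <- step_at(curves[curves$half == "high", ], grid)
  expect_true(all(lo >= hi - 1e-12))
  expect_true(any(lo > hi))
})

test_that("the full inferential battery returns coherent tables", {
  res <- run_pipeline(small_config(n_hc = 80, n_pd = 150, seed = 13))
  gc <- res$analysis$group_comparisons
  expect_setequal(gc$test, c(battery_tests(), "composite"))
  expect_true(all(gc$q >= gc$p - 1e-12, na.rm = TRUE))
  cox <- res$analysis$cox
  expect_equal(nrow(cox), 20L)  # 2 outcomes x (9 tests + composite)
  est <- cox[cox$estimable, ]
  expect_true(all(est$ci_low <= est$hr & est$hr <= est$ci_high))
  expect_true(all(est$hr > 0))
  expect_true(all(cox$q >= cox$p - 1e-12, na.rm = TRUE))
  chi <- res$analysis$chisq
  expect_equal(unname(chi$pd_decline + chi$pd_no_change +
                        chi$pd_improvement),
               unname(gc$n[match(chi$test, gc$test)] -
                        vapply(chi$test, function(t) {
                          sum(res$scores$group == "HC" &
                                !is.na(res$scores[[paste0("z_", t)]]))
                        }, 0)))
})
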