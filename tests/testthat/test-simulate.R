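test_that("configuration validation names the offending field", {
  expect_error(sim_config(retention = 1.2), "retention")
  expect_error(sim_config(visit_months = c(0, 24, 12)), "visit_months")
  expect_error(sim_config(visit_months = c(12, 24)), "visit_months")
  expect_error(sim_config(moca_noise = -1), "moca_noise")
  cal <- default_battery_calibration()
  cal$hc_sd0[1] <- 0
  expect_error(sim_config(battery = cal), "SDs must be > 0")
  cal <- default_battery_calibration()
  cal$deficit[1] <- 2.0   # unreachable for the default ability shift
  expect_error(sim_config(battery = cal), "not reachable")
})

test_that("identical seeds reproduce the cohort exactly; different seeds do not", {
  cfg <- small_config(n_hc = 25, n_pd = 25, seed = 42)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_cohort(small_config(n_hc = 25, n_pd = 25, seed = 43))
  expect_false(identical(s1$visits$SDMT, s3$visits$SDMT))
})

test_that("latent event times follow the proportional-hazards construction", {
  cfg <- small_config(seed = 1)
  set.seed(10)
  expect_error(simulate_event_times(cfg, c(0, NA)), "finite")
  expect_error(simulate_event_times(cfg, c(0, Inf)), "finite")
  # Strong effect, two point masses: low ability must fail first.
  strong <- sim_config(hazard = list(shape = 0.65, scale = 300,
                                     beta_sim = 3, gap_shape = 0.5,
                                     gap_scale = 700))
  set.seed(11)
  ab <- rep(c(-2, 2), each = 4000)
  tt <- simulate_event_times(strong, ab)
  expect_lt(median(tt$ci_time[ab == -2]), median(tt$ci_time[ab == 2]))
  expect_true(all(tt$pdd_time >= tt$ci_time))
  expect_true(all(tt$ci_time[is.finite(tt$ci_time)] <=
                    max(cfg$visit_months) + cfg$visit_jitter))
})

test_that("ability-independent hazards give exchangeable event times", {
  null_hz <- sim_config(hazard = list(shape = 0.65, scale = 300,
                                      beta_sim = 0, gap_shape = 0.5,
                                      gap_scale = 700))
  set.seed(12)
  ab <- rnorm(4000)
  tt <- simulate_event_times(null_hz, ab)
  grp <- ab > median(ab)
  obs <- is.finite(tt$ci_time)
  # Event probability must not differ between ability halves.
  p <- prop.test(table(grp, obs))$p.value
  expect_gt(p, 0.001)
})

test_that("MoCA rendering respects the state bands and round-trips exactly", {
  set.seed(3)
  none <- render_moca_series(seq(0, 60, 12), Inf, Inf)
  expect_true(all(none >= 26))
  mid <- render_moca_series(seq(0, 60, 12), 24, 48)
  expect_true(all(mid[1:2] >= 26))
  expect_true(all(mid[3:4] >= 22 & mid[3:4] <= 25))
  expect_true(all(mid[5:6] <= 21))
  expect_error(render_moca_series(0:5, 24, 12), "invariant violation")

  # Derived statuses reproduce the generative onsets.
  v <- visit_rows("rt", seq(0, 60, 12), mid, education = 16)
  out <- derive_event_times(v)
  expect_equal(out$ci_time, 24)
  expect_equal(out$pdd_time, 48)
})

test_that("the noiseless cohort round-trips: derived outcomes equal the truth", {
  for (seed in 1:20) {
    cfg <- small_config(n_hc = 0, n_pd = 40, seed = seed)
    sim <- simulate_cohort(cfg)
    out <- derive_event_times(sim$visits)
    tr <- sim$truth[match(out$subject_id, sim$truth$subject_id), ]
    expect_equal(out$ci_event, !is.na(tr$ci_onset_obs))
    expect_equal(out$pdd_event, !is.na(tr$pdd_onset_obs))
    expect_equal(out$ci_time[out$ci_event],
                 tr$ci_onset_obs[out$ci_event])
    expect_equal(out$pdd_time[out$pdd_event],
                 tr$pdd_onset_obs[out$pdd_event])
    expect_equal(out$censor_time, tr$censor_month)
  }
})

test_that("a larger practice-gain deficit lowers the mean PD z-score", {
  means <- vapply(c(0.1, 0.5, 1.0), function(d) {
    cfg <- sdmt_config(n_hc = 250, n_pd = 600, seed = 7, deficit = d)
    sim <- simulate_cohort(cfg)
    paired <- pair_battery(sim$visits)
    m <- fit_srb_model(paired[paired$group == "HC", ], "SDMT")
    z <- orient_z(apply_srb(m, paired[paired$group == "PD", ]), "SDMT")
    mean(z, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("a null configuration makes PD and HC scores indistinguishable", {
  # Two-sample p-values should be approximately uniform across seeds.
  pvals <- vapply(1:60, function(seed) {
    cfg <- sdmt_null_config(n_hc = 50, n_pd = 50, seed = 1000 + seed)
    sim <- simulate_cohort(cfg)
    paired <- pair_battery(sim$visits)
    gain <- paired$SDMT_followup - paired$SDMT_baseline
    t.test(gain ~ paired$group)$p.value
  }, 0)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.001)
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("retest intervals vary within the configured window", {
  cfg <- small_config(n_hc = 40, n_pd = 0, seed = 9)
  sim <- simulate_cohort(cfg)
  iv <- unique(sim$visits[, c("subject_id", "retest_interval")])
  expect_true(all(iv$retest_interval >= 11 & iv$retest_interval <= 13))
  expect_gt(length(unique(iv$retest_interval)), 3)
})
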