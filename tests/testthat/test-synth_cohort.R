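test_that("cohort sampling is deterministic and respects its couplings", {
  m <- cached_map()
  cfg <- cohort_config(n_participants = 2, master_seed = 5)
  s1 <- sample_cohort(cfg, default_geo, map = m)
  s2 <- sample_cohort(cfg, default_geo, map = m)
  attr(s1, "map") <- attr(s2, "map") <- NULL
  expect_identical(s1, s2)

  big <- cohort_config(n_participants = 100, master_seed = 6)
  specs <- sample_cohort(big, default_geo, map = m)
  a1 <- vapply(specs, `[[`, numeric(1), "a1")
  ehr <- vapply(specs, `[[`, numeric(1), "expected_hit_rate")
  skill <- vapply(specs, `[[`, numeric(1), "skill")
  expect_gt(cor(ehr, a1), 0.5)        # coupling on
  expect_true(all(vapply(specs, function(s) s$a1 >= s$a1_hit, logical(1))))
  expect_true(all(vapply(specs, `[[`, numeric(1), "kr_latency_center") >= 0.817))
  expect_true(all(vapply(specs, `[[`, numeric(1), "kr_latency_center") <= 0.910))

  off <- cohort_config(n_participants = 100, master_seed = 6, a1_slope = 0)
  specs0 <- sample_cohort(off, default_geo, map = m)
  a10 <- vapply(specs0, `[[`, numeric(1), "a1")
  sk0 <- vapply(specs0, `[[`, numeric(1), "skill")
  expect_lt(abs(cor(sk0, a10)), 0.2)  # no-coupling null

  expect_error(cohort_config(n_participants = 5, skill_range = c(0.5, 0.5)),
               "degenerate")
  expect_error(cohort_config(n_participants = 1), ">= 2")
  expect_error(cohort_config(srate = 250), "500")
  expect_error(cohort_config(kr_range = c(0.5, 0.9)), "0.817")
})

test_that("behavior generation obeys the stop rule at both extremes", {
  cfg <- cohort_config(n_participants = 2, min_trials = 400,
                       max_trials = 600)
  # hopeless aim: every trial misses, stop rule fires at exactly 400
  bad <- manual_spec(theta_mean = 100, theta_sd = 1,
                     theta_dot_mean = 600, theta_dot_sd = 5, seed = 2)
  tt <- generate_behavior(bad, default_geo, cfg)
  expect_identical(nrow(tt), 400L)
  expect_false(tt$label[400] == "hit")
  expect_true(all(tt$theta_dot > 50))

  # deterministic perfect aim: session runs to the hard cap
  perfect <- manual_spec(theta_mean = 206, theta_sd = 1e-9,
                         theta_dot_mean = 600, theta_dot_sd = 1e-9, seed = 2)
  tp <- generate_behavior(perfect, default_geo, cfg)
  expect_identical(nrow(tp), 600L)
  expect_true(all(tp$label == "hit"))

  # inter-trial pacing ~2.2 s
  expect_equal(mean(diff(tt$release_time)), 2.2, tolerance = 0.05)

  # impossible validity: angular velocities never exceed 50 deg/s
  stuck <- manual_spec(theta_dot_mean = -500, theta_dot_sd = 1e-6, seed = 2)
  expect_error(generate_behavior(stuck, default_geo, cfg),
               "generation failure")
})

test_that("realized hit rates track the solution-map integral", {
  m <- cached_map()
  cfg <- cohort_config(n_participants = 2, min_trials = 400,
                       max_trials = 600)
  for (tsd in c(10, 25, 45)) {
    sp <- manual_spec(theta_mean = 206, theta_sd = tsd,
                      theta_dot_mean = 600, theta_dot_sd = 40 + 3 * tsd,
                      seed = 77 + tsd)
    tt <- generate_behavior(sp, default_geo, cfg)
    expected <- expected_hit_rate(m, 206, tsd, 600, 40 + 3 * tsd)
    expect_lt(abs(mean(tt$label == "hit") - expected), 0.05)
  }
})

test_that("markers pair releases and feedbacks at the trial's KR latency", {
  cfg <- cohort_config(n_participants = 2, min_trials = 40, max_trials = 50)
  sp <- manual_spec(noise_sd = 5, blink_rate = 10, seed = 8)
  tt <- generate_behavior(sp, default_geo, cfg)
  rec <- generate_eeg(sp, tt, cfg)
  ev <- rec$events
  expect_identical(nrow(ev), 2L * nrow(tt))
  rel <- ev[ev$label == "release", ]
  fb <- ev[ev$label == "feedback", ]
  expect_identical(rel$trial, tt$trial)
  lag <- (fb$sample[match(tt$trial, fb$trial)] -
          rel$sample[match(tt$trial, rel$trial)]) / rec$srate
  expect_true(all(abs(lag - tt$t_kr) <= 1 / rec$srate))
  # byte-identical regeneration under the same seed
  rec2 <- generate_eeg(sp, tt, cfg)
  expect_identical(rec$data, rec2$data)
})

test_that("noise-free records read out the injected components exactly", {
  cfg <- cohort_config(n_participants = 2, min_trials = 40, max_trials = 50)
  sp <- manual_spec(a1 = 12, a2 = 6, a1_hit = 3.6, seed = 9)
  tt <- manual_trials(c("error", "hit", "error"), t_kr = 0.85)
  rec <- generate_eeg(sp, tt, cfg)
  fs <- rec$srate
  rel <- rec$events[rec$events$label == "release", "sample"]

  # error trial: pulse peak at exactly +250 ms is -a1 (boxcar starts later)
  expect_equal(unname(rec$data["FCz", rel[1] + 0.25 * fs]), -12, tolerance = 1e-9)
  # mid-boxcar plateau carries -a2 alone
  expect_equal(unname(rec$data["FCz", rel[1] + 0.60 * fs]), -6, tolerance = 1e-6)
  # before 325 ms the boxcar contributes nothing
  expect_equal(unname(rec$data["FCz", rel[1] + 0.31 * fs]),
               -12 * exp(-(0.06^2) / (2 * 0.025^2)), tolerance = 1e-6)
  # hit trial: the smaller pulse, and a feedback-locked readout
  fb2 <- rec$events[rec$events$label == "feedback" &
                    rec$events$trial == 2, "sample"]
  expect_equal(unname(rec$data["FCz", fb2 + round((-0.85 + 0.25) * fs)]), -3.6,
               tolerance = 1e-9)
  # fixed scalp spread
  expect_equal(unname(rec$data["Fz", rel[1] + 0.25 * fs]), -12 * 0.8,
               tolerance = 1e-9)
  expect_equal(unname(rec$data["Pz", rel[1] + 0.25 * fs]), -12 * 0.2,
               tolerance = 1e-9)
  expect_equal(unname(rec$data["M2", rel[1] + 0.25 * fs]), 0, tolerance = 1e-12)
})

test_that("trial overlap is rejected", {
  cfg <- cohort_config(n_participants = 2)
  sp <- manual_spec(seed = 10)
  tt <- manual_trials(c("error", "hit"), iti = 1.2)
  expect_error(generate_eeg(sp, tt, cfg), "spacing")
})

test_that("averaging recovers the pulse depth under realistic noise", {
  sp <- manual_spec(a1 = 12, a1_hit = 3.6, a2 = 6, noise_sd = 10, seed = 123)
  eps <- simulate_category_epochs(sp, n_error = 50, n_hit = 50)
  avg <- average_epochs(eps$error)
  tr <- avg$amplitudes["FCz", ]
  sel <- which(avg$times >= 0.24 & avg$times <= 0.26)
  imin <- sel[which.min(tr[sel])]
  # minimum lies within 250 +/- 10 ms at depth a1 +/- 15%
  win <- which(avg$times >= 0.15 & avg$times <= 0.32)
  expect_lte(abs(avg$times[win[which.min(tr[win])]] - 0.25), 0.010)
  expect_lt(abs(-tr[imin] - 12) / 12, 0.15)
})

test_that("skill maps onto the study's hit-rate span", {
  m <- cached_map()
  cfg <- cohort_config(n_participants = 40, master_seed = 11)
  specs <- sample_cohort(cfg, default_geo, map = m)
  ehr <- vapply(specs, `[[`, numeric(1), "expected_hit_rate")
  expect_lt(min(ehr), 0.55)
  expect_gt(max(ehr), 0.90)
  expect_gt(mean(ehr), 0.6); expect_lt(mean(ehr), 0.85)
})
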