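test_that("release kinematics follow the lever geometry", {
  geo <- default_geo
  r0 <- release_from_lever(0, 0, geo)
  expect_equal(r0$position, c(0.4, -0.9), tolerance = 1e-12)
  expect_equal(r0$velocity, c(0, 0))

  r90 <- release_from_lever(90, 100, geo)
  expect_equal(r90$position, c(0, -0.5), tolerance = 1e-12)
  expect_equal(r90$velocity, c(-0.4 * 100 * pi / 180, 0), tolerance = 1e-12)

  # finite-difference oracle on the rotating lever tip
  tip <- function(th) geo$pivot + geo$lever_length *
    c(cos(th * pi / 180), sin(th * pi / 180))
  h <- 1e-6
  r <- release_from_lever(30, 200, geo)
  expect_equal(r$position, tip(30), tolerance = 1e-12)
  fd_vel <- (tip(30 + 200 * h) - tip(30 - 200 * h)) / (2 * h)
  expect_equal(r$velocity, fd_vel, tolerance = 1e-6)
})

test_that("closed-form flight matches its invariants and degenerate cases", {
  geo <- default_geo
  w <- geo$omega
  # circular orbit constructed directly (not reachable from the lever)
  rel <- structure(list(position = c(0.3, 0), velocity = c(0, 0.3 * w)),
                   class = "release_state")
  tr <- simulate_trajectory(rel, geo)
  radii <- sqrt(rowSums(tr$positions^2))
  expect_false(tr$truncated_at_post)
  expect_true(all(abs(radii - 0.3) < 1e-9))
  expect_equal(tr$times[1], 0)
  expect_true(all(diff(tr$times) > 0))
  expect_equal(tr$positions[1, ], rel$position)

  # zero-velocity throw oscillates through the post and is truncated
  tr0 <- simulate_trajectory(release_from_lever(0, 0, geo), geo)
  expect_true(tr0$truncated_at_post)
  rl <- sqrt(sum(tr0$positions[nrow(tr0$positions), ]^2))
  expect_lte(rl, geo$post_radius)
  expect_gt(sqrt(sum(tr0$positions[nrow(tr0$positions) - 1, ]^2)),
            geo$post_radius)

  expect_error(simulate_trajectory(
    structure(list(position = c(NA, 0), velocity = c(0, 0)),
              class = "release_state"), geo), "non-finite")
  expect_error(simulate_trajectory(release_from_lever(0, 0, geo), geo,
                                   duration = 0.5), "period")
})

test_that("per-axis harmonic energy is conserved along analytic flights", {
  geo <- default_geo
  rel <- random_releases(100, seed = 11)
  times <- seq(0, 2, by = 1e-3)
  for (i in seq_len(nrow(rel))) {
    r <- release_from_lever(rel$theta[i], rel$theta_dot[i], geo)
    st <- trajectory_state(r, geo, times)
    for (ax in 1:2) {
      u <- st$positions[, ax] - geo$post_center[ax]
      e <- geo$omega^2 * u^2 + st$velocities[, ax]^2
      if (max(e) > 0)
        expect_lt(diff(range(e)) / max(e), 1e-9)
    }
  }
})

test_that("scoring matches closed-form distances and the hit rule", {
  geo <- default_geo
  w <- geo$omega
  rel <- structure(list(position = c(0.3, 0), velocity = c(0, 0.3 * w)),
                   class = "release_state")
  out <- score_trial(simulate_trajectory(rel, geo), geo)
  expect_equal(out$min_distance, sqrt(0.35^2 + 1^2) - 0.3, tolerance = 1e-5)
  expect_identical(out$label, "error")
  expect_gt(out$t_kr, 0)

  # orbit passing exactly through the target center half a period in
  # (perpendicular velocity large enough that the ellipse clears the post)
  perp <- c(1.0, -0.35) / sqrt(1.0^2 + 0.35^2)
  rel2 <- structure(list(position = -geo$target_center,
                         velocity = 1.2 * perp),
                    class = "release_state")
  out2 <- score_trial(simulate_trajectory(rel2, geo), geo)
  expect_lt(out2$min_distance, 1e-5)
  expect_identical(out2$label, "hit")
  expect_equal(out2$t_kr, pi / w, tolerance = 1e-3)

  expect_error(score_trial(list(times = numeric(), positions = NULL), geo),
               "empty")
})

test_that("refined argmin agrees with a dense-grid search", {
  geo <- default_geo
  rel <- random_releases(60, seed = 21)
  sc <- score_release_states(rel$theta, rel$theta_dot, geo)
  for (i in seq_len(nrow(rel))) {
    bf <- brute_min_distance(rel$theta[i], rel$theta_dot[i], geo, dt = 1e-5)
    expect_lt(abs(sc$min_distance[i] - bf$min_distance), 1e-4)
    expect_lt(abs(sc$t_kr[i] - bf$t_kr), 5e-4)
    expect_identical(sc$truncated[i], bf$truncated)
  }
})

test_that("vectorized scoring equals the single-trial path", {
  geo <- default_geo
  rel <- random_releases(50, seed = 31)
  sc <- score_release_states(rel$theta, rel$theta_dot, geo)
  for (i in seq_len(nrow(rel))) {
    one <- score_trial(simulate_trajectory(
      release_from_lever(rel$theta[i], rel$theta_dot[i], geo), geo), geo)
    expect_equal(sc$min_distance[i], one$min_distance, tolerance = 1e-12)
    expect_equal(sc$t_kr[i], one$t_kr, tolerance = 1e-12)
    expect_identical(sc$label[i], one$label)
  }
})

test_that("minimal distance is stable under time-grid refinement", {
  geo <- default_geo
  rel <- random_releases(25, seed = 41)
  a <- score_release_states(rel$theta, rel$theta_dot, geo, dt = 1e-3)
  b <- score_release_states(rel$theta, rel$theta_dot, geo, dt = 1e-4)
  expect_true(all(abs(a$min_distance - b$min_distance) < 1e-4))
})

test_that("omega calibration recovers a fixed point and scales time", {
  geo <- default_geo
  rel <- data.frame(theta = 206, theta_dot = 600)
  g35 <- task_geometry(omega = 3.5)
  t35 <- score_release_states(rel$theta, rel$theta_dot, g35)$t_kr
  w <- calibrate_omega(geo, rel, target_t_kr = t35)
  expect_equal(w, 3.5, tolerance = 1e-3)

  # zero-velocity release: pure cosine motion, time scales exactly as 1/omega
  rel0 <- data.frame(theta = 0, theta_dot = 1e-9)
  t1 <- score_release_states(rel0$theta, rel0$theta_dot, g35)$t_kr
  g70 <- task_geometry(omega = 7.0)
  t2 <- score_release_states(rel0$theta, rel0$theta_dot, g70)$t_kr
  expect_equal(t2 / t1, 0.5, tolerance = 1e-2)

  # calibrated default geometry puts the median KR latency in the study band
  wd <- calibrate_omega(geo, default_release_set(), target_t_kr = 0.85)
  gd <- task_geometry(omega = wd)
  scd <- score_release_states(default_release_set()$theta,
                              default_release_set()$theta_dot, gd)
  expect_gte(median(scd$t_kr), 0.817)
  expect_lte(median(scd$t_kr), 0.910)
  expect_equal(wd, default_geo$omega, tolerance = 1e-3)
})

test_that("solution-space map flags validity and finds a hit region", {
  geo <- default_geo
  m <- map_solution_space(geo, seq(90, 270, by = 1), seq(20, 1010, by = 10),
                          dt = 2e-3)
  expect_identical(dim(m$label), c(181L, 100L))
  expect_true(all(!m$valid[, m$theta_dot_grid <= 50]))
  expect_true(any(m$label == "hit" & m$valid))
  # hit label implies sub-threshold distance, exhaustively
  expect_true(all(m$min_distance[m$label == "hit"] < geo$hit_threshold))
  expect_true(all(m$min_distance[m$label == "error"] >= geo$hit_threshold))
})

test_that("expected hit rate tracks the dispersion of the release strategy", {
  m <- cached_map()
  hr <- vapply(c(5, 15, 30, 50),
               function(s) expected_hit_rate(m, 206, s, 600, 40 + 3 * s),
               numeric(1))
  expect_true(all(diff(hr) < 0))
  expect_gt(hr[1], 0.9)
  expect_lt(hr[4], 0.6)
})
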