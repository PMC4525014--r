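sine_recording <- function(freq, dur = 20, srate = 500, channel = "FCz") {
  t <- seq(0, dur - 1 / srate, by = 1 / srate)
  make_recording(matrix(sin(2 * pi * freq * t), 1,
                        dimnames = list(channel, NULL)), srate = srate)
}

test_that("band-pass keeps 10 Hz nearly untouched and crushes 50 Hz", {
  rec10 <- bandpass_filter(sine_recording(10))
  mid <- 2501:7500   # steady-state region
  t <- (mid - 1) / 500
  fit <- lm(rec10$data[1, mid] ~ sin(2 * pi * 10 * t) + cos(2 * pi * 10 * t) - 1)
  amp <- sqrt(sum(coef(fit)^2))
  phase <- atan2(-coef(fit)[2], coef(fit)[1]) * 180 / pi
  expect_gte(amp, 0.95); expect_lte(amp, 1.0)
  expect_lt(abs(phase), 1)

  rec50 <- bandpass_filter(sine_recording(50))
  expect_lt(max(abs(rec50$data[1, mid])), 0.2)
})

test_that("two-pass filtering has a symmetric impulse response", {
  x <- numeric(10001); x[5001] <- 1
  rec <- make_recording(matrix(x, 1, dimnames = list("Cz", NULL)))
  y <- bandpass_filter(rec)$data[1, ]
  expect_lt(max(abs(y[5001 + 1:4000] - y[5001 - 1:4000])), 1e-8)
})

test_that("filter, re-reference and baseline are linear operators", {
  set.seed(21)
  n <- 4000
  ch <- c("FCz", "Cz", "M2", "VEOGU", "VEOGD")
  X <- matrix(rnorm(5 * n), 5, dimnames = list(ch, NULL))
  Y <- matrix(rnorm(5 * n), 5, dimnames = list(ch, NULL))
  a <- 1.7; b <- -0.6
  combo <- function(op) {
    lhs <- op(make_recording(a * X + b * Y))$data
    rhs <- a * op(make_recording(X))$data + b * op(make_recording(Y))$data
    max(abs(lhs - rhs))
  }
  expect_lt(combo(bandpass_filter), 1e-9)
  expect_lt(combo(rereference_avg_mastoids), 1e-9)
})

test_that("averaged-mastoids re-referencing follows the reference algebra", {
  n <- 1000
  ch <- c("FCz", "Cz", "M2", "VEOGU", "VEOGD")
  base <- matrix(rnorm(5 * n), 5, dimnames = list(ch, NULL))

  z <- base; z["M2", ] <- 0
  expect_equal(rereference_avg_mastoids(make_recording(z))$data, z)

  k <- base; k["M2", ] <- 2
  out <- rereference_avg_mastoids(make_recording(k))
  expect_equal(out$data["FCz", ], k["FCz", ] - 1)
  expect_equal(out$data["VEOGU", ], k["VEOGU", ])  # EOG untouched
  expect_identical(out$reference, "averaged_mastoids")

  # a source of opposite sign on the two mastoids cancels from scalp:
  # recorded scalp = p - m1, recorded M2 = m2 - m1, with m1 = -m2 = s
  s <- sin(seq_len(n) / 20)
  p <- base; p["M2", ] <- 0
  obs <- p
  obs[c("FCz", "Cz"), ] <- sweep(p[c("FCz", "Cz"), ], 2, s, `-`)
  obs["M2", ] <- -2 * s
  out2 <- rereference_avg_mastoids(make_recording(obs))
  expect_equal(out2$data["FCz", ], p["FCz", ], tolerance = 1e-12)

  expect_error(rereference_avg_mastoids(
    make_recording(base[c("FCz", "Cz"), ])), "mastoid")
})

test_that("ocular removal is the identity without EOG variance", {
  n <- 3000
  ch <- c(c("F3", "Fz", "F4", "FCz", "C3", "Cz", "C4", "P3", "Pz", "P4"),
          "M2", "VEOGU", "VEOGD")
  X <- matrix(rnorm(13 * n), 13, dimnames = list(ch, NULL))
  X[c("VEOGU", "VEOGD"), ] <- 0
  for (m in c("regression", "infomax")) {
    out <- remove_ocular(make_recording(X), method = m)
    expect_equal(out$data, X)
  }
})

test_that("both cleaning methods strip the generator's blink source", {
  sp <- manual_spec(noise_sd = 4, blink_rate = 25, seed = 17)
  cfg <- cohort_config(n_participants = 2, min_trials = 60, max_trials = 70)
  tt <- generate_behavior(sp, default_geo, cfg)
  rec <- generate_eeg(sp, tt, cfg)
  blink <- attr(rec, "truth")$blink_source
  expect_gt(abs(cor(rec$data["Fz", ], blink)), 0.5)
  for (m in c("regression", "infomax")) {
    cleaned <- remove_ocular(rec, method = m)
    expect_lt(abs(cor(cleaned$data["Fz", ], blink)), 0.1)
  }
})

test_that("infomax unmixes a noiseless super-Gaussian mixture", {
  set.seed(42)
  n <- 20000
  lap <- function(n) sample(c(-1, 1), n, TRUE) * rexp(n)
  pulses <- function(n) {
    x <- numeric(n)
    for (i in sort(sample(n - 50, 60)))
      x[i:(i + 40)] <- x[i:(i + 40)] + sin(seq(0, pi, length.out = 41))
    x * 5
  }
  S <- rbind(lap(n), pulses(n), rt(n, df = 3))
  A <- matrix(c(1, 0.5, 0.3, 0.4, 1, 0.6, 0.2, 0.3, 1), 3, 3, byrow = TRUE)
  ic <- infomax_ica(A %*% S)
  P <- ic$unmixing %*% A
  P <- P / apply(abs(P), 1, max)
  expect_true(ic$converged)
  expect_lt(max(abs(P[row(P) != col(P)])), 0.05)
  # determinism given the seed
  ic2 <- infomax_ica(A %*% S)
  expect_identical(ic$unmixing, ic2$unmixing)
})

test_that("epoch extraction slices the continuous record exactly", {
  n <- 6000
  ch <- c("FCz", "M2")
  ramp <- matrix(rep(seq_len(n), each = 2) + c(0, 1000), 2,
                 dimnames = list(ch, NULL))
  ev <- data.frame(label = rep(c("release", "feedback"), 3),
                   trial = rep(1:3, each = 2),
                   sample = c(1000, 1425, 2500, 2925, 4000, 4425),
                   stringsAsFactors = FALSE)
  rec <- make_recording(ramp, events = ev)
  es <- extract_epochs(rec, "release")
  expect_identical(dim(es$epochs), c(3L, 2L, 800L))
  expect_equal(es$times[1], -0.6)
  expect_equal(as.numeric(es$epochs[2, 1, ]), ramp[1, (2500 - 300):(2500 + 499)])
  ef <- extract_epochs(rec, "feedback")
  expect_identical(dim(ef$epochs)[3], 900L)
  expect_equal(as.numeric(ef$epochs[1, 2, ]), ramp[2, (1425 - 500):(1425 + 399)])
  expect_error(extract_epochs(rec, "release", window = c(0.5, 0.1)),
               "degenerate")

  # events whose window would leave the record are dropped and logged
  ev2 <- rbind(ev, data.frame(label = "release", trial = 4L, sample = 5900L))
  es2 <- extract_epochs(make_recording(ramp, events = ev2), "release")
  expect_identical(dim(es2$epochs)[1], 3L)
  expect_identical(es2$rejection_log$trial, 4L)
})

test_that("whole-segment baseline zeroes means and keeps shape", {
  times <- seq(-0.6, 0.998, by = 0.002)
  arr <- array(0, c(3, 1, 800), dimnames = list(NULL, "FCz", NULL))
  arr[1, 1, ] <- 5
  arr[2, 1, ] <- sin(2 * pi * 5 * (times + 0.6))[1:800]
  set.seed(31); arr[3, 1, ] <- rnorm(800)
  es <- baseline_correct(make_epochs(arr, times))
  expect_true(all(abs(es$epochs[1, 1, ]) < 1e-12))
  expect_equal(es$epochs[2, 1, ], arr[2, 1, ] - mean(arr[2, 1, ]),
               tolerance = 1e-12)
  expect_lt(abs(mean(es$epochs[3, 1, ])), 1e-9)
  expect_equal(var(es$epochs[3, 1, ]), var(arr[3, 1, ]), tolerance = 1e-12)
})

test_that("artifact rejection drops exactly the offending epochs", {
  times <- seq(-0.6, 0.998, by = 0.002)
  arr <- array(rnorm(5 * 2 * 800, sd = 5), c(5, 2, 800),
               dimnames = list(NULL, c("FCz", "VEOGU"), NULL))
  es <- reject_artifacts(make_epochs(arr, times))
  expect_identical(dim(es$epochs)[1], 5L)

  arr2 <- arr
  arr2[3, 1, 400] <- 150                      # amplitude violation
  arr2[5, 1, 200:201] <- c(-30, 30)           # gradient violation
  arr2[2, 2, 100] <- 500                      # EOG channel: never checked
  es2 <- reject_artifacts(make_epochs(arr2, times))
  expect_identical(es2$trial_ids, c(1L, 2L, 4L))
  log <- es2$rejection_log
  expect_identical(log$criterion[log$trial == 3], "amplitude")
  expect_identical(log$criterion[log$trial == 5], "gradient")
})

test_that("rejections grow with the blink rate when cleaning is off", {
  cfg <- cohort_config(n_participants = 2, min_trials = 50, max_trials = 60)
  counts <- vapply(c(0, 8, 30), function(br) {
    sp <- manual_spec(noise_sd = 8, blink_rate = br, seed = 55)
    tt <- generate_behavior(sp, default_geo, cfg)
    rec <- generate_eeg(sp, tt, cfg)
    es <- reject_artifacts(baseline_correct(extract_epochs(rec, "release")))
    sum(es$rejection_log$criterion %in% c("amplitude", "gradient"))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
})
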