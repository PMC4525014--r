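# Shared fixtures and independent oracles, built in code at test time.

default_geo <- task_geometry()

# The default placement solution map is expensive; compute it once per run.
cached_map <- local({
  map <- NULL
  function() {
    if (is.null(map)) map <<- map_solution_space(default_geo, seq(90, 270, 1),
                                                 seq(70, 1060, 10), dt = 2e-3)
    map
  }
})

# Independent oracle: classical 4th-order Runge-Kutta integration of the
# ball dynamics r'' = -omega^2 (r - post), vectorized over release states.
# Returns positions at `times` as a list of x and y matrices (state x time).
rk4_trajectories <- function(theta, theta_dot, geometry, times) {
  n <- length(theta)
  th <- theta * pi / 180
  thd <- theta_dot * pi / 180
  L <- geometry$lever_length
  w2 <- geometry$omega^2
  px <- geometry$post_center[1]; py <- geometry$post_center[2]
  S <- cbind(x = geometry$pivot[1] + L * cos(th),
             y = geometry$pivot[2] + L * sin(th),
             vx = -L * thd * sin(th),
             vy = L * thd * cos(th))
  deriv <- function(s) cbind(s[, 3], s[, 4],
                             -w2 * (s[, 1] - px), -w2 * (s[, 2] - py))
  dt <- diff(times[1:2])
  X <- matrix(NA_real_, n, length(times))
  Y <- matrix(NA_real_, n, length(times))
  X[, 1] <- S[, 1]; Y[, 1] <- S[, 2]
  for (k in 2:length(times)) {
    k1 <- deriv(S)
    k2 <- deriv(S + dt / 2 * k1)
    k3 <- deriv(S + dt / 2 * k2)
    k4 <- deriv(S + dt * k3)
    S <- S + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    X[, k] <- S[, 1]; Y[, k] <- S[, 2]
  }
  list(x = X, y = Y)
}

# Independent oracle: dense-grid minimal distance for one release state,
# positions computed from the closed form re-derived here (not the package
# path), truncated at the post, no sub-sample refinement.
brute_min_distance <- function(theta, theta_dot, geometry, dt = 1e-5) {
  w <- geometry$omega
  th <- theta * pi / 180
  thd <- theta_dot * pi / 180
  L <- geometry$lever_length
  t <- seq(0, 2 * pi / w, by = dt)
  x0 <- geometry$pivot[1] + L * cos(th) - geometry$post_center[1]
  y0 <- geometry$pivot[2] + L * sin(th) - geometry$post_center[2]
  vx <- -L * thd * sin(th); vy <- L * thd * cos(th)
  x <- x0 * cos(w * t) + vx / w * sin(w * t)
  y <- y0 * cos(w * t) + vy / w * sin(w * t)
  inside <- which(x * x + y * y <= geometry$post_radius^2)
  if (length(inside)) {
    keep <- seq_len(inside[1])
    x <- x[keep]; y <- y[keep]; t <- t[keep]
  }
  d <- sqrt((x + geometry$post_center[1] - geometry$target_center[1])^2 +
            (y + geometry$post_center[2] - geometry$target_center[2])^2)
  i <- which.min(d)
  list(min_distance = d[i], t_kr = t[i], truncated = length(inside) > 0)
}

# Independent oracle: brute-force filter-and-sort categorization.
brute_categorize <- function(trials, hit_max = 0.05, err_min = 0.12,
                             cap = 50L) {
  hits <- trials[trials$min_distance < hit_max, ]
  hits <- hits[order(hits$min_distance, hits$trial), ]
  errs <- trials[trials$min_distance > err_min, ]
  errs <- errs[order(-errs$min_distance, errs$trial), ]
  list(hit_ids = sort(utils::head(hits$trial, cap)),
       error_ids = sort(utils::head(errs$trial, cap)))
}

# Random plausible release states (valid-velocity region of the task).
random_releases <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(theta = runif(n, 90, 270), theta_dot = runif(n, 60, 1000))
}

# Minimal synthetic recording with named channels.
make_recording <- function(data, srate = 500, events = NULL,
                           reference = "left_mastoid") {
  if (is.null(events)) events <- data.frame(label = character(),
                                            trial = integer(),
                                            sample = integer(),
                                            stringsAsFactors = FALSE)
  eeg_recording(data, srate, rownames(data), events, reference)
}

# A participant spec with explicit fields, bypassing cohort sampling.
manual_spec <- function(id = "T01", a1 = 12, a2 = 6, a1_hit = 3.6,
                        kr = 0.85, noise_sd = 0, blink_rate = 0, seed = 99,
                        theta_mean = 206, theta_sd = 12,
                        theta_dot_mean = 600, theta_dot_sd = 80) {
  sp <- list(id = id, skill = NA_real_,
             theta_mean = theta_mean, theta_sd = theta_sd,
             theta_dot_mean = theta_dot_mean, theta_dot_sd = theta_dot_sd,
             expected_hit_rate = NA_real_,
             a1 = a1, a2 = a2, a1_hit = a1_hit,
             kr_latency_center = kr, noise_sd = noise_sd,
             blink_rate = blink_rate, seed = seed)
  class(sp) <- "participant_spec"
  sp
}

# Wrap a trials x channels x time array as an epoch_set.
make_epochs <- function(arr, times, sync = "release") {
  es <- list(epochs = arr, times = times, trial_ids = seq_len(dim(arr)[1]),
             channels = dimnames(arr)[[2]], srate = 500, sync = sync,
             window = range(times),
             rejection_log = data.frame(trial = integer(),
                                        criterion = character()))
  class(es) <- "epoch_set"
  es
}

# Wrap a single-channel trace as an erp_waveform.
wave_from <- function(x, times, channel = "FCz", sync = "release") {
  w <- list(amplitudes = matrix(x, 1, dimnames = list(channel, NULL)),
            times = times, channels = channel, sync = sync,
            n_trials = 1L, category = NA_character_)
  class(w) <- "erp_waveform"
  w
}

# Hand-built one-participant trial table on the EEG sample grid.
manual_trials <- function(labels, t_kr = 0.85, id = "T01", iti = 2.2) {
  n <- length(labels)
  data.frame(participant = id, trial = seq_len(n),
             theta = rep(206, n), theta_dot = rep(600, n),
             min_distance = ifelse(labels == "hit", 0.02, 0.2),
             label = labels,
             t_kr = rep(t_kr, length.out = n),
             release_time = round((2 + (seq_len(n) - 1) * iti) * 500) / 500,
             stringsAsFactors = FALSE)
}
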