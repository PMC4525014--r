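#' Cohort-level generation settings
#'
#' Collects every tunable of the synthetic cohort: its size, the skill
#' distribution, the coupling between skill and the first-deflection
#' amplitude, the EEG channel set and noise structure, and the session
#' pacing.  Defaults emulate the study conditions: 29 participants, about
#' 400--437 trials each, hit rates spanning roughly 48--96%,
#' knowledge-of-results latencies within 817--910 ms, 500 Hz EEG on ten
#' 10--20 scalp channels plus right mastoid and four EOG channels.
#'
#' @param n_participants Cohort size (>= 2), default 29.
#' @param skill_range Range of the uniform skill distribution on `[0, 1]`.
#' @param kr_range Range (s) from which per-participant knowledge-of-results
#'   latency centers are drawn; a sub-range of the task's 0.817--0.910 s
#'   band that the default geometry can realize on its solution manifold.
#' @param a1_base,a1_slope,a1_noise_sd First-deflection amplitude model
#'   (microvolts): `a1 = a1_base + a1_slope * E[hit rate] + N(0,
#'   a1_noise_sd)`, truncated below at 0.5.  A positive slope couples skill
#'   to amplitude, mirroring the observed negative correlation between hit
#'   percentage and (negative) deflection amplitude.
#' @param a1_hit_frac Hit-trial pulse amplitude as a fraction of `a1`.
#' @param a2_base,a2_noise_sd Second (broad) deflection amplitude model
#'   (microvolts).
#' @param noise_sd Background EEG noise SD per channel (microvolts).
#' @param blink_rate Blink events per minute on the EOG channels.
#' @param channels EEG channel labels to synthesize.
#' @param srate Sampling rate (Hz); fixed at 500 for study-conform data.
#' @param iti_mean,iti_sd Inter-trial (release-to-release) interval (s).
#' @param min_trials Session stop rule: the session ends with the first
#'   error after this many trials (default 400).
#' @param max_trials Hard cap on session length.
#' @param master_seed Master seed; all per-participant seeds derive from it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 29L,
                          skill_range = c(0, 1),
                          kr_range = c(0.820, 0.885),
                          a1_base = 4, a1_slope = 10, a1_noise_sd = 1.0,
                          a1_hit_frac = 0.3,
                          a2_base = 6, a2_noise_sd = 1,
                          noise_sd = 10, blink_rate = 10,
                          channels = c(scalp_channels(), mastoid_channel(),
                                       eog_channels()),
                          srate = 500,
                          iti_mean = 2.2, iti_sd = 0.15,
                          min_trials = 400L, max_trials = 600L,
                          master_seed = 1L) {
  if (n_participants < 2) stop("n_participants must be >= 2")
  if (srate != 500) stop("study-conform data are sampled at 500 Hz")
  if (kr_range[1] < 0.817 || kr_range[2] > 0.910)
    stop("kr_range must lie within [0.817, 0.910] s")
  if (diff(skill_range) == 0 && a1_slope != 0 && n_participants > 1)
    stop("degenerate skill distribution with amplitude coupling requested")
  cfg <- list(n_participants = as.integer(n_participants),
              skill_range = skill_range, kr_range = kr_range,
              a1_base = a1_base, a1_slope = a1_slope,
              a1_noise_sd = a1_noise_sd, a1_hit_frac = a1_hit_frac,
              a2_base = a2_base, a2_noise_sd = a2_noise_sd,
              noise_sd = noise_sd, blink_rate = blink_rate,
              channels = channels, srate = srate,
              iti_mean = iti_mean, iti_sd = iti_sd,
              min_trials = as.integer(min_trials),
              max_trials = as.integer(max_trials),
              master_seed = as.integer(master_seed))
  class(cfg) <- "cohort_config"
  cfg
}

# Skill in [0, 1] -> release-angle dispersion (deg).  Fixed once against the
# default geometry's solution map so the cohort hit rates span ~48-96%.
skill_to_theta_sd <- function(skill) 50 - 35 * skill
theta_sd_to_theta_dot_sd <- function(theta_sd) 40 + 3 * theta_sd

# Session cache for the (deterministic, geometry-keyed) default solution map.
.map_cache <- new.env(parent = emptyenv())

default_solution_map <- function(geometry) {
  key <- paste(format(unlist(unclass(geometry)), digits = 15), collapse = ",")
  if (!is.null(.map_cache[[key]])) return(.map_cache[[key]])
  map <- map_solution_space(geometry, seq(90, 270, by = 1),
                            seq(70, 1060, by = 10))
  .map_cache[[key]] <- map
  map
}

#' Sample a cohort of participant specifications
#'
#' Draws per-participant skill and knowledge-of-results latency, places each
#' participant's aim point on the solution manifold at the cell whose
#' closest-approach time matches the drawn latency, converts skill to
#' release dispersions, computes the expected hit rate by normal-mass
#' integration over the solution map, and couples the first-deflection
#' amplitude to that expected hit rate.  Fully deterministic given the
#' master seed.
#'
#' @param config A [cohort_config()].
#' @param geometry A [task_geometry()] (calibrated).
#' @param map Optional precomputed [map_solution_space()]; computed from the
#'   default placement grids when missing.
#' @return List of `participant_spec` objects; the map is attached as
#'   attribute `"map"`.
#' @export
sample_cohort <- function(config, geometry = task_geometry(), map = NULL) {
  if (is.null(map)) map <- default_solution_map(geometry)
  aims <- aim_points(map)
  n <- config$n_participants
  set.seed(config$master_seed)
  seeds <- sample.int(2^31 - 10L, n)
  skill <- stats::runif(n, config$skill_range[1], config$skill_range[2])
  kr <- stats::runif(n, config$kr_range[1], config$kr_range[2])
  a1_noise <- stats::rnorm(n, 0, config$a1_noise_sd)
  a2 <- pmax(config$a2_base + stats::rnorm(n, 0, config$a2_noise_sd), 0)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    aim <- aims[which.min(abs(aims$t_kr - kr[i])), ]
    theta_sd <- skill_to_theta_sd(skill[i])
    theta_dot_sd <- theta_sd_to_theta_dot_sd(theta_sd)
    ehr <- expected_hit_rate(map, aim$theta, theta_sd,
                             aim$theta_dot, theta_dot_sd)
    a1 <- max(config$a1_base + config$a1_slope * ehr + a1_noise[i], 0.5)
    sp <- list(id = sprintf("P%02d", i), skill = skill[i],
               theta_mean = aim$theta, theta_sd = theta_sd,
               theta_dot_mean = aim$theta_dot, theta_dot_sd = theta_dot_sd,
               expected_hit_rate = ehr,
               a1 = a1, a2 = a2[i], a1_hit = config$a1_hit_frac * a1,
               kr_latency_center = aim$t_kr,
               noise_sd = config$noise_sd, blink_rate = config$blink_rate,
               seed = seeds[i])
    class(sp) <- "participant_spec"
    specs[[i]] <- sp
  }
  attr(specs, "map") <- map
  specs
}

#' Generate one participant's behavioral session
#'
#' Draws release angle and angular velocity i.i.d. normal around the
#' participant's aim point, redraws trials violating the 50 deg/s validity
#' rule, scores every throw through the task physics, and applies the
#' session stop rule: the session ends with the first miss after
#' `min_trials` trials (subject to the `max_trials` hard cap).  Release
#' times advance by the configured inter-trial interval.
#'
#' @param spec A `participant_spec`.
#' @param geometry A [task_geometry()].
#' @param config A [cohort_config()] (pacing and stop-rule settings).
#' @return A trial-table data frame (one row per throw).
#' @export
generate_behavior <- function(spec, geometry = task_geometry(),
                              config = cohort_config()) {
  set.seed(spec$seed)
  need <- config$max_trials
  theta <- numeric(0); theta_dot <- numeric(0)
  draws <- 0L
  while (length(theta) < need) {
    k <- need - length(theta)
    th <- stats::rnorm(k, spec$theta_mean, spec$theta_sd)
    td <- stats::rnorm(k, spec$theta_dot_mean, spec$theta_dot_sd)
    ok <- td > 50
    theta <- c(theta, th[ok]); theta_dot <- c(theta_dot, td[ok])
    draws <- draws + k
    if (draws >= 10000L && length(theta) == 0)
      stop("generation failure: no valid trial in 10000 draws for ", spec$id)
    if (draws > 50 * need) stop("generation failure: validity rate too low for ", spec$id)
  }
  sc <- score_release_states(theta, theta_dot, geometry)
  miss <- which(sc$label != "hit" & seq_len(need) >= config$min_trials)
  ntr <- if (length(miss)) miss[1] else config$max_trials
  sc <- sc[seq_len(ntr), ]
  iti <- pmax(stats::rnorm(ntr, config$iti_mean, config$iti_sd), 1.9)
  release_time <- 2.0 + cumsum(iti) - iti[1]
  # snap to the EEG sample grid so event-locked components land on samples
  release_time <- round(release_time * config$srate) / config$srate
  data.frame(participant = spec$id, trial = seq_len(ntr),
             theta = sc$theta, theta_dot = sc$theta_dot,
             min_distance = sc$min_distance, label = sc$label,
             t_kr = sc$t_kr, release_time = release_time,
             stringsAsFactors = FALSE)
}

# --- deterministic signal building blocks -------------------------------

#' 1/f ("pink") background noise
#'
#' FFT-shaped Gaussian noise with power falling as 1/f above a 0.5 Hz knee
#' (flat below it, emulating the amplifier high-pass region), rescaled to
#' the requested standard deviation.  Deterministic given the RNG state.
#'
#' @param n Number of samples.
#' @param srate Sampling rate (Hz).
#' @param sd Target standard deviation.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, srate, sd = 1) {
  if (sd == 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3, 5))   # composite FFT length, truncated after
  white <- stats::rnorm(m)
  f <- seq(0, m - 1) / m * srate
  f <- pmin(f, srate - f)
  w <- 1 / sqrt(pmax(f, 0.5))
  w[1] <- 0
  x <- Re(stats::fft(stats::fft(white) * w, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x) * sd
}

gaussian_pulse <- function(times, center, sigma, amplitude) {
  amplitude * exp(-((times - center)^2) / (2 * sigma^2))
}

# Boxcar from `onset` to `offset` with half-cosine ramps of width `ramp`
# lying inside the interval, so the contribution is exactly zero outside
# [onset, offset].
smoothed_boxcar <- function(times, onset, offset, amplitude, ramp = 0.02) {
  y <- numeric(length(times))
  if (offset <= onset) return(y)
  ramp <- min(ramp, (offset - onset) / 2)
  up <- times >= onset & times < onset + ramp
  y[up] <- 0.5 * (1 - cos(pi * (times[up] - onset) / ramp))
  y[times >= onset + ramp & times <= offset - ramp] <- 1
  dn <- times > offset - ramp & times <= offset
  y[dn] <- 0.5 * (1 - cos(pi * (offset - times[dn]) / ramp))
  amplitude * y
}

blink_template <- function(times, onset, amplitude, width = 0.4) {
  sel <- times >= onset & times <= onset + width
  y <- numeric(length(times))
  y[sel] <- amplitude * 0.5 * (1 - cos(2 * pi * (times[sel] - onset) / width))
  y
}

# Fixed fronto-central scalp spread of the error components (unit at FCz).
component_spread <- function() {
  c(FCz = 1.0, Fz = 0.8, Cz = 0.8, F3 = 0.5, F4 = 0.5, C3 = 0.5, C4 = 0.5,
    P3 = 0.2, Pz = 0.2, P4 = 0.2)
}

# Fixed propagation of the blink source into the montage (unit at VEOGU).
blink_spread <- function() {
  c(VEOGU = 1.0, VEOGD = -0.6, HEOGL = 0.12, HEOGR = 0.10,
    F3 = 0.45, Fz = 0.50, F4 = 0.45, FCz = 0.35,
    C3 = 0.15, Cz = 0.18, C4 = 0.15, P3 = 0.05, Pz = 0.05, P4 = 0.05)
}

# Error-component time courses at FCz for one trial, on the continuous
# sample grid.  Returns a list of (index, values) contributions.
trial_components_fcz <- function(spec, label, release_time, t_kr, srate,
                                 pulse_sigma = 0.025, boxcar_onset = 0.325) {
  span <- if (label == "hit") c(0.25 - 6 * pulse_sigma, 0.25 + 6 * pulse_sigma)
          else c(0.25 - 6 * pulse_sigma, t_kr + 0.01)
  i0 <- floor((release_time + span[1]) * srate)
  i1 <- ceiling((release_time + span[2]) * srate)
  idx <- i0:i1
  tt <- idx / srate - release_time   # time after release; release on-grid
  v <- gaussian_pulse(tt, 0.25, pulse_sigma,
                      if (label == "hit") -spec$a1_hit else -spec$a1)
  if (label != "hit")
    v <- v + smoothed_boxcar(tt, boxcar_onset, t_kr, -spec$a2)
  list(idx = idx + 1L, values = v)
}

#' Generate one participant's continuous synthetic EEG
#'
#' Builds a continuous 500 Hz multichannel record spanning the behavioral
#' session: 1/f background plus a 10 Hz rhythm on every channel (the right
#' mastoid carries its own, independent noise), an error-specific sharp
#' negative Gaussian pulse peaking 250 ms after release (width 25 ms,
#' amplitude `-a1`) plus a broad smoothed-boxcar negativity from 325 ms
#' after release until that trial's knowledge-of-results time (amplitude
#' `-a2`) on error trials, a smaller pulse (`-a1_hit`) on hit trials, all
#' injected at FCz and spread to neighboring channels by a fixed
#' fronto-central attenuation map; blink artifacts on the EOG channels
#' propagated into frontal channels with fixed coefficients; and `release`
#' / `feedback` event markers for every trial.  Byte-identical output given
#' the participant seed.
#'
#' @param spec A `participant_spec`.
#' @param trials The participant's trial table.
#' @param config A [cohort_config()].
#' @return An [eeg_recording()].
#' @export
generate_eeg <- function(spec, trials, config = cohort_config()) {
  if (!nrow(trials)) stop("empty trial table")
  fs <- config$srate
  if (any(diff(trials$release_time) < 1.6))
    stop("generation error: release spacing below the epoch span (1.6 s)")
  dur <- trials$release_time[nrow(trials)] + 2.0
  n <- ceiling(dur * fs)
  chans <- config$channels
  set.seed(spec$seed + 1L)
  data <- matrix(0, nrow = length(chans), ncol = n,
                 dimnames = list(chans, NULL))
  tglob <- (seq_len(n) - 1) / fs
  for (j in seq_along(chans)) {
    ctype <- channel_type(chans[j])
    nsd <- if (ctype == "eog") 0.3 * spec$noise_sd else spec$noise_sd
    if (nsd > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      data[j, ] <- pink_noise(n, fs, 0.8 * nsd) +
        sqrt(2) * 0.6 * nsd * sin(2 * pi * 10 * tglob + phase)
    }
  }
  spread <- component_spread()
  comp <- numeric(n)
  for (i in seq_len(nrow(trials))) {
    cc <- trial_components_fcz(spec, trials$label[i], trials$release_time[i],
                               trials$t_kr[i], fs)
    ok <- cc$idx >= 1 & cc$idx <= n
    comp[cc$idx[ok]] <- comp[cc$idx[ok]] + cc$values[ok]
  }
  for (ch in intersect(names(spread), chans))
    data[ch, ] <- data[ch, ] + spread[ch] * comp
  bl <- numeric(n)
  if (spec$blink_rate > 0) {
    nb <- stats::rpois(1, spec$blink_rate / 60 * dur)
    if (nb > 0) {
      onsets <- sort(stats::runif(nb, 0, dur - 0.4))
      amps <- pmax(stats::rnorm(nb, 160, 40), 30)
      for (b in seq_len(nb)) {
        i0 <- max(1L, floor(onsets[b] * fs) + 1L)
        i1 <- min(n, ceiling((onsets[b] + 0.4) * fs) + 1L)
        bl[i0:i1] <- bl[i0:i1] +
          blink_template(tglob[i0:i1], onsets[b], amps[b])
      }
      bs <- blink_spread()
      for (ch in intersect(names(bs), chans))
        data[ch, ] <- data[ch, ] + bs[ch] * bl
    }
  }
  rel_smp <- as.integer(round(trials$release_time * fs)) + 1L
  fb_smp <- rel_smp + as.integer(round(trials$t_kr * fs))
  ev <- rbind(data.frame(label = "release", trial = trials$trial,
                         sample = rel_smp, stringsAsFactors = FALSE),
              data.frame(label = "feedback", trial = trials$trial,
                         sample = fb_smp, stringsAsFactors = FALSE))
  ev <- ev[order(ev$sample), ]
  rownames(ev) <- NULL
  rec <- eeg_recording(data, fs, chans, ev, reference = "left_mastoid")
  # ground truth for validation: injected FCz component and blink source
  attr(rec, "truth") <- list(fcz_component = comp, blink_source = bl)
  rec
}

#' Directly synthesize category epochs at one channel
#'
#' Reduced generator for Monte-Carlo calibration studies: produces
#' release-locked epochs of the two trial categories at a single channel,
#' with the same component shapes and background noise model as
#' [generate_eeg()], but without building (and re-cutting) a continuous
#' session record.  Used where hundreds of replicate cohorts are needed.
#'
#' @param spec A `participant_spec`.
#' @param n_error,n_hit Number of epochs per category.
#' @param t_kr Per-error-trial knowledge-of-results latencies (s); defaults
#'   to the participant's latency center.
#' @param srate Sampling rate (Hz).
#' @param window Epoch window (s relative to release).
#' @return List with `error` and `hit` epoch sets (single channel `FCz`).
#' @export
simulate_category_epochs <- function(spec, n_error = 50L, n_hit = 50L,
                                     t_kr = NULL, srate = 500,
                                     window = c(-0.6, 1.0)) {
  set.seed(spec$seed + 2L)
  nsmp <- round((window[2] - window[1]) * srate)
  times <- window[1] + (seq_len(nsmp) - 1) / srate
  if (is.null(t_kr)) t_kr <- rep(spec$kr_latency_center, n_error)
  stopifnot(length(t_kr) == n_error)
  mk <- function(k, label, tkr) {
    ep <- array(0, c(k, 1, nsmp), dimnames = list(NULL, "FCz", NULL))
    for (i in seq_len(k)) {
      x <- pink_noise(nsmp, srate, 0.8 * spec$noise_sd) +
        sqrt(2) * 0.6 * spec$noise_sd *
          sin(2 * pi * 10 * (times - times[1]) + stats::runif(1, 0, 2 * pi))
      x <- x + gaussian_pulse(times, 0.25, 0.025,
                              if (label == "hit") -spec$a1_hit else -spec$a1)
      if (label == "error")
        x <- x + smoothed_boxcar(times, 0.325, tkr[i], -spec$a2)
      ep[i, 1, ] <- x
    }
    es <- list(epochs = ep, times = times, trial_ids = seq_len(k),
               channels = "FCz", srate = srate, sync = "release",
               window = window,
               rejection_log = data.frame(trial = integer(),
                                          criterion = character(),
                                          stringsAsFactors = FALSE))
    class(es) <- "epoch_set"
    es
  }
  list(error = mk(n_error, "error", t_kr), hit = mk(n_hit, "hit", NULL))
}
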