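#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the given per-pass order and applies it
#' forward and backward (two-pass filtering: zero net phase shift, squared
#' magnitude response, effective order doubled).  Edge transients are
#' controlled by reflection padding; because the 0.2 Hz high-pass corner has
#' a multi-second impulse response, the pad length is tied to the low corner
#' (three time constants, `3 * srate / low` samples) rather than to the
#' filter order alone.  Only scalp and mastoid channels are filtered; the
#' EOG channels pass through unchanged (they are used as artifact
#' references, not analyzed).
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges (Hz); defaults 0.2--30.
#' @param order Per-pass Butterworth order (default 2).
#' @param channels Labels to filter; default scalp + mastoid.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low = 0.2, high = 30, order = 2,
                            channels = NULL) {
  nyq <- rec$srate / 2
  if (low <= 0 || high >= nyq || low >= high)
    stop("band must satisfy 0 < low < high < Nyquist")
  if (is.null(channels))
    channels <- rec$labels[channel_type(rec$labels) %in% c("scalp", "mastoid")]
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  for (ch in channels)
    rec$data[ch, ] <- filtfilt_reflect(bf, rec$data[ch, ], rec$srate, low)
  rec
}

# Two-pass (forward-backward) filtering with reflection padding.
filtfilt_reflect <- function(bf, x, srate, low) {
  n <- length(x)
  pad <- min(n - 1L, ceiling(3 * srate / low))
  xp <- c(2 * x[1] - x[(pad + 1L):2L],
          x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filter(bf, xp)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[pad + seq_len(n)]
}

#' Re-reference scalp channels to averaged mastoids
#'
#' Recordings are referenced online to the left mastoid; with the right
#' mastoid recorded as channel `M2`, switching to the averaged-mastoids
#' reference is the algebraic transform `x' = x - M2/2` for every scalp
#' channel.  EOG channels and `M2` itself are untouched.
#'
#' @param rec An [eeg_recording()] with online reference `left_mastoid`.
#' @return The re-referenced recording, reference descriptor updated.
#' @export
rereference_avg_mastoids <- function(rec) {
  m2 <- mastoid_channel()
  if (!m2 %in% rec$labels) stop("missing right-mastoid channel ", m2)
  if (!identical(rec$reference, "left_mastoid"))
    stop("expected online reference 'left_mastoid', got ", rec$reference)
  sc <- rec$labels[channel_type(rec$labels) == "scalp"]
  rec$data[sc, ] <- sweep(rec$data[sc, , drop = FALSE], 2,
                          rec$data[m2, ] / 2, `-`)
  rec$reference <- "averaged_mastoids"
  rec
}

bipolar_eog <- function(rec) {
  need <- eog_channels()
  if (sum(need %in% rec$labels) < 2) stop("need at least 2 EOG channels")
  heog <- if (all(c("HEOGL", "HEOGR") %in% rec$labels))
    rec$data["HEOGL", ] - rec$data["HEOGR", ] else NULL
  veog <- if (all(c("VEOGU", "VEOGD") %in% rec$labels))
    rec$data["VEOGU", ] - rec$data["VEOGD", ] else NULL
  cbind(HEOG = heog, VEOG = veog)
}

#' Remove ocular artifacts from a continuous recording
#'
#' Two methods operating on the continuous (filtered) signal:
#' \describe{
#'   \item{regression}{least-squares propagation coefficients of each scalp
#'     channel onto the bipolar horizontal and vertical EOG derivations,
#'     subtracted from the scalp channels.}
#'   \item{infomax}{natural-gradient Infomax independent component analysis
#'     (logistic nonlinearity, learning-rate annealing, convergence when the
#'     relative weight change drops below `tol` or after `max_iter` sweeps)
#'     on the scalp channels; components whose time courses correlate with
#'     either bipolar EOG at `|r| > 0.8` are zeroed and the data re-mixed.
#'     On non-convergence a warning is issued and the regression method is
#'     used instead.}
#' }
#' If the EOG channels carry no variance both methods are the identity.
#'
#' @param rec An [eeg_recording()] with at least two EOG channels.
#' @param method `"regression"`, `"infomax"`, or `"none"`.
#' @param cor_limit Absolute EOG correlation above which a component is
#'   removed (infomax).
#' @param max_samples Number of evenly spaced samples used to learn the
#'   unmixing matrix (the full record is then unmixed and re-mixed).
#' @param tol,max_iter Infomax convergence parameters.
#' @param seed Seed of the ICA block permutation (determinism).
#' @return The cleaned recording; attribute `"ocular"` records the method and
#'   removed components.
#' @export
remove_ocular <- function(rec, method = c("infomax", "regression", "none"),
                          cor_limit = 0.8, max_samples = 20000L,
                          tol = 1e-6, max_iter = 512L, seed = 1L) {
  method <- match.arg(method)
  if (method == "none") return(rec)
  eog <- bipolar_eog(rec)
  if (all(apply(eog, 2, stats::var) < .Machine$double.eps)) {
    attr(rec, "ocular") <- list(method = method, removed = integer())
    return(rec)
  }
  sc <- rec$labels[channel_type(rec$labels) == "scalp"]
  X <- rec$data[sc, , drop = FALSE]
  if (method == "regression") {
    rec$data[sc, ] <- regress_out_eog(X, eog)
    attr(rec, "ocular") <- list(method = "regression", removed = integer())
    return(rec)
  }
  nmin <- 20 * nrow(X)^2
  if (ncol(X) < nmin)
    stop(sprintf("infomax needs at least %d samples (20 x channels^2), got %d",
                 nmin, ncol(X)))
  ica <- infomax_ica(X, max_samples = max_samples, tol = tol,
                     max_iter = max_iter, seed = seed)
  if (!ica$converged) {
    warning("Infomax ICA did not converge; falling back to regression")
    rec$data[sc, ] <- regress_out_eog(X, eog)
    attr(rec, "ocular") <- list(method = "regression_fallback",
                                removed = integer())
    return(rec)
  }
  S <- ica$unmixing %*% sweep(X, 1, ica$center, `-`)
  rmax <- apply(abs(stats::cor(t(S), eog)), 1, max)
  bad <- which(rmax > cor_limit)
  if (length(bad)) {
    S[bad, ] <- 0
    rec$data[sc, ] <- ica$mixing %*% S + ica$center
  }
  attr(rec, "ocular") <- list(method = "infomax", removed = bad,
                              eog_correlation = rmax)
  rec
}

regress_out_eog <- function(X, eog) {
  E <- scale(eog, scale = FALSE)
  Y <- scale(t(X), scale = FALSE)      # samples x channels, centered
  B <- solve(crossprod(E), crossprod(E, Y))
  X - t(E %*% B)
}

#' Natural-gradient Infomax independent component analysis
#'
#' Batch Infomax with the logistic nonlinearity on sphered data: weight
#' updates `dW = lr * (I + (1 - 2 g(u)) u^T / B) W` over data blocks visited
#' in a seeded random order per sweep, with the learning rate annealed
#' whenever successive weight-change directions disagree by more than 60
#' degrees.  Initial weights are the identity and the permutation stream is
#' seeded, so the decomposition is fully deterministic given `seed`.
#' Sweeping stops when the Frobenius norm of the per-sweep weight change
#' drops below `tol` (exactly separable data) or after `max_iter` sweeps
#' (typical EEG, whose near-Gaussian background subspace has no unique
#' rotation to converge to); `converged` is `FALSE` only when the weights
#' blow up irrecoverably.  The logistic nonlinearity targets super-Gaussian
#' sources, which is what ocular artifacts are.
#'
#' @param X Channels x samples matrix.
#' @param max_samples Evenly spaced subsample used for learning.
#' @param lrate Initial learning rate.
#' @param tol Early-stopping threshold on the Frobenius norm of the weight
#'   change per sweep.
#' @param max_iter Maximum sweeps.
#' @param seed Seed of the per-sweep block permutation.
#' @return List with `unmixing` (sources = unmixing %*% (X - center)),
#'   `mixing` (its inverse), `center`, `converged`, `iterations`.
#' @export
infomax_ica <- function(X, max_samples = 20000L, lrate = NULL,
                        tol = 1e-6, max_iter = 512L, seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  nch <- nrow(X)
  center <- rowMeans(X)
  Xc <- X - center
  idx <- if (ncol(Xc) > max_samples)
    round(seq(1, ncol(Xc), length.out = max_samples)) else seq_len(ncol(Xc))
  Z <- Xc[, idx, drop = FALSE]
  cv <- tcrossprod(Z) / ncol(Z)
  eg <- eigen(cv, symmetric = TRUE)
  if (any(eg$values < 1e-12 * eg$values[1]))
    stop("rank-deficient data: cannot sphere")
  sph <- eg$vectors %*% diag(1 / sqrt(eg$values), nch) %*% t(eg$vectors)
  Z <- sph %*% Z
  n <- ncol(Z)
  block <- max(8L, floor(sqrt(n / 3)))
  if (is.null(lrate)) lrate <- 0.01 / log(nch^2)
  W <- diag(nch)
  I <- diag(nch)
  delta_old <- NULL
  converged <- TRUE
  it <- 0L
  restarts <- 0L
  starts <- seq(1L, n - block + 1L, by = block)
  perm_rng <- local({
    rs <- as.integer(seed)
    function(n) { set.seed(rs); rs <<- rs + 1L; sample.int(n) }
  })
  while (it < max_iter) {
    it <- it + 1L
    W0 <- W
    blowup <- FALSE
    perm <- perm_rng(n)
    for (s in starts) {
      u <- W %*% Z[, perm[s:(s + block - 1L)], drop = FALSE]
      y <- 1 / (1 + exp(-u))
      W <- W + lrate * (I + ((1 - 2 * y) %*% t(u)) / block) %*% W
      if (max(abs(W)) > 1e8) { blowup <- TRUE; break }
    }
    if (blowup) {
      restarts <- restarts + 1L
      if (restarts > 40L) { converged <- FALSE; W <- diag(nch); break }
      lrate <- lrate * 0.5
      W <- diag(nch)
      delta_old <- NULL
      next
    }
    delta <- as.vector(W - W0)
    change <- sqrt(sum(delta^2))
    if (!is.null(delta_old)) {
      cosang <- sum(delta * delta_old) /
        sqrt(sum(delta^2) * sum(delta_old^2) + 1e-300)
      if (cosang < 0.5) lrate <- lrate * 0.9
    }
    delta_old <- delta
    if (change < tol) break
  }
  unmixing <- W %*% sph
  list(unmixing = unmixing, mixing = solve(unmixing), center = center,
       converged = converged, iterations = it)
}

default_epoch_window <- function(sync) {
  switch(sync,
         release = c(-0.6, 1.0),
         feedback = c(-1.0, 0.8),
         stop("unknown sync label: ", sync))
}

#' Extract fixed-length epochs around synchronization events
#'
#' One epoch per event of the requested type; the window is half-open
#' (`start` inclusive, `end` exclusive) so that the release window
#' (-0.6, +1.0) s yields exactly 800 samples at 500 Hz and the feedback
#' window (-1.0, +0.8) s exactly 900.  Events whose window would exceed the
#' record bounds are dropped and logged.
#'
#' @param rec An [eeg_recording()] with events.
#' @param sync `"release"` or `"feedback"`.
#' @param window Length-2 numeric `(start, end)` in seconds relative to the
#'   event; defaults to the study windows above.
#' @return Object of class `epoch_set`: `epochs` (trials x channels x time
#'   array), `times`, `trial_ids`, `channels`, `sync`, `window`,
#'   `rejection_log`.
#' @export
extract_epochs <- function(rec, sync = c("release", "feedback"),
                           window = NULL) {
  sync <- match.arg(sync)
  if (is.null(window)) window <- default_epoch_window(sync)
  if (window[1] >= window[2]) stop("degenerate window")
  ev <- rec$events[rec$events$label == sync, ]
  if (!nrow(ev)) stop("no events with sync label '", sync, "'")
  fs <- rec$srate
  off0 <- round(window[1] * fs)
  nsmp <- round((window[2] - window[1]) * fs)
  first <- ev$sample + off0
  ok <- first >= 1 & (first + nsmp - 1) <= ncol(rec$data)
  dropped <- ev$trial[!ok]
  ev <- ev[ok, ]
  ep <- array(NA_real_, c(nrow(ev), length(rec$labels), nsmp),
              dimnames = list(NULL, rec$labels, NULL))
  for (i in seq_len(nrow(ev))) {
    s0 <- ev$sample[i] + off0
    ep[i, , ] <- rec$data[, s0:(s0 + nsmp - 1L)]
  }
  log <- if (length(dropped))
    data.frame(trial = dropped, criterion = "window_out_of_bounds",
               stringsAsFactors = FALSE)
  else data.frame(trial = integer(), criterion = character(),
                  stringsAsFactors = FALSE)
  es <- list(epochs = ep, times = off0 / fs + (seq_len(nsmp) - 1) / fs,
             trial_ids = ev$trial, channels = rec$labels, srate = fs,
             sync = sync, window = window, rejection_log = log)
  class(es) <- "epoch_set"
  es
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples, sync=%s [%g, %g] s\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$sync, x$window[1], x$window[2]))
  invisible(x)
}

#' Whole-segment baseline correction
#'
#' Subtracts, per epoch and channel, the mean of the complete segment (not a
#' pre-stimulus interval): with two event-locked deflections and no quiet
#' pre-stimulus period, the full-window mean serves as the baseline.
#'
#' @param es An [extract_epochs()] result.
#' @return The baseline-corrected epoch set.
#' @export
baseline_correct <- function(es) {
  stopifnot(dim(es$epochs)[1] > 0)
  m <- apply(es$epochs, c(1, 2), mean)
  es$epochs <- es$epochs - as.vector(m)  # recycles over the time dimension
  es
}

#' Threshold-based artifact rejection
#'
#' Automated stand-in for visual inspection: drops epochs whose scalp
#' channels exceed an absolute amplitude limit or a sample-to-sample
#' gradient limit.  Rejected trial ids and the triggering criterion are
#' appended to the rejection log.
#'
#' @param es An epoch set.
#' @param amp_limit Absolute amplitude limit (microvolts), default 100.
#' @param grad_limit Sample-to-sample step limit (microvolts), default 50.
#' @return The epoch set with offending epochs removed.
#' @export
reject_artifacts <- function(es, amp_limit = 100, grad_limit = 50) {
  stopifnot(amp_limit > 0, grad_limit > 0)
  sc <- which(channel_type(es$channels) == "scalp")
  n <- dim(es$epochs)[1]
  bad_amp <- logical(n); bad_grad <- logical(n)
  for (i in seq_len(n)) {
    x <- es$epochs[i, sc, , drop = FALSE]
    bad_amp[i] <- any(abs(x) > amp_limit)
    bad_grad[i] <- any(abs(x[, , -1, drop = FALSE] -
                           x[, , -dim(x)[3], drop = FALSE]) > grad_limit)
  }
  bad <- bad_amp | bad_grad
  if (any(bad)) {
    log <- data.frame(trial = es$trial_ids[bad],
                      criterion = ifelse(bad_amp[bad], "amplitude", "gradient"),
                      stringsAsFactors = FALSE)
    es$rejection_log <- rbind(es$rejection_log, log)
    es$epochs <- es$epochs[!bad, , , drop = FALSE]
    es$trial_ids <- es$trial_ids[!bad]
  }
  es
}

#' Keep only epochs with the given trial ids
#' @param es An epoch set.
#' @param ids Trial ids to keep.
#' @return The subsetted epoch set.
#' @export
subset_epochs <- function(es, ids) {
  keep <- es$trial_ids %in% ids
  es$epochs <- es$epochs[keep, , , drop = FALSE]
  es$trial_ids <- es$trial_ids[keep]
  es
}
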