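#' Geometry and dynamics of the virtual skittles work space
#'
#' Builds the fixed spatial layout of the semi-virtual throwing task: a
#' central post, a circular target up and to the right of it, and a lever
#' (manipulandum) pivoted below the post.  The ball, once released from the
#' lever tip, moves as a two-dimensional isotropic harmonic oscillator about
#' the post center, so every untruncated flight is a centered ellipse.  All
#' positions are in meters in the screen plane, angles in degrees
#' (counter-clockwise positive, 0 along +x).
#'
#' @param post_center Numeric length-2, center of the post (m).
#' @param post_radius Post radius (m); flights entering this disc are
#'   truncated (ball knocked out by the post).
#' @param target_center Numeric length-2, target center (m).
#' @param target_radius Target radius (m).
#' @param ball_radius Ball radius (m).
#' @param lever_length Lever length (m).
#' @param pivot Numeric length-2, lever pivot position (m).
#' @param omega Angular frequency of the ball dynamics (rad/s).  The default
#'   was fixed once with [calibrate_omega()] so that the median time of
#'   closest approach for representative successful throws is 0.85 s, the
#'   center of the 817--910 ms knowledge-of-results latency band.
#' @param hit_threshold Hit criterion (m): a trial is a hit when the minimal
#'   distance between ball path and target center is below this.  Defaults to
#'   `target_radius + ball_radius` (0.10 m).
#' @param post_includes_ball_radius If `TRUE` the collision radius of the
#'   post is `post_radius + ball_radius` instead of `post_radius`.
#' @param damping Exponential velocity damping coefficient (1/s); 0 (the
#'   default) gives the undamped elliptic flight.
#'
#' @return An object of class `skittles_geometry`.
#' @export
#' @examples
#' geo <- task_geometry()
#' rel <- release_from_lever(120, 400, geo)
#' tr  <- simulate_trajectory(rel, geo)
#' score_trial(tr, geo)
task_geometry <- function(post_center = c(0, 0),
                          post_radius = 0.25,
                          target_center = c(0.35, 1.00),
                          target_radius = 0.05,
                          ball_radius = 0.05,
                          lever_length = 0.40,
                          pivot = c(0, -0.9),
                          omega = 3.6319,
                          hit_threshold = target_radius + ball_radius,
                          post_includes_ball_radius = FALSE,
                          damping = 0) {
  geo <- list(post_center = as.numeric(post_center),
              post_radius = post_radius,
              target_center = as.numeric(target_center),
              target_radius = target_radius,
              ball_radius = ball_radius,
              lever_length = lever_length,
              pivot = as.numeric(pivot),
              omega = omega,
              hit_threshold = hit_threshold,
              post_includes_ball_radius = post_includes_ball_radius,
              damping = damping)
  class(geo) <- "skittles_geometry"
  validate_geometry(geo)
  geo
}

validate_geometry <- function(geo) {
  stopifnot(inherits(geo, "skittles_geometry"))
  pos <- c(post_radius = geo$post_radius, target_radius = geo$target_radius,
           ball_radius = geo$ball_radius, lever_length = geo$lever_length,
           omega = geo$omega, hit_threshold = geo$hit_threshold)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("geometry scalars must be positive and finite: ",
         paste(names(pos)[!is.finite(pos) | pos <= 0], collapse = ", "))
  sep <- sqrt(sum((geo$target_center - geo$post_center)^2))
  if (sep <= geo$post_radius + geo$target_radius)
    stop("target must lie outside the post disc")
  invisible(geo)
}

post_collision_radius <- function(geo) {
  geo$post_radius + if (isTRUE(geo$post_includes_ball_radius)) geo$ball_radius else 0
}

#' Release state from lever angle and angular velocity
#'
#' Converts the lever state at the moment of ball release into the initial
#' condition of the ball flight: the lever-tip position and its tangential
#' velocity.
#'
#' @param theta Lever angle at release (degrees, 0 along +x,
#'   counter-clockwise positive).
#' @param theta_dot Lever angular velocity at release (degrees/s).
#' @param geometry A [task_geometry()].
#' @return An object of class `release_state` with fields `position`,
#'   `velocity`, `release_angle`, `release_angular_velocity`.
#' @export
release_from_lever <- function(theta, theta_dot, geometry) {
  th <- theta * pi / 180
  thd <- theta_dot * pi / 180
  L <- geometry$lever_length
  rel <- list(position = geometry$pivot + L * c(cos(th), sin(th)),
              velocity = L * thd * c(-sin(th), cos(th)),
              release_angle = theta,
              release_angular_velocity = theta_dot)
  class(rel) <- "release_state"
  rel
}

#' Closed-form ball state at given times
#'
#' Evaluates the analytic solution of the isotropic harmonic ball dynamics
#' about the post center, per axis `u(t) = u0 cos(wt) + (v0/w) sin(wt)`
#' (relative to the post), together with its velocity.  With a nonzero
#' damping coefficient the amplitude decays as `exp(-damping * t)`.
#'
#' @param release A `release_state`.
#' @param geometry A [task_geometry()].
#' @param times Numeric vector of times (s, from release).
#' @return List with `positions` and `velocities`, each an `n x 2` matrix.
#' @export
trajectory_state <- function(release, geometry, times) {
  w <- geometry$omega
  u0 <- release$position - geometry$post_center
  v0 <- release$velocity
  ct <- cos(w * times); st <- sin(w * times)
  pos <- cbind(u0[1] * ct + (v0[1] / w) * st,
               u0[2] * ct + (v0[2] / w) * st)
  vel <- cbind(-u0[1] * w * st + v0[1] * ct,
               -u0[2] * w * st + v0[2] * ct)
  if (geometry$damping > 0) {
    dec <- exp(-geometry$damping * times)
    pos <- pos * dec
    vel <- vel * dec - geometry$damping * pos
  }
  pos[, 1] <- pos[, 1] + geometry$post_center[1]
  pos[, 2] <- pos[, 2] + geometry$post_center[2]
  list(positions = pos, velocities = vel)
}

#' Simulate one ball flight
#'
#' Samples the closed-form elliptic flight on a regular time grid and
#' truncates it at the first sample at which the ball enters the post disc.
#'
#' @param release A `release_state` (finite position and velocity).
#' @param geometry A [task_geometry()].
#' @param duration Flight duration to simulate (s); defaults to one orbital
#'   period `2*pi/omega`, which covers the full closed orbit.
#' @param dt Sampling step (s); must be at most 1 ms, matching the 1000 Hz
#'   behavioral sampling of the task.
#' @return An object of class `ball_trajectory` with fields `times`,
#'   `positions` (n x 2), `truncated_at_post`, `truncation_time` (or `NA`).
#'   The release state is kept as an attribute for downstream refinement.
#' @export
simulate_trajectory <- function(release, geometry, duration = NULL, dt = 1e-3) {
  if (!all(is.finite(release$position)) || !all(is.finite(release$velocity)))
    stop("non-finite release state")
  period <- 2 * pi / geometry$omega
  if (is.null(duration)) duration <- period
  if (duration < period - 1e-12)
    stop("duration must cover at least one orbital period 2*pi/omega")
  if (dt > 1e-3 + 1e-12) stop("dt must be <= 1 ms")
  times <- seq(0, duration, by = dt)
  st <- trajectory_state(release, geometry, times)
  pos <- st$positions
  pr <- post_collision_radius(geometry)
  r2 <- (pos[, 1] - geometry$post_center[1])^2 +
        (pos[, 2] - geometry$post_center[2])^2
  inside <- which(r2 <= pr^2)
  truncated <- length(inside) > 0
  trunc_time <- NA_real_
  if (truncated) {
    k <- inside[1]
    trunc_time <- if (k > 1)
      refine_post_crossing(release$position[1] - geometry$post_center[1],
                           release$position[2] - geometry$post_center[2],
                           release$velocity[1], release$velocity[2],
                           geometry, times[k - 1], times[k])
    else times[k]
    times <- times[seq_len(k)]
    pos <- pos[seq_len(k), , drop = FALSE]
  }
  tr <- list(times = times, positions = pos,
             truncated_at_post = truncated,
             truncation_time = trunc_time)
  attr(tr, "release") <- release
  class(tr) <- "ball_trajectory"
  tr
}

# Parabolic vertex through three equally spaced samples; returns offset in
# [-1, 1] grid units and the interpolated ordinate.  Ties break to the left
# (earliest time).
parabolic_vertex <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  off <- ifelse(denom > 0, 0.5 * (ym1 - yp1) / denom, 0)
  off <- pmin(pmax(off, -1), 1)
  yv <- y0 - 0.25 * (ym1 - yp1) * off
  list(offset = off, value = yv)
}

# Bisection on the closed form for the time at which the ball first enters
# the post disc, vectorized over trials; initial conditions relative to the
# post center.  `tlo` must be outside the disc and `thi` inside.
refine_post_crossing <- function(x0, y0, vx0, vy0, geometry, tlo, thi) {
  pr2 <- post_collision_radius(geometry)^2
  w <- geometry$omega
  f <- function(t) {
    ct <- cos(w * t); st <- sin(w * t)
    X <- x0 * ct + (vx0 / w) * st
    Y <- y0 * ct + (vy0 / w) * st
    if (geometry$damping > 0) {
      dec <- exp(-geometry$damping * t)
      X <- X * dec; Y <- Y * dec
    }
    X * X + Y * Y - pr2
  }
  for (k in 1:50) {
    tm <- (tlo + thi) / 2
    inside <- f(tm) <= 0
    thi[inside] <- tm[inside]
    tlo[!inside] <- tm[!inside]
  }
  (tlo + thi) / 2
}

# Refine the discrete closest approach by evaluating the closed form on a
# micro-grid of 41 points across [t0 - dt, t0 + dt] (clamped to [0, tmax]),
# then a parabolic vertex step whose candidate is re-evaluated exactly.
# Vectorized over trials; initial conditions are relative to the post
# center.  Near-zero (cone-shaped) minima stay accurate because every
# candidate distance is an exact closed-form evaluation.
closest_approach_refine <- function(x0, y0, vx0, vy0, geometry, t0, dt, tmax) {
  w <- geometry$omega
  tx <- geometry$target_center[1] - geometry$post_center[1]
  ty <- geometry$target_center[2] - geometry$post_center[2]
  n <- length(t0)
  offs <- seq(-dt, dt, length.out = 41L)
  TT <- outer(t0, offs, `+`)
  TT[TT < 0] <- 0
  TT <- pmin(TT, tmax)
  dist_at <- function(TM) {
    CT <- cos(w * TM); ST <- sin(w * TM)
    XX <- x0 * CT + (vx0 / w) * ST
    YY <- y0 * CT + (vy0 / w) * ST
    if (geometry$damping > 0) {
      dec <- exp(-geometry$damping * TM)
      XX <- XX * dec; YY <- YY * dec
    }
    sqrt((XX - tx)^2 + (YY - ty)^2)
  }
  DD <- dist_at(TT)
  j <- max.col(-DD, ties.method = "first")
  rows <- seq_len(n)
  dmin <- DD[cbind(rows, j)]
  tmin <- TT[cbind(rows, j)]
  interior <- j > 1L & j < 41L
  if (any(interior)) {
    r <- rows[interior]; a <- j[interior]
    h <- TT[cbind(r, a)] - TT[cbind(r, a - 1L)]
    equal <- abs((TT[cbind(r, a + 1L)] - TT[cbind(r, a)]) - h) < 1e-12
    v <- parabolic_vertex(DD[cbind(r, a - 1L)], DD[cbind(r, a)],
                          DD[cbind(r, a + 1L)])
    tv <- TT[cbind(r, a)] + ifelse(equal, v$offset * h, 0)
    tv <- pmin(pmax(tv, 0), tmax[interior])
    dv <- dist_at(matrix(tv, ncol = 1))[, 1]
    better <- dv < dmin[interior]
    dmin[interior][better] <- dv[better]
    tmin[interior][better] <- tv[better]
  }
  list(t = tmin, d = dmin)
}

#' Score one trial from its trajectory
#'
#' Finds the minimal distance between the sampled ball path and the target
#' center over the first orbital period (or up to post truncation), refining
#' the discrete argmin by local parabolic interpolation.  A trial is a `hit`
#' when that distance is below the hit threshold and the flight was not
#' truncated by the post; post-truncated flights are labeled `post_hit`
#' (unambiguous misses downstream), everything else `error`.
#'
#' @param trajectory A `ball_trajectory`.
#' @param geometry A [task_geometry()].
#' @return An object of class `trial_outcome`: `min_distance` (m), `t_kr`
#'   (s, the time of closest approach, i.e. the moment of knowledge of
#'   results), `label`.
#' @export
score_trial <- function(trajectory, geometry) {
  if (length(trajectory$times) == 0) stop("empty trajectory")
  period <- 2 * pi / geometry$omega
  keep <- trajectory$times <= period + 1e-12
  times <- trajectory$times[keep]
  pos <- trajectory$positions[keep, , drop = FALSE]
  d <- sqrt((pos[, 1] - geometry$target_center[1])^2 +
            (pos[, 2] - geometry$target_center[2])^2)
  i <- which.min(d)
  t_kr <- times[i]
  dmin <- d[i]
  release <- attr(trajectory, "release")
  if (!is.null(release) && length(times) > 1) {
    # exact micro-grid refinement from the closed form
    dt <- times[2] - times[1]
    ref <- closest_approach_refine(
      release$position[1] - geometry$post_center[1],
      release$position[2] - geometry$post_center[2],
      release$velocity[1], release$velocity[2],
      geometry, t_kr, dt,
      if (trajectory$truncated_at_post) trajectory$truncation_time
      else times[length(times)])
    t_kr <- ref$t
    dmin <- ref$d
  } else if (i > 1 && i < length(d)) {
    v <- parabolic_vertex(d[i - 1], d[i], d[i + 1])
    dt <- times[2] - times[1]
    t_kr <- times[i] + v$offset * dt
    dmin <- max(v$value, 0)
  }
  label <- if (trajectory$truncated_at_post) "post_hit"
           else if (dmin < geometry$hit_threshold) "hit" else "error"
  out <- list(min_distance = dmin, t_kr = t_kr, label = label,
              truncated_at_post = trajectory$truncated_at_post)
  class(out) <- "trial_outcome"
  out
}

#' Vectorized simulation and scoring of many release states
#'
#' The workhorse behind cohort generation and solution-space mapping:
#' simulates and scores every `(theta, theta_dot)` pair with shared
#' trigonometric grids, chunked to bound memory.  Identical in result to
#' [simulate_trajectory()] + [score_trial()] per trial.
#'
#' @param theta,theta_dot Equal-length vectors of release angles (deg) and
#'   angular velocities (deg/s).
#' @param geometry A [task_geometry()].
#' @param dt Sampling step (s), at most 1 ms.
#' @param chunk Rows per processing block.
#' @return Data frame with columns `theta`, `theta_dot`, `min_distance`,
#'   `t_kr`, `label`, `truncated`.
#' @export
score_release_states <- function(theta, theta_dot, geometry, dt = 1e-3,
                                 chunk = 2000L) {
  stopifnot(length(theta) == length(theta_dot))
  n <- length(theta)
  period <- 2 * pi / geometry$omega
  times <- seq(0, period, by = dt)
  nt <- length(times)
  w <- geometry$omega
  ct <- cos(w * times); st_ <- sin(w * times)
  if (geometry$damping > 0) {
    dec <- exp(-geometry$damping * times)
    ct <- ct * dec; st_ <- st_ * dec
  }
  L <- geometry$lever_length
  pr2 <- post_collision_radius(geometry)^2
  out_d <- numeric(n); out_t <- numeric(n); out_trunc <- logical(n)
  th <- theta * pi / 180
  thd <- theta_dot * pi / 180
  x0 <- geometry$pivot[1] + L * cos(th) - geometry$post_center[1]
  y0 <- geometry$pivot[2] + L * sin(th) - geometry$post_center[2]
  vx0 <- -L * thd * sin(th)
  vy0 <-  L * thd * cos(th)
  tx <- geometry$target_center[1] - geometry$post_center[1]
  ty <- geometry$target_center[2] - geometry$post_center[2]
  idx_blocks <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  for (ii in idx_blocks) {
    X <- outer(x0[ii], ct) + outer(vx0[ii] / w, st_)
    Y <- outer(y0[ii], ct) + outer(vy0[ii] / w, st_)
    R2 <- X * X + Y * Y
    M <- R2 <= pr2
    has_trunc <- rowSums(M) > 0
    first_in <- integer(length(ii))
    first_in[has_trunc] <- max.col(M[has_trunc, , drop = FALSE], ties.method = "first")
    X <- X - tx; Y <- Y - ty
    D <- sqrt(X * X + Y * Y)
    if (any(has_trunc)) {
      cutoff <- rep(nt + 1L, length(ii))
      cutoff[has_trunc] <- first_in[has_trunc]
      D[col(D) > cutoff[row(D)]] <- Inf
    }
    amin <- max.col(-D, ties.method = "first")
    rows <- seq_along(ii)
    tmax <- times[ifelse(has_trunc, first_in, nt)]
    tr_ref <- has_trunc & first_in > 1L
    if (any(tr_ref))
      tmax[tr_ref] <- refine_post_crossing(
        x0[ii][tr_ref], y0[ii][tr_ref], vx0[ii][tr_ref], vy0[ii][tr_ref],
        geometry, times[first_in[tr_ref] - 1L], times[first_in[tr_ref]])
    ref <- closest_approach_refine(x0[ii], y0[ii], vx0[ii], vy0[ii],
                                   geometry, times[amin], dt, tmax)
    out_d[ii] <- ref$d
    out_t[ii] <- ref$t
    out_trunc[ii] <- has_trunc
  }
  label <- ifelse(out_trunc, "post_hit",
                  ifelse(out_d < geometry$hit_threshold, "hit", "error"))
  data.frame(theta = theta, theta_dot = theta_dot,
             min_distance = out_d, t_kr = out_t,
             label = label, truncated = out_trunc,
             stringsAsFactors = FALSE)
}

#' Calibrate the dynamics frequency to a target feedback latency
#'
#' One-dimensional bracketed search for the angular frequency `omega` at
#' which the median time of closest approach over a representative set of
#' release states matches a target knowledge-of-results latency.
#'
#' @param geometry A [task_geometry()] (its `omega` is ignored).
#' @param releases Data frame with columns `theta`, `theta_dot`.
#' @param target_t_kr Target median closest-approach time (s).
#' @param interval Search bracket for omega (rad/s).
#' @return The calibrated omega (rad/s).
#' @export
calibrate_omega <- function(geometry, releases, target_t_kr = 0.85,
                            interval = c(1, 12)) {
  stopifnot(nrow(releases) > 0, target_t_kr > 0)
  obj <- function(w) {
    g <- geometry; g$omega <- w
    sc <- score_release_states(releases$theta, releases$theta_dot, g)
    abs(stats::median(sc$t_kr) - target_t_kr)
  }
  if (obj(interval[1]) < obj(interval[1] + diff(interval) / 100) &&
      obj(interval[2]) < obj(interval[2] - diff(interval) / 100))
    stop("calibration failure: no bracketing interval for omega")
  opt <- stats::optimize(obj, interval = interval, tol = 1e-5)
  opt$minimum
}

#' Map the task's solution space
#'
#' Exhaustive simulation over a grid of release angles and angular
#' velocities, recording the outcome of every cell.  Cells with angular
#' velocity at or below 50 deg/s are flagged invalid (the task's valid-trial
#' rule); their outcome is still computed.
#'
#' @param geometry A [task_geometry()].
#' @param theta_grid Release angles (deg).
#' @param theta_dot_grid Release angular velocities (deg/s).
#' @param dt Sampling step (s) for the underlying flights.
#' @return An object of class `solution_map`: matrices `label`,
#'   `min_distance`, `t_kr` of dim `length(theta_grid) x
#'   length(theta_dot_grid)`, a logical `valid` matrix, and the grids.
#' @export
map_solution_space <- function(geometry, theta_grid, theta_dot_grid, dt = 1e-3) {
  stopifnot(length(theta_grid) > 0, length(theta_dot_grid) > 0)
  g <- expand.grid(theta = theta_grid, theta_dot = theta_dot_grid)
  sc <- score_release_states(g$theta, g$theta_dot, geometry, dt = dt)
  dims <- c(length(theta_grid), length(theta_dot_grid))
  out <- list(theta_grid = theta_grid, theta_dot_grid = theta_dot_grid,
              label = matrix(sc$label, dims[1], dims[2]),
              min_distance = matrix(sc$min_distance, dims[1], dims[2]),
              t_kr = matrix(sc$t_kr, dims[1], dims[2]),
              valid = matrix(rep(theta_dot_grid > 50, each = dims[1]),
                             dims[1], dims[2]),
              geometry = geometry)
  class(out) <- "solution_map"
  out
}

#' Expected hit rate of a normal release-strategy under a solution map
#'
#' Approximates the probability of a hit for a participant whose release
#' angle and angular velocity are independent normals, by weighting the
#' solution-map cells with the corresponding bivariate normal cell masses,
#' restricted to the valid region (the generator redraws invalid trials).
#'
#' @param map A [map_solution_space()] result.
#' @param theta_mean,theta_sd Release-angle distribution (deg).
#' @param theta_dot_mean,theta_dot_sd Angular-velocity distribution (deg/s).
#' @return Expected hit rate in `[0, 1]`.
#' @export
expected_hit_rate <- function(map, theta_mean, theta_sd,
                              theta_dot_mean, theta_dot_sd) {
  cellw <- function(grid, m, s) {
    mid <- c(-Inf, (grid[-1] + grid[-length(grid)]) / 2, Inf)
    diff(stats::pnorm(mid, m, s))
  }
  wth <- cellw(map$theta_grid, theta_mean, theta_sd)
  wtd <- cellw(map$theta_dot_grid, theta_dot_mean, theta_dot_sd)
  W <- outer(wth, wtd) * map$valid
  tot <- sum(W)
  if (tot <= 0) return(0)
  sum(W[map$label == "hit"]) / tot
}

#' Representative skilled release states
#'
#' A small fixed grid of release states on the around-the-post solution
#' branch, used as the calibration set for [calibrate_omega()]: under the
#' default geometry all of them hit the target and their median closest
#' approach occurs near the center of the task's feedback-latency band.
#'
#' @return Data frame with columns `theta` (deg) and `theta_dot` (deg/s).
#' @export
default_release_set <- function() {
  expand.grid(theta = seq(185, 225, by = 10),
              theta_dot = seq(350, 750, by = 100))
}

#' Candidate aim points along the solution manifold
#'
#' Extracts, from a solution map, one robust aim point per release angle:
#' the cell lying 40% into the contiguous run of hitting angular velocities,
#' i.e. well inside the hit region rather than on its edge.  Cohort
#' generation picks per-participant aim points from this set by their
#' closest-approach time, which is how participants acquire distinct
#' knowledge-of-results latencies.
#'
#' @param map A [map_solution_space()] result.
#' @param min_run Minimum length of the hit run for a row to qualify.
#' @return Data frame with columns `theta`, `theta_dot`, `t_kr`.
#' @export
aim_points <- function(map, min_run = 5L) {
  rows <- lapply(seq_along(map$theta_grid), function(i) {
    j <- which(map$label[i, ] == "hit" & map$valid[i, ])
    if (length(j) < min_run || any(diff(j) != 1)) return(NULL)
    jm <- j[ceiling(length(j) * 0.4)]
    data.frame(theta = map$theta_grid[i],
               theta_dot = map$theta_dot_grid[jm],
               t_kr = map$t_kr[i, jm])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no aim points: hit region empty or fragmented")
  out
}
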