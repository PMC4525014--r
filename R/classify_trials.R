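#' Categorize a participant's trials into clear hits and clear errors
#'
#' Within one participant, trials are sorted by the minimal ball-target
#' distance; up to `cap` trials from the lower end with distance below
#' `hit_max` become the hit category and up to `cap` trials from the upper
#' end with distance above `err_min` the error category.  Trials in the
#' marginal band between the two thresholds are never categorized, so the
#' two categories are maximally discriminable.  Post-truncated trials enter
#' by their truncated-trajectory distance (they are unambiguous misses).
#' Ties in distance break by trial index, so the assignment is deterministic
#' and invariant under row shuffling.
#'
#' @param trials Trial table rows of a single participant.
#' @param hit_max Hit threshold (m), default 0.05.
#' @param err_min Error threshold (m), default 0.12.
#' @param cap Maximum trials per category, default 50.
#' @param error_from `"largest"` (default): errors are the `cap` largest
#'   distances above `err_min`; `"smallest_above"`: the `cap` smallest above
#'   it.
#' @return Object of class `category_assignment`: `hit_ids`, `error_ids`,
#'   `n_hit`, `n_error`, `included` (decided later), `reason`.
#' @export
categorize <- function(trials, hit_max = 0.05, err_min = 0.12, cap = 50L,
                       error_from = c("largest", "smallest_above")) {
  error_from <- match.arg(error_from)
  stopifnot(length(unique(trials$participant)) <= 1)
  if (any(!is.finite(trials$min_distance))) stop("non-finite distances")
  ord <- order(trials$min_distance, trials$trial)
  d <- trials$min_distance[ord]
  id <- trials$trial[ord]
  hit_ids <- id[d < hit_max]
  hit_ids <- hit_ids[seq_len(min(cap, length(hit_ids)))]
  above <- d > err_min
  error_ids <- if (error_from == "largest") {
    cand <- rev(id[above])
    cand[seq_len(min(cap, length(cand)))]
  } else {
    cand <- id[above]
    cand[seq_len(min(cap, length(cand)))]
  }
  out <- list(participant = if (nrow(trials)) trials$participant[1] else NA_character_,
              hit_ids = sort(hit_ids), error_ids = sort(error_ids),
              n_hit = length(hit_ids), n_error = length(error_ids),
              included = NA, reason = NA_character_)
  class(out) <- "category_assignment"
  out
}

#' Apply the minimum-trials inclusion rule
#'
#' A participant enters the ERP analysis only when, after artifact
#' rejection, at least `min_n` trials survive in each category.
#'
#' @param assignments List of [categorize()] results.
#' @param post_rejection_counts Data frame with columns `participant`,
#'   `n_hit`, `n_error`: category sizes counted after artifact rejection.
#' @param min_n Minimum surviving trials per category (default 20).
#' @return The assignments with `included`/`reason` set.
#' @export
apply_trial_count_rule <- function(assignments, post_rejection_counts,
                                   min_n = 20L) {
  for (i in seq_along(assignments)) {
    a <- assignments[[i]]
    row <- post_rejection_counts[
      post_rejection_counts$participant == a$participant, , drop = FALSE]
    if (!nrow(row)) stop("no post-rejection counts for ", a$participant)
    ok <- row$n_hit[1] >= min_n && row$n_error[1] >= min_n
    assignments[[i]]$included <- ok
    assignments[[i]]$reason <- if (ok) NA_character_ else "insufficient_trials"
  }
  assignments
}

#' Screen the cohort for outlying performance or release-angle dispersion
#'
#' Computes, per participant, the hit percentage (all target hits, not
#' necessarily in series) and the standard deviation of the release angle,
#' then z-scores both against the cohort of currently included participants
#' and excludes anyone at `|z| >= k` on either measure.  The screen is a
#' single pass: exclusions do not trigger re-computation of the cohort
#' mean and SD.
#'
#' @param tables Trial table covering all participants (or a list of
#'   per-participant tables).
#' @param k Exclusion threshold in SD units (default 2).
#' @param included Optional character vector of participants still in the
#'   analysis (e.g. after the minimum-trials rule); the z-scores are formed
#'   over these.
#' @return Object of class `cohort_screen`: data frame with
#'   `hit_percentage`, `angle_sd`, the z-scores, and `included` flags.
#' @export
screen_cohort <- function(tables, k = 2.0, included = NULL) {
  if (is.list(tables) && !is.data.frame(tables))
    tables <- do.call(rbind, tables)
  stats_df <- do.call(rbind, lapply(split(tables, tables$participant),
    function(tt) data.frame(participant = tt$participant[1],
                            hit_percentage = 100 * mean(tt$label == "hit"),
                            angle_sd = stats::sd(tt$theta),
                            n_trials = nrow(tt),
                            stringsAsFactors = FALSE)))
  rownames(stats_df) <- NULL
  if (nrow(stats_df) < 3) stop("need at least 3 participants to screen")
  if (is.null(included)) included <- stats_df$participant
  inc <- stats_df$participant %in% included
  zs <- function(x) {
    mu <- mean(x[inc]); s <- stats::sd(x[inc])
    if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
    (x - mu) / s
  }
  stats_df$z_hit <- zs(stats_df$hit_percentage)
  stats_df$z_angle <- zs(stats_df$angle_sd)
  if (all(is.na(stats_df$z_hit)) && all(is.na(stats_df$z_angle))) {
    warning("zero cohort variance on both measures; screening skipped")
    stats_df$screened_out <- FALSE
  } else {
    stats_df$screened_out <-
      (!is.na(stats_df$z_hit) & abs(stats_df$z_hit) >= k) |
      (!is.na(stats_df$z_angle) & abs(stats_df$z_angle) >= k)
  }
  stats_df$included <- inc & !stats_df$screened_out
  out <- list(table = stats_df, k = k)
  class(out) <- "cohort_screen"
  out
}
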