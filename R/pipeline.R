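#' Full run configuration
#'
#' Nests every stage's parameters into one reproducible record.  All
#' thresholds are echoed into the run manifest.  Defaults equal the study
#' protocol's stated values where stated (filter band, epoch windows,
#' category thresholds and caps, inclusion minimum, screening criterion).
#'
#' @param cohort A [cohort_config()].
#' @param geometry A [task_geometry()].
#' @param filter_band Band edges (Hz) of the zero-phase Butterworth
#'   band-pass; `NULL` disables filtering.
#' @param filter_order Per-pass Butterworth order.
#' @param ocular_method `"infomax"`, `"regression"`, or `"none"`.
#' @param ica_seed Seed of the Infomax block permutation.
#' @param amp_limit,grad_limit Artifact-rejection limits (microvolts).
#' @param hit_max,err_min,cap Categorization thresholds (m) and per-category
#'   cap.
#' @param min_n Minimum post-rejection trials per category for inclusion.
#' @param screen_k Cohort-screening threshold in SD units.
#' @param sync Synchronizations to analyze: `"release"`, `"feedback"`, or
#'   `"both"`.
#' @param frac Fractional-minimum threshold of the window detection.
#' @param windows Manual window override: a list with entries per sync, each
#'   `list(window1 = c(s, e), window2 = c(s, e))`; `NULL` (default) detects
#'   windows from the grand-average difference wave.
#' @param write_raw Write each participant's raw EEG as a BrainVision-style
#'   triplet and re-read it before preprocessing (full on-disk provenance);
#'   disable to keep everything in memory.
#' @param keep_waveforms Keep per-participant ERP waveforms in the result.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       geometry = task_geometry(),
                       filter_band = c(0.2, 30), filter_order = 2,
                       ocular_method = "infomax", ica_seed = 1L,
                       amp_limit = 100, grad_limit = 50,
                       hit_max = 0.05, err_min = 0.12, cap = 50L,
                       min_n = 20L, screen_k = 2.0,
                       sync = c("both", "release", "feedback"),
                       frac = 0.5, windows = NULL,
                       write_raw = TRUE, keep_waveforms = FALSE) {
  sync <- match.arg(sync)
  cfg <- list(cohort = cohort, geometry = geometry,
              filter_band = filter_band, filter_order = filter_order,
              ocular_method = ocular_method, ica_seed = as.integer(ica_seed),
              amp_limit = amp_limit, grad_limit = grad_limit,
              hit_max = hit_max, err_min = err_min, cap = as.integer(cap),
              min_n = as.integer(min_n), screen_k = screen_k,
              sync = sync, frac = frac, windows = windows,
              write_raw = write_raw, keep_waveforms = keep_waveforms)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar overrides in the file are applied on top of the defaults of
#' [run_config()], [cohort_config()] and [task_geometry()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  geo <- do.call(task_geometry, as_args(raw$geometry, task_geometry))
  coh <- do.call(cohort_config, as_args(raw$cohort, cohort_config))
  rest <- raw[setdiff(names(raw), c("geometry", "cohort"))]
  do.call(run_config, c(list(cohort = coh, geometry = geo),
                        as_args(rest, run_config)))
}

as_args <- function(lst, fn) {
  if (is.null(lst)) return(list())
  keep <- intersect(names(lst), names(formals(fn)))
  lapply(lst[keep], function(v) if (is.list(v)) unlist(v) else v)
}

preprocess_recording <- function(rec, config) {
  if (!is.null(config$filter_band))
    rec <- bandpass_filter(rec, config$filter_band[1], config$filter_band[2],
                           config$filter_order)
  rec <- rereference_avg_mastoids(rec)
  rec <- remove_ocular(rec, method = config$ocular_method,
                       seed = config$ica_seed)
  rec
}

epochs_for_sync <- function(rec, sync, config) {
  es <- extract_epochs(rec, sync)
  es <- baseline_correct(es)
  reject_artifacts(es, config$amp_limit, config$grad_limit)
}

#' Run the complete pipeline
#'
#' Simulate cohort -> (optionally) write and re-read raw data -> filter,
#' re-reference, remove ocular artifacts -> epoch, baseline-correct, reject
#' -> categorize and apply both exclusion levels -> average, difference
#' waves, window detection, statistics.  Every stage's parameters, seeds and
#' counts are recorded in a JSON manifest; per-participant trial tables and
#' category assignments are written as TSV.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Object of class `ern_results`: per-sync window statistics, the
#'   screen table, exclusion bookkeeping, and the manifest (also on disk).
#' @export
run_all <- function(config, out_dir = tempfile("ernsim_run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  syncs <- if (config$sync == "both") c("release", "feedback") else config$sync
  specs <- sample_cohort(config$cohort, config$geometry)
  n <- length(specs)
  message(sprintf("stage simulate: %d participants", n))

  tables <- list(); assigns <- list(); counts <- list()
  epochs <- list(release = list(), feedback = list())
  for (sp in specs) {
    tt <- generate_behavior(sp, config$geometry, config$cohort)
    write_trial_table(tt, file.path(out_dir, paste0(sp$id, "_trials.tsv")))
    rec <- generate_eeg(sp, tt, config$cohort)
    if (config$write_raw) {
      base <- file.path(out_dir, paste0(sp$id, "_raw"))
      write_brainvision(rec, base)
      rec <- read_brainvision(base)
    }
    rec <- preprocess_recording(rec, config)
    a <- categorize(tt, config$hit_max, config$err_min, config$cap)
    n_hit <- n_err <- Inf
    for (sy in syncs) {
      es <- epochs_for_sync(rec, sy, config)
      epochs[[sy]][[sp$id]] <- list(
        error = subset_epochs(es, a$error_ids),
        hit = subset_epochs(es, a$hit_ids))
      n_hit <- min(n_hit, dim(epochs[[sy]][[sp$id]]$hit$epochs)[1])
      n_err <- min(n_err, dim(epochs[[sy]][[sp$id]]$error$epochs)[1])
    }
    tables[[sp$id]] <- tt
    assigns[[sp$id]] <- a
    counts[[sp$id]] <- data.frame(participant = sp$id, n_hit = n_hit,
                                  n_error = n_err, stringsAsFactors = FALSE)
    rm(rec)
  }
  counts <- do.call(rbind, counts)
  message(sprintf("stage preprocess: %d participants epoched", n))

  assigns <- apply_trial_count_rule(assigns, counts, config$min_n)
  kept1 <- names(assigns)[vapply(assigns, `[[`, logical(1), "included")]
  screen <- if (n >= 3) {
    screen_cohort(do.call(rbind, tables), config$screen_k, included = kept1)
  } else {
    warning("cohort too small to screen (need >= 3); skipping the screen")
    st <- do.call(rbind, lapply(tables, function(tt)
      data.frame(participant = tt$participant[1],
                 hit_percentage = 100 * mean(tt$label == "hit"),
                 angle_sd = stats::sd(tt$theta), n_trials = nrow(tt),
                 z_hit = NA_real_, z_angle = NA_real_,
                 screened_out = FALSE,
                 included = tt$participant[1] %in% kept1,
                 stringsAsFactors = FALSE)))
    rownames(st) <- NULL
    structure(list(table = st, k = config$screen_k), class = "cohort_screen")
  }
  included <- screen$table$participant[screen$table$included]
  message(sprintf("stage classify: %d -> %d (trial counts) -> %d (screen)",
                  n, length(kept1), length(included)))

  hitpct <- stats::setNames(screen$table$hit_percentage,
                            screen$table$participant)
  results <- list()
  for (sy in syncs) {
    if (length(included) < 2) {
      results[[sy]] <- list(computable = FALSE)
      next
    }
    dws <- list()
    for (id in included) {
      e <- epochs[[sy]][[id]]
      dws[[id]] <- difference_wave(average_epochs(e$error, "error"),
                                   average_epochs(e$hit, "hit"))
    }
    gd <- grand_average(dws)
    kr_med <- vapply(tables[included], function(tt) stats::median(tt$t_kr),
                     numeric(1))
    kr_bounds <- range(kr_med)
    manual <- config$windows[[sy]]
    win <- if (is.null(manual)) detect_windows(gd, kr_bounds, config$frac)
           else list(window1 = manual$window1, window2 = manual$window2,
                     defined = c(window1 = !is.null(manual$window1),
                                 window2 = !is.null(manual$window2)),
                     sync = sy, manual = TRUE)
    st <- list()
    for (wn in c("window1", "window2"))
      if (isTRUE(win$defined[[wn]]))
        st[[wn]] <- window_stats(dws, win[[wn]], hitpct)
    results[[sy]] <- list(computable = TRUE, windows = win, stats = st,
                          grand_difference = gd,
                          waveforms = if (config$keep_waveforms) dws)
    amps <- do.call(rbind, lapply(names(st), function(wn)
      data.frame(participant = names(st[[wn]]$amplitudes), window = wn,
                 amplitude = unname(st[[wn]]$amplitudes),
                 stringsAsFactors = FALSE)))
    if (!is.null(amps))
      utils::write.table(amps, file.path(out_dir,
        paste0("amplitudes_", sy, ".tsv")), sep = "\t", quote = FALSE,
        row.names = FALSE)
  }
  message("stage stats: done")

  manifest <- list(
    package_version = as.character(utils::packageVersion("ernsim")),
    master_seed = config$cohort$master_seed,
    parameters = config_to_manifest(config),
    participants = list(
      generated = n,
      excluded_insufficient_trials = setdiff(names(assigns), kept1),
      excluded_screen = setdiff(kept1, included),
      included = included),
    counts = counts,
    screen = screen$table,
    results = lapply(results, summarize_sync))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out <- list(results = results, screen = screen, assignments = assigns,
              counts = counts, included = included, manifest = manifest,
              out_dir = out_dir)
  class(out) <- "ern_results"
  out
}

config_to_manifest <- function(config) {
  list(geometry = unclass(config$geometry),
       cohort = unclass(config$cohort),
       filter_band = config$filter_band, filter_order = config$filter_order,
       ocular_method = config$ocular_method, ica_seed = config$ica_seed,
       amp_limit = config$amp_limit, grad_limit = config$grad_limit,
       hit_max = config$hit_max, err_min = config$err_min, cap = config$cap,
       min_n = config$min_n, screen_k = config$screen_k,
       sync = config$sync, frac = config$frac)
}

summarize_sync <- function(res) {
  if (!isTRUE(res$computable)) return(list(computable = FALSE))
  out <- list(computable = TRUE)
  for (wn in c("window1", "window2")) {
    if (isTRUE(res$windows$defined[[wn]])) {
      s <- res$stats[[wn]]
      out[[wn]] <- list(window = res$windows[[wn]],
                        mean_amplitude = mean(s$amplitudes),
                        t = s$t, df = s$df, p = s$p, r = s$r, p_r = s$p_r)
    } else out[[wn]] <- list(defined = FALSE)
  }
  out
}

#' @export
print.ern_results <- function(x, ...) {
  cat(sprintf("<ern_results> %d included participants (of %d)\n",
              length(x$included), nrow(x$screen$table)))
  for (sy in names(x$results)) {
    r <- x$results[[sy]]
    if (!isTRUE(r$computable)) { cat(" ", sy, ": not computable\n"); next }
    for (wn in names(r$stats)) {
      s <- r$stats[[wn]]
      cat(sprintf("  %s %s [%.3f, %.3f] s: mean %.2f uV, t(%d) = %.2f, p = %.3g, r = %.2f (p = %.3g)\n",
                  sy, wn, s$window[1], s$window[2], mean(s$amplitudes),
                  s$df, s$t, s$p, s$r, s$p_r))
    }
  }
  invisible(x)
}
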