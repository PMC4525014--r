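#' @name channels
#' @title Channel conventions
#' @description The study montage: ten 10--20 scalp sites, a right-mastoid
#'   reference channel (the online reference is the left mastoid, which is
#'   therefore not a recorded channel), and four periocular EOG electrodes
#'   (left/right canthi, above/below the right eye).
#' @keywords internal
NULL

scalp_channels <- function() c("F3", "Fz", "F4", "FCz", "C3", "Cz", "C4",
                               "P3", "Pz", "P4")
mastoid_channel <- function() "M2"
eog_channels <- function() c("HEOGL", "HEOGR", "VEOGU", "VEOGD")

#' Channel type lookup
#' @param labels Character vector of channel labels.
#' @return Character vector: `"scalp"`, `"mastoid"`, `"eog"` or `"other"`.
#' @export
channel_type <- function(labels) {
  ifelse(labels %in% scalp_channels(), "scalp",
  ifelse(labels %in% mastoid_channel(), "mastoid",
  ifelse(labels %in% eog_channels(), "eog", "other")))
}

#' Construct a continuous EEG recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts; row names
#'   are taken as channel labels when `labels` is missing.
#' @param srate Sampling rate (Hz); study-conform data use 500 Hz.
#' @param labels Channel labels.
#' @param events Data frame with columns `label` (`"release"`, `"feedback"`,
#'   or other preserved marker text), `trial` (integer id, `NA` for foreign
#'   markers) and `sample` (1-based index).
#' @param reference Reference descriptor, e.g. `"left_mastoid"` (online) or
#'   `"averaged_mastoids"` (after offline re-referencing).
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, labels = rownames(data),
                          events = empty_events(), reference = "left_mastoid") {
  stopifnot(is.matrix(data), !is.null(labels), length(labels) == nrow(data))
  rownames(data) <- labels
  rec <- list(data = data, srate = srate, labels = labels,
              events = events, reference = reference)
  class(rec) <- "eeg_recording"
  validate_recording(rec)
  rec
}

empty_events <- function() {
  data.frame(label = character(), trial = integer(), sample = integer(),
             stringsAsFactors = FALSE)
}

validate_recording <- function(rec) {
  ev <- rec$events
  if (nrow(ev)) {
    if (any(ev$sample < 1 | ev$sample > ncol(rec$data)))
      stop("event sample indices outside record length")
    rel <- ev[ev$label == "release", ]
    if (nrow(rel) > 1 && any(diff(rel$trial) <= 0))
      stop("release events must be strictly increasing in trial id")
  }
  invisible(rec)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events, ref=%s\n",
              nrow(x$data), ncol(x$data), x$srate, nrow(x$events), x$reference))
  invisible(x)
}

marker_of_label <- function(label) {
  c(release = "S  1", feedback = "S  2")[label]
}

#' Write a recording as a BrainVision-style file triplet
#'
#' Produces `<basepath>.vhdr` (text header), `<basepath>.vmrk` (text marker
#' file) and `<basepath>.eeg` (multiplexed IEEE float32 binary, microvolts).
#' Release and feedback events are written as stimulus markers `S  1` and
#' `S  2` with the trial id carried in the marker description; writing is
#' deterministic byte-for-byte and round-trip stable through
#' [read_brainvision()] up to float32 quantization of the samples.
#'
#' @param rec An [eeg_recording()].
#' @param basepath Path without extension.
#' @return `basepath`, invisibly.
#' @export
write_brainvision <- function(rec, basepath) {
  if (any(!is.finite(rec$data))) stop("non-finite samples")
  base <- basename(basepath)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "; Written by ernsim",
           "",
           "[Common Infos]",
           paste0("DataFile=", base, ".eeg"),
           paste0("MarkerFile=", base, ".vmrk"),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nrow(rec$data)),
           sprintf("SamplingInterval=%.10g", 1e6 / rec$srate),
           "",
           "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "",
           "[Channel Infos]",
           sprintf("Ch%d=%s,,1,uV", seq_len(nrow(rec$data)), rec$labels),
           "",
           "[Comment]",
           paste0("Reference=", rec$reference))
  mrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
           "",
           "[Common Infos]",
           paste0("DataFile=", base, ".eeg"),
           "",
           "[Marker Infos]",
           "Mk1=New Segment,,1,1,0,0")
  ev <- rec$events
  if (nrow(ev)) {
    known <- ev$label %in% c("release", "feedback")
    desc <- ifelse(known,
                   sprintf("%s tid=%d", marker_of_label(ev$label), ev$trial),
                   ev$label)
    type <- ifelse(known, "Stimulus", "Comment")
    mrk <- c(mrk, sprintf("Mk%d=%s,%s,%d,1,0", seq_len(nrow(ev)) + 1L,
                          type, desc, ev$sample))
  }
  writeLines(hdr, paste0(basepath, ".vhdr"))
  writeLines(mrk, paste0(basepath, ".vmrk"))
  con <- file(paste0(basepath, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  invisible(basepath)
}

ini_value <- function(lines, key) {
  hit <- grep(paste0("^", key, "="), lines, value = TRUE)
  if (!length(hit)) stop("missing header field: ", key)
  sub(paste0("^", key, "="), "", hit[1])
}

#' Read a BrainVision-style file triplet
#'
#' Inverse of [write_brainvision()].  Stimulus markers `S  1` / `S  2` are
#' mapped back to `release` / `feedback` events with their trial ids; any
#' other marker is preserved verbatim with an `NA` trial id and is ignored
#' by downstream stages.
#'
#' @param basepath Path without extension.
#' @return An [eeg_recording()].
#' @export
read_brainvision <- function(basepath) {
  hdr <- readLines(paste0(basepath, ".vhdr"))
  nchan <- as.integer(ini_value(hdr, "NumberOfChannels"))
  srate <- 1e6 / as.numeric(ini_value(hdr, "SamplingInterval"))
  fmt <- ini_value(hdr, "BinaryFormat")
  if (fmt != "IEEE_FLOAT_32") stop("unsupported binary format: ", fmt)
  chlines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", chlines), ",", fixed = TRUE),
                   `[`, character(1), 1)
  if (length(labels) != nchan) stop("header channel count mismatch")
  refline <- grep("^Reference=", hdr, value = TRUE)
  reference <- if (length(refline)) sub("^Reference=", "", refline[1]) else "unknown"

  datafile <- paste0(basepath, ".eeg")
  nbytes <- file.size(datafile)
  if (is.na(nbytes)) stop("missing data file: ", datafile)
  if (nbytes %% (4L * nchan) != 0)
    stop(sprintf("header/data length mismatch: %d bytes not divisible by %d (4 bytes x %d channels)",
                 nbytes, 4L * nchan, nchan))
  con <- file(datafile, "rb")
  vals <- readBin(con, "numeric", n = nbytes / 4L, size = 4L, endian = "little")
  close(con)
  data <- matrix(vals, nrow = nchan)
  rownames(data) <- labels

  mrk <- readLines(paste0(basepath, ".vmrk"))
  mklines <- grep("^Mk[0-9]+=", mrk, value = TRUE)
  ev <- empty_events()
  for (ln in mklines) {
    parts <- strsplit(sub("^Mk[0-9]+=", "", ln), ",", fixed = TRUE)[[1]]
    if (length(parts) < 4 || parts[1] == "New Segment") next
    desc <- parts[2]
    pos <- as.integer(parts[3])
    m <- regmatches(desc, regexec("^(S  [12]) tid=([0-9]+)$", desc))[[1]]
    if (length(m) == 3) {
      lab <- if (m[2] == "S  1") "release" else "feedback"
      ev <- rbind(ev, data.frame(label = lab, trial = as.integer(m[3]),
                                 sample = pos, stringsAsFactors = FALSE))
    } else {
      ev <- rbind(ev, data.frame(label = desc, trial = NA_integer_,
                                 sample = pos, stringsAsFactors = FALSE))
    }
  }
  eeg_recording(data, srate, labels, ev, reference)
}

trial_table_columns <- function() {
  c("participant", "trial", "theta", "theta_dot", "min_distance",
    "label", "t_kr", "release_time")
}

#' Write a behavioral trial table as TSV
#'
#' Floats are written with 17 significant digits so that
#' [read_trial_table()] restores them bitwise.
#'
#' @param trials Trial-table data frame (one row per throw).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  miss <- setdiff(trial_table_columns(), names(trials))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  df <- trials[trial_table_columns()]
  for (cn in c("theta", "theta_dot", "min_distance", "t_kr", "release_time"))
    df[[cn]] <- sprintf("%.17g", df[[cn]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a behavioral trial table from TSV
#'
#' @param path Input path.
#' @return Data frame with the fixed trial-table columns; outcome labels are
#'   validated against the vocabulary `hit` / `error` / `post_hit`.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(trial_table_columns(), names(df))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  bad <- which(!df$label %in% c("hit", "error", "post_hit"))
  if (length(bad))
    stop(sprintf("unknown outcome label '%s' at row %d", df$label[bad[1]], bad[1]))
  df$participant <- as.character(df$participant)
  df$trial <- as.integer(df$trial)
  df[trial_table_columns()]
}
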