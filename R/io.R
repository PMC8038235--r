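#' Construct a wrist recording
#'
#' A wrist recording is a tibble of timestamped tri-axial acceleration
#' samples (`t` in seconds from recording start, `ax`, `ay`, `az` in g)
#' carrying the wrist side, the nominal sample rate and the absolute
#' start time as attributes.
#'
#' @param samples data frame with columns `t`, `ax`, `ay`, `az`.
#' @param side `"right"` or `"left"`.
#' @param sample_rate nominal sampling frequency in samples/second (> 0).
#' @param start_time absolute start of the recording, in seconds (numeric
#'   epoch time or 0 for a local clock).
#' @return a `wrist_recording` tibble.
#' @export
wrist_recording <- function(samples, side = c("right", "left"),
                            sample_rate, start_time = 0) {
  side <- match.arg(side)
  req <- c("t", "ax", "ay", "az")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("samples is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "actasym_format_error")
  }
  out <- tibble::as_tibble(samples[req])
  if (nrow(out) < 1) {
    abort("a wrist recording needs at least one sample",
          class = "actasym_validation_error")
  }
  finite_rows <- rowSums(!is.finite(as.matrix(out))) == 0
  if (!all(finite_rows)) {
    abort(paste0("non-finite value in sample row ", which(!finite_rows)[1]),
          class = "actasym_validation_error")
  }
  if (any(diff(out$t) <= 0)) {
    row <- which(diff(out$t) <= 0)[1] + 1L
    abort(paste0("timestamps must be strictly increasing (violated at row ",
                 row, ")"),
          class = "actasym_validation_error")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    abort("sample_rate must be a single positive number",
          class = "actasym_validation_error")
  }
  structure(out,
            side = side, sample_rate = as.numeric(sample_rate),
            start_time = as.numeric(start_time),
            class = c("wrist_recording", class(tibble::tibble())))
}

#' Read a raw wrist recording from CSV
#'
#' Two dialects are recognised: `t,ax,ay,az` with `t` in seconds from the
#' recording start, and `timestamp,ax,ay,az` with ISO-8601 timestamps
#' (converted to seconds from the first sample, which becomes
#' `start_time`). Accelerations are in g and are never rescaled.
#'
#' @param path CSV file path.
#' @param side wrist side of this sensor.
#' @param sample_rate nominal sampling frequency (samples/second). The
#'   original device spec does not travel with the CSV, so it is required
#'   metadata here; all downstream computations are rate-agnostic.
#' @param start_time recording start (seconds); ignored for the
#'   `timestamp` dialect, which carries its own.
#' @return a [wrist_recording()].
#' @export
read_wrist_recording <- function(path, side = c("right", "left"),
                                 sample_rate, start_time = 0) {
  side <- match.arg(side)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "actasym_format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    abort(paste0("empty recording file: ", path),
          class = "actasym_format_error")
  }
  names(df) <- tolower(names(df))
  if ("timestamp" %in% names(df) && !("t" %in% names(df))) {
    ts <- as.POSIXct(df$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(ts)) {
      abort("unparseable ISO-8601 timestamp", class = "actasym_format_error")
    }
    start_time <- as.numeric(ts[1])
    df$t <- as.numeric(ts) - start_time
  }
  if (!all(c("t", "ax", "ay", "az") %in% names(df))) {
    abort(paste0("expected columns t,ax,ay,az (or timestamp,ax,ay,az) in ",
                 path),
          class = "actasym_format_error")
  }
  wrist_recording(df, side = side, sample_rate = sample_rate,
                  start_time = start_time)
}

#' Write a raw wrist recording to CSV
#'
#' Writes the `t,ax,ay,az` dialect at full double precision, so
#' write/read round trips are lossless.
#'
#' @param rec a [wrist_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_wrist_recording <- function(rec, path) {
  stopifnot(inherits(rec, "wrist_recording"))
  readr::write_csv(tibble::as_tibble(rec)[c("t", "ax", "ay", "az")], path)
  invisible(path)
}

#' Pair two wrist recordings into a synchronized dual recording
#'
#' The two sensors are worn simultaneously; their declared start times
#' may differ by a bounded clock skew. The overlap window is the
#' intersection of the two absolute time spans; samples outside it are
#' excluded downstream (by [epoch_activity()]).
#'
#' @param right,left [wrist_recording()] objects for the respective sides.
#' @param max_clock_skew maximum tolerated difference between declared
#'   start times, seconds. Default 60 s (one epoch).
#' @return a `dual_recording`: list with elements `right`, `left`,
#'   `overlap_start`, `overlap_end` (absolute seconds).
#' @export
pair_recordings <- function(right, left, max_clock_skew = 60) {
  stopifnot(inherits(right, "wrist_recording"),
            inherits(left, "wrist_recording"))
  if (!identical(attr(right, "side"), "right") ||
      !identical(attr(left, "side"), "left")) {
    abort("pair_recordings() needs a right-side and a left-side recording",
          class = "actasym_pairing_error")
  }
  s_r <- attr(right, "start_time"); s_l <- attr(left, "start_time")
  if (abs(s_r - s_l) > max_clock_skew) {
    abort(sprintf("declared start times differ by %.1f s (> max_clock_skew %.1f s)",
                  abs(s_r - s_l), max_clock_skew),
          class = "actasym_pairing_error")
  }
  span <- function(rec) {
    s <- attr(rec, "start_time")
    c(s + rec$t[1], s + rec$t[nrow(rec)])
  }
  sp_r <- span(right); sp_l <- span(left)
  ov <- c(max(sp_r[1], sp_l[1]), min(sp_r[2], sp_l[2]))
  if (ov[2] <= ov[1]) {
    abort("recordings do not overlap in time", class = "actasym_pairing_error")
  }
  structure(list(right = right, left = left,
                 overlap_start = ov[1], overlap_end = ov[2]),
            class = "dual_recording")
}

#' @export
print.dual_recording <- function(x, ...) {
  cat(sprintf("<dual_recording> overlap %.1f h (%.1f .. %.1f s)\n",
              (x$overlap_end - x$overlap_start) / 3600,
              x$overlap_start, x$overlap_end))
  invisible(x)
}

# ---- cohort tables ---------------------------------------------------------

.aetiologies <- c("LAA", "CE", "SVO", "SUAe")
.comorbidity_tokens <- c("HT", "D", "CHD", "COPD", "HF", "AF")

validate_cohort <- function(df) {
  req <- c("code", "hemiparesis", "aspects", "aetiology", "comorbidities",
           "mrs", "ar2_abs")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "actasym_format_error")
  }
  df <- tibble::as_tibble(df[req])
  if (anyDuplicated(df$code)) {
    abort("patient codes must be unique", class = "actasym_validation_error")
  }
  df$hemiparesis <- tolower(as.character(df$hemiparesis))
  if (!all(df$hemiparesis %in% c("right", "left", "r", "l"))) {
    abort("hemiparesis must be right/left", class = "actasym_validation_error")
  }
  df$hemiparesis <- c(r = "right", l = "left", right = "right",
                      left = "left")[df$hemiparesis]
  if (!all(df$mrs %in% 0:6)) {
    abort("mrs must be an integer in 0..6", class = "actasym_validation_error")
  }
  if (!all(is.finite(df$ar2_abs)) || any(df$ar2_abs < 0 | df$ar2_abs > 100)) {
    abort("ar2_abs must lie in [0, 100] percent",
          class = "actasym_validation_error")
  }
  if (!all(df$aspects %in% 0:10)) {
    abort("aspects must be an integer in 0..10",
          class = "actasym_validation_error")
  }
  if (!all(df$aetiology %in% .aetiologies)) {
    abort(paste0("aetiology must be one of ",
                 paste(.aetiologies, collapse = "/")),
          class = "actasym_validation_error")
  }
  df$comorbidities <- ifelse(is.na(df$comorbidities) |
                               tolower(df$comorbidities) == "none",
                             "", df$comorbidities)
  df$mrs <- as.integer(df$mrs)
  df$aspects <- as.integer(df$aspects)
  df
}

#' Read a cohort table from CSV
#'
#' Expected header (case-insensitive):
#' `code,hemiparesis,aspects,aetiology,comorbidities,mrs,ar2_abs`, with
#' comorbidities as `;`-separated tokens (HT, D, CHD, COPD, HF, AF) and
#' `ar2_abs` the absolute asymmetry index in percent.
#'
#' @param path CSV file path.
#' @return a validated cohort tibble.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "actasym_format_error")
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("cannot parse cohort CSV: ",
                                     conditionMessage(e)),
                              class = "actasym_format_error"))
  if (nrow(df) == 0) {
    abort("cohort table is empty", class = "actasym_format_error")
  }
  names(df) <- tolower(names(df))
  if ("comorbidities" %in% names(df)) {
    df$comorbidities <- as.character(df$comorbidities)
  }
  validate_cohort(df)
}

#' Write a cohort table to CSV
#' @param cohort cohort tibble (see [read_cohort_table()] for the schema).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  readr::write_csv(validate_cohort(cohort), path, na = "")
  invisible(path)
}

#' The packaged 20-patient acute-stroke cohort
#'
#' Per-patient hemiparesis side, ASPECTS, TOAST aetiology, comorbidities,
#' 90-day mRS and the absolute 24-h asymmetry index (percent) for the
#' published 20-patient acute ischemic stroke cohort on which the index's
#' prognostic accuracy was established.
#'
#' @return a 20-row cohort tibble.
#' @export
stroke_cohort <- function() {
  read_cohort_table(system.file("extdata", "stroke_cohort_20.csv",
                                package = "actasym", mustWork = TRUE))
}

# ---- epoch tables ----------------------------------------------------------

#' Read/write paired epoch-activity tables
#'
#' CSV dialect `epoch_start_s,activity_right,activity_left`: one row per
#' synchronized 1-minute (by default) epoch, activities in g.
#'
#' @param path CSV file path.
#' @param epoch_length epoch length in seconds carried as metadata.
#' @return `read_epoch_table()`: a `paired_activity` tibble as produced
#'   by [pair_epochs()]. `write_epoch_table()`: `path`, invisibly.
#' @export
read_epoch_table <- function(path, epoch_length = 60) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "actasym_format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("epoch_start_s", "activity_right", "activity_left")
  if (!all(req %in% names(df))) {
    abort("expected columns epoch_start_s,activity_right,activity_left",
          class = "actasym_format_error")
  }
  new_paired_activity(df$epoch_start_s, df$activity_right, df$activity_left,
                      epoch_length = epoch_length, n_dropped = 0L)
}

#' @rdname read_epoch_table
#' @param pairs a `paired_activity` tibble from [pair_epochs()].
#' @export
write_epoch_table <- function(pairs, path) {
  stopifnot(inherits(pairs, "paired_activity"))
  out <- tibble::tibble(epoch_start_s = pairs$epoch_start,
                        activity_right = pairs$activity_right,
                        activity_left = pairs$activity_left)
  readr::write_csv(out, path)
  invisible(path)
}
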