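#' Construct an EEG recording
#'
#' A thin container for a continuous multi-channel EEG recording:
#' a channels x time numeric matrix in microvolts, its sampling rate,
#' channel labels (10/20 names), and optional event markers.
#'
#' @param samples numeric matrix, channels x time, microvolts.
#' @param rate sampling rate in samples/s (> 0).
#' @param channel_labels character vector, one label per channel.
#' @param events data.frame with columns `marker` (character) and `sample`
#'   (0-based sample index into the recording), or `NULL`.
#' @return an object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(1024), 2), 256, c("Fz", "Cz"))
eeg_recording <- function(samples, rate, channel_labels,
                          events = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop_("`rate` must be a single positive number, got %s", format(rate))
  channel_labels <- as.character(channel_labels)
  if (nrow(samples) != length(channel_labels))
    stop_("channel count mismatch: %d data rows but %d labels",
          nrow(samples), length(channel_labels))
  if (is.null(events))
    events <- data.frame(marker = character(), sample = integer())
  if (!all(c("marker", "sample") %in% names(events)))
    stop_("`events` needs columns `marker` and `sample`")
  if (nrow(events) &&
      (any(events$sample < 0) || any(events$sample >= ncol(samples))))
    stop_("event sample indices must lie in [0, %d)", ncol(samples))
  structure(list(samples = samples, rate = rate,
                 channel_labels = channel_labels, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate, nrow(x$events)))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' Read an EEG recording
#'
#' `matrix_csv` is the package's plain-text dialect: one row per sample, one
#' column per channel, plus a YAML sidecar `<path>.yaml` holding `rate`,
#' `channel_labels` and optional `events`.  `edf`/`bdf` parse the standard
#' European Data Format (16-bit) and its BioSemi 24-bit variant.
#'
#' @param path file path.
#' @param dialect one of `"matrix_csv"`, `"edf"`, `"bdf"`.
#' @return an [eeg_recording()].
#' @export
read_eeg_recording <- function(path, dialect = c("matrix_csv", "edf", "bdf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_("file not found: %s", path)
  if (dialect %in% c("edf", "bdf")) return(read_edf(path))
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop_("matrix_csv sidecar missing: %s (rate metadata is never guessed)", sc)
  meta <- yaml::read_yaml(sc)
  if (is.null(meta$rate))
    stop_("sidecar %s lacks `rate`; refusing to guess a sampling rate", sc)
  if (is.null(meta$channel_labels))
    stop_("sidecar %s lacks `channel_labels`", sc)
  dat <- tryCatch(read.csv(path, check.names = FALSE),
                  error = function(e) stop_("cannot parse %s as CSV: %s",
                                            path, conditionMessage(e)))
  labels <- as.character(meta$channel_labels)
  if (ncol(dat) != length(labels))
    stop_("%s: %d data columns but %d channel labels in sidecar",
          path, ncol(dat), length(labels))
  bad <- which(!vapply(dat, is.numeric, logical(1)))
  if (length(bad))
    stop_("%s: non-numeric data in column(s) %s", path,
          paste(bad, collapse = ", "))
  ev <- NULL
  if (!is.null(meta$events))
    ev <- data.frame(marker = vapply(meta$events, function(e) as.character(e$marker), ""),
                     sample = vapply(meta$events, function(e) as.integer(e$sample), 0L))
  eeg_recording(t(as.matrix(dat)), meta$rate, labels, ev)
}

#' Write an EEG recording
#'
#' Inverse of [read_eeg_recording()].  The `matrix_csv` writer is canonical
#' (full `%.17g` precision), so read -> write round-trips are byte-identical.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param dialect `"matrix_csv"` or `"edf"` (`"bdf"` via [write_edf()]).
#' @return `path`, invisibly.
#' @export
write_eeg_recording <- function(rec, path, dialect = c("matrix_csv", "edf", "bdf")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rec, "eeg_recording"))
  if (dialect %in% c("edf", "bdf"))
    return(write_edf(rec, path, bits = if (dialect == "bdf") 24L else 16L))
  lines <- c(paste(rec$channel_labels, collapse = ","),
             apply(rec$samples, 2, function(col) paste(fmt_num(col), collapse = ",")))
  writeLines(lines, path)
  meta <- list(rate = rec$rate, channel_labels = as.list(rec$channel_labels))
  if (nrow(rec$events))
    meta$events <- lapply(seq_len(nrow(rec$events)), function(i)
      list(marker = rec$events$marker[i], sample = rec$events$sample[i]))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

# ---- gaze tables -----------------------------------------------------------

gaze_cols <- c("participant_id", "viewing", "trailer_id", "time_ms",
               "x_px", "y_px", "valid")

#' Validate a gaze sample table
#'
#' Checks the seven-column contract of gaze tables: `viewing` in \{1, 2\},
#' non-decreasing `time_ms` within each (participant, viewing, trailer)
#' trace, no duplicated time stamps within a trace, and a logical `valid`
#' flag (0/1 accepted).  Invalid samples are kept, flagged, never dropped.
#'
#' @param df data.frame with columns `participant_id`, `viewing`,
#'   `trailer_id`, `time_ms`, `x_px`, `y_px`, `valid`.
#' @return the validated data.frame, classed `gaze_table`.
#' @export
gaze_table <- function(df) {
  miss <- setdiff(gaze_cols, names(df))
  if (length(miss)) stop_("gaze table lacks column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[gaze_cols]
  if (!all(df$viewing %in% c(1L, 2L)))
    stop_("`viewing` outside {1,2} in row(s): %s",
          paste(head(which(!df$viewing %in% c(1L, 2L)), 5L), collapse = ", "))
  df$valid <- as.logical(df$valid)
  if (anyNA(df$valid)) stop_("`valid` must be logical or 0/1")
  key <- interaction(df$participant_id, df$viewing, df$trailer_id, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    tt <- df$time_ms[idx]
    if (is.unsorted(tt))
      stop_("non-monotone time within trace %s at row(s): %s", k,
            paste(head(idx[which(diff(tt) < 0) + 1L], 5L), collapse = ", "))
    if (anyDuplicated(tt))
      stop_("duplicated (participant, viewing, trailer, time) in trace %s at row(s): %s",
            k, paste(head(idx[duplicated(tt)], 5L), collapse = ", "))
  }
  class(df) <- c("gaze_table", "data.frame")
  df
}

#' Read a gaze sample table from CSV/TSV
#'
#' @param path file path; tab-separated when the extension is `.tsv`.
#' @return a validated [gaze_table()].
#' @export
read_gaze_table <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  gaze_table(read.csv(path, sep = sep))
}

#' Write a gaze table (inverse of [read_gaze_table()])
#' @param gt a [gaze_table()].
#' @param path output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(gt, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  write.table(as.data.frame(gt), path, sep = sep, row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Split a gaze table into per-trace time series
#'
#' Groups rows by (participant, viewing, trailer) and returns one trace per
#' group: an n x 2 pixel-coordinate matrix with its validity flags, all on
#' the common sampling grid.  Order of samples is preserved as read.
#'
#' @param gt a [gaze_table()].
#' @param trailer restrict to one `trailer_id` (`NULL` = all; required if
#'   the table holds several trailers and traces must share a grid).
#' @param viewing restrict to viewing 1 or 2 (`NULL` pools both).
#' @return list of traces: `list(participant, viewing, trailer, time_ms,
#'   xy, valid)`.
#' @export
gaze_traces <- function(gt, trailer = NULL, viewing = NULL) {
  df <- as.data.frame(gt)
  if (!is.null(trailer)) df <- df[df$trailer_id == trailer, , drop = FALSE]
  if (!is.null(viewing)) df <- df[df$viewing == viewing, , drop = FALSE]
  if (!nrow(df)) stop_("no gaze rows after filtering")
  key <- interaction(df$participant_id, df$viewing, df$trailer_id, drop = TRUE)
  traces <- lapply(split(df, key), function(d)
    list(participant = d$participant_id[1L], viewing = d$viewing[1L],
         trailer = d$trailer_id[1L], time_ms = d$time_ms,
         xy = cbind(d$x_px, d$y_px), valid = d$valid))
  n <- vapply(traces, function(tr) length(tr$time_ms), 0L)
  if (length(unique(n)) != 1L)
    stop_("traces on inconsistent grids: lengths %s",
          paste(unique(n), collapse = ", "))
  t0 <- traces[[1L]]$time_ms
  for (tr in traces)
    if (any(tr$time_ms != t0))
      stop_("traces on inconsistent grids: time stamps differ")
  unname(traces)
}

# ---- behavioral and KPI tables --------------------------------------------

#' Read a behavioral response table
#'
#' Expects CSV columns `participant_id`, `viewing`, `trailer_id`, `liking`
#' (integer 0-10), `wtw`, `wtr` (yes/no or 0/1: willingness to watch /
#' refer).  The liking instrument is nominally 1-10 but observed responses
#' can include 0, so 0-10 is accepted.
#'
#' @param path file path.
#' @return data.frame with `wtw`/`wtr` as logicals.
#' @export
read_response_table <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  response_table(read.csv(path))
}

#' Validate a behavioral response table (see [read_response_table()])
#' @param df data.frame of responses.
#' @return validated data.frame.
#' @export
response_table <- function(df) {
  need <- c("participant_id", "viewing", "trailer_id", "liking", "wtw", "wtr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("response table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  to_lgl <- function(x) {
    if (is.character(x)) x <- tolower(x) == "yes"
    as.logical(x)
  }
  df$wtw <- to_lgl(df$wtw); df$wtr <- to_lgl(df$wtr)
  if (anyNA(df$wtw) || anyNA(df$wtr)) stop_("wtw/wtr must be yes/no or 0/1")
  if (any(df$liking < 0 | df$liking > 10 | df$liking != round(df$liking)))
    stop_("`liking` must be an integer in 0..10")
  if (!all(df$viewing %in% c(1L, 2L))) stop_("`viewing` outside {1,2}")
  key <- paste(df$participant_id, df$viewing, df$trailer_id)
  if (anyDuplicated(key))
    stop_("duplicate response for (participant, viewing, trailer): %s",
          key[anyDuplicated(key)])
  df
}

#' Read a per-movie KPI table
#'
#' One row per movie with the sales-performance KPI (opening-weekend
#' revenue divided by production budget) at the premiere and each of the
#' eight following weekends: columns `movie`, `premiere`, `wknd1`..`wknd8`.
#'
#' @param path file path.
#' @return data.frame of KPI values (all >= 0).
#' @export
read_kpi_table <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  df <- read.csv(path)
  need <- c("movie", "premiere", paste0("wknd", 1:8))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("KPI table lacks column(s): %s", paste(miss, collapse = ", "))
  if (any(as.matrix(df[need[-1]]) < 0)) stop_("KPI values must be >= 0")
  if (anyDuplicated(df$movie)) stop_("duplicated movie ids in KPI table")
  df
}

#' The packaged 15-movie box-office KPI table
#'
#' Sales-performance KPI (weekend revenue / production budget) for the 15
#' movies of the trailer study the package is designed around, at the
#' premiere weekend and the eight weekends after it.
#'
#' @return data.frame, 15 rows x 10 columns.
#' @export
#' @examples
#' head(movie_kpi())
movie_kpi <- function() {
  read_kpi_table(system.file("extdata", "movie_kpi.csv",
                             package = "trailermetrics", mustWork = TRUE))
}
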