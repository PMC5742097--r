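# Continuous-signal conditioning: resample to 256 Hz, zero-phase high-pass
# and notch filtering, average reference, then epoching with baseline
# removal.  All filters are applied forward-backward (signal::filtfilt), so
# the chain is zero-phase; the first/last second of the continuous output
# carry filter transients, which the +/- 2 s epoch padding absorbs.

filtfilt_rows <- function(x, flt) {
  for (i in seq_len(nrow(x))) x[i, ] <- signal::filtfilt(flt, x[i, ])
  x
}

#' Condition a continuous EEG recording
#'
#' Downsamples to `target_rate` (integer factors only, with an 8th-order
#' Butterworth anti-alias low-pass at 80% of the new Nyquist), applies a
#' zero-phase Butterworth high-pass to remove DC drift, zero-phase
#' Butterworth band-stop notches at the power-line frequency and its first
#' harmonic (bandwidth f0/Q), and finally re-references every sample to the
#' average across channels.
#'
#' @param rec an [eeg_recording()] with `rate >= target_rate`, an integer
#'   multiple of it, and at least 2 channels.
#' @param target_rate output sampling rate, samples/s.
#' @param highpass_hz high-pass cutoff, Hz.
#' @param notch_hz frequencies to notch out, Hz (set `NULL` to skip).
#' @param notch_q notch quality factor (bandwidth = f0 / Q).
#' @param order high-pass Butterworth order (effective order doubles under
#'   forward-backward filtering).
#' @return an [eeg_recording()] at `target_rate` whose channel-mean is zero
#'   at every sample; event sample indices are rescaled.
#' @export
preprocess_continuous <- function(rec, target_rate = 256, highpass_hz = 1.5,
                                  notch_hz = c(50, 100), notch_q = 30,
                                  order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$samples) < 2L)
    stop_("average reference needs >= 2 channels, got %d", nrow(rec$samples))
  if (rec$rate < target_rate)
    stop_("recording rate %g < target %g: upsampling refused", rec$rate,
          target_rate)
  factor <- rec$rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop_("rate %g is not an integer multiple of %g", rec$rate, target_rate)
  factor <- as.integer(round(factor))
  x <- rec$samples
  if (factor > 1L) {
    aa <- signal::butter(8, 0.8 * (target_rate / 2) / (rec$rate / 2),
                         type = "low")
    x <- filtfilt_rows(x, aa)
    x <- x[, seq(1L, ncol(x), by = factor), drop = FALSE]
  }
  fs <- target_rate
  hp <- signal::butter(order, highpass_hz / (fs / 2), type = "high")
  x <- filtfilt_rows(x, hp)
  for (f0 in notch_hz) {
    bw <- f0 / notch_q
    bs <- signal::butter(2, c(f0 - bw / 2, f0 + bw / 2) / (fs / 2),
                         type = "stop")
    x <- filtfilt_rows(x, bs)
  }
  x <- sweep(x, 2L, colMeans(x))
  ev <- rec$events
  if (nrow(ev)) ev$sample <- ev$sample %/% factor
  eeg_recording(x, fs, rec$channel_labels, ev)
}

#' Construct an EEG epoch
#'
#' @param samples channels x time matrix at `rate`.
#' @param rate samples/s.
#' @param t0_offset_ms time of the first sample relative to trailer onset.
#' @param trailer_id,participant_id,viewing identifiers.
#' @return object of class `eeg_epoch`.
#' @export
eeg_epoch <- function(samples, rate, t0_offset_ms, trailer_id = NA,
                      participant_id = NA, viewing = NA) {
  structure(list(samples = as.matrix(samples), rate = rate,
                 t0_offset_ms = t0_offset_ms, trailer_id = trailer_id,
                 participant_id = participant_id, viewing = viewing),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> trailer %s: %d ch x %d samples @ %g Hz, t0 %+d ms\n",
              x$trailer_id, nrow(x$samples), ncol(x$samples), x$rate,
              x$t0_offset_ms))
  invisible(x)
}

#' Cut trailer epochs out of a continuous recording
#'
#' One epoch per trailer presentation, spanning `pre_ms` before the trailer
#' start marker to `post_ms` after the end marker (half-open sample window,
#' 0-based indices).  The per-channel mean over the baseline window
#' `[-pre_ms, 0)` ms is subtracted.
#'
#' @param rec conditioned [eeg_recording()].
#' @param trailer_events data.frame with columns `trailer_id`,
#'   `start_sample`, `end_sample` (0-based sample indices at `rec$rate`;
#'   `end_sample` is exclusive, marking the trailer's finish time).
#' @param pre_ms,post_ms padding before onset / after finish, ms.
#' @param participant_id,viewing carried into each epoch's metadata.
#' @return list of [eeg_epoch()] objects, one per row of `trailer_events`.
#' @export
epoch_signal <- function(rec, trailer_events, pre_ms = 2000, post_ms = 2000,
                         participant_id = NA, viewing = NA) {
  stopifnot(inherits(rec, "eeg_recording"))
  need <- c("trailer_id", "start_sample", "end_sample")
  if (!all(need %in% names(trailer_events)))
    stop_("`trailer_events` needs columns %s", paste(need, collapse = ", "))
  if (anyNA(trailer_events$end_sample))
    stop_("missing end marker for trailer %s",
          trailer_events$trailer_id[which(is.na(trailer_events$end_sample))[1L]])
  pre <- round(pre_ms * rec$rate / 1000)
  post <- round(post_ms * rec$rate / 1000)
  lapply(seq_len(nrow(trailer_events)), function(i) {
    id <- trailer_events$trailer_id[i]
    s0 <- trailer_events$start_sample[i]
    s1 <- trailer_events$end_sample[i]
    if (s1 <= s0) stop_("trailer %s: end marker before start", id)
    i0 <- s0 - pre
    i1 <- s1 + post                              # exclusive
    if (i0 < 0L || i1 > ncol(rec$samples))
      stop_("trailer %s: epoch window [%d, %d) exceeds recording of %d samples",
            id, i0, i1, ncol(rec$samples))
    x <- rec$samples[, (i0 + 1L):i1, drop = FALSE]
    baseline <- rowMeans(rec$samples[, (i0 + 1L):s0, drop = FALSE])
    eeg_epoch(x - baseline, rec$rate, -pre_ms, id, participant_id, viewing)
  })
}
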