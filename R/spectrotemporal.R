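# Complex Morlet spectro-temporal decomposition.  Each epoch channel is
# convolved (FFT-based, zero-phase "same" alignment) with complex Morlet
# kernels on a half-Hz grid; instantaneous power is the squared coefficient
# magnitude, then averaged inside consecutive non-overlapping 125 ms bins
# to an 8 samples/s power series.

morlet_kernel <- function(f, fs, n_cycles) {
  sigma <- n_cycles / (2 * pi * f)
  half <- ceiling(3.5 * sigma * fs)
  t <- (-half:half) / fs
  env <- exp(-t^2 / (2 * sigma^2))
  k <- env * exp(2i * pi * f * t)
  # unit-amplitude sinusoid at f -> |coefficient| ~ 1 (power ~ 1 uV^2)
  k * (2 / sum(env))
}

#' Morlet time-frequency power of an epoch
#'
#' @param epoch an [eeg_epoch()] (or channels x time matrix via `rate`).
#' @param freqs analysis frequencies, Hz; default the half-Hz grid 1-80
#'   (159 values).
#' @param n_cycles Morlet width in cycles, constant across frequencies.
#' @param power_rate output power sampling rate, samples/s; power is the
#'   mean squared coefficient magnitude within each 1/power_rate bin.
#' @param rate input sampling rate, only if `epoch` is a bare matrix.
#' @return object of class `tfr_power`: list with `power` (channels x
#'   frequencies x time array, non-negative), `freqs`, `power_rate`, and the
#'   epoch's metadata.
#' @export
morlet_power <- function(epoch, freqs = seq(1, 80, by = 0.5), n_cycles = 7,
                         power_rate = 8, rate = NULL) {
  if (inherits(epoch, "eeg_epoch")) {
    x <- epoch$samples; fs <- epoch$rate; meta <- epoch
  } else {
    if (is.null(rate)) stop_("`rate` required when `epoch` is a matrix")
    x <- as.matrix(epoch); fs <- rate; meta <- NULL
  }
  D <- nrow(x); T <- ncol(x)
  if (any(freqs <= 0)) stop_("frequencies must be positive")
  kmax <- 2L * ceiling(3.5 * n_cycles / (2 * pi * min(freqs)) * fs) + 1L
  if (T < kmax)
    stop_("epoch of %d samples shorter than the %g Hz wavelet (%d samples)",
          T, min(freqs), kmax)
  bin <- fs / power_rate
  if (abs(bin - round(bin)) > 1e-9)
    stop_("sampling rate %g not divisible by power rate %g", fs, power_rate)
  bin <- as.integer(round(bin))
  n_bins <- T %/% bin
  nfft <- nextn(T + kmax - 1L, 2L)
  X <- mvfft(rbind(t(x), matrix(0, nfft - T, D)))
  pow <- array(0, dim = c(D, length(freqs), n_bins))
  binf <- rep(seq_len(n_bins), each = bin)
  for (j in seq_along(freqs)) {
    k <- morlet_kernel(freqs[j], fs, n_cycles)
    half <- (length(k) - 1L) %/% 2L
    K <- fft(c(k, rep(0, nfft - length(k))))
    co <- mvfft(X * K, inverse = TRUE) / nfft
    co <- co[(half + 1L):(half + T), , drop = FALSE]   # "same" alignment
    p2 <- Mod(co[seq_len(n_bins * bin), , drop = FALSE])^2
    pow[, j, ] <- t(rowsum(p2, binf) / bin)
  }
  structure(list(power = pow, freqs = freqs, power_rate = power_rate,
                 trailer_id = meta$trailer_id %||% NA,
                 participant_id = meta$participant_id %||% NA,
                 viewing = meta$viewing %||% NA,
                 t0_offset_ms = meta$t0_offset_ms %||% NA),
            class = "tfr_power")
}

#' @export
print.tfr_power <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tfr_power> %d ch x %d freqs (%g-%g Hz) x %d power samples @ %g Hz\n",
              d[1L], d[2L], min(x$freqs), max(x$freqs), d[3L], x$power_rate))
  invisible(x)
}

#' Average time-frequency power over a frequency band
#'
#' Band edges are inclusive on the analysis grid: every grid frequency f
#' with `f_lo <= f <= f_hi` enters the mean.
#'
#' @param tfr a [morlet_power()] result.
#' @param band numeric length-2, `c(f_lo, f_hi)` in Hz.
#' @return object of class `band_power`: `X` (channels x time matrix of
#'   band-averaged instantaneous power, non-negative), `band`, `power_rate`
#'   and the epoch's identifiers.
#' @export
band_average <- function(tfr, band) {
  stopifnot(inherits(tfr, "tfr_power"), length(band) == 2L)
  if (band[1L] >= band[2L]) stop_("band must satisfy f_lo < f_hi")
  if (band[1L] < min(tfr$freqs) - 1e-9 || band[2L] > max(tfr$freqs) + 1e-9)
    stop_("band [%g, %g] outside the analysis grid [%g, %g]",
          band[1L], band[2L], min(tfr$freqs), max(tfr$freqs))
  sel <- which(tfr$freqs >= band[1L] - 1e-9 & tfr$freqs <= band[2L] + 1e-9)
  X <- apply(tfr$power[, sel, , drop = FALSE], c(1L, 3L), mean)
  band_power(X, band, power_rate = tfr$power_rate,
             participant_id = tfr$participant_id, viewing = tfr$viewing,
             trailer_id = tfr$trailer_id)
}

#' Construct a band-power epoch (channels x time instantaneous power)
#'
#' @param X channels x time numeric matrix of band-averaged power.
#' @param band numeric length-2 band in Hz.
#' @param power_rate samples/s of the power series.
#' @param participant_id,viewing,trailer_id identifiers.
#' @return object of class `band_power`.
#' @export
band_power <- function(X, band, power_rate = 8, participant_id = NA,
                       viewing = NA, trailer_id = NA) {
  X <- as.matrix(X)
  structure(list(X = X, band = band, power_rate = power_rate,
                 participant_id = participant_id, viewing = viewing,
                 trailer_id = trailer_id),
            class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf("<band_power> band %g-%g Hz: %d ch x %d samples\n",
              x$band[1L], x$band[2L], nrow(x$X), ncol(x$X)))
  invisible(x)
}
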