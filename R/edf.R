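# Minimal European Data Format reader/writer.
#
# Covers the subset the pipeline needs: fixed 256-byte header, per-signal
# headers, contiguous data records of 16-bit (EDF) or 24-bit (BDF) little-
# endian integers with linear physical scaling.  All signals must share one
# sampling rate.  EDF+ annotation channels are not parsed; event markers
# travel in the matrix_csv sidecar instead.

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read an EDF or BDF file
#'
#' @param path file path; the variant (16- vs 24-bit) is detected from the
#'   version field of the header.
#' @return an [eeg_recording()] with physical units as stored (microvolts
#'   for standard EEG exports).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  ver_raw <- readBin(con, "raw", 8L)
  bdf <- ver_raw[1L] == as.raw(255L)
  readBin(con, "raw", 160L)                      # patient + recording ids
  readBin(con, "raw", 16L)                       # start date + time
  hdr_bytes <- suppressWarnings(as.integer(read_ascii(con, 8L)))
  read_ascii(con, 44L)                           # reserved
  n_rec <- suppressWarnings(as.integer(read_ascii(con, 8L)))
  rec_dur <- suppressWarnings(as.numeric(read_ascii(con, 8L)))
  ns <- suppressWarnings(as.integer(read_ascii(con, 4L)))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0)
    stop_("%s: malformed EDF header (ns=%s, records=%s, duration=%s)",
          path, ns, n_rec, rec_dur)
  fld <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- fld(16L); fld(80L); fld(8L)
  pmin <- as.numeric(fld(8L)); pmax <- as.numeric(fld(8L))
  dmin <- as.numeric(fld(8L)); dmax <- as.numeric(fld(8L))
  fld(80L)
  spr <- as.integer(fld(8L))
  fld(32L)
  if (length(unique(spr)) != 1L)
    stop_("%s: signals with different sampling rates are not supported", path)
  if (!is.na(hdr_bytes) && hdr_bytes != 256L * (1L + ns))
    stop_("%s: header size field %d inconsistent with %d signals (byte %d)",
          path, hdr_bytes, ns, 256L * (1L + ns))
  bps <- if (bdf) 3L else 2L
  n_per_rec <- ns * spr[1L]
  x <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    if (bdf) {
      b <- readBin(con, "raw", n_per_rec * 3L)
      if (length(b) < n_per_rec * 3L)
        stop_("%s: truncated data record %d (byte %d)", path, r,
              256L * (1L + ns) + (r - 1L) * n_per_rec * bps + length(b))
      u <- as.integer(b)
      v <- u[c(TRUE, FALSE, FALSE)] + 256L * u[c(FALSE, TRUE, FALSE)] +
        65536L * u[c(FALSE, FALSE, TRUE)]
      v <- ifelse(v >= 8388608L, v - 16777216L, v)
    } else {
      v <- readBin(con, "integer", n_per_rec, size = 2L, signed = TRUE,
                   endian = "little")
      if (length(v) < n_per_rec)
        stop_("%s: truncated data record %d (byte %d)", path, r,
              256L * (1L + ns) + (r - 1L) * n_per_rec * bps + 2L * length(v))
    }
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    x[, cols] <- matrix(v, nrow = spr[1L])[, seq_len(ns)] |> t()
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  x <- x * gain + (pmin - dmin * gain)
  eeg_recording(x, spr[1L] / rec_dur, labels)
}

#' Write an EDF or BDF file
#'
#' Linear 16-bit (EDF) or 24-bit (BDF) quantization over each channel's
#' observed range; lossy by at most range / 2^bits per sample.
#'
#' @param rec an [eeg_recording()].
#' @param path output path.
#' @param bits 16 (EDF) or 24 (BDF).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, bits = 16L) {
  stopifnot(inherits(rec, "eeg_recording"), bits %in% c(16L, 24L))
  ns <- nrow(rec$samples); nt <- ncol(rec$samples)
  con <- file(path, "wb"); on.exit(close(con))
  pad <- function(s, w) {
    s <- substr(s, 1L, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  if (bits == 24L) {
    writeBin(as.raw(255L), con); wr("BIOSEMI", 7L)
  } else wr("0", 8L)
  wr("", 80L); wr("", 80L)
  wr("01.01.26", 8L); wr("00.00.00", 8L)
  wr(format(256L * (1L + ns)), 8L)
  wr(if (bits == 24L) "24BIT" else "EDF", 44L)
  wr("1", 8L)                                    # one data record
  wr(format(nt / rec$rate), 8L)
  wr(format(ns), 4L)
  dmax <- if (bits == 24L) 8388607L else 32767L
  # symmetric physical range whose 8-char ASCII header field is exact, so
  # scaling on read matches scaling on write to quantization precision
  hdr_bound <- function(lim) {              # shortest string >= lim, <= 7 ch
    v <- lim * 1.001 + 1e-9
    for (k in 1:30) {
      s <- ""
      for (d in 7:1) {
        s <- formatC(v, digits = d, format = "g")
        if (nchar(s) <= 7L) break
      }
      if (nchar(s) <= 7L && as.numeric(s) >= lim) return(s)
      v <- v * 1.01
    }
    stop_("physical range %g not representable in an EDF header", lim)
  }
  Ms <- vapply(seq_len(ns), function(i)
    hdr_bound(max(abs(rec$samples[i, ]), 1e-6)), "")
  M <- as.numeric(Ms)
  pmin <- -M; pmax <- M
  for (l in rec$channel_labels) wr(l, 16L)
  for (i in 1:ns) wr("", 80L)
  for (i in 1:ns) wr("uV", 8L)
  for (s in paste0("-", Ms)) wr(s, 8L)
  for (s in Ms) wr(s, 8L)
  for (i in 1:ns) wr(format(-dmax - 1L), 8L)
  for (i in 1:ns) wr(format(dmax), 8L)
  for (i in 1:ns) wr("", 80L)
  for (i in 1:ns) wr(format(nt), 8L)
  for (i in 1:ns) wr("", 32L)
  for (i in 1:ns) {
    g <- (pmax[i] - pmin[i]) / (2 * as.numeric(dmax) + 1)
    d <- as.integer(round((rec$samples[i, ] - pmin[i]) / g)) - dmax - 1L
    if (bits == 24L) {
      u <- ifelse(d < 0L, d + 16777216L, d)
      b <- as.raw(rbind(u %% 256L, (u %/% 256L) %% 256L, u %/% 65536L))
      writeBin(b, con)
    } else writeBin(d, con, size = 2L, endian = "little")
  }
  invisible(path)
}
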