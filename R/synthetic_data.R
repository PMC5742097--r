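# Generators that plant, at controllable strength, exactly the structure
# the two metrics look for: a spatially fixed cross-viewing band-power
# component (congruency), a shared gaze attractor path (asynchrony), and
# KPIs linearly coupled to a ground-truth metric (regression harness).
# All randomness flows from one master seed through named substreams
# (derive_seed), so each generator is independently reproducible.

#' Simulation configuration
#'
#' Desk-scale defaults (8 subjects, 6 trailers of 30 s, 8 channels) keep a
#' full synthetic study cheap while preserving the structure of the real
#' design (two viewings per trailer, per-trailer coupling strengths).
#'
#' @param n_subjects participants (each sees every trailer twice).
#' @param n_trailers number of trailers.
#' @param trailer_dur_s trailer duration, seconds.
#' @param n_channels EEG channels D.
#' @param snr_congruency per-trailer variance ratio of the planted shared
#'   band-power component to channel noise (>= 0; recycled to
#'   `n_trailers`).  The population value of the congruency eigenvalue is
#'   `snr / (2 snr + 2)`.
#' @param gaze_sync per-trailer gaze synchrony rho in \[0, 1\]: weight of
#'   the shared attractor path in every trace (recycled).
#' @param kpi_intercept,kpi_beta,kpi_noise_sd linear coupling of the
#'   premiere KPI to the ground-truth metric.
#' @param jitter_px gaze measurement jitter SD, pixels.
#' @param invalid_rate fraction of gaze samples flagged invalid.
#' @param screen `c(width_px, height_px)`.
#' @param seed master seed (mandatory).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 8, n_trailers = 6, trailer_dur_s = 30,
                       n_channels = 8,
                       snr_congruency = seq(0.5, 4, length.out = n_trailers),
                       gaze_sync = seq(0.1, 0.9, length.out = n_trailers),
                       kpi_intercept = 0.35, kpi_beta = 0.8,
                       kpi_noise_sd = 0.08, jitter_px = 5,
                       invalid_rate = 0.02, screen = c(1024, 768), seed) {
  if (missing(seed)) stop_("`seed` is mandatory")
  if (any(c(n_subjects, n_trailers, trailer_dur_s, n_channels) <= 0))
    stop_("all sizes must be positive")
  snr_congruency <- rep_len(snr_congruency, n_trailers)
  gaze_sync <- rep_len(gaze_sync, n_trailers)
  if (any(snr_congruency < 0)) stop_("snr_congruency must be >= 0")
  if (any(gaze_sync < 0 | gaze_sync > 1)) stop_("gaze_sync must lie in [0, 1]")
  if (kpi_noise_sd < 0) stop_("kpi_noise_sd must be >= 0")
  structure(list(n_subjects = n_subjects, n_trailers = n_trailers,
                 trailer_dur_s = trailer_dur_s, n_channels = n_channels,
                 snr_congruency = snr_congruency, gaze_sync = gaze_sync,
                 kpi_intercept = kpi_intercept, kpi_beta = kpi_beta,
                 kpi_noise_sd = kpi_noise_sd, jitter_px = jitter_px,
                 invalid_rate = invalid_rate, screen = screen,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# smooth screen-traversing path: sum of low-frequency sinusoids, scaled to
# stay inside the central 80% of the extent
smooth_path <- function(n, rate, extent) {
  t <- (seq_len(n) - 1L) / rate
  f <- runif(4, 0.03, 0.35)
  a <- runif(4, 0.3, 1)
  ph <- runif(4, 0, 2 * pi)
  raw <- colSums(a * sin(outer(2 * pi * f, t) + ph))
  extent / 2 + raw / max(abs(raw), 1e-12) * 0.4 * extent
}

ar1_std <- function(n, coef = 0.9) {
  z <- as.numeric(stats::filter(rnorm(n), coef, method = "recursive"))
  (z - mean(z)) / sd(z)
}

#' Simulate a paired-viewing EEG study
#'
#' `level = "bandpower"` (default) generates, per trailer and subject, the
#' two D x T instantaneous-power matrices the congruency step consumes:
#' a smooth (AR(1)) standardized component time course, shared between the
#' subject's two viewings, is mixed into channels through one fixed random
#' unit topography and scaled by `sqrt(snr)`; independent unit-variance
#' channel noise is added per viewing.  `level = "raw"` generates
#' continuous 256 Hz recordings in which the shared course amplitude-
#' modulates a gamma-band carrier (61 Hz, random phase per viewing) mixed
#' through the same topography, with start/end event markers — feedable to
#' the full [preprocess_continuous()] / [morlet_power()] chain.
#'
#' @param cfg a [sim_config()].
#' @param level `"bandpower"` or `"raw"`.
#' @param power_rate band-power sampling rate (bandpower level).
#' @return list with one element per trailer: `trailer_id`, `snr`,
#'   `topography` (the planted mixing vector), and `subjects` — per subject
#'   `list(X1, X2)` band-power matrices, or `list(rec1, rec2, events)`
#'   recordings at the raw level.
#' @export
simulate_eeg_study <- function(cfg, level = c("bandpower", "raw"),
                               power_rate = 8) {
  stopifnot(inherits(cfg, "sim_config"))
  level <- match.arg(level)
  D <- cfg$n_channels
  with_seed(derive_seed(cfg$seed, paste0("eeg_", level)), {
    lapply(seq_len(cfg$n_trailers), function(tr) {
      m <- rnorm(D); m <- m / sqrt(sum(m^2))
      snr <- cfg$snr_congruency[tr]
      subjects <- lapply(seq_len(cfg$n_subjects), function(s) {
        if (level == "bandpower") {
          T <- as.integer(cfg$trailer_dur_s * power_rate)
          z <- ar1_std(T)
          mk <- function() sqrt(snr) * tcrossprod(m, z) +
            matrix(rnorm(D * T), D)
          list(X1 = mk(), X2 = mk())
        } else {
          fs <- 256
          margin <- 3 * fs                       # covers epoch pad + filter edge
          nt <- as.integer(cfg$trailer_dur_s * fs)
          n <- nt + 2L * margin
          env <- 1 + 0.8 * ar1_std(n, 0.995)     # slow amplitude modulation
          mk <- function() {
            carrier <- cos(2 * pi * 61 * (seq_len(n) - 1L) / fs +
                             runif(1, 0, 2 * pi))
            x <- sqrt(snr) * 10 * tcrossprod(m, env * carrier) +
              matrix(rnorm(D * n, sd = 10), D)
            eeg_recording(x, fs, sprintf("ch%02d", seq_len(D)),
                          data.frame(marker = c("start", "end"),
                                     sample = c(margin, margin + nt)))
          }
          list(rec1 = mk(), rec2 = mk(),
               events = data.frame(trailer_id = tr, start_sample = margin,
                                   end_sample = margin + nt))
        }
      })
      list(trailer_id = tr, snr = snr, topography = m, subjects = subjects)
    })
  })
}

#' Simulate a gaze study
#'
#' Each trailer gets one smooth random attractor path on the screen; every
#' trace (participant x viewing) follows
#' `rho * attractor + (1 - rho) * own smooth wander + jitter`, on a 60 Hz
#' grid, with samples flagged invalid at `invalid_rate`.  `rho = 1` is the
#' fully guided limit, `rho = 0` fully idiosyncratic viewing.
#'
#' @param cfg a [sim_config()].
#' @param rate gaze sampling rate, samples/s.
#' @return a [gaze_table()] covering all participants, viewings, trailers.
#' @export
simulate_gaze_study <- function(cfg, rate = 60) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- as.integer(cfg$trailer_dur_s * rate)
  time_ms <- (seq_len(n) - 1L) * 1000 / rate
  with_seed(derive_seed(cfg$seed, "gaze"), {
    rows <- list()
    for (tr in seq_len(cfg$n_trailers)) {
      rho <- cfg$gaze_sync[tr]
      ax <- smooth_path(n, rate, cfg$screen[1L])
      ay <- smooth_path(n, rate, cfg$screen[2L])
      for (p in seq_len(cfg$n_subjects)) for (v in 1:2) {
        wx <- smooth_path(n, rate, cfg$screen[1L])
        wy <- smooth_path(n, rate, cfg$screen[2L])
        x <- rho * ax + (1 - rho) * wx + rnorm(n, sd = cfg$jitter_px)
        y <- rho * ay + (1 - rho) * wy + rnorm(n, sd = cfg$jitter_px)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = sprintf("p%02d", p), viewing = v,
          trailer_id = tr, time_ms = time_ms,
          x_px = pmin(pmax(x, 0), cfg$screen[1L]),
          y_px = pmin(pmax(y, 0), cfg$screen[2L]),
          valid = runif(n) >= cfg$invalid_rate)
      }
    }
    gaze_table(do.call(rbind, rows))
  })
}

#' Simulate behavioral responses and KPI records
#'
#' The premiere KPI is linear in the supplied ground-truth metric
#' (`kpi_intercept + kpi_beta * metric + N(0, kpi_noise_sd)`, floored at
#' 0); weekend KPIs decay geometrically (factor `decay`) with lognormal
#' multiplicative noise.  Liking responses follow the scaled metric with a
#' participant random effect; willingness-to-watch/refer are Bernoulli in
#' the liking.
#'
#' @param cfg a [sim_config()].
#' @param true_metrics numeric, one ground-truth metric value per trailer.
#' @param decay weekend-over-weekend geometric decay of the KPI.
#' @param weekend_noise_sd SD of the lognormal weekend noise.
#' @return `list(responses = , kpi = )`: a [response_table()] and a KPI
#'   data.frame (`movie`, `premiere`, `wknd1`..`wknd8`).
#' @export
simulate_behavior_kpi <- function(cfg, true_metrics, decay = 0.45,
                                  weekend_noise_sd = 0.15) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(true_metrics) != cfg$n_trailers)
    stop_("need one metric value per trailer (%d != %d)",
          length(true_metrics), cfg$n_trailers)
  with_seed(derive_seed(cfg$seed, "behavior_kpi"), {
    premiere <- cfg$kpi_intercept + cfg$kpi_beta * true_metrics +
      rnorm(cfg$n_trailers, sd = cfg$kpi_noise_sd)
    if (any(premiere < 0)) {
      warning("negative simulated KPI floored at 0")
      premiere <- pmax(premiere, 0)
    }
    kpi <- data.frame(movie = seq_len(cfg$n_trailers), premiere = premiere)
    for (j in 1:8)
      kpi[[paste0("wknd", j)]] <- premiere * decay^j *
        exp(rnorm(cfg$n_trailers, sd = weekend_noise_sd))
    scaled <- (true_metrics - min(true_metrics)) /
      max(max(true_metrics) - min(true_metrics), 1e-12)
    pe <- rnorm(cfg$n_subjects, sd = 1)          # participant random effect
    rows <- list()
    for (p in seq_len(cfg$n_subjects)) for (v in 1:2)
      for (tr in seq_len(cfg$n_trailers)) {
        lik <- round(2 + 6 * scaled[tr] + pe[p] + rnorm(1, sd = 1))
        lik <- min(10L, max(0L, as.integer(lik)))
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = sprintf("p%02d", p), viewing = v,
          trailer_id = tr, liking = lik,
          wtw = runif(1) < plogis(lik - 5),
          wtr = runif(1) < plogis(lik - 6))
      }
    list(responses = response_table(do.call(rbind, rows)), kpi = kpi)
  })
}
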