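# Attentional asynchrony: share of sliding gaze windows whose inter-viewer
# pairwise distances are indistinguishable from a permutation null that
# destroys temporal alignment (window order shuffled independently per
# trace).  A window is "divergent" when at least `frac` of its distances
# fall inside the central `ci_level` interval of that null; the metric is
# the fraction of divergent windows among the classifiable ones.

trace_list <- function(traces, trailer = NULL, viewing = NULL) {
  if (inherits(traces, "gaze_table") || is.data.frame(traces))
    traces <- gaze_traces(traces, trailer = trailer, viewing = viewing)
  n <- vapply(traces, function(tr) nrow(tr$xy), 0L)
  if (length(unique(n)) != 1L)
    stop_("traces on inconsistent grids: lengths %s",
          paste(unique(n), collapse = ", "))
  traces
}

#' Segment gaze traces into sliding windows
#'
#' Windows of `win_ms` duration hop by `hop_ms` (80% overlap at the
#' defaults) over the common trace grid; half-open sample windows, 0-based
#' starts.  A trace set shorter than one window yields zero windows.
#'
#' @param traces list from [gaze_traces()] (or a [gaze_table()]).
#' @param win_ms,hop_ms window length and hop, ms.
#' @param rate gaze sampling rate, samples/s.
#' @return data.frame with `window_index` (0-based), `start_sample`
#'   (0-based), `start_ms`; `floor((n - m)/h) + 1` rows for n samples,
#'   m = window samples, h = hop samples.
#' @export
segment_windows <- function(traces, win_ms = 250, hop_ms = 50, rate = 60) {
  traces <- trace_list(traces)
  n <- nrow(traces[[1L]]$xy)
  m <- as.integer(round(win_ms * rate / 1000))
  h <- as.integer(round(hop_ms * rate / 1000))
  if (m < 1L || h < 1L) stop_("window/hop too short for the sampling rate")
  if (n < m)
    return(data.frame(window_index = integer(), start_sample = integer(),
                      start_ms = numeric()))
  starts <- seq(0L, n - m, by = h)
  data.frame(window_index = seq_along(starts) - 1L, start_sample = starts,
             start_ms = starts * 1000 / rate)
}

win_samples <- function(win_ms, rate) as.integer(round(win_ms * rate / 1000))

# eligible traces for one window: >= min_valid of samples valid
window_members <- function(traces, start_sample, m, min_valid) {
  idx <- start_sample + seq_len(m)
  which(vapply(traces, function(tr) mean(tr$valid[idx]) >= min_valid, TRUE))
}

#' Pairwise inter-viewer gaze distances within one window
#'
#' Euclidean pixel distances between time-matched samples of every
#' unordered pair of distinct traces; a sample contributes only when valid
#' in both traces, and a trace enters the window only when at least
#' `min_valid` of its window samples are valid.
#'
#' @param traces list from [gaze_traces()].
#' @param start_sample 0-based first sample of the window.
#' @param win_ms window length, ms.
#' @param rate gaze sampling rate, samples/s.
#' @param min_valid minimum valid-sample share for a trace to enter.
#' @return numeric vector of distances (length 0 marks the window
#'   unclassifiable: fewer than two usable traces or no co-valid samples).
#' @export
pairwise_gaze_distances <- function(traces, start_sample, win_ms = 250,
                                    rate = 60, min_valid = 0.5) {
  traces <- trace_list(traces)
  m <- win_samples(win_ms, rate)
  mem <- window_members(traces, start_sample, m, min_valid)
  if (length(mem) < 2L) return(numeric())
  idx <- start_sample + seq_len(m)
  out <- vector("list", length(mem) * (length(mem) - 1L) %/% 2L)
  k <- 0L
  for (i in seq_along(mem)[-length(mem)]) for (j in (i + 1L):length(mem)) {
    a <- traces[[mem[i]]]; b <- traces[[mem[j]]]
    ok <- a$valid[idx] & b$valid[idx]
    d <- sqrt(rowSums((a$xy[idx, , drop = FALSE] -
                         b$xy[idx, , drop = FALSE])^2))[ok]
    k <- k + 1L; out[[k]] <- d
  }
  unlist(out, use.names = FALSE)
}

#' Permutation null of pairwise gaze distances
#'
#' For each of `n_draws` permutations the window order of every trace is
#' shuffled independently, destroying temporal alignment across
#' participants and viewings while preserving each trace's within-window
#' structure; pairwise distances are then pooled over draws, pairs and
#' window slots and summarized by the central `ci_level` interval.  When a
#' full pooling would exceed `max_pool` distances, each draw evaluates a
#' random subset of window slots so the pool stays near `max_pool`
#' (Monte-Carlo quantiles either way).  Deterministic given `seed`.
#'
#' @inheritParams pairwise_gaze_distances
#' @param hop_ms window hop, ms.
#' @param n_draws number of permutation draws.
#' @param seed RNG seed for the permutation stream.
#' @param ci_level central interval mass (0.90 gives the 5th/95th
#'   percentiles, linear interpolation).
#' @param max_pool cap on the total number of pooled distances.
#' @return object of class `null_distribution`: `q_lo`, `q_hi`, `n_draws`,
#'   `seed`, `n_pool`, `ci_level`, `degenerate` (`q_lo == q_hi`).
#' @export
estimate_null_distribution <- function(traces, win_ms = 250, hop_ms = 50,
                                       rate = 60, n_draws = 1000, seed = 1,
                                       ci_level = 0.90, min_valid = 0.5,
                                       max_pool = 2e5) {
  traces <- trace_list(traces)
  if (length(traces) < 2L) stop_("need >= 2 traces for a null distribution")
  wins <- segment_windows(traces, win_ms, hop_ms, rate)
  W <- nrow(wins)
  if (W < 1L) stop_("traces too short for a single window")
  m <- win_samples(win_ms, rate)
  P <- length(traces)
  idx <- outer(wins$start_sample, seq_len(m), `+`)    # W x m sample indices
  xs <- lapply(traces, function(tr) matrix(tr$xy[idx, 1L], W))
  ys <- lapply(traces, function(tr) matrix(tr$xy[idx, 2L], W))
  vs <- lapply(traces, function(tr) matrix(tr$valid[idx], W))
  n_pairs <- P * (P - 1L) %/% 2L
  slots_per_draw <- min(W, max(1L, ceiling(max_pool / (n_draws * n_pairs * m))))
  pool <- with_seed(seed, {
    acc <- vector("list", n_draws)
    for (b in seq_len(n_draws)) {
      perms <- lapply(seq_len(P), function(i) sample.int(W))
      slots <- if (slots_per_draw < W) sample.int(W, slots_per_draw)
               else seq_len(W)
      dd <- vector("list", n_pairs)
      k <- 0L
      for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
        ri <- perms[[i]][slots]; rj <- perms[[j]][slots]
        ok <- vs[[i]][ri, , drop = FALSE] & vs[[j]][rj, , drop = FALSE]
        d <- sqrt((xs[[i]][ri, , drop = FALSE] - xs[[j]][rj, , drop = FALSE])^2 +
                  (ys[[i]][ri, , drop = FALSE] - ys[[j]][rj, , drop = FALSE])^2)
        k <- k + 1L; dd[[k]] <- d[ok]
      }
      acc[[b]] <- unlist(dd, use.names = FALSE)
    }
    unlist(acc, use.names = FALSE)
  })
  if (!length(pool)) stop_("no valid sample pairs: cannot form a null")
  alpha <- (1 - ci_level) / 2
  q <- unname(quantile(pool, c(alpha, 1 - alpha), type = 7))
  structure(list(q_lo = q[1L], q_hi = q[2L], n_draws = n_draws, seed = seed,
                 n_pool = length(pool), ci_level = ci_level,
                 degenerate = isTRUE(q[1L] == q[2L])),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %g%% interval [%.2f, %.2f] px (%d draws, pool %d%s)\n",
              100 * x$ci_level, x$q_lo, x$q_hi, x$n_draws, x$n_pool,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Classify one gaze window against the permutation null
#'
#' Under the default `"inside"` rule a window is *divergent* when the share
#' of its distances lying inside `[q_lo, q_hi]` is at least `frac`
#' (boundary counts as divergent): null-like dispersion means gaze was not
#' jointly guided.  The `"outside"` rule inverts the region (share outside
#' the interval >= `frac`).  A degenerate null classifies as non-divergent;
#' an empty distance set is unclassifiable.
#'
#' @param distances numeric vector from [pairwise_gaze_distances()].
#' @param null a [estimate_null_distribution()] result.
#' @param frac divergence threshold on the distance share.
#' @param rule `"inside"` (default) or `"outside"`.
#' @return one of `"divergent"`, `"non_divergent"`, `"unclassifiable"`.
#' @export
classify_window <- function(distances, null, frac = 0.30,
                            rule = c("inside", "outside")) {
  rule <- match.arg(rule)
  stopifnot(inherits(null, "null_distribution"))
  if (!length(distances)) return("unclassifiable")
  if (null$degenerate) return("non_divergent")
  inside <- mean(distances >= null$q_lo & distances <= null$q_hi)
  share <- if (rule == "inside") inside else 1 - inside
  if (share >= frac) "divergent" else "non_divergent"
}

#' Attentional asynchrony of one trailer
#'
#' The fraction of classifiable sliding windows labelled divergent by
#' [classify_window()]; 0 = attention tightly guided throughout, 1 = gaze
#' patterns indistinguishable from temporally misaligned viewing.
#'
#' @param traces list from [gaze_traces()], or a [gaze_table()] (then
#'   `trailer`/`viewing` select the trace set; `viewing = NULL` pools both
#'   viewings, 1 or 2 gives the per-viewing variant).
#' @param trailer,viewing trace selection when `traces` is a table.
#' @inheritParams estimate_null_distribution
#' @inheritParams classify_window
#' @return object of class `attentional_asynchrony`: `score` in \[0, 1\],
#'   per-window `labels` data.frame, and the `null` used.
#' @export
attentional_asynchrony <- function(traces, trailer = NULL, viewing = NULL,
                                   win_ms = 250, hop_ms = 50, rate = 60,
                                   frac = 0.30, ci_level = 0.90,
                                   n_draws = 1000, seed = 1,
                                   min_valid = 0.5, max_pool = 2e5,
                                   rule = c("inside", "outside")) {
  rule <- match.arg(rule)
  traces <- trace_list(traces, trailer = trailer, viewing = viewing)
  if (length(traces) < 2L) stop_("need >= 2 traces")
  wins <- segment_windows(traces, win_ms, hop_ms, rate)
  if (!nrow(wins)) stop_("traces too short for a single window")
  null <- estimate_null_distribution(traces, win_ms, hop_ms, rate, n_draws,
                                     seed, ci_level, min_valid, max_pool)
  labels <- vapply(wins$start_sample, function(s0)
    classify_window(pairwise_gaze_distances(traces, s0, win_ms, rate,
                                            min_valid),
                    null, frac, rule), "")
  classifiable <- labels != "unclassifiable"
  if (!any(classifiable)) stop_("no classifiable window")
  structure(list(score = mean(labels[classifiable] == "divergent"),
                 labels = cbind(wins, label = labels), null = null,
                 n_traces = length(traces)),
            class = "attentional_asynchrony")
}

#' @export
print.attentional_asynchrony <- function(x, ...) {
  tab <- table(x$labels$label)
  cat(sprintf("<attentional_asynchrony> score = %.3f over %d windows (%s)\n",
              x$score, nrow(x$labels),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}
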