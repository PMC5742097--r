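# Stated-preference summaries, box-office KPI, and the leave-one-out
# outlier rule applied before any regression.

#' Behavioral metrics per trailer
#'
#' Pools responses across participants and both viewings: `LM` is the mean
#' liking score, `WTW`/`WTR` the yes-fractions of the willingness-to-watch
#' and willingness-to-refer questions.
#'
#' @param responses a [response_table()] data.frame.
#' @return data.frame with one row per `trailer_id`: `LM`, `WTW`, `WTR`,
#'   `n_responses`.
#' @export
behavioral_metrics <- function(responses) {
  responses <- response_table(responses)
  if (!nrow(responses)) stop_("empty response table")
  sp <- split(responses, responses$trailer_id)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(trailer_id = d$trailer_id[1L], LM = mean(d$liking),
               WTW = mean(d$wtw), WTR = mean(d$wtr), n_responses = nrow(d))))
  rownames(out) <- NULL
  out
}

#' Box-office sales-performance KPI
#'
#' Weekend revenue divided by the production budget, a dimensionless
#' indicator that normalizes for marketing capacity and reach.
#'
#' @param revenue weekend revenue, USD (>= 0); vectorized.
#' @param budget production budget, USD (> 0); vectorized.
#' @return `revenue / budget`.
#' @export
#' @examples
#' compute_kpi(25e6, 50e6)  # 0.5
compute_kpi <- function(revenue, budget) {
  if (any(budget <= 0)) stop_("budget must be > 0")
  if (any(revenue < 0)) stop_("revenue must be >= 0")
  revenue / budget
}

#' Leave-one-out KPI outlier rule
#'
#' Movie i is excluded when its KPI lies at least `z_thresh` sample
#' standard deviations above the mean of the *other* movies:
#' `(kpi_i - mean(kpi_-i)) / sd(kpi_-i) >= z_thresh`.  If the others have
#' zero spread, any value different from their common mean is excluded.
#' The rule is scale-invariant.
#'
#' @param kpis numeric vector of premiere KPIs (length >= 3).
#' @param z_thresh exclusion threshold in leave-one-out z units.
#' @return logical exclusion mask with attribute `"z"` holding the
#'   leave-one-out z-scores.
#' @export
#' @examples
#' flag_outlier(c(0, 0, 0, 0, 10))
flag_outlier <- function(kpis, z_thresh = 4) {
  if (length(kpis) < 3L) stop_("need >= 3 KPI values, got %d", length(kpis))
  z <- vapply(seq_along(kpis), function(i) {
    s <- sd(kpis[-i])
    if (s == 0) {
      if (kpis[i] == mean(kpis[-i])) 0 else Inf
    } else (kpis[i] - mean(kpis[-i])) / s
  }, 0)
  structure(z >= z_thresh, z = z)
}
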