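# Regression harness: univariate/bivariate OLS with the R^2 / adjusted-R^2
# / F identities, case-resampling bootstrap SE on R^2, Benjamini-Hochberg
# correction, correlation screening, and the model x weekend sweep.

#' F statistic implied by an R-squared
#'
#' `F = (r2/k) / ((1 - r2)/(n - k - 1))` for an OLS fit with intercept.
#'
#' @param r2 coefficient of determination.
#' @param n observations; @param k predictors.
#' @return the F statistic on (k, n-k-1) degrees of freedom.
#' @export
#' @examples
#' r2_to_f(0.49, 14, 1)  # 11.53
r2_to_f <- function(r2, n, k) (r2 / k) / ((1 - r2) / (n - k - 1))

#' Adjusted R-squared
#'
#' `1 - (1 - r2)(n - 1)/(n - k - 1)`.
#'
#' @inheritParams r2_to_f
#' @return adjusted R-squared.
#' @export
#' @examples
#' adjusted_r2(0.7370, 14, 2)  # 0.69
adjusted_r2 <- function(r2, n, k) 1 - (1 - r2) * (n - 1) / (n - k - 1)

as_pred_matrix <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

#' Ordinary least squares with intercept
#'
#' @param X predictor vector or matrix (columns = predictors, non-constant).
#' @param y response vector.
#' @return object of class `regression_result`: `r2`, `r2_adj`, `F`,
#'   `df = c(k, n-k-1)`, `p`, `coefficients` (with intercept), `n`,
#'   `residuals`.  The identities `r2_adj = 1-(1-r2)(n-1)/(n-k-1)` and
#'   `F = (r2/k)/((1-r2)/(n-k-1))` hold to numerical precision.
#' @export
fit_linear_model <- function(X, y) {
  X <- as_pred_matrix(X)
  y <- as.numeric(y)
  n <- length(y); k <- ncol(X)
  if (nrow(X) != n) stop_("X has %d rows but y has %d values", nrow(X), n)
  if (anyNA(X) || anyNA(y)) stop_("missing values in X or y")
  if (n <= k + 1L) stop_("n = %d too small for %d predictor(s)", n, k)
  if (any(apply(X, 2L, sd) == 0)) stop_("constant predictor column")
  if (sd(y) == 0) stop_("zero-variance response")
  fit <- lm.fit(cbind(`(Intercept)` = 1, X), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  Fv <- r2_to_f(r2, n, k)
  structure(list(r2 = r2, r2_adj = adjusted_r2(r2, n, k), F = Fv,
                 df = c(k, n - k - 1L),
                 p = pf(Fv, k, n - k - 1L, lower.tail = FALSE),
                 coefficients = fit$coefficients, n = n,
                 residuals = fit$residuals),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> R2 = %.3f (adj %.3f), F(%d,%d) = %.2f, p = %.3g, n = %d\n",
              x$r2, x$r2_adj, x$df[1L], x$df[2L], x$F, x$p, x$n))
  invisible(x)
}

boot_r2_one <- function(Xi, y, n) {
  fit <- lm.fit(Xi, y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Bootstrap standard error of R-squared
#'
#' Case resampling over rows (movies): refit on each resample and return
#' the sample SD of the `B` R-squared values.  Resamples with a constant
#' predictor column or zero response variance are redrawn (reported via a
#' message).  Deterministic given `seed`.
#'
#' @inheritParams fit_linear_model
#' @param B number of bootstrap resamples (>= 2).
#' @param seed RNG seed.
#' @return the bootstrap SE (single number).
#' @export
bootstrap_r2_se <- function(X, y, B = 2000, seed = 1) {
  if (B < 2L) stop_("B must be >= 2")
  X <- as_pred_matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 4L) stop_("need n >= 4 for a meaningful bootstrap")
  fit_linear_model(X, y)                         # validate the full fit
  r2s <- numeric(B)
  redraws <- 0L
  with_seed(seed, for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      if (all(apply(Xb, 2L, sd) > 0) && sd(yb) > 0) break
      redraws <- redraws + 1L
      if (redraws > 100L * B) stop_("too many degenerate bootstrap resamples")
    }
    r2s[b] <- boot_r2_one(cbind(1, Xb), yb, n)
  })
  if (redraws) message(sprintf("redrew %d degenerate resample(s)", redraws))
  sd(r2s)
}

#' Percentile bootstrap confidence interval for an OLS slope
#'
#' Case-resampling percentile interval for the slope of `y ~ x`, used by
#' the coverage checks on the synthetic KPI generator.
#'
#' @param x,y numeric vectors.
#' @param B resamples; @param level interval mass; @param seed RNG seed.
#' @return `c(lo, hi)`.
#' @export
bootstrap_slope_ci <- function(x, y, B = 1000, level = 0.95, seed = 1) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L, B >= 2L)
  slopes <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    vapply(seq_len(B), function(b) {
      xi <- x[idx[, b]]; yi <- y[idx[, b]]
      v <- sum((xi - mean(xi))^2)
      if (v == 0) NA_real_ else sum((xi - mean(xi)) * (yi - mean(yi))) / v
    }, 0)
  })
  slopes <- slopes[is.finite(slopes)]
  alpha <- (1 - level) / 2
  unname(quantile(slopes, c(alpha, 1 - alpha), type = 7))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate control; a light validating wrapper around
#' [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted (monotone, <= 1) q-values in input order.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
fdr_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop_("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Pearson correlation screen of metric columns against a KPI
#'
#' @param study data.frame (one row per trailer).
#' @param metric_cols character vector of metric column names.
#' @param kpi_col KPI column name.
#' @return data.frame `metric`, `r`, `p`; constant columns are flagged with
#'   `NA` (undefined correlation), never reported as 0.
#' @export
correlation_screen <- function(study, metric_cols, kpi_col) {
  y <- study[[kpi_col]]
  if (is.null(y)) stop_("no column `%s`", kpi_col)
  out <- lapply(metric_cols, function(mc) {
    x <- study[[mc]]
    if (is.null(x)) stop_("no column `%s`", mc)
    ok <- complete.cases(x, y)
    if (sum(ok) < 3L) stop_("fewer than 3 paired observations for `%s`", mc)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      warning(sprintf("constant column in pair (%s, %s): r undefined",
                      mc, kpi_col))
      return(data.frame(metric = mc, r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(x[ok], y[ok])
    data.frame(metric = mc, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, out)
}

default_models <- function(combined_band = c(52, 70)) {
  cg <- function(b) sprintf("cogn_%d_%d", b[1L], b[2L])
  list("Att-Asy-1" = "asy_v1", "Att-Asy-2" = "asy_v2",
       "Cogn-40-48" = "cogn_40_48", "Cogn-52-60" = "cogn_52_60",
       "Cogn-60-70" = "cogn_60_70", "Cogn-52-70" = "cogn_52_70",
       "Att+Cogn" = c("asy_v1", cg(combined_band)))
}

#' Model-by-weekend regression sweep
#'
#' Fits every model (predictor set) against the premiere KPI and each of
#' the eight weekend KPIs; Benjamini-Hochberg correction is applied across
#' the nine outcomes within each model row.  Rows flagged in the `outlier`
#' column are removed before fitting.
#'
#' @param study data.frame with one row per trailer: metric columns (the
#'   default models expect `asy_v1`, `asy_v2`, `cogn_40_48`, `cogn_52_60`,
#'   `cogn_60_70`, `cogn_52_70`), KPI columns `premiere`, `wknd1`..`wknd8`,
#'   and optionally a logical `outlier` column.
#' @param models named list of predictor-column sets; the default is the
#'   seven-model configuration (two per-viewing asynchrony models, four
#'   gamma-band congruency models, and the combined
#'   asynchrony-plus-congruency model).
#' @param B bootstrap resamples for the SE on R-squared (`0` skips it).
#' @param seed RNG seed for the bootstrap.
#' @param combined_band gamma band used by the combined model.
#' @return data.frame of class `sweep_table`: one row per model x outcome
#'   with `r2`, `r2_adj`, `F`, `p`, `p_fdr`, `se_r2`, `n`.
#' @export
weekend_sweep <- function(study, models = NULL, B = 2000, seed = 1,
                          combined_band = c(52, 70)) {
  models <- models %||% default_models(combined_band)
  outcomes <- c("premiere", paste0("wknd", 1:8))
  miss <- setdiff(outcomes, names(study))
  if (length(miss)) stop_("study table lacks KPI column(s): %s",
                          paste(miss, collapse = ", "))
  if ("outlier" %in% names(study)) study <- study[!study$outlier, , drop = FALSE]
  rows <- list()
  for (mi in seq_along(models)) {
    cols <- models[[mi]]
    miss <- setdiff(cols, names(study))
    if (length(miss)) stop_("model `%s` needs missing metric column(s): %s",
                            names(models)[mi], paste(miss, collapse = ", "))
    X <- as.matrix(study[cols])
    fits <- lapply(outcomes, function(oc) fit_linear_model(X, study[[oc]]))
    ps <- vapply(fits, `[[`, 0, "p")
    qs <- fdr_adjust(ps)
    ses <- if (B >= 2L)
      vapply(seq_along(outcomes), function(i)
        bootstrap_r2_se(X, study[[outcomes[i]]], B = B,
                        seed = derive_seed(seed, paste0(names(models)[mi],
                                                        outcomes[i]))), 0)
      else rep(NA_real_, length(outcomes))
    rows[[mi]] <- data.frame(
      model = names(models)[mi], outcome = outcomes,
      r2 = vapply(fits, `[[`, 0, "r2"),
      r2_adj = vapply(fits, `[[`, 0, "r2_adj"),
      F = vapply(fits, `[[`, 0, "F"),
      p = ps, p_fdr = qs, se_r2 = ses,
      n = vapply(fits, `[[`, 0L, "n"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_table", "data.frame")
  out
}
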