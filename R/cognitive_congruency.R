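# Cognitive congruency: the largest generalized eigenvalue of the
# cross-viewing band-power covariance against the sum of within-viewing
# covariances.  lambda = max_w  w'R12 w / w'(R11+R22)w, solved as a
# symmetric-definite generalized eigenvalue problem via Cholesky reduction.

#' Subject-aggregated viewing covariances of band power
#'
#' Given, for each subject, the band-power matrices of the first and second
#' viewing of one trailer (D channels x T power samples), computes
#' `R11 = (1/(S T)) sum_s X1s X1s'`, `R22` analogously, and the symmetrized
#' cross-viewing covariance `R12`.  Each channel's power series is centered
#' within its epoch before the products, so common power offsets do not
#' inflate the metric.
#'
#' @param pairs list with one element per subject: `list(X1 = , X2 = )`
#'   where each is a [band_power()] or a bare D x T matrix.  A subject
#'   missing one viewing (`NULL`) is dropped with a warning.
#' @param band,trailer_id carried into the result (taken from the first
#'   [band_power()] if present).
#' @return object of class `covariance_set` with `R11`, `R22`, `R12`
#'   (symmetrized), `n_subjects`, `T`, `D`, `band`, `trailer_id`.
#' @export
viewing_covariances <- function(pairs, band = NULL, trailer_id = NULL) {
  get_x <- function(p) if (inherits(p, "band_power")) p$X else
    if (is.null(p)) NULL else as.matrix(p)
  keep <- vapply(pairs, function(p)
    !is.null(get_x(p$X1)) && !is.null(get_x(p$X2)), TRUE)
  if (any(!keep))
    warning(sprintf("excluding %d subject(s) missing a viewing", sum(!keep)))
  pairs <- pairs[keep]
  if (!length(pairs)) stop_("no subject contributes both viewings")
  X1s <- lapply(pairs, function(p) get_x(p$X1))
  X2s <- lapply(pairs, function(p) get_x(p$X2))
  D <- nrow(X1s[[1L]]); T <- ncol(X1s[[1L]])
  for (s in seq_along(pairs)) {
    dims <- c(dim(X1s[[s]]), dim(X2s[[s]]))
    if (any(dims != c(D, T, D, T)))
      stop_("subject %d: viewing dimensions (%s) differ from %d x %d",
            s, paste(dims, collapse = ", "), D, T)
  }
  R11 <- R22 <- R12 <- matrix(0, D, D)
  for (s in seq_along(pairs)) {
    x1 <- X1s[[s]] - rowMeans(X1s[[s]])
    x2 <- X2s[[s]] - rowMeans(X2s[[s]])
    R11 <- R11 + tcrossprod(x1)
    R22 <- R22 + tcrossprod(x2)
    R12 <- R12 + tcrossprod(x1, x2)
  }
  n <- length(pairs) * T
  R12 <- (R12 + t(R12)) / (2 * n)
  if (!all(is.finite(R11), is.finite(R22), is.finite(R12)))
    stop_("non-finite covariance entries (NaN/Inf in the band power?)")
  bp1 <- pairs[[1L]]$X1
  structure(list(R11 = R11 / n, R22 = R22 / n, R12 = R12,
                 n_subjects = length(pairs), T = T, D = D,
                 band = band %||% (if (inherits(bp1, "band_power")) bp1$band),
                 trailer_id = trailer_id %||%
                   (if (inherits(bp1, "band_power")) bp1$trailer_id else NA)),
            class = "covariance_set")
}

#' @export
print.covariance_set <- function(x, ...) {
  cat(sprintf("<covariance_set> D=%d, %d subject(s) x %d samples, band %s\n",
              x$D, x$n_subjects, x$T,
              if (is.null(x$band)) "?" else paste(x$band, collapse = "-")))
  invisible(x)
}

#' Solve the congruency generalized eigenvalue problem
#'
#' Finds the spatial filter `w` maximizing `w'R12 w / w'(R11+R22+gI)w`,
#' i.e. the largest eigenvalue of `lambda (R11+R22+gI) w = R12 w`.  For PSD
#' within-viewing covariances and a cross-covariance built from the same
#' data, `|lambda| <= 1/2`; identical viewings attain exactly 1/2 (at
#' `shrinkage = 0`).
#'
#' @param cov a [viewing_covariances()] result.
#' @param shrinkage ridge `g` added to the denominator diagonal; `NULL`
#'   (default) uses `1e-6 * trace(R11+R22)/D`, `0` disables it.
#' @return object of class `congruency_result`: `lam` (the metric), `w`
#'   (spatial filter, unit norm), `a` (forward-model topography),
#'   `spectrum` (all generalized eigenvalues, decreasing), `shrinkage`,
#'   `band`, `trailer_id`.
#' @export
solve_congruency <- function(cov, shrinkage = NULL) {
  stopifnot(inherits(cov, "covariance_set"))
  A <- cov$R11 + cov$R22
  if (!all(is.finite(A), is.finite(cov$R12)))
    stop_("non-finite covariances")
  g <- shrinkage %||% (1e-6 * sum(diag(A)) / cov$D)
  if (g < 0) stop_("shrinkage must be >= 0")
  A <- A + diag(g, cov$D)
  L <- tryCatch(t(chol(A)), error = function(e)
    stop_("R11 + R22 (+ shrinkage) is not positive definite; %s%s",
          conditionMessage(e), " -- try a larger `shrinkage`"))
  B <- (cov$R12 + t(cov$R12)) / 2
  M <- forwardsolve(L, t(forwardsolve(L, B)))
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  w <- backsolve(t(L), eg$vectors[, 1L])
  w <- w / sqrt(sum(w^2))
  res <- structure(list(lam = eg$values[1L], w = w, a = NULL,
                        spectrum = eg$values, shrinkage = g,
                        band = cov$band, trailer_id = cov$trailer_id),
                   class = "congruency_result")
  res$a <- forward_model(res, cov)
  res
}

#' @export
print.congruency_result <- function(x, ...) {
  cat(sprintf("<congruency_result> lambda = %.4f (band %s, trailer %s)\n",
              x$lam,
              if (is.null(x$band)) "?" else paste(x$band, collapse = "-"),
              x$trailer_id))
  invisible(x)
}

#' Forward-model topography of a spatial filter
#'
#' Maps the backward projection `w` to the scalp pattern it extracts:
#' `a = Rbar w / (w' Rbar w)` with `Rbar = (R11 + R22)/2`, after
#' normalizing `w` to unit length, so any rescaling of the filter leaves
#' the topography unchanged.
#'
#' @param result a [solve_congruency()] result (or any list with `w`).
#' @param cov the [viewing_covariances()] the filter was computed from.
#' @return numeric topography vector of length D.
#' @export
forward_model <- function(result, cov) {
  w <- result$w
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop_("w' Rbar w = 0: filter carries no variance")
  w <- w / nw
  Rbar <- (cov$R11 + cov$R22) / 2
  den <- drop(crossprod(w, Rbar %*% w))
  if (den == 0) stop_("w' Rbar w = 0: filter carries no variance")
  drop(Rbar %*% w) / den
}

#' Cognitive congruency of one trailer and band
#'
#' Convenience wrapper: [viewing_covariances()] then [solve_congruency()].
#'
#' @inheritParams viewing_covariances
#' @inheritParams solve_congruency
#' @return a `congruency_result`; `$lam` is the metric.
#' @export
#' @examples
#' X <- matrix(rexp(4 * 100), 4)
#' cognitive_congruency(list(list(X1 = X, X2 = X)), shrinkage = 0)$lam  # 0.5
cognitive_congruency <- function(pairs, shrinkage = NULL, band = NULL,
                                 trailer_id = NULL) {
  solve_congruency(viewing_covariances(pairs, band = band,
                                       trailer_id = trailer_id),
                   shrinkage = shrinkage)
}
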